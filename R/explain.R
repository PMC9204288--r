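#' Grad-CAM attention map
#'
#' Gradient-weighted class activation mapping over a convolutional feature
#' map: each channel's weight is the spatial mean of its gradient
#' (`alpha_c = mean(gradients[c, , ])`), the raw map is the ReLU of the
#' weighted channel sum, and the map is normalized by its maximum so
#' values lie in \[0, 1\] (an identically zero map stays zero). Optionally
#' bilinearly upsampled to the source image size.
#'
#' @param activations C x h x w array of channel activations.
#' @param gradients C x h x w array of the target-class score gradients
#'   with respect to `activations`.
#' @param target_size Optional `c(H, W)` to upsample the map to.
#' @param id Optional source-image identifier carried as an attribute.
#' @return Object of class `cam_heatmap`: h x w (or H x W) matrix in
#'   \[0, 1\].
#' @export
grad_cam <- function(activations, gradients, target_size = NULL, id = NULL) {
  if (!is.array(activations) || length(dim(activations)) != 3) {
    stop("activations must be a C x h x w array")
  }
  if (!identical(dim(activations), dim(gradients))) {
    stop("activations and gradients must have identical shape")
  }
  C <- dim(activations)[1]
  alpha <- apply(gradients, 1, mean)
  raw <- matrix(0, dim(activations)[2], dim(activations)[3])
  for (c_ in seq_len(C)) {
    raw <- raw + alpha[c_] * activations[c_, , ]
  }
  raw <- pmax(raw, 0)
  mx <- max(raw)
  heat <- if (mx > 0) raw / mx else raw
  if (!is.null(target_size)) {
    heat <- resize_bilinear(heat, target_size[1], target_size[2])
    heat <- pmin(pmax(heat, 0), 1)
  }
  attr(heat, "id") <- id
  class(heat) <- c("cam_heatmap", class(heat))
  heat
}

#' Grad-CAM through the built-in extractor
#'
#' Taps the last convolutional feature map of the toy extractor (the
#' pooled 8 x 15 x 15 stem output), backpropagates the pre-softmax score
#' of the target class (default: the predicted class) through the dense
#' head, and forms the [grad_cam()] map upsampled to the input image size.
#'
#' @param extractor A (typically fine-tuned) [builtin_toy_extractor()].
#' @param img Intensity matrix in \[0, 1\].
#' @param class Target class 0/1; `NULL` (default) uses the predicted one.
#' @param id Optional image identifier.
#' @return A `cam_heatmap` the size of `img`.
#' @export
extractor_grad_cam <- function(extractor, img, class = NULL, id = NULL) {
  stopifnot(inherits(extractor, "toy_extractor"))
  maps <- toy_conv_maps(extractor, img)
  z <- as.vector(maps)
  fw <- toy_forward(extractor, z)
  if (is.null(class)) class <- which.max(fw$logits) - 1L
  # backward from the pre-softmax score of `class` to the pooled stem maps
  dlogits <- c(0, 0)
  dlogits[class + 1] <- 1
  dg <- as.vector(extractor$W2 %*% dlogits)
  drhat <- dg * extractor$gamma
  dr <- drhat / sqrt(extractor$run_var + 1e-5)
  df <- dr * (fw$f > 0)
  dz <- as.vector(extractor$W1 %*% df)
  grad_maps <- array(dz, dim(maps))
  grad_cam(maps, grad_maps, target_size = dim(img), id = id)
}

#' Write a heatmap as TSV / PNG overlay
#'
#' The TSV stores the raw \[0, 1\] matrix at full precision. The overlay
#' renders the grayscale image with the heatmap blended into the red
#' channel (blue for low attention) — presentation only.
#'
#' @param heat A `cam_heatmap`.
#' @param path Output file path.
#' @param img Background intensity matrix for the overlay (same size).
#' @param alpha Overlay opacity in \[0, 1\] (default 0.5).
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(heat, path) {
  utils::write.table(unclass(heat), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_tsv
#' @export
write_cam_overlay_png <- function(heat, img, path, alpha = 0.5) {
  if (!all(dim(heat) == dim(img))) stop("heatmap and image sizes differ")
  h <- unclass(heat)
  rgb <- array(0, c(nrow(img), ncol(img), 3))
  rgb[, , 1] <- (1 - alpha) * img + alpha * h
  rgb[, , 2] <- (1 - alpha) * img
  rgb[, , 3] <- (1 - alpha) * img + alpha * (1 - h)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
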