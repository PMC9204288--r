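#' Synthetic two-class image specification
#'
#' Describes the generator for brain-MRI-like grayscale slices: a centered
#' mid-intensity ellipse ("tissue") on a dark background with additive
#' noise; positive (unhealthy) images additionally contain 1-3 bright
#' circular lesion blobs inside the ellipse. Defaults mirror the empirical
#' setting the pipeline targets: 256 x 256 images and a heavy ~9:1
#' positive:negative imbalance (177 vs 20).
#'
#' Noise is Gaussian clipped at ±4.5 standard deviations so that, at the
#' default contrast, lesion pixels (and only lesion pixels) exceed the
#' tissue mean by more than 5 noise standard deviations — a checkable
#' separability guarantee.
#'
#' @param n_pos,n_neg Positive / negative image counts (defaults 177 / 20).
#' @param image_size Side length in pixels, >= 32 (default 256).
#' @param lesion_radius_range Min/max lesion radius in pixels (default 8-20).
#' @param lesion_contrast Intensity added inside a lesion (default 0.45);
#'   must exceed the noise sd (the separability knob).
#' @param background_noise_sd Noise standard deviation (default 0.04).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 177, n_neg = 20, image_size = 256,
                           lesion_radius_range = c(8, 20),
                           lesion_contrast = 0.45,
                           background_noise_sd = 0.04, seed = 1L) {
  if (n_pos < 0 || n_neg < 0) stop("counts must be >= 0")
  if (image_size < 32) stop("image_size must be >= 32")
  if (length(lesion_radius_range) != 2 ||
      lesion_radius_range[1] > lesion_radius_range[2] ||
      lesion_radius_range[1] < 1) {
    stop("lesion_radius_range must be an increasing pair of radii >= 1")
  }
  if (lesion_contrast <= background_noise_sd) {
    stop("lesion_contrast must exceed background_noise_sd")
  }
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               image_size = as.integer(image_size),
               lesion_radius_range = lesion_radius_range,
               lesion_contrast = lesion_contrast,
               background_noise_sd = background_noise_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# internal: logical ellipse mask, semi-axes as fractions of the side
ellipse_mask <- function(S, fx = 0.33, fy = 0.42, shrink = 1) {
  cx <- (S + 1) / 2
  a <- fx * S * shrink
  b <- fy * S * shrink
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  ((x - cx) / a)^2 + ((y - cx) / b)^2 <= 1
}

#' Generate a synthetic labeled image set
#'
#' Deterministic per seed; bit-identical images for identical specs. The
#' returned set carries the ground-truth lesion masks of the positive
#' images (`$masks`), enabling localization checks of attention maps.
#'
#' @param spec A [synthetic_spec()]; needs `n_pos + n_neg >= 2` and both
#'   classes present for pipeline use.
#' @return A [labeled_image_set()] with negatives first, then positives.
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_pos + spec$n_neg < 2) stop("need at least two images")
  S <- spec$image_size
  tissue <- ellipse_mask(S)
  inner <- ellipse_mask(S, shrink = 0.7)
  inner_idx <- which(inner, arr.ind = TRUE)
  base <- matrix(0.05, S, S)
  base[tissue] <- 0.45
  clip_z <- 4.5
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(0L, spec$n_neg), rep(1L, spec$n_pos))
  images <- vector("list", n)
  masks <- vector("list", n)
  withr::with_seed(spec$seed, {
    for (i in seq_len(n)) {
      noise <- matrix(stats::rnorm(S * S), S, S)
      noise <- pmin(pmax(noise, -clip_z), clip_z) * spec$background_noise_sd
      img <- base + noise
      if (labels[i] == 1) {
        n_les <- sample(1:3, 1)
        mask <- matrix(FALSE, S, S)
        for (l in seq_len(n_les)) {
          r <- stats::runif(1, spec$lesion_radius_range[1],
                            spec$lesion_radius_range[2])
          ctr <- inner_idx[sample(nrow(inner_idx), 1), ]
          xg <- matrix(seq_len(S), S, S, byrow = TRUE)
          yg <- matrix(seq_len(S), S, S)
          disk <- (xg - ctr[2])^2 + (yg - ctr[1])^2 <= r^2
          disk <- disk & tissue
          img[disk] <- img[disk] + spec$lesion_contrast
          mask <- mask | disk
        }
        masks[[i]] <- mask
      }
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
  })
  ids <- sprintf("%s_%03d", ifelse(labels == 1, "pos", "neg"), seq_len(n))
  labeled_image_set(images, labels, ids, masks = masks)
}

#' Generate a synthetic two-cluster feature table
#'
#' Two unit-covariance Gaussian clusters in `dim` dimensions whose means
#' are `class_separation * sqrt(dim)` apart (offset `class_separation / 2`
#' per coordinate on either side of the origin), with one-hot targets.
#' `class_separation = 0` yields pure noise; around 6 the classes are
#' essentially perfectly separable.
#'
#' @param n_pos,n_neg Samples per class, >= 1.
#' @param dim Feature dimension, >= 1.
#' @param class_separation Mean distance in units of `sqrt(dim)`.
#' @param seed Integer seed.
#' @return list with `X` ((n_pos+n_neg) x dim matrix), `Y` (one-hot
#'   targets, columns "0","1"), `labels` (0/1 vector, negatives first).
#' @export
generate_feature_table <- function(n_pos, n_neg, dim, class_separation,
                                   seed = 1L) {
  if (n_pos < 1 || n_neg < 1) stop("both class counts must be >= 1")
  if (dim < 1) stop("dim must be >= 1")
  if (class_separation < 0) stop("class_separation must be >= 0")
  n <- n_pos + n_neg
  labels <- c(rep(0L, n_neg), rep(1L, n_pos))
  X <- withr::with_seed(as.integer(seed), {
    M <- matrix(stats::rnorm(n * dim), n, dim)
    off <- class_separation / 2
    M + outer(ifelse(labels == 1, off, -off), rep(1, dim))
  })
  colnames(X) <- paste0("f", seq_len(dim))
  list(X = X, Y = one_hot(labels, c(0, 1)), labels = labels)
}
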