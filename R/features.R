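#' Fine-tuning configuration
#'
#' Hyper-parameters of the backbone fine-tuning stage and the downstream
#' randomized head. Defaults are the published operating point: mini-batch
#' 10, 4 epochs, learning rate 1e-4, 400 hidden nodes.
#'
#' @param minibatch_size Samples per gradient step (default 10).
#' @param max_epoch Training epochs (default 4, kept small against
#'   overfitting on small datasets).
#' @param learning_rate SGD step size (default 1e-4).
#' @param hidden_nodes_V Hidden nodes of the randomized head (default 400).
#' @param backbone_name Backbone identifier (default `"densenet201"`;
#'   `"builtin-toy"` selects the dependency-free built-in extractor).
#' @param seed Integer seed.
#' @return Object of class `fine_tune_config`.
#' @export
fine_tune_config <- function(minibatch_size = 10, max_epoch = 4,
                             learning_rate = 1e-4, hidden_nodes_V = 400,
                             backbone_name = "densenet201", seed = 1L) {
  num <- c(minibatch_size = minibatch_size, max_epoch = max_epoch,
           learning_rate = learning_rate, hidden_nodes_V = hidden_nodes_V)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all numeric fine-tuning parameters must be positive")
  }
  cfg <- list(minibatch_size = as.integer(minibatch_size),
              max_epoch = as.integer(max_epoch),
              learning_rate = learning_rate,
              hidden_nodes_V = as.integer(hidden_nodes_V),
              backbone_name = backbone_name,
              seed = as.integer(seed))
  class(cfg) <- "fine_tune_config"
  cfg
}

#' Labeled image set
#'
#' Container for a two-class grayscale image collection: a list of H x W
#' intensity matrices in \[0, 1\], binary labels (1 = positive/unhealthy,
#' 0 = negative/healthy) and unique sample ids.
#'
#' @param images List of numeric matrices with values in \[0, 1\].
#' @param labels Integer/numeric vector of 0/1 labels, one per image.
#' @param ids Unique character ids (default `img_001`, ...).
#' @param masks Optional list of logical ground-truth lesion masks (used by
#'   the synthetic generator; `NULL` entries for negatives).
#' @return Object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, ids = NULL, masks = NULL) {
  if (!is.list(images) || length(images) < 1) stop("images must be a non-empty list")
  if (length(labels) != length(images)) stop("images and labels lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  ok <- vapply(images, function(im) {
    is.matrix(im) && is.numeric(im) && all(is.finite(im)) &&
      min(im) >= 0 && max(im) <= 1
  }, TRUE)
  if (!all(ok)) stop("every image must be a finite numeric matrix in [0, 1]")
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  if (anyDuplicated(ids)) stop("ids must be unique")
  obj <- list(images = images, labels = as.integer(labels),
              ids = as.character(ids), masks = masks)
  class(obj) <- "labeled_image_set"
  obj
}

#' @export
print.labeled_image_set <- function(x, ...) {
  dims <- dim(x$images[[1]])
  cat(sprintf("Labeled image set: %d images (%d positive / %d negative), %dx%d\n",
              length(x$images), sum(x$labels == 1), sum(x$labels == 0),
              dims[1], dims[2]))
  invisible(x)
}

#' Subset a labeled image set
#'
#' @param data A [labeled_image_set()].
#' @param idx Index vector.
#' @return The subset as a `labeled_image_set`.
#' @export
subset_images <- function(data, idx) {
  labeled_image_set(data$images[idx], data$labels[idx], data$ids[idx],
                    masks = if (is.null(data$masks)) NULL else data$masks[idx])
}

#' Modified classifier head specification
#'
#' The ordered layer list appended to a pretrained backbone after its
#' original softmax and classification layers are removed: a 128-unit fully
#' connected layer (the designated feature tap), ReLU, batch normalization,
#' a 2-unit fully connected layer, softmax, and the classification layer.
#'
#' @param num_features_in Width of the backbone's penultimate output, >= 1.
#' @return Object of class `head_spec`: list of 6 layer descriptors; the
#'   attribute `feature_tap` gives the index of the layer whose output is
#'   the feature embedding (the first, FC128).
#' @export
build_modified_head <- function(num_features_in) {
  if (length(num_features_in) != 1 || !is.finite(num_features_in) ||
      num_features_in < 1) {
    stop("num_features_in must be a positive integer")
  }
  spec <- list(
    list(type = "fc", inputs = as.integer(num_features_in), units = 128L),
    list(type = "relu"),
    list(type = "batchnorm", units = 128L),
    list(type = "fc", inputs = 128L, units = 2L),
    list(type = "softmax"),
    list(type = "classification")
  )
  attr(spec, "feature_tap") <- 1L
  class(spec) <- "head_spec"
  spec
}

#' @export
print.head_spec <- function(x, ...) {
  for (i in seq_along(x)) {
    l <- x[[i]]
    tap <- if (i == attr(x, "feature_tap")) "  <- feature tap" else ""
    cat(sprintf("%d: %s%s%s\n", i, l$type,
                if (!is.null(l$units)) sprintf(" (%d)", l$units) else "", tap))
  }
  invisible(x)
}

#' Preprocess an image for the built-in extractor
#'
#' Clamp intensities to \[0, 1\] and bilinearly resize (align-corners) to
#' the extractor's square input size. Idempotent: applying it twice equals
#' applying it once.
#'
#' @param img Numeric intensity matrix.
#' @param size Target side length (default 64, the toy extractor's input).
#' @return `size x size` matrix in \[0, 1\].
#' @export
preprocess_image <- function(img, size = 64L) {
  img <- pmin(pmax(img, 0), 1)
  if (nrow(img) == size && ncol(img) == size) return(img)
  resize_bilinear(img, size, size)
}

#' Built-in toy feature extractor
#'
#' A small, dependency-free convolution-pool-projection network standing in
#' for a pretrained deep backbone so the whole pipeline runs anywhere:
#' 64 x 64 input, 8 frozen random 5 x 5 convolution filters + ReLU,
#' 4 x 4 average pooling (the Grad-CAM tap, 8 x 15 x 15), then the
#' modified head of [build_modified_head()]: FC128 (the feature tap), ReLU,
#' batch norm, FC2, softmax. The convolutional stem is frozen random; the
#' dense layers are trainable by [fine_tune()].
#'
#' @param seed Integer seed for the frozen random weights.
#' @return Object of class `c("toy_extractor", "feature_extractor")`.
#' @export
builtin_toy_extractor <- function(seed = 1L) {
  C <- 8L; ksz <- 5L; input <- 64L; pool <- 4L
  conv_side <- input - ksz + 1L          # 60
  map_side <- conv_side %/% pool         # 15
  n_flat <- C * map_side * map_side      # 1800
  pars <- withr::with_seed(as.integer(seed), {
    list(
      filters = array(stats::rnorm(ksz * ksz * C, sd = 0.3), c(ksz, ksz, C)),
      W1 = matrix(stats::rnorm(n_flat * 128, sd = 1 / sqrt(n_flat)), n_flat, 128),
      b1 = numeric(128),
      gamma = rep(1, 128), beta = numeric(128),
      run_mean = numeric(128), run_var = rep(1, 128),
      W2 = matrix(stats::rnorm(128 * 2, sd = 1 / sqrt(128)), 128, 2),
      b2 = numeric(2)
    )
  })
  ex <- c(pars, list(
    C = C, ksz = ksz, input_size = input, pool = pool,
    map_side = map_side, n_flat = n_flat, embed_dim = 128L,
    seed = as.integer(seed),
    metadata = list(backbone = "builtin-toy", input_size = input,
                    provenance = "random frozen stem, untrained head")
  ))
  class(ex) <- c("toy_extractor", "feature_extractor")
  ex
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("Feature extractor [%s]: %dx%d input -> %d-d embedding\n",
              x$metadata$backbone, x$input_size, x$input_size, x$embed_dim))
  invisible(x)
}

# internal: valid convolution + ReLU + average pooling -> C x s x s array
toy_conv_maps <- function(ex, img) {
  img <- preprocess_image(img, ex$input_size)
  side <- ex$input_size - ex$ksz + 1L
  maps <- array(0, c(ex$C, ex$map_side, ex$map_side))
  pool_idx <- (seq_len(ex$map_side) - 1L) * ex$pool
  for (c_ in seq_len(ex$C)) {
    Z <- matrix(0, side, side)
    f <- ex$filters[, , c_]
    for (dy in seq_len(ex$ksz)) {
      for (dx in seq_len(ex$ksz)) {
        Z <- Z + f[dy, dx] * img[dy:(dy + side - 1), dx:(dx + side - 1)]
      }
    }
    Z <- pmax(Z, 0)
    # 4x4 average pooling via the running-sum trick on rows then columns
    P <- matrix(0, ex$map_side, ex$map_side)
    for (py in seq_len(ex$pool)) {
      for (px in seq_len(ex$pool)) {
        P <- P + Z[pool_idx + py, pool_idx + px]
      }
    }
    maps[c_, , ] <- P / (ex$pool^2)
  }
  maps
}

# internal: flattened pooled stem output (length n_flat), column-major over
# the C x s x s array so reshaping is lossless
toy_stem_vec <- function(ex, img) {
  as.vector(toy_conv_maps(ex, img))
}

# internal: dense forward pass from stem vector; inference-mode batch norm
toy_forward <- function(ex, z) {
  f <- as.vector(z %*% ex$W1) + ex$b1            # FC128 (feature tap)
  r <- pmax(f, 0)
  rhat <- (r - ex$run_mean) / sqrt(ex$run_var + 1e-5)
  g <- ex$gamma * rhat + ex$beta
  logits <- as.vector(g %*% ex$W2) + ex$b2
  list(f = f, r = r, rhat = rhat, g = g, logits = logits,
       probs = exp(logits - max(logits)) / sum(exp(logits - max(logits))))
}

#' Extract the 128-dimensional feature embedding
#'
#' Taps the extractor at its FC128 layer: the embedding of an image is the
#' linear output of the 128-unit fully connected layer, before the ReLU /
#' batch-norm / FC2 classifier that follows it. Layers after the tap can
#' change freely without affecting the features.
#'
#' @param extractor A [builtin_toy_extractor()] (possibly fine-tuned).
#' @param data A [labeled_image_set()].
#' @return N x 128 feature matrix, rows in `data` order.
#' @export
extract_features <- function(extractor, data) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!inherits(data, "labeled_image_set") || length(data$images) < 1) {
    stop("data must be a non-empty labeled_image_set")
  }
  Z <- t(vapply(data$images, function(im) toy_stem_vec(extractor, im),
                numeric(extractor$n_flat)))
  sweep(Z %*% extractor$W1, 2, extractor$b1, "+")
}

#' Fine-tune a feature extractor
#'
#' Mini-batch SGD on the softmax cross-entropy of the modified head,
#' using the configuration's batch size, epoch count and learning rate.
#' For the built-in toy extractor the dense layers (FC128, batch-norm
#' affine, FC2) are updated by explicit backpropagation while the random
#' convolutional stem stays frozen; batch-norm uses batch statistics in
#' training and running statistics (momentum 0.1) at inference. External
#' pretrained backbones (e.g. `"densenet201"`) require a deep-learning
#' runtime and are not bundled; passing a backbone name raises an error
#' explaining this.
#'
#' @param backbone A `feature_extractor` (or a backbone name string, which
#'   errors unless a runtime provides it).
#' @param data Training [labeled_image_set()]; must contain both classes.
#' @param cfg A [fine_tune_config()].
#' @return The fine-tuned extractor; attribute `loss_history` holds the
#'   mean cross-entropy per epoch.
#' @export
fine_tune <- function(backbone, data, cfg) {
  stopifnot(inherits(cfg, "fine_tune_config"))
  if (is.character(backbone)) {
    stop(sprintf(paste0(
      "backbone '%s' requires an external pretrained deep-learning runtime, ",
      "which is not bundled; use builtin_toy_extractor()"), backbone))
  }
  stopifnot(inherits(backbone, "toy_extractor"))
  if (!inherits(data, "labeled_image_set")) stop("data must be a labeled_image_set")
  if (length(unique(data$labels)) < 2) {
    stop("fine-tuning requires at least one sample of each class")
  }
  ex <- backbone
  N <- length(data$images)
  Z <- t(vapply(data$images, function(im) toy_stem_vec(ex, im),
                numeric(ex$n_flat)))
  Yoh <- one_hot(data$labels, c(0, 1))
  lr <- cfg$learning_rate
  eps <- 1e-5
  momentum <- 0.1
  loss_hist <- numeric(cfg$max_epoch)
  withr::with_seed(as.integer(cfg$seed), {
    for (epoch in seq_len(cfg$max_epoch)) {
      ord <- sample(N)
      losses <- c()
      for (start in seq(1, N, by = cfg$minibatch_size)) {
        idx <- ord[start:min(start + cfg$minibatch_size - 1, N)]
        B <- length(idx)
        zb <- Z[idx, , drop = FALSE]
        yb <- Yoh[idx, , drop = FALSE]
        f <- sweep(zb %*% ex$W1, 2, ex$b1, "+")
        r <- pmax(f, 0)
        mu <- colMeans(r)
        va <- colMeans(sweep(r, 2, mu, "-")^2)
        invstd <- 1 / sqrt(va + eps)
        rhat <- sweep(sweep(r, 2, mu, "-"), 2, invstd, "*")
        g <- sweep(sweep(rhat, 2, ex$gamma, "*"), 2, ex$beta, "+")
        logits <- sweep(g %*% ex$W2, 2, ex$b2, "+")
        lmax <- apply(logits, 1, max)
        pe <- exp(logits - lmax)
        probs <- pe / rowSums(pe)
        losses <- c(losses, -mean(log(rowSums(probs * yb) + 1e-12)))
        # backward
        dlogits <- unname(probs - yb) / B
        dW2 <- crossprod(g, dlogits)
        db2 <- colSums(dlogits)
        dg <- dlogits %*% t(ex$W2)
        dbeta <- colSums(dg)
        dgamma <- colSums(dg * rhat)
        drhat <- sweep(dg, 2, ex$gamma, "*")
        dr <- sweep(drhat - matrix(colMeans(drhat), B, 128, byrow = TRUE) -
                      sweep(rhat, 2, colMeans(drhat * rhat), "*"),
                    2, invstd, "*")
        df <- dr * (f > 0)
        dW1 <- crossprod(zb, df)
        db1 <- colSums(df)
        ex$W1 <- ex$W1 - lr * dW1
        ex$b1 <- ex$b1 - lr * db1
        ex$gamma <- ex$gamma - lr * dgamma
        ex$beta <- ex$beta - lr * dbeta
        ex$W2 <- ex$W2 - lr * dW2
        ex$b2 <- ex$b2 - lr * db2
        ex$run_mean <- (1 - momentum) * ex$run_mean + momentum * mu
        ex$run_var <- (1 - momentum) * ex$run_var + momentum * va
      }
      loss_hist[epoch] <- mean(losses)
    }
  })
  ex$metadata$provenance <- sprintf(
    "fine-tuned %d epochs, batch %d, lr %g, seed %d",
    cfg$max_epoch, cfg$minibatch_size, lr, cfg$seed)
  attr(ex, "loss_history") <- loss_hist
  ex
}

#' Classify images with the extractor's own softmax head
#'
#' Used by Grad-CAM to pick the target class when none is given.
#'
#' @param extractor A fine-tuned (or fresh) toy extractor.
#' @param img A single intensity matrix.
#' @return list(class = 0/1, probs = length-2 softmax vector).
#' @export
extractor_predict <- function(extractor, img) {
  fw <- toy_forward(extractor, toy_stem_vec(extractor, img))
  list(class = as.integer(which.max(fw$logits)) - 1L,
       probs = unname(fw$probs))
}

#' Serialize / restore a feature extractor
#'
#' Written as a directory of full-precision CSV arrays plus JSON metadata.
#'
#' @param extractor A toy extractor.
#' @param dir Output directory.
#' @return `save_extractor` returns `dir` invisibly; `load_extractor` the
#'   extractor.
#' @export
save_extractor <- function(extractor, dir) {
  stopifnot(inherits(extractor, "toy_extractor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.table(as.matrix(x), file.path(dir, paste0(name, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  wr(matrix(extractor$filters, nrow = extractor$ksz * extractor$ksz), "filters")
  for (nm in c("W1", "b1", "gamma", "beta", "run_mean", "run_var", "W2", "b2")) {
    wr(extractor[[nm]], nm)
  }
  jsonlite::write_json(
    c(extractor$metadata,
      list(seed = extractor$seed, C = extractor$C, ksz = extractor$ksz,
           pool = extractor$pool)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  ex <- builtin_toy_extractor(seed = as.integer(meta$seed))
  rd <- function(name) {
    unname(as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")),
                                       sep = ",")))
  }
  ex$filters <- array(rd("filters"), c(ex$ksz, ex$ksz, ex$C))
  ex$W1 <- rd("W1")
  ex$W2 <- rd("W2")
  for (nm in c("b1", "gamma", "beta", "run_mean", "run_var", "b2")) {
    ex[[nm]] <- as.numeric(rd(nm)[, 1])
  }
  ex$metadata <- list(backbone = meta$backbone, input_size = meta$input_size,
                      provenance = meta$provenance)
  ex
}

#' Read a directory-per-class image folder
#'
#' Layout: `root/neg/*.png` and `root/pos/*.png` (or any two
#' lexicographically ordered class subdirectories: the first is the
#' negative/healthy class, the second positive/unhealthy). PNG images are
#' read with the `png` package and averaged to grayscale if RGB.
#'
#' @param root Directory containing exactly two class subdirectories.
#' @return A [labeled_image_set()].
#' @export
read_image_dir <- function(root) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) != 2) {
    stop(sprintf("expected 2 class subdirectories under %s, found %d",
                 root, length(dirs)))
  }
  images <- list(); labels <- integer(); ids <- character()
  for (k in 1:2) {
    files <- sort(list.files(dirs[k], pattern = "\\.png$", full.names = TRUE))
    for (fp in files) {
      im <- png::readPNG(fp)
      if (length(dim(im)) == 3) im <- apply(im[, , 1:3, drop = FALSE], c(1, 2), mean)
      images[[length(images) + 1]] <- im
      labels <- c(labels, k - 1L)
      ids <- c(ids, paste0(basename(dirs[k]), "/", basename(fp)))
    }
  }
  labeled_image_set(images, labels, ids)
}

#' Write a labeled image set as a directory-per-class PNG folder
#'
#' @param data A [labeled_image_set()].
#' @param root Output directory; subfolders `neg/` and `pos/` are created.
#' @return `root`, invisibly.
#' @export
write_image_dir <- function(data, root) {
  stopifnot(inherits(data, "labeled_image_set"))
  sub <- c("neg", "pos")
  for (s in sub) dir.create(file.path(root, s), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(data$images)) {
    cls <- sub[data$labels[i] + 1]
    fn <- file.path(root, cls, paste0(gsub("[^A-Za-z0-9_.-]", "_", data$ids[i]), ".png"))
    png::writePNG(data$images[[i]], fn)
  }
  invisible(root)
}
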