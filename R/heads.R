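#' Random hidden layer
#'
#' Constructs the frozen random hidden layer shared by the three randomized
#' network heads: input weights `W` (V x n) and biases `d` (length V), drawn
#' i.i.d. uniform on \[-1, 1\] from a dedicated generator seeded by `seed`,
#' passed through a sigmoid. The layer never changes after construction;
#' only the output layer of a head is trained (in closed form).
#'
#' @param n Input (feature) dimension, >= 1.
#' @param V Number of hidden nodes, >= 1 (pipeline default: 400).
#' @param seed Integer seed; identical seeds give bit-identical layers.
#' @return Object of class `random_hidden_layer` with fields `W`, `d`, `n`,
#'   `V`, `seed`, `activation`.
#' @export
make_hidden_layer <- function(n, V, seed = 1L) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  if (length(V) != 1 || !is.finite(V) || V < 1 || V != round(V)) {
    stop("V must be a positive integer")
  }
  vals <- withr::with_seed(as.integer(seed), stats::runif(V * n + V, -1, 1))
  layer <- list(
    W = matrix(vals[seq_len(V * n)], nrow = V, ncol = n),
    d = vals[V * n + seq_len(V)],
    n = as.integer(n),
    V = as.integer(V),
    seed = as.integer(seed),
    activation = "sigmoid"
  )
  class(layer) <- "random_hidden_layer"
  layer
}

#' @export
print.random_hidden_layer <- function(x, ...) {
  cat(sprintf("Random hidden layer: %d inputs -> %d sigmoid nodes (seed %d)\n",
              x$n, x$V, x$seed))
  invisible(x)
}

#' Hidden-layer output matrix
#'
#' Computes the N x V sigmoid activation matrix with entry
#' `(i, j) = s(w_j . x_i + d_j)`. All entries are strictly in (0, 1).
#'
#' @param layer A [make_hidden_layer()] object.
#' @param X N x n feature matrix (rows = samples).
#' @return N x V activation matrix.
#' @export
hidden_output <- function(layer, X) {
  stopifnot(inherits(layer, "random_hidden_layer"))
  X <- as_feature_matrix(X)
  if (ncol(X) != layer$n) {
    stop(sprintf("feature dimension %d does not match layer input dimension %d",
                 ncol(X), layer$n))
  }
  sigmoid(sweep(X %*% t(layer$W), 2, layer$d, "+"))
}

# internal shared trainer: solve min ||A B - Y||_F by minimum-norm LS
fit_output_layer <- function(A, Y, tol, ridge) {
  lstsq_pinv(A, Y, tol = tol, ridge = ridge)
}

# internal: optional z-score scaling of features, parameters kept for predict
scale_params <- function(X, scale) {
  if (!scale) return(NULL)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = mu, sd = sd)
}

apply_scale <- function(X, sp) {
  if (is.null(sp)) return(X)
  sweep(sweep(X, 2, sp$center, "-"), 2, sp$sd, "/")
}

#' Train a Schmidt network head
#'
#' A Schmidt network is a single-hidden-layer network with frozen random
#' hidden weights whose output weights `P` AND output bias `q` are obtained
#' jointly as the minimum-norm least-squares solution of
#' `[A | 1] [P; q] = Y`, where `A` is the sigmoid hidden activation matrix
#' and the ones column carries the bias (so a constant target is fit
#' exactly by `P = 0, q = const`).
#'
#' @param X N x n feature matrix.
#' @param Y N x m one-hot target matrix, or a label vector (one-hot encoded
#'   internally with classes in sorted order).
#' @param layer Frozen [make_hidden_layer()]; its input dimension must equal
#'   `ncol(X)`.
#' @param ridge Optional ridge penalty for ill-conditioned designs (default 0).
#' @param tol Relative singular-value cutoff of the pseudo-inverse.
#' @param scale If `TRUE`, z-score the features before the hidden layer
#'   (off by default: upstream deep features are used as-is).
#' @return Object of class `c("snn_model", "rnn_head")` with output weights
#'   `P` (V x m) and bias `q` (length m).
#' @seealso [train_elm()], [train_rvfl()], [predict.rnn_head()]
#' @export
train_snn <- function(X, Y, layer, ridge = 0, tol = 1e-12, scale = FALSE) {
  X <- as_feature_matrix(X)
  Y <- as_target_matrix(Y, nrow(X))
  sp <- scale_params(X, scale)
  Xs <- apply_scale(X, sp)
  A <- hidden_output(layer, Xs)
  B <- fit_output_layer(cbind(A, 1), Y, tol, ridge)
  model <- list(
    kind = "snn",
    hidden = layer,
    P = B[seq_len(layer$V), , drop = FALSE],
    q = B[layer$V + 1, ],
    classes = colnames(Y) %||% as.character(seq_len(ncol(Y)) - 1L),
    m = ncol(Y),
    scale = sp
  )
  class(model) <- c("snn_model", "rnn_head")
  model
}

#' Train an extreme learning machine head
#'
#' Same frozen-random hidden layer as the Schmidt network but no output
#' bias: `P = pinv(A) Y` with `A` the N x V hidden activation matrix.
#'
#' @inheritParams train_snn
#' @return Object of class `c("elm_model", "rnn_head")` with `P` (V x m).
#' @export
train_elm <- function(X, Y, layer, ridge = 0, tol = 1e-12, scale = FALSE) {
  X <- as_feature_matrix(X)
  Y <- as_target_matrix(Y, nrow(X))
  sp <- scale_params(X, scale)
  A <- hidden_output(layer, apply_scale(X, sp))
  model <- list(
    kind = "elm",
    hidden = layer,
    P = fit_output_layer(A, Y, tol, ridge),
    classes = colnames(Y) %||% as.character(seq_len(ncol(Y)) - 1L),
    m = ncol(Y),
    scale = sp
  )
  class(model) <- c("elm_model", "rnn_head")
  model
}

#' Train a random vector functional link head
#'
#' Like the ELM but the output layer also receives direct (shortcut) links
#' from the inputs: the design matrix is the column concatenation
#' `[X | K]` of the raw features and the hidden activations, and
#' `p = pinv([X | K]) Y`. The first n rows of `p` multiply the direct
#' links. No ones column is appended by default; set `add_bias = TRUE` to
#' include one.
#'
#' @inheritParams train_snn
#' @param add_bias Append a ones column to the design (default `FALSE`).
#' @return Object of class `c("rvfl_model", "rnn_head")` with `p`
#'   ((n + V \[+ 1\]) x m).
#' @export
train_rvfl <- function(X, Y, layer, ridge = 0, tol = 1e-12, scale = FALSE,
                       add_bias = FALSE) {
  X <- as_feature_matrix(X)
  Y <- as_target_matrix(Y, nrow(X))
  sp <- scale_params(X, scale)
  Xs <- apply_scale(X, sp)
  K <- hidden_output(layer, Xs)
  D <- cbind(Xs, K)
  if (add_bias) D <- cbind(D, 1)
  model <- list(
    kind = "rvfl",
    hidden = layer,
    p = fit_output_layer(D, Y, tol, ridge),
    add_bias = add_bias,
    classes = colnames(Y) %||% as.character(seq_len(ncol(Y)) - 1L),
    m = ncol(Y),
    scale = sp
  )
  class(model) <- c("rvfl_model", "rnn_head")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: raw score matrix for any head
head_scores <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$hidden$n) {
    stop(sprintf("feature dimension %d does not match model input dimension %d",
                 ncol(X), model$hidden$n))
  }
  Xs <- apply_scale(X, model$scale)
  switch(model$kind,
    snn = sweep(hidden_output(model$hidden, Xs) %*% model$P, 2, model$q, "+"),
    elm = hidden_output(model$hidden, Xs) %*% model$P,
    rvfl = {
      D <- cbind(Xs, hidden_output(model$hidden, Xs))
      if (isTRUE(model$add_bias)) D <- cbind(D, 1)
      D %*% model$p
    },
    stop("unknown head kind")
  )
}

#' Predict with a randomized-network head
#'
#' Scores are the raw linear outputs of the trained head (plus the output
#' bias for a Schmidt network). The predicted class is the argmax over
#' columns; ties break deterministically toward the lowest class index.
#'
#' @param object A model from [train_snn()], [train_elm()] or [train_rvfl()].
#' @param X N x n feature matrix.
#' @param type `"both"` (default) returns `list(scores, labels)`;
#'   `"score"` the N x m score matrix; `"class"` the label vector.
#' @param ... Unused.
#' @export
predict.rnn_head <- function(object, X, type = c("both", "score", "class"), ...) {
  type <- match.arg(type)
  S <- head_scores(object, X)
  colnames(S) <- object$classes
  if (type == "score") return(S)
  lab <- object$classes[max.col(S, ties.method = "first")]
  if (type == "class") return(lab)
  list(scores = S, labels = lab)
}

#' @export
print.rnn_head <- function(x, ...) {
  cat(sprintf("%s head: %d features -> %d hidden -> %d classes (seed %d)\n",
              toupper(x$kind), x$hidden$n, x$hidden$V, x$m, x$hidden$seed))
  invisible(x)
}

#' Serialize / restore a trained head
#'
#' Models are written as a portable directory of named real arrays (CSV,
#' full precision) plus a `metadata.json` describing the head kind and
#' dimensions, so they can be inspected or reloaded anywhere.
#'
#' @param model A trained `rnn_head`.
#' @param dir Output directory (created if missing).
#' @return `save_rnn_head` returns `dir` invisibly; `load_rnn_head` the model.
#' @export
save_rnn_head <- function(model, dir) {
  stopifnot(inherits(model, "rnn_head"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.table(as.matrix(x), file.path(dir, paste0(name, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  wr(model$hidden$W, "W")
  wr(model$hidden$d, "d")
  if (model$kind == "rvfl") wr(model$p, "p") else wr(model$P, "P")
  if (model$kind == "snn") wr(model$q, "q")
  if (!is.null(model$scale)) {
    wr(model$scale$center, "scale_center")
    wr(model$scale$sd, "scale_sd")
  }
  meta <- list(
    kind = model$kind, n = model$hidden$n, V = model$hidden$V, m = model$m,
    seed = model$hidden$seed, classes = model$classes,
    add_bias = isTRUE(model$add_bias), scaled = !is.null(model$scale)
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_rnn_head
#' @export
load_rnn_head <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  rd <- function(name) {
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".csv")), sep = ","))
  }
  layer <- list(
    W = unname(rd("W")), d = as.numeric(rd("d")[, 1]),
    n = as.integer(meta$n), V = as.integer(meta$V),
    seed = as.integer(meta$seed), activation = "sigmoid"
  )
  class(layer) <- "random_hidden_layer"
  model <- list(kind = meta$kind, hidden = layer,
                classes = as.character(meta$classes), m = as.integer(meta$m))
  if (meta$kind == "rvfl") {
    model$p <- unname(rd("p"))
    model$add_bias <- isTRUE(meta$add_bias)
  } else {
    model$P <- unname(rd("P"))
  }
  if (meta$kind == "snn") model$q <- as.numeric(rd("q")[, 1])
  if (isTRUE(meta$scaled)) {
    model$scale <- list(center = as.numeric(rd("scale_center")[, 1]),
                        sd = as.numeric(rd("scale_sd")[, 1]))
  }
  class(model) <- c(paste0(meta$kind, "_model"), "rnn_head")
  model
}

#' Read / write feature and target matrices as CSV
#'
#' One row per sample; an optional header row carries column names.
#'
#' @param path File path.
#' @param header Whether the file has (or should be written with) a header.
#' @param X Matrix to write.
#' @return `read_feature_csv` returns a numeric matrix.
#' @export
read_feature_csv <- function(path, header = TRUE) {
  X <- utils::read.csv(path, header = header, check.names = FALSE)
  as_feature_matrix(data.matrix(X), arg = path)
}

#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(X, path, header = TRUE) {
  utils::write.table(X, path, sep = ",", row.names = FALSE,
                     col.names = header && !is.null(colnames(X)),
                     qmethod = "double")
  invisible(path)
}
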