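#' Logistic sigmoid
#'
#' `s(z) = 1 / (1 + exp(-z))`, applied elementwise. Values are strictly in
#' (0, 1) for finite input.
#'
#' @param z Numeric vector, matrix or array.
#' @return Object of the same shape with entries in (0, 1).
#' @export
sigmoid <- function(z) {
  1 / (1 + exp(-z))
}

#' Minimum-norm least squares via SVD pseudo-inverse
#'
#' Solves `min ||A X - B||_F` returning the minimum-norm solution
#' `X = pinv(A) B`. Singular values below `tol * max(sigma)` are treated as
#' zero. A ridge penalty (`ridge > 0`) switches to the regularised solution
#' `(A'A + ridge I)^{-1} A'B` for ill-conditioned designs.
#'
#' @param A Numeric design matrix (N x c).
#' @param B Numeric right-hand side (N x m) or vector.
#' @param tol Relative singular-value cutoff (default 1e-12).
#' @param ridge Non-negative ridge penalty (default 0 = plain pseudo-inverse).
#' @return c x m coefficient matrix.
#' @export
lstsq_pinv <- function(A, B, tol = 1e-12, ridge = 0) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), is.numeric(A), is.numeric(B))
  if (!all(is.finite(A)) || !all(is.finite(B))) {
    stop("lstsq_pinv: non-finite entries in the system")
  }
  if (ridge < 0) stop("lstsq_pinv: ridge must be >= 0")
  if (ridge > 0) {
    G <- crossprod(A) + diag(ridge, ncol(A))
    return(solve(G, crossprod(A, B)))
  }
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), ncol(B)))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  V %*% ((crossprod(U, B)) / d)
}

#' Round half away from zero
#'
#' Display rounding used in reports: 2-decimal half-up, matching printed
#' tables, unlike base `round()`'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Bilinear image resize
#'
#' Align-corners bilinear interpolation of a 2-D intensity grid. Resizing to
#' the input size is the identity, which makes preprocessing idempotent.
#'
#' @param img Numeric matrix.
#' @param height,width Output dimensions.
#' @return `height x width` numeric matrix.
#' @export
resize_bilinear <- function(img, height, width) {
  stopifnot(is.matrix(img), height >= 1, width >= 1)
  h <- nrow(img)
  w <- ncol(img)
  ys <- if (height == 1) rep((h + 1) / 2, 1) else (seq_len(height) - 1) * (h - 1) / (height - 1) + 1
  xs <- if (width == 1) rep((w + 1) / 2, 1) else (seq_len(width) - 1) * (w - 1) / (width - 1) + 1
  y0 <- if (h == 1) rep(1, height) else pmin(floor(ys), h - 1)
  x0 <- if (w == 1) rep(1, width) else pmin(floor(xs), w - 1)
  y1 <- pmin(y0 + 1, h)
  x1 <- pmin(x0 + 1, w)
  fy <- ys - y0
  fx <- xs - x0
  # outer-product weights over the four neighbouring pixels
  a <- img[y0, x0, drop = FALSE]
  b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]
  d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, height, width)
  wx <- matrix(fx, height, width, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

# internal: validated feature matrix (N x n, finite)
as_feature_matrix <- function(X, arg = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(sprintf("%s must be numeric", arg))
  if (nrow(X) < 1 || ncol(X) < 1) stop(sprintf("%s must have N >= 1 rows and n >= 1 columns", arg))
  if (!all(is.finite(X))) stop(sprintf("%s contains non-finite entries", arg))
  X
}

#' One-hot encode class labels
#'
#' @param labels Vector of class labels (any atomic type).
#' @param classes Optional ordered class set; defaults to `sort(unique(labels))`.
#' @return N x m 0/1 matrix with one 1 per row; column names are the classes.
#' @export
one_hot <- function(labels, classes = NULL) {
  if (length(labels) < 1) stop("labels must be non-empty")
  if (is.null(classes)) classes <- sort(unique(labels))
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("labels contain values outside `classes`")
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), idx)] <- 1
  colnames(Y) <- as.character(classes)
  Y
}

# internal: validated one-hot target matrix
as_target_matrix <- function(Y, N = NULL) {
  if (is.null(dim(Y))) Y <- one_hot(Y)
  Y <- as.matrix(Y)
  if (!is.null(N) && nrow(Y) != N) stop("X and Y must have the same number of rows")
  if (!all(is.finite(Y))) stop("Y contains non-finite entries")
  Y
}
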