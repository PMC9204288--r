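# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (QR solver, scalar loops, exhaustive pair counting) and
# share no code with the package's SVD/vectorized implementations.

# Frobenius residual of the QR-based least-squares fit (base R, not SVD)
ls_residual_oracle <- function(A, Y) {
  # tight pivot tolerance: sigmoid columns can be nearly collinear and the
  # default 1e-7 would drop them, overstating the attainable residual
  fit <- lm.fit(A, Y, tol = 1e-12)
  sqrt(sum(as.matrix(fit$residuals)^2))
}

# Minimum-norm least-squares coefficients via MASS's generalized inverse
minnorm_oracle <- function(A, Y) {
  MASS::ginv(A) %*% Y
}

# Elementwise scalar-loop sigmoid hidden layer
hidden_output_loop <- function(W, d, X) {
  N <- nrow(X); V <- nrow(W)
  out <- matrix(0, N, V)
  for (i in seq_len(N)) {
    for (j in seq_len(V)) {
      z <- sum(W[j, ] * X[i, ]) + d[j]
      out[i, j] <- 1 / (1 + exp(-z))
    }
  }
  out
}

# Exhaustive pair-counting AUC, ties counted one half
pair_count_auc <- function(scores, labels, positive = 1) {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (p in ps) for (n in ns) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# Four-way counting loop for confusion matrices
confusion_loop <- function(truth, pred) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    else if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    else if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    else tn <- tn + 1
  }
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

# Scalar-loop Grad-CAM: weighted channel sum, ReLU, divide by max
grad_cam_loop <- function(act, grad) {
  C <- dim(act)[1]; h <- dim(act)[2]; w <- dim(act)[3]
  raw <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    v <- 0
    for (c_ in seq_len(C)) v <- v + mean(grad[c_, , ]) * act[c_, y, x]
    raw[y, x] <- max(0, v)
  }
  if (max(raw) > 0) raw / max(raw) else raw
}

# Nearest-centroid classifier accuracy (oracle for separable Gaussians)
nearest_centroid_acc <- function(X, labels) {
  mu0 <- colMeans(X[labels == 0, , drop = FALSE])
  mu1 <- colMeans(X[labels == 1, , drop = FALSE])
  d0 <- rowSums(sweep(X, 2, mu0)^2)
  d1 <- rowSums(sweep(X, 2, mu1)^2)
  mean((d1 < d0) == (labels == 1))
}

# Small separable image set + desk-scale training config for the toy
# extractor (random-init stand-in needs a larger step than a pretrained
# backbone; see the methods vignette)
toy_train_cfg <- function(seed, epochs = 6, lr = 0.05) {
  fine_tune_config(learning_rate = lr, max_epoch = epochs,
                   backbone_name = "builtin-toy", seed = seed)
}

small_image_set <- function(seed, n_pos = 14, n_neg = 6, size = 64) {
  generate_images(synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                                 image_size = size, seed = seed))
}
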