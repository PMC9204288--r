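test_that("make_hidden_layer is seeded, bounded and validates arguments", {
  l1 <- make_hidden_layer(2, 3, seed = 7)
  l2 <- make_hidden_layer(2, 3, seed = 7)
  expect_identical(l1$W, l2$W)
  expect_identical(l1$d, l2$d)

  big <- make_hidden_layer(1, 400, seed = 0)
  expect_equal(dim(big$W), c(400L, 1L))
  expect_length(big$d, 400)
  expect_true(all(abs(big$W) <= 1) && all(abs(big$d) <= 1))

  expect_error(make_hidden_layer(2, 0, seed = 0), "V must be")
  expect_error(make_hidden_layer(0, 3, seed = 0), "n must be")
  expect_false(identical(make_hidden_layer(2, 3, seed = 1)$W, l1$W))
})

test_that("hidden_output matches sigmoid values and the scalar-loop oracle", {
  l <- make_hidden_layer(2, 3, seed = 1)
  l$W[] <- 0
  l$d[] <- 0
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(unname(hidden_output(l, X)), matrix(0.5, 4, 3))

  single <- make_hidden_layer(2, 1, seed = 1)
  single$W[] <- c(1, 0)
  single$d[] <- 0
  expect_equal(hidden_output(single, matrix(c(0, 0), 1)), matrix(0.5))
  expect_equal(hidden_output(single, matrix(c(10, 0), 1)),
               matrix(1 / (1 + exp(-10))), tolerance = 1e-12)

  l2 <- make_hidden_layer(3, 4, seed = 42)
  X2 <- matrix(rnorm(15), 5, 3)
  expect_equal(hidden_output(l2, X2), hidden_output_loop(l2$W, l2$d, X2),
               tolerance = 1e-12)
  expect_true(all(hidden_output(l2, X2) > 0 & hidden_output(l2, X2) < 1))

  expect_error(hidden_output(l2, matrix(rnorm(10), 5, 2)), "dimension")
})

test_that("hidden_output is monotone in a coordinate with positive weight", {
  l <- make_hidden_layer(3, 5, seed = 9)
  x <- matrix(rnorm(3), 1, 3)
  j <- which(l$W[, 2] > 0)
  x2 <- x
  x2[2] <- x[2] + 1
  expect_true(all(hidden_output(l, x2)[, j] > hidden_output(l, x)[, j]))
})

test_that("train_snn solves the joint ones-augmented least-squares problem", {
  # constant target: exactly representable by P = 0, q = const
  l <- make_hidden_layer(2, 3, seed = 1)
  X <- matrix(rnorm(12), 6, 2)
  Yc <- matrix(rep(c(0.3, 0.7), each = 6), 6, 2)
  m <- train_snn(X, Yc, l)
  fit <- predict(m, X)$scores
  expect_lt(max(abs(fit - Yc)), 1e-8)

  # minimum-norm solution equals the independent generalized-inverse oracle
  Y <- withr::with_seed(5, one_hot(sample(0:1, 6, TRUE), 0:1))
  m2 <- train_snn(X, Y, l)
  A_aug <- cbind(hidden_output(l, X), 1)
  expect_equal(rbind(m2$P, m2$q), unname(minnorm_oracle(A_aug, Y)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # interpolation when the augmented design has full row rank
  l8 <- make_hidden_layer(2, 8, seed = 2)
  X4 <- matrix(rnorm(8), 4, 2)
  A4 <- cbind(hidden_output(l8, X4), 1)
  expect_equal(qr(A4)$rank, 4)
  Y4 <- one_hot(c(0, 1, 1, 0), 0:1)
  m3 <- train_snn(X4, Y4, l8)
  expect_lt(max(abs(predict(m3, X4)$scores - Y4)), 1e-6)

  expect_error(train_snn(X[0, , drop = FALSE], Y[0, , drop = FALSE], l), "N >= 1")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(train_snn(Xbad, Y, l), "non-finite")
})

test_that("train_elm solves pinv(A) Y with no bias column", {
  l <- make_hidden_layer(2, 3, seed = 1)
  X <- matrix(rnorm(12), 6, 2)
  m0 <- train_elm(X, matrix(0, 6, 2), l)
  expect_equal(m0$P, matrix(0, 3, 2), ignore_attr = TRUE)

  Y <- withr::with_seed(5, one_hot(sample(0:1, 6, TRUE), 0:1))
  m <- train_elm(X, Y, l)
  A <- hidden_output(l, X)
  expect_equal(m$P, unname(minnorm_oracle(A, Y)), tolerance = 1e-8,
               ignore_attr = TRUE)

  l8 <- make_hidden_layer(2, 8, seed = 2)
  X4 <- matrix(rnorm(8), 4, 2)
  expect_equal(qr(hidden_output(l8, X4))$rank, 4)
  Y4 <- one_hot(c(1, 0, 1, 0), 0:1)
  m2 <- train_elm(X4, Y4, l8)
  expect_lt(max(abs(predict(m2, X4)$scores - Y4)), 1e-6)
})

test_that("train_rvfl concatenates direct links with hidden activations", {
  # degenerate hidden layer (W = 0, d = 0): K collapses to a 0.5 column,
  # so the fit equals least squares on [X | 0.5 * 1]
  l <- make_hidden_layer(2, 3, seed = 1)
  l$W[] <- 0; l$d[] <- 0
  X <- matrix(rnorm(12), 6, 2)
  Y <- withr::with_seed(8, one_hot(sample(0:1, 6, TRUE), 0:1))
  m <- train_rvfl(X, Y, l)
  D_equiv <- cbind(X, 0.5)
  fit_oracle <- D_equiv %*% qr.coef(qr(D_equiv), Y)
  expect_equal(unname(predict(m, X)$scores), unname(fit_oracle), tolerance = 1e-8)

  l2 <- make_hidden_layer(2, 3, seed = 1)
  m2 <- train_rvfl(X, Y, l2)
  D <- cbind(X, hidden_output(l2, X))
  expect_equal(m2$p, unname(minnorm_oracle(D, Y)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(nrow(m2$p), 2 + 3)  # first n rows multiply the direct links

  l4 <- make_hidden_layer(2, 4, seed = 3)
  X5 <- matrix(rnorm(10), 5, 2)
  Y5 <- one_hot(c(0, 1, 0, 1, 1), 0:1)
  expect_equal(qr(cbind(X5, hidden_output(l4, X5)))$rank, 5)
  m3 <- train_rvfl(X5, Y5, l4)
  expect_lt(max(abs(predict(m3, X5)$scores - Y5)), 1e-6)
})

test_that("predict argmax breaks ties toward the lowest class index", {
  l <- make_hidden_layer(2, 8, seed = 2)
  X4 <- matrix(rnorm(8), 4, 2)
  Y4 <- one_hot(c(1, 0, 1, 0), 0:1)
  m <- train_elm(X4, Y4, l)
  # direct argmax checks on the scoring path
  m_stub <- m
  m_stub$P <- matrix(0, 8, 2)
  s <- predict(m, X4)$scores
  expect_identical(max.col(matrix(c(0.9, 0.1), 1), "first"), 1L)
  expect_identical(max.col(matrix(c(0.5, 0.5), 1), "first"), 1L)
  # all-zero output weights score both classes equally -> everything class 0
  expect_true(all(predict(m_stub, X4)$labels == "0"))
  # interpolating ELM reproduces the argmax of Y exactly
  expect_identical(predict(m, X4)$labels, as.character(c(1, 0, 1, 0)))
  expect_error(predict(m, matrix(rnorm(9), 3, 3)), "dimension")
})

test_that("all heads reach the QR-oracle residual on random small instances", {
  # numerically rank-deficient designs (kappa > 1e8) are excluded: beyond
  # that the attainable residual is not identifiable at double precision
  # and any two least-squares solvers legitimately disagree
  set.seed(101)
  for (rep in 1:30) {
    N <- sample(3:20, 1); n <- sample(1:5, 1); V <- sample(1:10, 1)
    X <- matrix(rnorm(N * n), N, n)
    Y <- one_hot(sample(0:1, N, TRUE), 0:1)
    l <- make_hidden_layer(n, V, seed = rep)
    A <- hidden_output(l, X)
    for (spec in list(
      list(model = train_snn(X, Y, l), design = cbind(A, 1)),
      list(model = train_elm(X, Y, l), design = A),
      list(model = train_rvfl(X, Y, l), design = cbind(X, A))
    )) {
      if (kappa(spec$design, exact = TRUE) > 1e8) next
      fit <- predict(spec$model, X)$scores
      expect_equal(sqrt(sum((fit - Y)^2)),
                   ls_residual_oracle(spec$design, Y), tolerance = 1e-8)
    }
  }
})

test_that("duplicating a sample leaves the (zero) residual unchanged when V >= N", {
  # in the interpolation regime every duplicate is already fit exactly
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2)
  Y <- one_hot(c(0, 1, 1, 0, 1, 0), 0:1)
  l <- make_hidden_layer(2, 12, seed = 4)
  for (trainer in list(train_snn, train_elm, train_rvfl)) {
    m1 <- trainer(X, Y, l)
    m2 <- trainer(rbind(X, X[3, ]), rbind(Y, Y[3, ]), l)
    r1 <- max(abs(predict(m1, X)$scores - Y))
    r2 <- max(abs(predict(m2, X)$scores - Y))
    expect_lt(r1, 1e-6)
    expect_lt(r2, 1e-6)
  }
})

test_that("training is deterministic and models survive serialization", {
  ft <- generate_feature_table(8, 8, 3, 2, seed = 6)
  l <- make_hidden_layer(3, 5, seed = 6)
  a <- train_snn(ft$X, ft$Y, l)
  b <- train_snn(ft$X, ft$Y, l)
  expect_identical(a$P, b$P)
  expect_identical(a$q, b$q)

  for (m in list(a, train_elm(ft$X, ft$Y, l), train_rvfl(ft$X, ft$Y, l))) {
    dir <- withr::local_tempdir()
    save_rnn_head(m, dir)
    m2 <- load_rnn_head(dir)
    expect_equal(predict(m2, ft$X)$scores, predict(m, ft$X)$scores,
                 tolerance = 1e-12)
    expect_identical(predict(m2, ft$X)$labels, predict(m, ft$X)$labels)
  }
})

test_that("z-score scaling and ridge options behave sanely", {
  ft <- generate_feature_table(20, 20, 4, 3, seed = 3)
  Xshift <- ft$X * 100 + 500
  l <- make_hidden_layer(4, 30, seed = 1)
  m <- train_elm(Xshift, ft$Y, l, scale = TRUE)
  acc <- mean(predict(m, Xshift)$labels == as.character(ft$labels))
  expect_gte(acc, 0.95)
  mr <- train_elm(ft$X, ft$Y, l, ridge = 1e-3)
  expect_true(all(is.finite(mr$P)))
})

test_that("feature CSV round-trips", {
  ft <- generate_feature_table(4, 3, 5, 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft$X, path)
  back <- read_feature_csv(path)
  expect_equal(unname(back), unname(ft$X), tolerance = 1e-12)
  expect_identical(colnames(back), colnames(ft$X))
})
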