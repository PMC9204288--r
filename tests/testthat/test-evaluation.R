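test_that("confusion counts match hand values and the counting-loop oracle", {
  cc <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 1, FP = 0, FN = 0))
  cc2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(cc2[c("TP", "FN", "FP", "TN")]), c(TP = 0, FN = 1, FP = 1, TN = 0))

  withr::with_seed(33, {
    truth <- sample(0:1, 50, TRUE)
    pred <- sample(0:1, 50, TRUE)
  })
  expect_equal(unlist(confusion(truth, pred)[c("TP", "FN", "FP", "TN")]),
               confusion_loop(truth, pred))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics follow the five formulas, with undefined-denominator flags", {
  perfect <- compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("acc", "sen", "spe", "pre", "f1")]),
               c(acc = 100, sen = 100, spe = 100, pre = 100, f1 = 100))

  r <- compute_metrics(list(TP = 35, TN = 2, FP = 2, FN = 0))
  expect_equal(round_half_up(r$acc), 94.87)
  expect_equal(r$sen, 100)
  expect_equal(r$spe, 50)
  expect_equal(round_half_up(r$pre), 94.59)
  expect_equal(round_half_up(r$f1), 97.22)

  expect_warning(u <- compute_metrics(list(TP = 3, FN = 1, FP = 0, TN = 0)),
                 "specificity undefined")
  expect_true(is.na(u$spe))
  expect_false(is.na(u$acc))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "all-zero")
})

test_that("F1 and accuracy identities hold on random confusion matrices", {
  withr::with_seed(11, {
    for (i in 1:50) {
      cc <- list(TP = sample(1:30, 1), FN = sample(0:10, 1),
                 FP = sample(1:10, 1), TN = sample(1:30, 1))
      r <- compute_metrics(cc)
      expect_equal(r$f1, 2 * r$pre * r$sen / (r$pre + r$sen), tolerance = 1e-10)
      total <- cc$TP + cc$FN + cc$FP + cc$TN
      expect_equal(r$acc,
                   (r$sen * (cc$TP + cc$FN) + r$spe * (cc$TN + cc$FP)) / total,
                   tolerance = 1e-10)
    }
  })
})

test_that("kfold_split yields stratified near-equal disjoint folds", {
  f <- kfold_split(rep(0:1, 5), k = 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  expect_identical(sort(unlist(f)), 1:10)

  lab197 <- c(rep(0, 20), rep(1, 177))
  f197 <- kfold_split(lab197, k = 5, seed = 2)
  expect_identical(sort(lengths(f197), decreasing = TRUE), c(40L, 40L, 39L, 39L, 39L))
  negs <- vapply(f197, function(i) sum(lab197[i] == 0), 0L)
  expect_true(all(negs == 4L))
  expect_identical(sort(unlist(f197)), seq_along(lab197))

  expect_error(kfold_split(rep(0:1, 2), k = 5), "must not exceed")
  expect_error(kfold_split(rep(0:1, 5), k = 1), "k must be")
})

test_that("fold partition invariant holds over random label vectors", {
  withr::with_seed(21, {
    for (i in 1:20) {
      N <- sample(10:60, 1)
      k <- sample(2:5, 1)
      labels <- sample(0:1, N, replace = TRUE, prob = c(0.3, 0.7))
      if (min(table(labels)) == 0) next
      f <- kfold_split(labels, k = k, seed = i)
      expect_identical(sort(unlist(f)), seq_len(N))
      expect_lte(diff(range(lengths(f))), 1)
      pos_counts <- vapply(f, function(ix) sum(labels[ix] == 1), 0L)
      expect_lte(diff(range(pos_counts)), 1L)
    }
  })
})

test_that("aggregation is mean plus population standard deviation", {
  agg <- aggregate_folds(c(100, 100, 94.87, 100, 97.44))
  expect_equal(round_half_up(agg$mean[["value"]]), 98.46)
  expect_equal(round_half_up(agg$std[["value"]]), 2.05)

  same <- aggregate_folds(c(100, 100, 100))
  expect_equal(same$std[["value"]], 0)

  spe <- aggregate_folds(c(100, 100, 50, 100, 75))
  expect_equal(spe$mean[["value"]], 85)
  expect_equal(spe$std[["value"]], 20)
})

test_that("roc_auc matches the pair-counting oracle and its conventions", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)

  withr::with_seed(9, {
    scores <- round(rnorm(8), 1)  # rounding forces some ties
    labels <- c(0, 0, 0, 1, 1, 1, 1, 0)
  })
  expect_equal(roc_auc(scores, labels), pair_count_auc(scores, labels))
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  expect_equal(roc_auc(qnorm(pnorm(scores)), labels), roc_auc(scores, labels),
               tolerance = 1e-12)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("run_cv_features is deterministic and isolates the head stage", {
  ft <- generate_feature_table(30, 30, 6, 4, seed = 12)
  a <- run_cv_features(ft$X, ft$labels, head = "elm", seed = 5)
  b <- run_cv_features(ft$X, ft$labels, head = "elm", seed = 5)
  expect_identical(a$aggregate$mean, b$aggregate$mean)
  expect_identical(a$scores, b$scores)
  # same seed, different head: identical folds, different model stage only
  s <- run_cv_features(ft$X, ft$labels, head = "snn", seed = 5)
  expect_identical(unclass(a$folds), unclass(s$folds))
})

test_that("cv reports are written in the published-table layout", {
  ft <- generate_feature_table(20, 20, 4, 5, seed = 2)
  cv <- run_cv_features(ft$X, ft$labels, head = "rvfl", seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  df <- write_cv_report(cv, csv, js)
  expect_identical(df$Fold, c(paste0("F", 1:5), "Avr", "Std"))
  back <- read.csv(csv)
  expect_identical(names(back), c("Fold", "Acc", "Sen", "Spe", "Pre", "F1"))
  expect_equal(nrow(back), 7)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$mean$acc, cv$aggregate$mean[["acc"]], tolerance = 1e-12)
  expect_equal(j$auc, cv$auc, tolerance = 1e-12)
})

test_that("a fold without negatives flags specificity instead of zeroing it", {
  # all-positive test fold: unstratified split of an extreme imbalance
  X <- generate_feature_table(18, 2, 4, 6, seed = 3)$X
  labels <- c(rep(0, 2), rep(1, 18))
  expect_warning(
    cv <- run_cv_features(X, labels, head = "elm", k = 5, seed = 4,
                          stratified = FALSE),
    "undefined"
  )
  expect_true(all(is.finite(cv$aggregate$mean)))
})
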