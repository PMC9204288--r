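#' Confusion counts for a two-class problem
#'
#' The unhealthy (lesion-bearing) class is the positive class throughout:
#' sensitivity is the true-positive rate on unhealthy samples, specificity
#' the true-negative rate on healthy samples.
#'
#' @param truth,pred Equal-length binary vectors (values in \{0, 1\} or the
#'   value given by `positive`).
#' @param positive The label counted as positive (default `1`).
#' @return Object of class `confusion_counts` with integer fields
#'   `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(truth, pred, positive = 1) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (length(truth) < 1) stop("empty label vectors")
  t_pos <- truth == positive
  p_pos <- pred == positive
  cc <- list(
    TP = sum(t_pos & p_pos), FN = sum(t_pos & !p_pos),
    FP = sum(!t_pos & p_pos), TN = sum(!t_pos & !p_pos)
  )
  class(cc) <- "confusion_counts"
  cc
}

#' Confusion-matrix performance metrics
#'
#' Computes, as percentages held at full precision:
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `Pre = TP/(TP+FP)` and `F1 = 2TP/(2TP+FP+FN)`. A metric whose
#' denominator is zero is flagged undefined (`NA`) with a warning rather
#' than silently reported as 0. Display formatting rounds half-up to two
#' decimals; see [format.metrics_report()].
#'
#' @param cc A [confusion()] object, or a list with fields TP/FN/FP/TN.
#' @return Object of class `metrics_report` with fields
#'   `acc`, `sen`, `spe`, `pre`, `f1` in \[0, 100\] (or `NA` if undefined).
#' @export
compute_metrics <- function(cc) {
  TP <- cc$TP; FN <- cc$FN; FP <- cc$FP; TN <- cc$TN
  counts <- c(TP, FN, FP, TN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero confusion counts")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", name), call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  rep <- list(
    acc = ratio(TP + TN, TP + TN + FP + FN, "accuracy"),
    sen = ratio(TP, TP + FN, "sensitivity"),
    spe = ratio(TN, TN + FP, "specificity"),
    pre = ratio(TP, TP + FP, "precision"),
    f1  = ratio(2 * TP, 2 * TP + FP + FN, "F1"),
    counts = cc
  )
  class(rep) <- "metrics_report"
  rep
}

#' @export
format.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("acc", "sen", "spe", "pre", "f1")])
  out <- ifelse(is.na(vals), "undef", sprintf("%.2f", round_half_up(vals, 2)))
  paste(sprintf("%s=%s", c("Acc", "Sen", "Spe", "Pre", "F1"), out), collapse = " ")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Seeded shuffle then partition of `0..N-1`-indexed samples (returned as
#' R's 1-based indices) into k near-equal folds. With `stratified = TRUE`
#' (default) each class is dealt separately, its surplus going to the
#' currently smallest folds, so per-fold class counts differ by at most one
#' and fold sizes differ by at most one.
#'
#' @param labels Length-N vector of class labels.
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Integer seed for the shuffle.
#' @param stratified Preserve the class ratio per fold (default `TRUE`).
#' @return Object of class `fold_assignment`: a list of k index vectors
#'   partitioning `seq_along(labels)`.
#' @export
kfold_split <- function(labels, k = 5, seed = 1L, stratified = TRUE) {
  N <- length(labels)
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  if (k > N) stop("k must not exceed the number of samples")
  folds <- vector("list", k)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        base <- length(idx) %/% k
        extra <- length(idx) %% k
        # surplus samples go to the folds that are currently smallest
        sizes <- vapply(folds, length, 0L)
        recipients <- order(sizes, sample(k))[seq_len(extra)]
        take <- rep(base, k)
        take[recipients] <- take[recipients] + 1L
        pos <- 0L
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], idx[pos + seq_len(take[f])])
          pos <- pos + take[f]
        }
      }
    } else {
      idx <- sample(N)
      take <- rep(N %/% k, k)
      extra <- N %% k
      if (extra > 0) take[seq_len(extra)] <- take[seq_len(extra)] + 1L
      pos <- 0L
      for (f in seq_len(k)) {
        folds[[f]] <- idx[pos + seq_len(take[f])]
        pos <- pos + take[f]
      }
    }
  })
  folds <- lapply(folds, sort)
  class(folds) <- "fold_assignment"
  folds
}

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and POPULATION standard deviation (divisor k, not k-1)
#' of each metric across folds — the convention under which the package's
#' summary rows reproduce published per-fold tables exactly. Folds where a
#' metric is flagged undefined are dropped from that metric's aggregation
#' with a warning.
#'
#' @param reports List of [compute_metrics()] reports (or a numeric vector,
#'   treated as a single metric named `value`).
#' @return Object of class `aggregate_report`: list with `mean` and `std`
#'   named vectors over acc/sen/spe/pre/f1 (or `value`), plus `k`.
#' @export
aggregate_folds <- function(reports) {
  if (is.numeric(reports)) {
    reports <- lapply(reports, function(v) list(value = v))
  }
  if (length(reports) < 1) stop("need at least one fold report")
  keys <- setdiff(intersect(names(reports[[1]]),
                            c("acc", "sen", "spe", "pre", "f1", "value")),
                  character(0))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mu <- std <- stats::setNames(numeric(length(keys)), keys)
  for (kk in keys) {
    v <- vapply(reports, function(r) as.numeric(r[[kk]]), 0)
    if (anyNA(v)) {
      warning(sprintf("dropping %d undefined fold value(s) for %s",
                      sum(is.na(v)), kk), call. = FALSE)
      v <- v[!is.na(v)]
    }
    mu[kk] <- mean(v)
    std[kk] <- pop_sd(v)
  }
  out <- list(mean = mu, std = std, k = length(reports))
  class(out) <- "aggregate_report"
  out
}

#' @export
print.aggregate_report <- function(x, ...) {
  for (kk in names(x$mean)) {
    cat(sprintf("%-5s Avr %6.2f  Std ±%.2f\n", kk,
                round_half_up(x$mean[kk], 2), round_half_up(x$std[kk], 2)))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (positive class = `positive`).
#' @param positive Positive-class label (default 1).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = 1) {
  if (length(scores) != length(labels)) stop("scores and labels must have equal length")
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False-positive vs true-positive rates at every distinct score threshold,
#' exportable as TSV via `write.table`.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive = 1) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), 0)
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Cross-validated evaluation of a randomized head on a feature table
#'
#' Runs stratified k-fold cross-validation of one head (SNN, RVFL or ELM)
#' directly on a precomputed feature matrix: for every fold, a fresh frozen
#' hidden layer is drawn, the head is trained in closed form on the other
#' folds and evaluated on the held-out fold.
#'
#' @param X N x n feature matrix.
#' @param labels Length-N binary labels (1 = positive/unhealthy).
#' @param head `"snn"`, `"rvfl"` or `"elm"`.
#' @param k Folds (default 5).
#' @param V Hidden nodes (default 400).
#' @param seed Seed controlling fold shuffle and hidden-layer draws.
#' @param stratified Stratified folds (default TRUE).
#' @param ridge,scale Passed to the head trainer.
#' @return Object of class `cv_result`: `fold_metrics` (list of
#'   [compute_metrics()] reports), `aggregate` ([aggregate_folds()]),
#'   `scores`/`truth` (out-of-fold positive-class scores for ROC),
#'   `auc`, `head`, `folds`.
#' @export
run_cv_features <- function(X, labels, head = c("snn", "rvfl", "elm"),
                            k = 5, V = 400, seed = 1L, stratified = TRUE,
                            ridge = 0, scale = FALSE) {
  head <- match.arg(head)
  X <- as_feature_matrix(X)
  if (nrow(X) != length(labels)) stop("X rows and labels must agree")
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("two classes required")
  folds <- kfold_split(labels, k = k, seed = seed, stratified = stratified)
  trainer <- switch(head, snn = train_snn, elm = train_elm, rvfl = train_rvfl)
  fold_metrics <- vector("list", k)
  oof_scores <- numeric(nrow(X))
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    layer <- make_hidden_layer(ncol(X), V, seed = as.integer(seed) + f)
    Ytr <- one_hot(labels[train_idx], classes)
    model <- trainer(X[train_idx, , drop = FALSE], Ytr, layer,
                     ridge = ridge, scale = scale)
    pred <- predict(model, X[test_idx, , drop = FALSE])
    pos_col <- match(as.character(classes[2]), model$classes)
    oof_scores[test_idx] <- pred$scores[, pos_col]
    fold_metrics[[f]] <- compute_metrics(
      confusion(labels[test_idx], pred$labels, positive = classes[2])
    )
  }
  out <- list(
    fold_metrics = fold_metrics,
    aggregate = aggregate_folds(fold_metrics),
    scores = oof_scores,
    truth = labels,
    auc = roc_auc(oof_scores, labels, positive = classes[2]),
    head = head,
    folds = folds
  )
  class(out) <- "cv_result"
  out
}

#' Full image-to-report cross-validation pipeline
#'
#' The end-to-end protocol on a labeled image set: for every fold the
#' feature extractor is fine-tuned on the training folds only, features are
#' tapped at the 128-unit embedding layer, the chosen randomized head is
#' trained in closed form on the training-fold features, and the held-out
#' fold is scored. Per-fold metric reports are aggregated as in
#' [aggregate_folds()].
#'
#' @param data A [labeled_image_set()].
#' @param cfg A [fine_tune_config()]; `cfg$hidden_nodes_V` sizes the head
#'   and `cfg$seed` drives folds, extractor and hidden layers.
#' @param head `"snn"`, `"rvfl"` or `"elm"`.
#' @param k Folds (default 5).
#' @param stratified Stratified folds (default TRUE).
#' @param backbone Feature extractor to fine-tune per fold; default a fresh
#'   [builtin_toy_extractor()] seeded from `cfg$seed`.
#' @return A `cv_result` (see [run_cv_features()]).
#' @export
run_cv_pipeline <- function(data, cfg, head = c("snn", "rvfl", "elm"),
                            k = 5, stratified = TRUE, backbone = NULL) {
  head <- match.arg(head)
  stopifnot(inherits(data, "labeled_image_set"), inherits(cfg, "fine_tune_config"))
  labels <- data$labels
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("two classes required")
  folds <- kfold_split(labels, k = k, seed = cfg$seed, stratified = stratified)
  trainer <- switch(head, snn = train_snn, elm = train_elm, rvfl = train_rvfl)
  fold_metrics <- vector("list", k)
  oof_scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    bb <- if (is.null(backbone)) builtin_toy_extractor(cfg$seed) else backbone
    fold_cfg <- cfg
    fold_cfg$seed <- as.integer(cfg$seed) + f
    extractor <- fine_tune(bb, subset_images(data, train_idx), fold_cfg)
    Ftr <- extract_features(extractor, subset_images(data, train_idx))
    Fte <- extract_features(extractor, subset_images(data, test_idx))
    layer <- make_hidden_layer(ncol(Ftr), cfg$hidden_nodes_V,
                               seed = as.integer(cfg$seed) + f)
    model <- trainer(Ftr, one_hot(labels[train_idx], classes), layer)
    pred <- predict(model, Fte)
    pos_col <- match(as.character(classes[2]), model$classes)
    oof_scores[test_idx] <- pred$scores[, pos_col]
    fold_metrics[[f]] <- compute_metrics(
      confusion(labels[test_idx], pred$labels, positive = classes[2])
    )
  }
  out <- list(
    fold_metrics = fold_metrics,
    aggregate = aggregate_folds(fold_metrics),
    scores = oof_scores,
    truth = labels,
    auc = roc_auc(oof_scores, labels, positive = classes[2]),
    head = head,
    folds = folds
  )
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, head = %s\n", length(x$fold_metrics),
              toupper(x$head)))
  for (f in seq_along(x$fold_metrics)) {
    cat(sprintf("  F%d  %s\n", f, format(x$fold_metrics[[f]])))
  }
  print(x$aggregate)
  cat(sprintf("AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Write a cross-validation report
#'
#' CSV mirrors the published table layout (one row per fold, then Avr and
#' Std rows, two half-up decimals); JSON carries full precision.
#'
#' @param cv A `cv_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the data.frame written to CSV.
#' @export
write_cv_report <- function(cv, csv_path = NULL, json_path = NULL) {
  keys <- c("acc", "sen", "spe", "pre", "f1")
  tab <- t(vapply(cv$fold_metrics,
                  function(r) unlist(r[keys]), numeric(length(keys))))
  df <- data.frame(Fold = paste0("F", seq_len(nrow(tab))),
                   round_half_up(tab, 2), check.names = FALSE)
  colnames(df) <- c("Fold", "Acc", "Sen", "Spe", "Pre", "F1")
  df <- rbind(df,
              data.frame(Fold = "Avr", t(round_half_up(cv$aggregate$mean, 2)) |>
                           `colnames<-`(c("Acc", "Sen", "Spe", "Pre", "F1"))),
              data.frame(Fold = "Std", t(round_half_up(cv$aggregate$std, 2)) |>
                           `colnames<-`(c("Acc", "Sen", "Spe", "Pre", "F1"))))
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      head = cv$head,
      folds = lapply(cv$fold_metrics, function(r) r[keys]),
      mean = as.list(cv$aggregate$mean),
      std = as.list(cv$aggregate$std),
      auc = cv$auc
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
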