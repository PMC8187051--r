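# Binary-classifier evaluation: confusion counts, the four standard
# indicators (ACC, MCC, Sn, Sp) and ROC/AUC, plus the two protocols used
# to benchmark the predictor: stratified k-fold cross-validation and
# train/test independent validation.

#' Confusion counts from true and predicted labels
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return Object of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `TN`, `FN` partitioning `n`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Build confusion counts directly
#' @param TP,FP,TN,FN Nonnegative integer counts, `n > 0` in total.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- as.integer(c(TP, FP, TN, FN))
  if (any(v < 0) || sum(v) == 0) stop("counts must be nonnegative, n > 0")
  structure(list(TP = v[1L], FP = v[2L], TN = v[3L], FN = v[4L]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' The four standard indicators from confusion counts
#'
#' Computes accuracy `ACC = (TP+TN)/n`, sensitivity `Sn = TP/(TP+FN)`
#' (recall of methylated sites), specificity `Sp = TN/(TN+FP)` (recall of
#' background) and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the MCC denominator is zero, MCC is 0 by the usual
#' convention; Sn/Sp are `NaN` when their class is absent.
#'
#' @param counts A `confusion_counts` object.
#' @param auc Optional AUC to attach to the report.
#' @param protocol Optional protocol tag (`"cv"` or `"independent"`).
#' @return Object of class `metrics_report`.
#' @export
metrics <- function(counts, auc = NA_real_, protocol = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  # doubles: the MCC denominator overflows 32-bit integers near n ~ 500
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  n <- TP + FP + TN + FN
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2)
  structure(list(counts = counts,
                 acc = (TP + TN) / n,
                 sn = TP / (TP + FN),
                 sp = TN / (TN + FP),
                 mcc = mcc,
                 auc = auc,
                 protocol = protocol),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4L, ...) {
  cat(sprintf("metrics%s: ", if (is.null(x$protocol)) "" else
    paste0(" (", x$protocol, ")")))
  cat(sprintf("ACC=%.*f MCC=%.*f Sn=%.*f Sp=%.*f", digits, x$acc,
              digits, x$mcc, digits, x$sn, digits, x$sp))
  if (!is.na(x$auc)) cat(sprintf(" AUC=%.*f", digits, x$auc))
  cat("\n  ")
  print(x$counts)
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values, collecting
#' (FPR, TPR) points, and integrates the curve with the trapezoid rule.
#' Tied scores form a single threshold step, so the integral equals the
#' Mann-Whitney statistic: the probability that a random positive outscores
#' a random negative, with ties counted 1/2.
#'
#' @param y_true Binary 0/1 labels, both classes present.
#' @param scores Real-valued scores, higher = more positive.
#' @return List with `auc` and `points`, a data.frame of
#'   `(fpr, tpr, threshold)` rows from (0,0) to (1,1) suitable for export.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(is.finite(scores)))
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  step_end <- which(!duplicated(ss, fromLast = TRUE))  # end of each tied run
  tp <- cumsum(ys == 1L)[step_end]
  fp <- cumsum(ys == 0L)[step_end]
  pts <- data.frame(fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos),
                    threshold = c(Inf, ss[step_end]))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
  list(auc = auc, points = pts)
}

#' Write ROC curve points as TSV
#'
#' @param roc Result of [roc_auc()].
#' @param path Output path; columns `fpr`, `tpr`, `threshold`.
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize scored predictions into a metrics report
#'
#' @param y_true Binary labels.
#' @param scores Probability scores in `[0, 1]`.
#' @param threshold Decision threshold (ties go positive).
#' @param protocol Optional protocol tag.
#' @return A `metrics_report` with AUC attached.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5,
                                 protocol = NULL) {
  rep <- metrics(confusion(y_true, as.integer(scores >= threshold)),
                 auc = roc_auc(y_true, scores)$auc, protocol = protocol)
  rep$scores <- scores
  rep$y_true <- as.integer(y_true)
  rep
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(list(
    protocol = report$protocol,
    counts = report$counts[c("TP", "FP", "TN", "FN")],
    acc = report$acc, mcc = report$mcc, sn = report$sn, sp = report$sp,
    auc = if (is.na(report$auc)) NULL else report$auc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cross-validated evaluation of the full stacked pipeline
#'
#' Outer stratified k-fold loop over a labelled window set: for each outer
#' fold the entire stacking procedure ([fit_stack()], with its own inner
#' fold split) is re-run on the remaining folds and the held-out fold is
#' scored through the test-side path. Out-of-fold predictions are pooled
#' and the metrics computed once on the concatenated predictions (not
#' averaged per fold).
#'
#' @param ws Labelled `window_set` with both classes.
#' @param config Stacking config ([default_stack_config()]).
#' @param k Outer fold count (default 10).
#' @param seed Outer fold seed; inner procedures derive per-fold seeds.
#' @return A `metrics_report` with `protocol = "cv"`, plus `$per_fold`
#'   (per-fold `metrics_report`s) and `$scores`/`$y_true` for the pooled
#'   predictions.
#' @export
crossvalidate <- function(ws, config = default_stack_config(), k = 10L,
                          seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(ws$label)) stop("cross-validation needs a labelled window set")
  enc <- encode_set(ws, config$encoder, config$ks)
  y <- enc$y
  outer <- make_folds(nrow(enc$X), y, k, seed)
  scores <- numeric(nrow(enc$X))
  per_fold <- vector("list", k)
  for (j in seq_len(k)) {
    hold <- outer$fold_of == j
    cfg <- config
    cfg$seed <- as.integer(seed) + 1000L * j   # fresh inner split per fold
    fitres <- fit_stack(enc$X[!hold, , drop = FALSE], y[!hold],
                        enc$X[hold, , drop = FALSE], cfg)
    pred <- predict_stack(fitres$ensemble, enc$X[hold, , drop = FALSE])
    scores[hold] <- pred$scores
    per_fold[[j]] <- evaluate_predictions(y[hold], pred$scores,
                                          config$threshold)
  }
  rep <- evaluate_predictions(y, scores, config$threshold, protocol = "cv")
  rep$per_fold <- per_fold
  rep
}

#' Independent-test evaluation of the stacked pipeline
#'
#' Fits the stacked ensemble on the training set and evaluates on a
#' disjoint labelled test set, the protocol that emulates a real
#' prediction task. A shared id or sequence between the two sets triggers
#' a warning (evaluation still runs).
#'
#' @param train,test Labelled `window_set`s of the same window length.
#' @param config Stacking config.
#' @return A `metrics_report` with `protocol = "independent"`; also
#'   carries `$base_auc` (per-base-learner test AUC from the averaged meta
#'   features), `$ensemble`, `$scores` and `$y_true`.
#' @export
independent_test <- function(train, test, config = default_stack_config()) {
  stopifnot(inherits(train, "window_set"), inherits(test, "window_set"))
  if (length(test) == 0L) stop("empty test set")
  if (is.null(train$label) || is.null(test$label)) {
    stop("both sets must be labelled")
  }
  if (any(test$id %in% train$id) || any(test$seq %in% train$seq)) {
    warning("train and test sets are not disjoint")
  }
  enc_tr <- encode_set(train, config$encoder, config$ks)
  enc_te <- encode_set(test, config$encoder, config$ks)
  fitres <- fit_stack(enc_tr$X, enc_tr$y, enc_te$X, config)
  scores <- score(fitres$ensemble$meta, fitres$B)
  rep <- evaluate_predictions(enc_te$y, scores, config$threshold,
                              protocol = "independent")
  rep$base_auc <- vapply(colnames(fitres$B), function(b)
    roc_auc(enc_te$y, fitres$B[, b])$auc, numeric(1))
  rep$ensemble <- fitres$ensemble
  rep
}
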