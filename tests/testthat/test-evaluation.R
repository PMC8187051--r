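# Confusion counts, the four indicators, ROC/AUC and the two protocols.

test_that("confusion counts enumerate agreement and disagreement", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$FP + perfect$FN, 0L)
  allpos <- confusion(rep(c(1, 0), 5), rep(1, 10))
  expect_identical(allpos$FP, 5L)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metric formulas match hand evaluation and handle degeneracy", {
  perfect <- metrics(confusion_counts(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_identical(c(perfect$acc, perfect$sn, perfect$sp, perfect$mcc),
                   c(1, 1, 1, 1))
  m <- metrics(confusion_counts(TP = 3, FP = 1, TN = 2, FN = 2))
  expect_equal(m$acc, 0.625)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 2 / 3)
  expect_equal(m$mcc, (3 * 2 - 1 * 2) / sqrt(240))  # sqrt(4*5*3*4)
  # zero-denominator convention: MCC = 0
  expect_identical(metrics(confusion_counts(5, 5, 0, 0))$mcc, 0)
  expect_identical(metrics(confusion_counts(0, 0, 5, 5))$mcc, 0)
})

test_that("metrics agree with the brute-force oracle on random tables", {
  withr::with_seed(14, {
    for (i in 1:1000) {
      v <- stats::rmultinom(1, sample(4:500, 1), rep(0.25, 4))
      if (sum(v) == 0) next
      got <- metrics(confusion_counts(v[1], v[2], v[3], v[4]))
      want <- brute_metrics(v[1], v[2], v[3], v[4])
      expect_equal(got$acc, want$acc)
      expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
      if (!is.nan(want$sn)) expect_equal(got$sn, want$sn)
      if (!is.nan(want$sp)) expect_equal(got$sp, want$sp)
    }
  })
})

test_that("curve-integrated AUC equals the pairwise Mann-Whitney statistic", {
  expect_identical(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  expect_identical(roc_auc(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))$auc,
               pairwise_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)))
  withr::with_seed(15, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      y <- as.integer(stats::runif(n) < 0.5)
      if (length(unique(y)) < 2) next
      s <- round(stats::runif(n), sample(1:3, 1))  # force ties often
      r <- roc_auc(y, s)
      expect_equal(r$auc, pairwise_auc(y, s), tolerance = 1e-9)
      expect_equal(r$points$fpr[1], 0)
      expect_equal(r$points$tpr[nrow(r$points)], 1)
      expect_true(all(diff(r$points$fpr) >= 0) &&
                    all(diff(r$points$tpr) >= 0))
    }
  })
  expect_error(roc_auc(rep(1, 4), stats::runif(4)), "both classes")
})

test_that("AUC matches an established ROC implementation", {
  withr::with_seed(16, {
    y <- as.integer(stats::runif(200) < 0.5)
    s <- stats::runif(200) + 0.4 * y
  })
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("pooled CV metrics equal metrics of concatenated counts", {
  withr::with_seed(17, {
    y <- as.integer(stats::runif(90) < 0.5)
    p <- as.integer(stats::runif(90) < 0.5)
    fold <- rep(1:3, each = 30)
  })
  pooled <- metrics(confusion(y, p))
  parts <- lapply(1:3, function(j) confusion(y[fold == j], p[fold == j]))
  added <- metrics(confusion_counts(
    sum(vapply(parts, `[[`, 0L, "TP")), sum(vapply(parts, `[[`, 0L, "FP")),
    sum(vapply(parts, `[[`, 0L, "TN")), sum(vapply(parts, `[[`, 0L, "FN"))))
  expect_equal(pooled$acc, added$acc)
  expect_equal(pooled$mcc, added$mcc)
})

test_that("report and ROC exports are readable", {
  rep <- evaluate_predictions(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6),
                              protocol = "independent")
  jp <- withr::local_tempfile(fileext = ".json")
  write_report(rep, jp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$acc, rep$acc)
  expect_equal(back$counts$TP, rep$counts$TP)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_roc_points(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6)), tp)
  pts <- utils::read.delim(tp)
  expect_identical(names(pts), c("fpr", "tpr", "threshold"))
})

cheap_cfg <- function() {
  default_stack_config(encoder = "multifeature", ks = 1:2,
                       bases = list("nb_multinomial", "bayesnet"),
                       k = 3)
}

test_that("cross-validation is deterministic and detects planted signal", {
  ws <- generate_windows(generator_config(40, 40, noise = 0.1, seed = 40))
  r1 <- crossvalidate(ws, cheap_cfg(), k = 3, seed = 2)
  r2 <- crossvalidate(ws, cheap_cfg(), k = 3, seed = 2)
  expect_identical(r1$acc, r2$acc)
  expect_identical(r1$scores, r2$scores)
  expect_gt(r1$acc, 0.8)
  expect_length(r1$per_fold, 3)
  # fold confusion counts add up to the pooled counts
  expect_identical(r1$counts$TP,
                   sum(vapply(r1$per_fold, function(p) p$counts$TP, 0L)))
})

test_that("label permutation destroys cross-validated signal", {
  ws <- generate_windows(generator_config(100, 100, noise = 0.1, seed = 41))
  ws$label <- withr::with_seed(42, sample(ws$label))
  r <- crossvalidate(ws, cheap_cfg(), k = 4, seed = 3)
  expect_gt(r$acc, 0.35)
  expect_lt(r$acc, 0.65)
  expect_lt(abs(r$mcc), 0.2)
})

test_that("independent validation runs end-to-end and guards its inputs", {
  train <- generate_windows(generator_config(40, 40, noise = 0.1, seed = 44))
  test <- generate_windows(generator_config(15, 15, noise = 0.1, seed = 45))
  test$id <- paste0("t_", test$id)
  r <- independent_test(train, test, cheap_cfg())
  expect_identical(r$protocol, "independent")
  expect_gt(r$acc, 0.7)
  expect_named(r$base_auc, c("nb_multinomial", "bayesnet"))
  # degenerate overlap warns but still reports
  dup <- train
  expect_warning(independent_test(train, dup, cheap_cfg()), "disjoint")
  expect_error(independent_test(train, test[integer(0)], cheap_cfg()),
               "empty")
  unlabelled <- window_set(test$id, test$seq)
  expect_error(independent_test(train, unlabelled, cheap_cfg()),
               "labelled")
})

test_that("train/test consistency: independent ACC tracks CV ACC", {
  ws <- generate_windows(generator_config(80, 80, noise = 0.1, seed = 46))
  bm <- generate_windows(generator_config(40, 40, noise = 0.1, seed = 47))
  bm$id <- paste0("t_", bm$id)
  cv_acc <- crossvalidate(ws, cheap_cfg(), k = 4, seed = 5)$acc
  ind_acc <- independent_test(ws, bm, cheap_cfg())$acc
  expect_lt(abs(cv_acc - ind_acc), 0.1)
})
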