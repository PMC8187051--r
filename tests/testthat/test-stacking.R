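# Fold construction and the two-stage out-of-fold stacking procedure.

small_encoded <- function(n_per_class = 40, seed = 30, noise = 0.1) {
  ws <- generate_windows(generator_config(n_per_class, n_per_class,
                                          noise = noise, seed = seed))
  encode_set(ws, "kmer", ks = 1:2)   # 20-dim: cheap but informative
}

test_that("stratified folds balance sizes and classes deterministically", {
  f <- make_folds(20, rep(c(1, 0), 10), k = 10, seed = 3)
  per_fold <- table(f$fold_of, rep(c(1, 0), 10))
  expect_true(all(per_fold == 1))    # one positive + one negative per fold
  f2 <- make_folds(20, rep(c(1, 0), 10), k = 10, seed = 3)
  expect_identical(f$fold_of, f2$fold_of)
  expect_false(identical(
    f$fold_of, make_folds(20, rep(c(1, 0), 10), k = 10, seed = 4)$fold_of))
  # the published training size: 1492 into 10 folds of 149/150
  f3 <- make_folds(1492, rep(c(1, 0), 746), k = 10, seed = 1)
  expect_setequal(unique(tabulate(f3$fold_of, 10)), c(149L, 150L))
  # general property: sizes within 1, class counts within 1 of proportion
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(30:200, 1)
      k <- sample(2:10, 1)
      y <- as.integer(stats::runif(n) < 0.4)
      if (length(unique(y)) < 2) next
      fa <- make_folds(n, y, k, seed = i)
      sizes <- tabulate(fa$fold_of, k)
      expect_lte(diff(range(sizes)), 1L)
      pos_per <- vapply(1:k, function(j) sum(y[fa$fold_of == j]), 0L)
      expect_lte(diff(range(pos_per)), 1L)
    }
  })
  expect_error(make_folds(5, rep(c(1, 0), length.out = 5), k = 10), "folds")
  expect_error(make_folds(10, rep(1L, 10), k = 2), "both classes")
})

test_that("a constant-score base learner propagates exactly through A and B", {
  enc <- small_encoded()
  folds <- make_folds(nrow(enc$X), enc$y, k = 5, seed = 1)
  oof <- oof_base_predictions("constant07", enc$X, enc$y,
                              enc$X[1:7, ], folds, seed = 1)
  expect_identical(oof$A, rep(0.7, nrow(enc$X)))
  expect_identical(oof$B, rep(0.7, 7L))
})

test_that("out-of-fold columns never see their own instance", {
  enc <- small_encoded()
  folds <- make_folds(nrow(enc$X), enc$y, k = 5, seed = 2)
  oof <- oof_base_predictions("memorizer", enc$X, enc$y, NULL, folds,
                              seed = 1)
  # instrumented check: each instance absent from its scorer's training set
  for (j in seq_len(folds$k)) {
    tr <- attr(oof$fold_models[[j]], "train_idx")
    expect_length(intersect(which(folds$fold_of == j), tr), 0)
  }
  # leakage sentinel: the memorizer scores unseen rows 0.5, so if OOF
  # scoring leaked training rows A would reproduce the labels exactly
  expect_identical(oof$A, rep(0.5, nrow(enc$X)))
  m_in <- fit(learner("memorizer"), enc$X, enc$y)
  expect_identical(score(m_in, enc$X), as.numeric(enc$y))  # in-sample != OOF
})

test_that("test-side meta features are the mean of the fold models' scores", {
  enc <- small_encoded()
  probe <- small_encoded(seed = 33)$X[1:3, ]
  folds <- make_folds(nrow(enc$X), enc$y, k = 4, seed = 5)
  oof <- oof_base_predictions("nb_multinomial", enc$X, enc$y, probe, folds,
                              seed = 7)
  by_hand <- rowMeans(vapply(oof$fold_models, function(m) score(m, probe),
                             numeric(3)))
  expect_equal(oof$B, by_hand, tolerance = 1e-15)
})

test_that("single-class training splits are reported by fold", {
  X <- matrix(stats::rnorm(40), 20)
  y <- rep(c(1L, 0L), each = 10)
  folds <- structure(list(n = 20L, k = 2L,
                          fold_of = rep(c(1L, 2L), each = 10L), seed = 0L),
                     class = "fold_assignment")
  expect_error(
    oof_base_predictions("logistic", X, y, NULL, folds),
    "excluding fold 1 contains a single class")
})

test_that("fit_stack produces aligned meta matrices and is reproducible", {
  enc <- small_encoded(30)
  te <- small_encoded(10, seed = 34)
  cfg <- default_stack_config(
    encoder = "kmer", ks = 1:2,
    bases = list("nb_multinomial", "voted_perceptron", "logistic"),
    k = 5)
  res <- fit_stack(enc$X, enc$y, te$X, cfg)
  expect_equal(dim(res$A), c(60L, 3L))
  expect_equal(dim(res$B), c(20L, 3L))
  expect_identical(colnames(res$A),
                   c("nb_multinomial", "voted_perceptron", "logistic"))
  expect_identical(attr(res$A, "role"), "train")
  expect_true(all(res$A >= 0 & res$A <= 1))
  res2 <- fit_stack(enc$X, enc$y, te$X, cfg)
  expect_identical(res$A, res2$A)
  expect_identical(res$B, res2$B)
  expect_identical(res$ensemble$meta$model$beta, res2$ensemble$meta$model$beta)
  expect_error(fit_stack(enc$X, enc$y,
                         config = default_stack_config(bases = list("svm"))),
               "at least two")
})

test_that("stacking keeps up with a perfectly informative base learner", {
  # first feature of this fabricated matrix IS the (noisy) posterior
  withr::with_seed(35, {
    n <- 200
    y <- rep(0:1, each = n / 2)
    oracle_col <- pmin(pmax(0.8 * y + 0.1 + stats::rnorm(n, sd = 0.05), 0), 1)
    X <- cbind(oracle_col, matrix(stats::runif(3 * n), n))
    te_y <- rep(0:1, each = 50)
    te_oracle <- pmin(pmax(0.8 * te_y + 0.1 + stats::rnorm(100, sd = 0.05),
                           0), 1)
    Xte <- cbind(te_oracle, matrix(stats::runif(300), 100))
  })
  cfg <- default_stack_config(
    bases = list("first_col", "nb_multinomial"), k = 5)
  res <- fit_stack(X, y, Xte, cfg)
  stack_scores <- score(res$ensemble$meta, res$B)
  stack_acc <- mean((stack_scores >= 0.5) == (te_y == 1))
  best_single <- max(vapply(colnames(res$B), function(b)
    mean((res$B[, b] >= 0.5) == (te_y == 1)), numeric(1)))
  expect_gte(stack_acc, best_single - 0.05)
})

test_that("with one effective base and a mean meta, the stack reduces to fold-averaged scoring", {
  enc <- small_encoded(25)
  te <- small_encoded(8, seed = 36)$X
  cfg <- default_stack_config(
    bases = list("nb_multinomial", "constant07"),
    meta = list(name = "mean_meta"), k = 4)
  res <- fit_stack(enc$X, enc$y, te, cfg)
  pred <- predict_stack(res$ensemble, te)
  folds <- res$ensemble$folds
  oof <- oof_base_predictions("nb_multinomial", enc$X, enc$y, te, folds,
                              seed = cfg$seed)
  # mean meta over {base, constant 0.7} is an affine map of the base score
  expect_equal(pred$scores, (oof$B + 0.7) / 2, tolerance = 1e-12)
})

test_that("predict_stack is row-order invariant and consistent with B", {
  enc <- small_encoded(25)
  te <- small_encoded(9, seed = 37)$X
  cfg <- default_stack_config(encoder = "kmer", ks = 1:2,
                              bases = list("nb_multinomial", "logistic"),
                              k = 4)
  res <- fit_stack(enc$X, enc$y, te, cfg)
  pred <- predict_stack(res$ensemble, te)
  expect_equal(pred$scores, score(res$ensemble$meta, res$B),
               tolerance = 1e-12)
  perm <- rev(seq_len(nrow(te)))
  pred_perm <- predict_stack(res$ensemble, te[perm, ])
  expect_equal(pred_perm$scores, pred$scores[perm])
  one <- predict_stack(res$ensemble, te[3, , drop = FALSE])
  expect_length(one$scores, 1)
  expect_true(one$scores >= 0 && one$scores <= 1)
  expect_error(predict_stack(res$ensemble, te[, 1:5]), "dimension")
})

test_that("ensemble bundles restore bit-identical scoring", {
  enc <- small_encoded(20)
  cfg <- default_stack_config(bases = list("nb_multinomial", "logistic"),
                              k = 3)
  res <- fit_stack(enc$X, enc$y, config = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(res$ensemble, path)
  back <- load_ensemble(path)
  probe <- small_encoded(6, seed = 38)$X
  expect_identical(predict_stack(back, probe)$scores,
                   predict_stack(res$ensemble, probe)$scores)
})

test_that("yaml and json configs override only the named fields", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("k: 5", "seed: 9", "encoder: eiip"), yml)
  cfg <- read_stack_config(yml)
  expect_identical(cfg$k, 5L)
  expect_identical(cfg$seed, 9L)
  expect_identical(cfg$encoder, "eiip")
  expect_length(cfg$bases, 4)          # defaults retained
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"bases": [{"name": "svm"}, {"name": "logistic"}], "k": 3}',
             jsn)
  cfg2 <- read_stack_config(jsn)
  expect_identical(vapply(cfg2$bases, `[[`, "", "name"),
                   c("svm", "logistic"))
  expect_identical(cfg2$k, 3L)
})
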