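# Two-stage stacked generalization.
#
# Stage 1: the training set is split into k stratified folds; each base
# learner is fitted k times, each time with one fold held out, and scores
# that held-out fold. Stacking the k held-out score blocks vertically
# gives one out-of-fold (OOF) column per base learner (the meta training
# matrix A). Each of the k fold models also scores the test set, and the
# k score vectors are averaged into the test meta column (matrix B).
# Stage 2: a logistic metaclassifier is trained on A against the training
# labels and applied to B. New data at deployment follows the same path
# as B: fold-model averaging, then the metaclassifier - base learners are
# never refitted on the full training set.
#
# Meta features are positive-class probabilities, not hard labels, so the
# test-side averaging preserves calibration and ranking information.

#' Stratified k-fold assignment
#'
#' Assigns `n` instances to `k` folds so that fold sizes differ by at most
#' one and each class is dealt cyclically across folds (per-fold class
#' counts within one of proportionality). Deterministic given `seed`; the
#' global RNG state is left untouched.
#'
#' @param n Instance count.
#' @param labels Binary 0/1 labels of length `n`, both classes present.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `fold_assignment` with fields `n`, `k`,
#'   `fold_of` (integer vector in `1..k`) and `seed`.
#' @export
make_folds <- function(n, labels, k = 10L, seed = 1L) {
  n <- as.integer(n)
  k <- as.integer(k)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("`labels` must have length n")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (n < k) stop(sprintf("cannot make %d folds from %d instances", k, n))
  fold_of <- integer(n)
  withr::with_seed(as.integer(seed), {
    ptr <- 0L
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- ptr + length(idx)
    }
    perm <- sample.int(k)              # avoid fold 1 always being largest
    fold_of <- perm[fold_of]
  })
  structure(list(n = n, k = k, fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: n=%d, k=%d, sizes %s (seed %d)\n",
              x$n, x$k, paste(tabulate(x$fold_of, x$k), collapse = "/"),
              x$seed))
  invisible(x)
}

#' Out-of-fold base-learner predictions
#'
#' Runs the stage-1 procedure for one base learner: for each fold j a
#' model is fitted on all other folds, scores its held-out fold (stacked
#' into the OOF column `A`) and, if a test matrix is given, scores the
#' test set; the k test-score vectors are averaged into `B`.
#'
#' Each returned fold model carries its training row indices in
#' `attr(, "train_idx")` so the no-leakage property can be audited.
#'
#' @param learner_name Registered learner name.
#' @param X_train,y_train Training features and binary labels.
#' @param X_test Optional test feature matrix.
#' @param folds A [make_folds()] assignment with `folds$n == nrow(X_train)`.
#' @param seed Base seed; fold j trains with seed `seed + j`.
#' @param hyper Hyperparameter list for the learner constructor.
#' @return List with `A` (length-n OOF score vector), `B` (length-m
#'   averaged test scores or `NULL`) and `fold_models`.
#' @export
oof_base_predictions <- function(learner_name, X_train, y_train,
                                 X_test = NULL, folds, seed = 1L,
                                 hyper = list()) {
  stopifnot(inherits(folds, "fold_assignment"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) != folds$n) stop("X_train rows must match folds$n")
  y_train <- as.integer(y_train)
  A <- numeric(folds$n)
  B_parts <- if (!is.null(X_test)) matrix(0, nrow(as.matrix(X_test)), folds$k)
  fold_models <- vector("list", folds$k)
  for (j in seq_len(folds$k)) {
    hold <- folds$fold_of == j
    if (!any(hold)) stop(sprintf("fold %d is empty", j))
    if (length(unique(y_train[!hold])) < 2L) {
      stop(sprintf(
        "training split excluding fold %d contains a single class", j))
    }
    mod <- fit(do.call(learner, c(list(learner_name), hyper)),
               X_train[!hold, , drop = FALSE], y_train[!hold],
               seed = as.integer(seed) + j)
    attr(mod, "train_idx") <- which(!hold)
    fold_models[[j]] <- mod
    A[hold] <- score(mod, X_train[hold, , drop = FALSE])
    if (!is.null(X_test)) B_parts[, j] <- score(mod, X_test)
  }
  list(A = A, B = if (!is.null(X_test)) rowMeans(B_parts),
       fold_models = fold_models)
}

#' Default stacking configuration
#'
#' The shipped configuration: multifeature encoding (k-mer 1..5 + EIIP),
#' four base learners (bayesnet, nb_multinomial, svm, voted_perceptron) at
#' their default hyperparameters, a logistic metaclassifier, 10 stratified
#' folds, seed 1 and decision threshold 0.5.
#'
#' @param encoder Encoding scheme name.
#' @param ks K values for k-mer based encoders.
#' @param bases List of `list(name=, hyper=)` base learner specs.
#' @param meta Metaclassifier spec, `list(name=, hyper=)`.
#' @param k Fold count for the stage-1 split.
#' @param seed Fold/learner seed.
#' @param threshold Decision threshold (ties go positive).
#' @return A config list understood by [fit_stack()] and friends.
#' @export
default_stack_config <- function(encoder = "multifeature", ks = 1:5,
                                 bases = list(
                                   list(name = "bayesnet"),
                                   list(name = "nb_multinomial"),
                                   list(name = "svm"),
                                   list(name = "voted_perceptron")),
                                 meta = list(name = "logistic"),
                                 k = 10L, seed = 1L, threshold = 0.5) {
  bases <- lapply(bases, function(b) {
    if (is.character(b)) b <- list(name = b)
    if (is.null(b$hyper)) b$hyper <- list()
    b
  })
  if (is.null(meta$hyper)) meta$hyper <- list()
  list(encoder = encoder, ks = ks, bases = bases, meta = meta,
       k = as.integer(k), seed = as.integer(seed), threshold = threshold)
}

#' Read a stacking configuration from YAML or JSON
#'
#' Fields absent from the file keep their [default_stack_config()] values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A config list.
#' @export
read_stack_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  def <- default_stack_config()
  for (nm in intersect(names(raw), names(def))) def[[nm]] <- raw[[nm]]
  do.call(default_stack_config, def)
}

#' Fit the two-stage stacked ensemble
#'
#' Builds the stratified fold assignment, computes one out-of-fold score
#' column per base learner (meta matrix `A`), averages fold-model scores
#' on the test set (`B`) and fits the metaclassifier on `(A, y_train)`.
#'
#' @param X_train,y_train Encoded training features and binary labels.
#' @param X_test Optional encoded test features (enables `B`).
#' @param config A [default_stack_config()]-style list with at least two
#'   base learners and one metaclassifier.
#' @return List with `ensemble` (class `stacked_ensemble`), `A` (n x
#'   n_bases OOF meta matrix, `attr(,"role") = "train"`) and `B` (m x
#'   n_bases averaged test meta matrix or `NULL`).
#' @export
fit_stack <- function(X_train, y_train, X_test = NULL,
                      config = default_stack_config()) {
  if (length(config$bases) < 2L) {
    stop("config must name at least two base learners")
  }
  X_train <- as.matrix(X_train)
  y_train <- as.integer(y_train)
  folds <- make_folds(nrow(X_train), y_train, config$k, config$seed)
  base_names <- vapply(config$bases, `[[`, character(1), "name")
  A <- matrix(NA_real_, nrow(X_train), length(base_names),
              dimnames = list(NULL, base_names))
  B <- if (!is.null(X_test)) {
    matrix(NA_real_, nrow(as.matrix(X_test)), length(base_names),
           dimnames = list(NULL, base_names))
  }
  fold_models <- stats::setNames(vector("list", length(base_names)),
                                 base_names)
  for (b in seq_along(config$bases)) {
    oof <- oof_base_predictions(config$bases[[b]]$name, X_train, y_train,
                                X_test, folds, seed = config$seed,
                                hyper = config$bases[[b]]$hyper)
    A[, b] <- oof$A
    if (!is.null(X_test)) B[, b] <- oof$B
    fold_models[[b]] <- oof$fold_models
  }
  meta <- fit(do.call(learner, c(list(config$meta$name), config$meta$hyper)),
              A, y_train, seed = config$seed)
  attr(A, "role") <- "train"
  if (!is.null(B)) attr(B, "role") <- "test"
  ensemble <- structure(
    list(base_names = base_names, fold_models = fold_models, meta = meta,
         folds = folds, config = config, dim = ncol(X_train),
         threshold = config$threshold),
    class = "stacked_ensemble")
  list(ensemble = ensemble, A = A, B = B)
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf(
    "stacked_ensemble: bases [%s] -> %s meta; k=%d folds, dim=%d, seed=%d\n",
    paste(x$base_names, collapse = ", "), x$meta$name, x$folds$k, x$dim,
    x$folds$seed))
  invisible(x)
}

#' Predict with a fitted stacked ensemble
#'
#' New rows follow the test-side path of the fitting procedure: each base
#' learner's k fold models score the rows and are averaged into one meta
#' feature per base, then the metaclassifier produces the final score.
#' Per-row computation, so scores are invariant to row order.
#'
#' @param ensemble A fitted `stacked_ensemble`.
#' @param X_new Feature matrix encoded with the ensemble's scheme.
#' @return List with `scores` (meta probabilities), `labels`
#'   (`score >= threshold`) and `base_features` (the averaged per-base
#'   score matrix).
#' @export
predict_stack <- function(ensemble, X_new) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ensemble$dim) {
    stop(sprintf("feature dimension %d does not match ensemble dimension %d",
                 ncol(X_new), ensemble$dim))
  }
  base_feats <- sapply(ensemble$base_names, function(b) {
    preds <- sapply(ensemble$fold_models[[b]], function(m) score(m, X_new))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
    rowMeans(preds)
  })
  if (is.null(dim(base_feats))) {
    base_feats <- matrix(base_feats, nrow = 1L,
                         dimnames = list(NULL, ensemble$base_names))
  }
  scores <- score(ensemble$meta, base_feats)
  list(scores = scores,
       labels = as.integer(scores >= ensemble$threshold),
       base_features = base_feats)
}

#' Save / load a fitted ensemble bundle
#'
#' The bundle is a single-file archive holding a format-version manifest
#' (package version, base learner names, encoder, fold assignment, seeds)
#' plus every fold model and the metaclassifier; loading restores
#' bit-identical scoring.
#'
#' @param ensemble A fitted `stacked_ensemble`.
#' @param path Bundle path.
#' @return `save_ensemble` invisibly returns `path`; `load_ensemble`
#'   returns the restored `stacked_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  saveRDS(list(
    manifest = list(
      format = 1L,
      package = as.character(utils::packageVersion("stack4mC")),
      bases = ensemble$base_names,
      encoder = ensemble$config$encoder,
      k = ensemble$folds$k, seed = ensemble$folds$seed),
    ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  bundle <- readRDS(path)
  if (is.null(bundle$manifest$format) || bundle$manifest$format != 1L) {
    stop("unrecognized ensemble bundle format")
  }
  bundle$ensemble
}
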