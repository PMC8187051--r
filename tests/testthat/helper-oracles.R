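# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: k-mer counting by direct substring scans,
# metrics by literal formula transcription, AUC by pairwise enumeration.

rand_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# overlapping k-mer frequencies by dictionary count over all substrings
brute_kmer <- function(seq, k) {
  L <- nchar(seq)
  mers <- substring(seq, 1:(L - k + 1), k:L)
  alphabet <- c("A", "C", "G", "T")
  all_mers <- do.call(paste0, rev(expand.grid(
    rep(list(alphabet), k), stringsAsFactors = FALSE)))
  counts <- vapply(sort(all_mers), function(m) sum(mers == m), numeric(1))
  counts / (L - k + 1)
}

# literal transcription of the four indicator formulas
brute_metrics <- function(TP, FP, TN, FN) {
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(acc = (TN + TP) / (TN + FN + FP + TP),
       sn = TP / (FN + TP),
       sp = TN / (FP + TN),
       mcc = if (den == 0) 0 else (TN * TP - FN * FP) / den)
}

# Mann-Whitney AUC by enumerating every positive-negative pair
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a tiny labelled dataset with an obvious planted signal, for smoke tests
toy_signal_set <- function(n_per_class = 60, seed = 42) {
  generate_windows(generator_config(n_per_class, n_per_class,
                                    motif = "GTACGTCA", noise = 0.1,
                                    seed = seed))
}

# learners that memorize/ignore training data, exercising the registry as
# the third-party extension point
register_probe_learners <- function() {
  register_learner("constant07", function() {
    l <- structure(list(name = "constant07", hyper = list(), fitted = FALSE,
                        model = NULL, meta = NULL),
                   class = c("constant07_learner", "mc_learner"))
    l
  })
  register_learner("memorizer", function() {
    structure(list(name = "memorizer", hyper = list(), fitted = FALSE,
                   model = NULL, meta = NULL),
              class = c("memorizer_learner", "mc_learner"))
  })
  register_learner("first_col", function() {
    structure(list(name = "first_col", hyper = list(), fitted = FALSE,
                   model = NULL, meta = NULL),
              class = c("firstcol_learner", "mc_learner"))
  })
  register_learner("mean_meta", function() {
    structure(list(name = "mean_meta", hyper = list(), fitted = FALSE,
                   model = NULL, meta = NULL),
              class = c("meanmeta_learner", "mc_learner"))
  })
}

fit.constant07_learner <- function(learner, X, y, seed = 1L, ...) {
  learner$fitted <- TRUE
  learner$meta <- list(n = nrow(X), dim = ncol(X), seed = seed)
  learner
}
score.constant07_learner <- function(learner, X, ...) rep(0.7, nrow(X))

fit.memorizer_learner <- function(learner, X, y, seed = 1L, ...) {
  learner$model <- list(keys = apply(X, 1, paste, collapse = ","),
                        y = as.integer(y))
  learner$fitted <- TRUE
  learner$meta <- list(n = nrow(X), dim = ncol(X), seed = seed)
  learner
}
score.memorizer_learner <- function(learner, X, ...) {
  keys <- apply(X, 1, paste, collapse = ",")
  hit <- match(keys, learner$model$keys)
  # seen rows get their training label with certainty, unseen rows 0.5
  as.numeric(ifelse(is.na(hit), 0.5, learner$model$y[hit]))
}

# scores equal to the first feature (assumed already in [0,1])
fit.firstcol_learner <- function(learner, X, y, seed = 1L, ...) {
  learner$fitted <- TRUE
  learner$meta <- list(n = nrow(X), dim = ncol(X), seed = seed)
  learner
}
score.firstcol_learner <- function(learner, X, ...) pmin(pmax(X[, 1], 0), 1)

# identity-like metaclassifier: the mean of its input columns
fit.meanmeta_learner <- fit.firstcol_learner
score.meanmeta_learner <- function(learner, X, ...) rowMeans(X)

# make the helper methods visible to dispatch from inside the package
local({
  ns <- asNamespace("stack4mC")
  for (cls in c("constant07_learner", "memorizer_learner",
                "firstcol_learner", "meanmeta_learner")) {
    registerS3method("fit", cls, get(paste0("fit.", cls)), envir = ns)
    registerS3method("score", cls, get(paste0("score.", cls)), envir = ns)
  }
})

register_probe_learners()
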