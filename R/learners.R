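# Uniform fit/score contract over heterogeneous classifiers.
#
# Every learner takes a numeric feature matrix and binary labels and, once
# fitted, returns one positive-class probability in [0, 1] per row. The
# hyperparameter defaults mirror the Weka defaults of the corresponding
# algorithms (LibSVM: RBF, C = 1, gamma = 1/dim; voted perceptron: one
# epoch; multinomial naive Bayes: Laplace alpha = 1; logistic: negligible
# ridge). Margin-based learners expose probabilities through a documented
# monotone squashing. All learners are deterministic given `seed`.

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner constructor
#'
#' The learner registry is the extension point for third-party
#' classifiers: any constructor returning an object that implements
#' [fit()] and [score()] can be registered and then used as a base or meta
#' learner in a stacking config.
#'
#' @param name Registry name.
#' @param constructor Function of hyperparameters returning a learner.
#' @return Invisibly, `name`.
#' @export
register_learner <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .learner_registry)
  invisible(name)
}

#' List registered learner names
#' @return Character vector.
#' @export
list_learners <- function() sort(ls(.learner_registry))

#' Construct a learner by registry name
#'
#' Built-in learners: `"bayesnet"` (discrete Bayes network on
#' MDL-discretized features), `"nb_multinomial"`, `"svm"` (RBF LibSVM via
#' e1071 with Platt-style calibration), `"voted_perceptron"` and
#' `"logistic"`.
#'
#' @param name Registered learner name.
#' @param ... Hyperparameters forwarded to the constructor.
#' @return An unfitted learner object (class `mc_learner`).
#' @export
learner <- function(name, ...) {
  if (!exists(name, envir = .learner_registry)) {
    stop("unknown learner: ", name, " (see list_learners())")
  }
  get(name, envir = .learner_registry)(...)
}

new_learner <- function(name, class, hyper = list()) {
  structure(list(name = name, hyper = hyper, fitted = FALSE, model = NULL,
                 meta = NULL),
            class = c(class, "mc_learner"))
}

#' @export
print.mc_learner <- function(x, ...) {
  hp <- if (length(x$hyper)) {
    paste(names(x$hyper), vapply(x$hyper, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("<%s learner> %s; %s\n", x$name,
              if (x$fitted) sprintf("fitted on n=%d, dim=%d",
                                    x$meta$n, x$meta$dim) else "unfitted",
              hp))
  invisible(x)
}

check_training_input <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  list(X = X, y = y)
}

check_scoring_input <- function(learner, X) {
  if (!isTRUE(learner$fitted)) stop("learner must be fitted before scoring")
  X <- as.matrix(X)
  if (ncol(X) != learner$meta$dim) {
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(X), learner$meta$dim))
  }
  X
}

#' Fit a learner
#'
#' @param learner An `mc_learner` (or any registered learner object).
#' @param X Numeric feature matrix (rows = instances).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed honoured by learners with internal randomness.
#' @param ... Passed to methods.
#' @return The fitted learner; training metadata (`n`, `dim`, `seed`,
#'   hyperparameters) is recorded in `$meta`.
#' @export
fit <- function(learner, X, y, seed = 1L, ...) UseMethod("fit")

#' Score instances with a fitted learner
#'
#' @param learner A fitted learner.
#' @param X Feature matrix with the training dimensionality.
#' @param ... Passed to methods.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
score <- function(learner, X, ...) UseMethod("score")

#' Threshold scores into hard labels
#'
#' Ties go positive: a score exactly equal to the threshold yields label 1.
#' This single tie rule is used throughout the package.
#'
#' @inheritParams score
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(learner, X, threshold = 0.5) {
  as.integer(score(learner, X) >= threshold)
}

record_fit <- function(learner, X, y, seed) {
  learner$fitted <- TRUE
  learner$meta <- list(n = nrow(X), dim = ncol(X), seed = as.integer(seed),
                       hyper = learner$hyper)
  learner
}

# ---- logistic (metaclassifier) -----------------------------------------

#' @rdname learner
#' @details `learner_logistic()` is maximum-likelihood logistic regression
#'   via [stats::glm()]; the Weka metaclassifier it mirrors applies a
#'   negligible ridge (1e-8), which is indistinguishable from the
#'   unpenalized fit. Collinear columns get coefficient 0.
#' @export
learner_logistic <- function() new_learner("logistic", "logistic_learner")

#' @export
fit.logistic_learner <- function(learner, X, y, seed = 1L, ...) {
  d <- check_training_input(X, y)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, d$X), d$y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  learner$model <- list(beta = beta)
  record_fit(learner, d$X, d$y, seed)
}

#' @export
score.logistic_learner <- function(learner, X, ...) {
  X <- check_scoring_input(learner, X)
  as.numeric(stats::plogis(cbind(1, X) %*% learner$model$beta))
}

# ---- multinomial naive Bayes -------------------------------------------

#' @rdname learner
#' @details `learner_nb_multinomial()` treats each row of nonnegative
#'   features as event counts/weights and applies Laplace smoothing
#'   `alpha` (default 1).
#' @param alpha Laplace smoothing pseudo-count.
#' @export
learner_nb_multinomial <- function(alpha = 1) {
  new_learner("nb_multinomial", "nbmulti_learner", list(alpha = alpha))
}

#' @export
fit.nbmulti_learner <- function(learner, X, y, seed = 1L, ...) {
  d <- check_training_input(X, y)
  if (any(d$X < 0)) stop("multinomial naive Bayes requires nonnegative features")
  a <- learner$hyper$alpha
  tot1 <- colSums(d$X[d$y == 1L, , drop = FALSE])
  tot0 <- colSums(d$X[d$y == 0L, , drop = FALSE])
  learner$model <- list(
    log_prior = log(c(mean(d$y == 0L), mean(d$y == 1L))),
    log_theta0 = log((tot0 + a) / sum(tot0 + a)),
    log_theta1 = log((tot1 + a) / sum(tot1 + a)))
  record_fit(learner, d$X, d$y, seed)
}

#' @export
score.nbmulti_learner <- function(learner, X, ...) {
  X <- check_scoring_input(learner, X)
  m <- learner$model
  l0 <- m$log_prior[1L] + as.numeric(X %*% m$log_theta0)
  l1 <- m$log_prior[2L] + as.numeric(X %*% m$log_theta1)
  1 / (1 + exp(l0 - l1))
}

# ---- support vector machine (LibSVM via e1071) -------------------------

#' @rdname learner
#' @details `learner_svm()` wraps LibSVM (e1071) with an RBF kernel,
#'   `cost = 1` and `gamma = 1/dim` by default and no feature scaling.
#'   Probabilities come from a Platt-style logistic calibration of the
#'   decision values, fitted deterministically on the training set.
#' @param cost Soft-margin cost C.
#' @param gamma RBF kernel width; `NULL` means `1/dim`.
#' @param kernel e1071 kernel name.
#' @param scale Let e1071 standardize columns (default `FALSE`).
#' @export
learner_svm <- function(cost = 1, gamma = NULL, kernel = "radial",
                        scale = FALSE) {
  new_learner("svm", "svm_learner",
              list(cost = cost, gamma = gamma, kernel = kernel,
                   scale = scale))
}

#' @export
fit.svm_learner <- function(learner, X, y, seed = 1L, ...) {
  d <- check_training_input(X, y)
  h <- learner$hyper
  gamma <- if (is.null(h$gamma)) 1 / ncol(d$X) else h$gamma
  mod <- e1071::svm(d$X, factor(d$y, levels = c(0L, 1L)),
                    kernel = h$kernel, cost = h$cost, gamma = gamma,
                    scale = h$scale)
  dv <- as.numeric(attr(stats::predict(mod, d$X, decision.values = TRUE),
                        "decision.values"))
  # Platt-style sigmoid on training decision values; glm orients the sign
  if (stats::sd(dv) < 1e-12) {
    platt <- c(stats::qlogis(max(min(mean(d$y), 1 - 1e-6), 1e-6)), 0)
  } else {
    cal <- suppressWarnings(
      stats::glm.fit(cbind(1, dv), d$y, family = stats::binomial()))
    platt <- cal$coefficients
  }
  learner$model <- list(svm = mod, platt = platt)
  record_fit(learner, d$X, d$y, seed)
}

#' @export
score.svm_learner <- function(learner, X, ...) {
  X <- check_scoring_input(learner, X)
  dv <- as.numeric(attr(stats::predict(learner$model$svm, X,
                                       decision.values = TRUE),
                        "decision.values"))
  as.numeric(stats::plogis(learner$model$platt[1L] +
                             learner$model$platt[2L] * dv))
}

# ---- voted perceptron ---------------------------------------------------

#' @rdname learner
#' @details `learner_voted_perceptron()` implements the Freund-Schapire
#'   voted perceptron with a linear (degree-1 polynomial) kernel and an
#'   implicit bias term. Training keeps every intermediate weight vector
#'   with its survival count; the score of an instance is the fraction of
#'   survival-weighted votes for the positive class, a monotone squashing
#'   of the vote margin into `[0, 1]`. The instance order is shuffled once
#'   under `seed` before the first epoch.
#' @param epochs Passes over the training data (default 1).
#' @export
learner_voted_perceptron <- function(epochs = 1L) {
  new_learner("voted_perceptron", "votedperc_learner",
              list(epochs = as.integer(epochs)))
}

#' @export
fit.votedperc_learner <- function(learner, X, y, seed = 1L, ...) {
  d <- check_training_input(X, y)
  Xa <- cbind(d$X, 1)           # bias absorbed as constant feature
  yy <- ifelse(d$y == 1L, 1, -1)
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(Xa)))
  n <- nrow(Xa)
  max_vecs <- n * learner$hyper$epochs + 1L
  U <- matrix(0, max_vecs, ncol(Xa))  # update vectors; weights = cumsum
  counts <- numeric(max_vecs)
  w <- numeric(ncol(Xa))
  kth <- 1L
  for (ep in seq_len(learner$hyper$epochs)) {
    for (i in ord) {
      pred <- if (sum(w * Xa[i, ]) > 0) 1 else -1
      if (pred == yy[i]) {
        counts[kth] <- counts[kth] + 1
      } else {
        kth <- kth + 1L
        U[kth, ] <- yy[i] * Xa[i, ]
        counts[kth] <- 1
        w <- w + U[kth, ]
      }
    }
  }
  W <- apply(U[seq_len(kth), , drop = FALSE], 2L, cumsum)
  if (kth == 1L) W <- matrix(W, nrow = 1L)
  learner$model <- list(W = W, counts = counts[seq_len(kth)])
  record_fit(learner, d$X, d$y, seed)
}

#' @export
score.votedperc_learner <- function(learner, X, ...) {
  X <- check_scoring_input(learner, X)
  m <- learner$model
  margins <- cbind(X, 1) %*% t(m$W)            # n x n_vectors
  as.numeric((margins > 0) %*% m$counts / sum(m$counts))
}

# built-ins registered at load time; bayesnet registers in its own file
register_builtin_learners <- function() {
  register_learner("logistic", learner_logistic)
  register_learner("nb_multinomial", learner_nb_multinomial)
  register_learner("svm", learner_svm)
  register_learner("voted_perceptron", learner_voted_perceptron)
  register_learner("bayesnet", learner_bayesnet)
}
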