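# Discrete Bayes network classifier on supervised-discretized features.
#
# Numeric features are first discretized with the Fayyad-Irani recursive
# entropy/MDL procedure (class-aware cut points, accepted only when the
# information gain beats the MDL coding cost). A feature with no accepted
# cut collapses to a single bin and is uninformative. On the discretized
# features the classifier is either:
#   * structure = "naive": class -> feature edges only (the structure a
#     max-one-parent search over a naive-Bayes start also selects), or
#   * structure = "tan": tree-augmented naive Bayes, where each feature
#     additionally gets at most one feature parent along the maximum
#     spanning tree of pairwise conditional mutual information given the
#     class. Quadratic in the feature count; intended for modest dims.
# Conditional probability tables use smoothing pseudo-count 0.5.

entropy2 <- function(n1, n0) {
  n <- n1 + n0
  p <- c(n1, n0) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Fayyad-Irani MDL cut points for one numeric feature against binary y.
mdl_cut_points <- function(x, y) {
  ord <- order(x, method = "radix")
  xs <- x[ord]
  ys <- y[ord]
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return()
    xr <- xs[lo:hi]
    yr <- ys[lo:hi]
    cand <- which(xr[-n] != xr[-1L])     # split after index i
    if (length(cand) == 0L) return()
    c1 <- cumsum(yr == 1L)
    c0 <- cumsum(yr == 0L)
    n1 <- c1[n]; n0 <- c0[n]
    ent_s <- entropy2(n1, n0)
    nl <- cand
    e_left <- vapply(cand, function(i) entropy2(c1[i], c0[i]), numeric(1))
    e_right <- vapply(cand, function(i) entropy2(n1 - c1[i], n0 - c0[i]),
                      numeric(1))
    went <- (nl * e_left + (n - nl) * e_right) / n
    best <- which.min(went)
    i <- cand[best]
    gain <- ent_s - went[best]
    k <- as.integer(n1 > 0L) + as.integer(n0 > 0L)
    k1 <- as.integer(c1[i] > 0L) + as.integer(c0[i] > 0L)
    k2 <- as.integer(n1 - c1[i] > 0L) + as.integer(n0 - c0[i] > 0L)
    delta <- log2(3^k - 2) -
      (k * ent_s - k1 * e_left[best] - k2 * e_right[best])
    if (gain <= (log2(n - 1L) + delta) / n) return()
    cuts[length(cuts) + 1L] <<- (xs[lo + i - 1L] + xs[lo + i]) / 2
    recurse(lo, lo + i - 1L)
    recurse(lo + i, hi)
  }
  recurse(1L, length(xs))
  sort(cuts)
}

bin_feature <- function(x, cuts) findInterval(x, cuts) + 1L

# smoothed log P(bin | class) table: nbins x 2 (cols = class 0, class 1)
cpt_1d <- function(bins, y, nbins, s = 0.5) {
  tab <- vapply(0:1, function(cl) {
    tabulate(bins[y == cl], nbins) + s
  }, numeric(nbins))
  log(sweep(matrix(tab, nbins), 2L, colSums(matrix(tab, nbins)), "/"))
}

# conditional mutual information I(Xi; Xj | Y) on binned features
cond_mutual_info <- function(bi, bj, y, ni, nj) {
  total <- 0
  for (cl in 0:1) {
    sel <- y == cl
    nc <- sum(sel)
    if (nc == 0L) next
    joint <- table(factor(bi[sel], levels = seq_len(ni)),
                   factor(bj[sel], levels = seq_len(nj))) / nc
    pi_ <- rowSums(joint)
    pj_ <- colSums(joint)
    nz <- joint > 0
    total <- total + (nc / length(y)) *
      sum(joint[nz] * log2(joint[nz] / outer(pi_, pj_)[nz]))
  }
  total
}

#' @rdname learner
#' @details `learner_bayesnet()` is a discrete Bayes network on
#'   supervised-discretized features (Fayyad-Irani MDL cuts), with CPT
#'   smoothing 0.5. `structure = "naive"` (default) uses class-to-feature
#'   edges only; `structure = "tan"` augments it with at most one feature
#'   parent per feature chosen by a maximum spanning tree over conditional
#'   mutual information.
#' @param structure `"naive"` or `"tan"`.
#' @param smoothing CPT pseudo-count.
#' @export
learner_bayesnet <- function(structure = c("naive", "tan"), smoothing = 0.5) {
  structure <- match.arg(structure)
  new_learner("bayesnet", "bayesnet_learner",
              list(structure = structure, smoothing = smoothing))
}

#' @export
fit.bayesnet_learner <- function(learner, X, y, seed = 1L, ...) {
  d <- check_training_input(X, y)
  s <- learner$hyper$smoothing
  p <- ncol(d$X)
  cuts <- lapply(seq_len(p), function(j) mdl_cut_points(d$X[, j], d$y))
  nbins <- vapply(cuts, length, integer(1)) + 1L
  active <- which(nbins > 1L)          # single-bin features carry no signal
  bins <- lapply(active, function(j) bin_feature(d$X[, j], cuts[[j]]))
  names(bins) <- as.character(active)

  model <- list(cuts = cuts, nbins = nbins, active = active,
                log_prior = log(c(mean(d$y == 0L) , mean(d$y == 1L))),
                structure = learner$hyper$structure)

  if (learner$hyper$structure == "naive" || length(active) < 2L) {
    model$cpt <- lapply(seq_along(active), function(a)
      cpt_1d(bins[[a]], d$y, nbins[active[a]], s))
    model$structure <- "naive"
  } else {
    na <- length(active)
    wmat <- matrix(0, na, na)
    for (a in seq_len(na - 1L)) {
      for (b in (a + 1L):na) {
        wmat[a, b] <- cond_mutual_info(bins[[a]], bins[[b]], d$y,
                                       nbins[active[a]], nbins[active[b]])
      }
    }
    g <- igraph::graph_from_adjacency_matrix(wmat + t(wmat), mode = "undirected",
                                             weighted = TRUE)
    tree <- igraph::mst(g, weights = -igraph::E(g)$weight)
    parent <- rep(NA_integer_, na)     # index into `active`, NA = root
    bf <- igraph::bfs(tree, root = 1, father = TRUE)
    parent_raw <- as.integer(bf$father)
    parent[!is.na(parent_raw)] <- parent_raw[!is.na(parent_raw)]
    # CPT per feature: P(bin | class, parent bin); root gets 1-d table
    model$parent <- parent
    model$cpt <- lapply(seq_len(na), function(a) {
      if (is.na(parent[a])) return(cpt_1d(bins[[a]], d$y, nbins[active[a]], s))
      np <- nbins[active[parent[a]]]
      ni <- nbins[active[a]]
      arr <- array(s, dim = c(ni, np, 2L))
      for (cl in 0:1) {
        sel <- d$y == cl
        arr[, , cl + 1L] <- arr[, , cl + 1L] +
          table(factor(bins[[a]][sel], levels = seq_len(ni)),
                factor(bins[[parent[a]]][sel], levels = seq_len(np)))
      }
      log(sweep(arr, c(2L, 3L), apply(arr, c(2L, 3L), sum), "/"))
    })
  }
  learner$model <- model
  record_fit(learner, d$X, d$y, seed)
}

#' @export
score.bayesnet_learner <- function(learner, X, ...) {
  X <- check_scoring_input(learner, X)
  m <- learner$model
  n <- nrow(X)
  l0 <- rep(m$log_prior[1L], n)
  l1 <- rep(m$log_prior[2L], n)
  if (length(m$active) > 0L) {
    binned <- lapply(seq_along(m$active), function(a)
      bin_feature(X[, m$active[a]], m$cuts[[m$active[a]]]))
    for (a in seq_along(m$active)) {
      b <- binned[[a]]
      if (m$structure == "naive" || is.na(m$parent[a])) {
        l0 <- l0 + m$cpt[[a]][cbind(b, 1L)]
        l1 <- l1 + m$cpt[[a]][cbind(b, 2L)]
      } else {
        bp <- binned[[m$parent[a]]]
        l0 <- l0 + m$cpt[[a]][cbind(b, bp, 1L)]
        l1 <- l1 + m$cpt[[a]][cbind(b, bp, 2L)]
      }
    }
  }
  1 / (1 + exp(l0 - l1))
}
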