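# Synthetic labelled window datasets with plantable class signal.
#
# Windows are drawn i.i.d. from a background nucleotide composition
# (uniform by default) and the centre position is forced to C so every
# window satisfies the 41-nt centre-C convention. Class signal can be
# planted in positives through two mechanisms that exercise the two
# encoders independently:
#   * a positional consensus motif, copied into a fixed offset and then
#     corrupted per position with probability `noise` (a noisy position is
#     resampled uniformly over A/C/G/T, so a motif position matches its
#     consensus with probability 1 - 3/4 * noise) - positional signal for
#     the EIIP encoder;
#   * a dinucleotide log-enrichment map applied through a first-order
#     Markov background - compositional signal for the k-mer encoder.
# The defaults of generate_benchmark_shaped() plant an 8-nt motif at
# offset 8 with noise 0.2, which puts the Bayes-optimal accuracy of the
# two-class problem near 0.98.

#' Configuration for the synthetic window generator
#'
#' @param n_pos,n_neg Class sizes (positives carry the planted signal).
#' @param L Window length (odd; default 41).
#' @param motif Optional consensus string over A/C/G/T planted in
#'   positives; `NULL` disables positional signal.
#' @param motif_start 1-based start offset of the motif. The motif must
#'   fit inside the window, and if it overlaps the centre position its
#'   letter there must be C (the centre is forced to C in every window).
#' @param noise Per-position corruption probability of planted motif
#'   letters (a corrupted position is redrawn uniformly over A/C/G/T).
#' @param kmer_bias Optional named numeric vector of dinucleotide
#'   log-enrichments (e.g. `c(CG = 0.7)`) applied to positives through a
#'   first-order Markov chain; `NULL` disables compositional signal.
#' @param background Background nucleotide probabilities (named A/C/G/T).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config and seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pos, n_neg, L = 41L, motif = "GTACGTCA",
                             motif_start = 8L, noise = 0.2,
                             kmer_bias = NULL,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             seed = 1L) {
  L <- as.integer(L)
  if (L < 1L || L %% 2L == 0L) stop("window length L must be odd")
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background < 0)) {
    stop("background must be named probabilities over A/C/G/T")
  }
  background <- background / sum(background)
  if (!is.null(motif)) {
    motif <- toupper(motif)
    if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
    motif_start <- as.integer(motif_start)
    m_end <- motif_start + nchar(motif) - 1L
    if (motif_start < 1L || m_end > L) {
      stop("motif does not fit inside the window")
    }
    ctr <- centre_position(L)
    if (motif_start <= ctr && ctr <= m_end &&
        substr(motif, ctr - motif_start + 1L, ctr - motif_start + 1L) != "C") {
      stop("motif overlaps the centre position with a non-C letter")
    }
  }
  if (!is.null(kmer_bias)) {
    if (is.null(names(kmer_bias)) || any(nchar(names(kmer_bias)) != 2L) ||
        any(grepl("[^ACGT]", names(kmer_bias)))) {
      stop("kmer_bias must be named by dinucleotides over A/C/G/T")
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = L, motif = motif, motif_start = motif_start,
                 noise = noise, kmer_bias = kmer_bias,
                 background = background, seed = as.integer(seed)),
            class = "generator_config")
}

NUCS <- c("A", "C", "G", "T")

# n x L character matrix of background letters; first-order Markov when a
# dinucleotide bias map is supplied
draw_background <- function(n, L, background, kmer_bias = NULL) {
  if (is.null(kmer_bias)) {
    return(matrix(sample(NUCS, n * L, replace = TRUE, prob = background),
                  n, L))
  }
  trans <- matrix(rep(background, each = 4L), 4L, 4L,
                  dimnames = list(NUCS, NUCS))  # rows: previous nucleotide
  for (d in names(kmer_bias)) {
    a <- substr(d, 1L, 1L); b <- substr(d, 2L, 2L)
    trans[a, b] <- trans[a, b] * exp(kmer_bias[[d]])
  }
  trans <- trans / rowSums(trans)
  m <- matrix("", n, L)
  m[, 1L] <- sample(NUCS, n, replace = TRUE, prob = background)
  for (pos in 2L:L) {
    prev <- match(m[, pos - 1L], NUCS)
    u <- stats::runif(n)
    cum <- t(apply(trans, 1L, cumsum))
    m[, pos] <- NUCS[max.col(cum[prev, , drop = FALSE] >= u,
                             ties.method = "first")]
  }
  m
}

#' Generate a labelled synthetic window set
#'
#' Draws `n_pos` positive windows (background plus the configured planted
#' signal) and `n_neg` negative windows (background only), forces the
#' centre position to C in all of them, and returns them as a labelled
#' [window_set()] (positives first). Deterministic given the config.
#'
#' @param config A [generator_config()].
#' @return Labelled `window_set` of `n_pos + n_neg` windows.
#' @export
generate_windows <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    L <- config$L
    ctr <- centre_position(L)
    pos <- draw_background(config$n_pos, L, config$background,
                           config$kmer_bias)
    neg <- draw_background(config$n_neg, L, config$background)
    if (!is.null(config$motif)) {
      letters_m <- strsplit(config$motif, "", fixed = TRUE)[[1L]]
      cols <- config$motif_start + seq_along(letters_m) - 1L
      for (i in seq_along(cols)) {
        planted <- rep(letters_m[i], config$n_pos)
        corrupt <- stats::runif(config$n_pos) < config$noise
        planted[corrupt] <- sample(NUCS, sum(corrupt), replace = TRUE)
        pos[, cols[i]] <- planted
      }
    }
    pos[, ctr] <- "C"
    neg[, ctr] <- "C"
    window_set(
      c(sprintf("pos_%05d", seq_len(config$n_pos)),
        sprintf("neg_%05d", seq_len(config$n_neg))),
      c(apply(pos, 1L, paste, collapse = ""),
        apply(neg, 1L, paste, collapse = "")),
      rep(1:0, c(config$n_pos, config$n_neg)))
  })
}

#' Generate a benchmark-shaped train/test pair
#'
#' Emulates the shape of the published mouse 4mC benchmark: a balanced
#' training set of 746 + 746 windows and a balanced independent test set
#' of 160 + 160 windows, all 41 nt with the centre C, drawn from one
#' generator configuration at the default mid-strength signal (8-nt motif,
#' noise 0.2). Train and test ids are disjoint by construction.
#'
#' @param seed Integer seed; train and test use distinct derived seeds.
#' @param n_train_pos,n_train_neg,n_test_pos,n_test_neg Class sizes.
#' @param ... Signal overrides passed to [generator_config()] (e.g.
#'   `motif`, `noise`, `kmer_bias`).
#' @return List with labelled `window_set`s `train` and `test`.
#' @export
generate_benchmark_shaped <- function(seed = 1L, n_train_pos = 746L,
                                      n_train_neg = 746L, n_test_pos = 160L,
                                      n_test_neg = 160L, ...) {
  seed <- as.integer(seed)
  train <- generate_windows(
    generator_config(n_train_pos, n_train_neg, seed = seed, ...))
  test <- generate_windows(
    generator_config(n_test_pos, n_test_neg, seed = seed + 499979L, ...))
  train$id <- paste0("train_", train$id)
  test$id <- paste0("test_", test$id)
  list(train = train, test = test)
}
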