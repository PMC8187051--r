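# Sequence -> numeric feature encodings.
#
# Two schemes drive the predictor:
#   * Kmer: overlapping k-nucleotide composition. For a sequence of length
#     L the frequency of k-mer X is F(X) / (L - k + 1), where F(X) counts
#     overlapping occurrences; each k-block therefore sums to 1. Columns
#     are ordered lexicographically with A < C < G < T within each block,
#     blocks in ascending k. With k = 1..5 a window yields
#     4 + 16 + 64 + 256 + 1024 = 1364 features.
#   * EIIP: each nucleotide is replaced by its electron-ion interaction
#     pseudopotential (A 0.1260, C 0.1340, G 0.0806, T 0.1335), giving one
#     feature per position (41 for the standard window).
# The multifeature encoding concatenates Kmer(1..5) then EIIP: 1405
# dimensions at L = 41. No scaling or pseudocounts are applied.

#' EIIP values per nucleotide
#'
#' Electron-ion interaction pseudopotential of each DNA nucleotide, used as
#' a per-position numeric encoding.
#'
#' @format Named numeric vector over A, C, G, T.
#' @export
EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

check_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT symbols")
  seq
}

new_feature_vector <- function(values, scheme) {
  structure(values, scheme = scheme)
}

#' Overlapping k-mer composition of a sequence
#'
#' Counts every overlapping k-nucleotide in the sequence and divides by the
#' number of k-mer positions, `L - k + 1`. The resulting 4^k-vector is
#' nonnegative and sums to 1; entries are named by k-mer in lexicographic
#' order (A < C < G < T).
#'
#' @param seq A DNA string over A/C/G/T (or a single-window `window_set`).
#' @param k K-mer size, `1 <= k <= nchar(seq)`.
#' @return Named numeric vector of length `4^k` with attribute `scheme`.
#' @export
#' @examples
#' encode_kmer("AAACTAGTC", 2)[["AA"]]  # 2 of 8 dinucleotides -> 0.25
encode_kmer <- function(seq, k) {
  if (inherits(seq, "window_set")) seq <- seq$seq[1L]
  seq <- check_dna(seq)
  k <- as.integer(k)
  L <- nchar(seq)
  if (k < 1L || k > L) stop(sprintf("k = %d out of range for length %d", k, L))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  new_feature_vector(counts / (L - k + 1L), sprintf("kmer%d", k))
}

#' Concatenated k-mer composition over several k
#'
#' Concatenates [encode_kmer()] blocks in ascending k. With the default
#' `ks = 1:5` a window maps to a 1364-dimensional vector
#' (4 + 16 + 64 + 256 + 1024); each block sums to 1, so the whole vector
#' sums to `length(ks)`.
#'
#' @inheritParams encode_kmer
#' @param ks Integer vector of k values (default `1:5`).
#' @return Named numeric vector of length `sum(4^ks)`.
#' @export
encode_kmer_multi <- function(seq, ks = 1:5) {
  if (length(ks) == 0L) stop("`ks` must name at least one k")
  ks <- sort(unique(as.integer(ks)))
  new_feature_vector(
    unlist(lapply(ks, function(k) encode_kmer(seq, k))),
    paste0("kmer", paste(range(ks), collapse = "-")))
}

#' EIIP positional encoding of a sequence
#'
#' Replaces each nucleotide by its electron-ion interaction pseudopotential
#' ([EIIP_VALUES]), producing one feature per sequence position.
#'
#' @inheritParams encode_kmer
#' @return Numeric vector of length `nchar(seq)`, named `eiip_pos<i>`.
#' @export
#' @examples
#' encode_eiip("AACTG")  # 0.1260 0.1260 0.1340 0.1335 0.0806
encode_eiip <- function(seq) {
  if (inherits(seq, "window_set")) seq <- seq$seq[1L]
  seq <- check_dna(seq)
  v <- EIIP_VALUES[strsplit(seq, "", fixed = TRUE)[[1L]]]
  names(v) <- sprintf("eiip_pos%d", seq_len(nchar(seq)))
  new_feature_vector(v, "eiip")
}

#' Combined k-mer + EIIP multifeature encoding
#'
#' Concatenates the k-mer composition blocks (ascending k) and the EIIP
#' positional block, in that order. For a 41-nt window with the default
#' `ks = 1:5` the result has 1364 + 41 = 1405 dimensions.
#'
#' @inheritParams encode_kmer_multi
#' @return Named numeric vector of length `sum(4^ks) + nchar(seq)`.
#' @export
encode_multifeature <- function(seq, ks = 1:5) {
  new_feature_vector(c(encode_kmer_multi(seq, ks), encode_eiip(seq)),
                     "multifeature")
}

# ---- encoding scheme contract ------------------------------------------

#' Define an encoding scheme
#'
#' An encoding scheme bundles a name, a dimension function of the window
#' length and a per-sequence encoder, so third-party encodings can plug
#' into [encode_set()] and the stacking pipeline alongside the built-in
#' `"kmer"`, `"eiip"` and `"multifeature"` schemes. Encoders must be
#' deterministic and side-effect free, with a fixed column order.
#'
#' @param name Scheme name.
#' @param dim Function of the window length L returning the feature count.
#' @param encode Function mapping one DNA string to a named numeric vector.
#' @return An object of class `encoding_scheme`.
#' @export
encoding_scheme <- function(name, dim, encode) {
  stopifnot(is.character(name), is.function(dim), is.function(encode))
  structure(list(name = name, dim = dim, encode = encode),
            class = "encoding_scheme")
}

.scheme_registry <- new.env(parent = emptyenv())

#' Register an encoding scheme by name
#'
#' @param scheme An [encoding_scheme()].
#' @return Invisibly, the scheme.
#' @export
register_encoding_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  assign(scheme$name, scheme, envir = .scheme_registry)
  invisible(scheme)
}

#' Look up an encoding scheme
#'
#' @param name Scheme name (`"kmer"`, `"eiip"`, `"multifeature"` or a
#'   registered third-party scheme).
#' @param ks K values for the k-mer based schemes (default `1:5`).
#' @return An `encoding_scheme`.
#' @export
get_encoding_scheme <- function(name, ks = 1:5) {
  if (inherits(name, "encoding_scheme")) return(name)
  switch(name,
    kmer = encoding_scheme("kmer",
                           function(L) sum(4L^ks),
                           function(s) encode_kmer_multi(s, ks)),
    eiip = encoding_scheme("eiip",
                           function(L) L,
                           encode_eiip),
    multifeature = encoding_scheme("multifeature",
                                   function(L) sum(4L^ks) + L,
                                   function(s) encode_multifeature(s, ks)),
    {
      if (!exists(name, envir = .scheme_registry)) {
        stop("unknown encoding scheme: ", name)
      }
      get(name, envir = .scheme_registry)
    })
}

# ---- set-level encoding -------------------------------------------------

# vectorized fast paths for the built-in schemes
encode_set_kmer <- function(seqs, ks) {
  x <- Biostrings::DNAStringSet(seqs)
  L <- nchar(seqs[1L])
  blocks <- lapply(sort(unique(as.integer(ks))), function(k) {
    Biostrings::oligonucleotideFrequency(x, width = k) / (L - k + 1L)
  })
  do.call(cbind, blocks)
}

encode_set_eiip <- function(seqs) {
  L <- nchar(seqs[1L])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  m <- matrix(EIIP_VALUES[chars], nrow = length(seqs), ncol = L)
  colnames(m) <- sprintf("eiip_pos%d", seq_len(L))
  m
}

#' Encode a window set into a feature matrix
#'
#' Applies an encoding scheme to every window, producing an `n x dim`
#' matrix in window-set order with the scheme's canonical column names as
#' the manifest. The built-in schemes use vectorized paths; any registered
#' `encoding_scheme` is applied row-wise.
#'
#' @param ws A `window_set` of uniform length.
#' @param scheme Scheme name or `encoding_scheme` object
#'   (default `"multifeature"`).
#' @param ks K values forwarded to the k-mer schemes.
#' @return List with `X` (feature matrix, rownames = window ids), `y`
#'   (integer labels or `NULL`) and `scheme` (name).
#' @export
encode_set <- function(ws, scheme = "multifeature", ks = 1:5) {
  stopifnot(inherits(ws, "window_set"))
  if (length(ws) == 0L) stop("cannot encode an empty window set")
  sch <- get_encoding_scheme(scheme, ks)
  X <- switch(sch$name,
    kmer = encode_set_kmer(ws$seq, ks),
    eiip = encode_set_eiip(ws$seq),
    multifeature = cbind(encode_set_kmer(ws$seq, ks),
                         encode_set_eiip(ws$seq)),
    {
      proto <- sch$encode(ws$seq[1L])
      vals <- vapply(ws$seq, sch$encode, proto * 0, USE.NAMES = FALSE)
      if (is.matrix(vals)) t(vals) else
        matrix(vals, ncol = 1L, dimnames = list(NULL, names(proto)))
    })
  rownames(X) <- ws$id
  list(X = X, y = ws$label, scheme = sch$name)
}

#' Write a feature matrix to disk
#'
#' `"tsv"` writes tab-separated text with a header row from the column
#' manifest and full `%.17g` precision so numeric values round-trip
#' bit-exactly; `"rds"` writes a native binary file for speed.
#'
#' @param X Numeric matrix with column names.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"rds"`.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(X, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(X, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(X)), collapse = "\t"), con)
  body <- matrix(sprintf("%.17g", X), nrow = nrow(X))
  writeLines(paste(rownames(X), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"rds"`.
#' @return Numeric matrix with row and column names restored.
#' @export
read_feature_matrix <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  d <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(d[, -1L, drop = FALSE])
  rownames(X) <- d[[1L]]
  X
}
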