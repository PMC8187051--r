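# Fixed-length DNA windows: the unit of prediction. A window is a short
# fragment (default 41 nt) centred on a candidate cytosine; the centre
# position of a window of odd length L is (L + 1) / 2 (1-based).

#' Construct a window set
#'
#' A `window_set` holds an ordered collection of equal-length DNA windows
#' over the alphabet A/C/G/T, each with an identifier and an optional binary
#' label (1 = methylated site, 0 = background). Iteration order is stable
#' and preserves input order.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of DNA sequences (uppercased internally).
#' @param labels Optional integer vector of 0/1 labels, aligned with `seqs`.
#' @return An object of class `window_set` with elements `id`, `seq` and
#'   `label` (`NULL` when unlabelled).
#' @export
#' @examples
#' ws <- window_set("w1", paste(rep("ACGT", 10), collapse = ""))
window_set <- function(ids, seqs, labels = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length")
  }
  if (anyDuplicated(ids)) {
    stop("window ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("sequences contain non-ACGT symbols: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  if (length(seqs) > 0L && length(unique(nchar(seqs))) > 1L) {
    stop("all windows in a set must have equal length")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(seqs)) {
      stop("`labels` must align with `seqs`")
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be binary (0/1)")
    }
  }
  structure(list(id = ids, seq = seqs, label = labels), class = "window_set")
}

#' @export
length.window_set <- function(x) length(x$id)

#' @export
`[.window_set` <- function(x, i) {
  window_set(x$id[i], x$seq[i], if (!is.null(x$label)) x$label[i])
}

#' @export
c.window_set <- function(...) {
  parts <- list(...)
  labs <- lapply(parts, `[[`, "label")
  has_lab <- !vapply(labs, is.null, logical(1))
  if (any(has_lab) && !all(has_lab)) {
    stop("cannot combine labelled and unlabelled window sets")
  }
  window_set(
    unlist(lapply(parts, `[[`, "id")),
    unlist(lapply(parts, `[[`, "seq")),
    if (all(has_lab)) unlist(labs)
  )
}

#' @export
print.window_set <- function(x, ...) {
  L <- if (length(x) > 0L) nchar(x$seq[1L]) else 0L
  cat(sprintf("window_set: %d windows of length %d nt", length(x), L))
  if (!is.null(x$label)) {
    cat(sprintf(" (%d positive / %d negative)",
                sum(x$label == 1L), sum(x$label == 0L)))
  }
  cat("\n")
  invisible(x)
}

#' Window length of a set
#' @param ws A `window_set`.
#' @return Integer window length (0 for an empty set).
#' @export
window_length <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (length(ws) == 0L) return(0L)
  nchar(ws$seq[1L])
}

# centre position of an odd-length window, 1-based
centre_position <- function(L) (L + 1L) %/% 2L

#' Read DNA windows from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' [window_set()], applying per-record validation. Records may be labelled
#' uniformly via `label` (the per-file convention: one file of positives,
#' one of negatives) or individually via a two-column tab-separated sidecar
#' of `id<TAB>label`.
#'
#' By default the methylation-window convention is enforced: every record
#' must be 41 nt long with a C at position 21 (the centre). Records that
#' contain non-ACGT symbols or fail the convention are handled per
#' `policy`: `"strict"` aborts naming the offending record, `"drop"`
#' excludes it with a message and keeps the rest. A summary count of
#' accepted/dropped records is always reported.
#'
#' @param fasta_path Path to a FASTA file.
#' @param label Optional single 0/1 label applied to every record.
#' @param sidecar Optional path to a tab-separated `id<TAB>label` file;
#'   every FASTA record id must appear in it.
#' @param check_convention Enforce the 41-nt centre-C window convention
#'   (default `TRUE`). Turn off to read windows of other lengths.
#' @param window_length Expected window length when `check_convention` is
#'   on (default 41).
#' @param policy `"strict"` (default) or `"drop"`.
#' @return A `window_set`, in file order.
#' @export
read_windows <- function(fasta_path, label = NULL, sidecar = NULL,
                         check_convention = TRUE, window_length = 41L,
                         policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  recs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  names(seqs) <- NULL
  n_in <- length(seqs)
  if (n_in == 0L) stop("FASTA file contains no records: ", fasta_path)

  reject <- function(bad, why) {
    if (!any(bad)) return(bad)
    if (policy == "strict") {
      stop(sprintf("record '%s' %s", ids[which(bad)[1L]], why))
    }
    message(sprintf("read_windows: dropping %d record(s) (%s): %s",
                    sum(bad), why,
                    paste(utils::head(ids[bad], 5L), collapse = ", ")))
    bad
  }

  keep <- rep(TRUE, n_in)
  bad <- keep & grepl("[^ACGT]", seqs)
  keep <- keep & !reject(bad, "contains non-ACGT symbols")
  if (check_convention) {
    ctr <- centre_position(window_length)
    bad <- keep & (nchar(seqs) != window_length |
                     substr(seqs, ctr, ctr) != "C")
    keep <- keep & !reject(
      bad, sprintf("violates the %d-nt centre-C window convention",
                   window_length))
  }
  ids <- ids[keep]
  seqs <- seqs[keep]
  message(sprintf("read_windows: accepted %d of %d record(s) from %s",
                  length(seqs), n_in, basename(fasta_path)))
  if (length(seqs) == 0L) stop("no records left after validation")

  labels <- NULL
  if (!is.null(sidecar)) {
    sc <- utils::read.delim(sidecar, header = FALSE,
                            colClasses = c("character", "integer"),
                            col.names = c("id", "label"))
    missing_ids <- setdiff(ids, sc$id)
    if (length(missing_ids) > 0L) {
      stop("record id(s) absent from sidecar: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    labels <- sc$label[match(ids, sc$id)]
  } else if (!is.null(label)) {
    labels <- rep(as.integer(label), length(seqs))
  }
  window_set(ids, seqs, labels)
}

#' Write a window set to FASTA
#'
#' Writes the windows as a multi-record FASTA file; reading the file back
#' with [read_windows()] reproduces ids, sequences and order exactly.
#' Labels are not stored in FASTA; pass `sidecar_path` to also write an
#' `id<TAB>label` sidecar.
#'
#' @param ws A non-empty `window_set`.
#' @param fasta_path Output path.
#' @param sidecar_path Optional path for a tab-separated label sidecar
#'   (requires a labelled set).
#' @return Invisibly, `fasta_path`.
#' @export
write_windows <- function(ws, fasta_path, sidecar_path = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (length(ws) == 0L) stop("cannot write an empty window set")
  x <- Biostrings::DNAStringSet(ws$seq)
  names(x) <- ws$id
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(sidecar_path)) {
    if (is.null(ws$label)) stop("window set has no labels to write")
    utils::write.table(data.frame(ws$id, ws$label), sidecar_path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Extract candidate cytosine-centred windows from a longer sequence
#'
#' Scans a DNA sequence and cuts one unlabelled window of length
#' `2 * flank + 1` around every C whose flanks fit entirely inside the
#' sequence, i.e. every C at 1-based positions `flank + 1` to
#' `length - flank`. Window ids encode the source position so predictions
#' can be mapped back.
#'
#' @param seq A single DNA string over A/C/G/T.
#' @param flank Number of nucleotides on each side of the centre C
#'   (default 20, giving 41-nt windows).
#' @param id Prefix for window ids (default `"win"`).
#' @return A (possibly empty) unlabelled `window_set`.
#' @export
#' @examples
#' extract_candidate_windows("AACAA", flank = 2)
extract_candidate_windows <- function(seq, flank = 20L, id = "win") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT symbols")
  n <- nchar(seq)
  flank <- as.integer(flank)
  if (n < 2L * flank + 1L) {
    stop(sprintf("sequence of length %d too short for flank %d", n, flank))
  }
  centres <- which(strsplit(seq, "", fixed = TRUE)[[1L]] == "C")
  centres <- centres[centres >= flank + 1L & centres <= n - flank]
  if (length(centres) == 0L) {
    return(window_set(character(0), character(0)))
  }
  window_set(sprintf("%s_pos%d", id, centres),
             substring(seq, centres - flank, centres + flank))
}
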