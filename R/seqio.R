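#' Construct a set of short RNA sequences
#'
#' An `rna_set` is the package's basic container: parallel vectors of
#' identifiers and sequences over the alphabet {A,C,G,U}, plus a class label
#' for the whole set. Sequences are normalized on construction: uppercased
#' and with T mapped to U, so DNA- and RNA-style input are interchangeable.
#'
#' @param id character vector of identifiers (need not be unique).
#' @param seq character vector of sequences, same length as `id`.
#' @param label one of `"positive"`, `"negative"`, `"unlabeled"`.
#' @param normalize if `TRUE` (default) uppercase and map T to U.
#' @return An object of class `rna_set`.
#' @export
rna_set <- function(id, seq, label = c("unlabeled", "positive", "negative"),
                    normalize = TRUE) {
  label <- match.arg(label)
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length")
  }
  if (normalize) seq <- normalize_seq(seq)
  structure(list(id = id, seq = seq, label = label), class = "rna_set")
}

#' @export
length.rna_set <- function(x) length(x$seq)

#' @export
print.rna_set <- function(x, ...) {
  cat(sprintf("rna_set: %d sequences (%s)\n", length(x), x$label))
  if (length(x) > 0) {
    n <- min(length(x), 5L)
    for (i in seq_len(n)) cat(sprintf("  %s  %s\n", x$id[i], x$seq[i]))
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

#' @export
as.data.frame.rna_set <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, length = nchar(x$seq),
             stringsAsFactors = FALSE)
}

#' Subset an rna_set by index
#' @param x an `rna_set`.
#' @param i integer or logical index.
#' @return The subsetted `rna_set` (label preserved).
#' @export
subset_set <- function(x, i) {
  stopifnot(inherits(x, "rna_set"))
  rna_set(x$id[i], x$seq[i], label = x$label, normalize = FALSE)
}

#' Normalize sequence strings to the {A,C,G,U} alphabet
#'
#' Uppercases and maps T to U. No other substitution is made; characters
#' outside {A,C,G,T,U} survive normalization and are caught later by
#' [filter_ambiguous()].
#'
#' @param seq character vector.
#' @return normalized character vector.
#' @export
normalize_seq <- function(seq) {
  chartr("t", "U", chartr("T", "U", toupper(seq)))
}

#' Read a FASTA file into an rna_set
#'
#' Multi-line and single-line sequence bodies are accepted. Sequences are
#' uppercased and T is mapped to U; entry order is preserved and duplicate
#' headers are kept. The FASTA description after the first whitespace is
#' retained as part of the identifier but plays no role in deduplication.
#'
#' @param path path to a FASTA file.
#' @param label class label to attach to the set.
#' @return An `rna_set`.
#' @export
read_fasta <- function(path, label = "unlabeled") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  nonempty <- which(nzchar(trimws(first)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(rna_set(character(), character(), label = label))
  }
  if (!startsWith(trimws(first[nonempty[1]]), ">")) {
    stop(sprintf("FASTA parse error in %s at line %d: expected '>' header, got: %s",
                 path, nonempty[1], first[nonempty[1]]))
  }
  xs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  rna_set(names(xs), as.character(xs), label = label)
}

#' Write an rna_set to FASTA
#'
#' Sequences are written single-line so the file round-trips byte-for-byte
#' through [read_fasta()].
#'
#' @param x an `rna_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "rna_set"))
  if (length(x) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to ", path)
    return(invisible(path))
  }
  xs <- Biostrings::BStringSet(x$seq)
  names(xs) <- x$id
  w <- max(nchar(x$seq), 1L)
  Biostrings::writeXStringSet(xs, path, width = max(w, 80L))
  invisible(path)
}

#' Remove sequences containing undefined bases
#'
#' Any character outside {A,C,G,U} after normalization (N, IUPAC ambiguity
#' codes, gaps, ...) marks a record as ambiguous and it is dropped. The
#' number of removals is reported as a message and attached as the
#' `"n_removed"` attribute.
#'
#' @param x an `rna_set`.
#' @return The filtered `rna_set` with attribute `n_removed`.
#' @export
filter_ambiguous <- function(x) {
  stopifnot(inherits(x, "rna_set"))
  keep <- grepl("^[ACGU]+$", x$seq)
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " sequence(s) removed (undefined bases)")
  }
  out <- subset_set(x, keep)
  attr(out, "n_removed") <- n_removed
  out
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence string (exact
#' identity after normalization; identifiers are ignored). The number of
#' removals is attached as the `"n_removed"` attribute.
#'
#' @param x an `rna_set`.
#' @return The deduplicated `rna_set` with attribute `n_removed`.
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "rna_set"))
  keep <- !duplicated(x$seq)
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " duplicate sequence(s) removed")
  }
  out <- subset_set(x, keep)
  attr(out, "n_removed") <- n_removed
  out
}
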