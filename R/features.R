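NUCS <- c("A", "C", "G", "U")

# signed position labels in feature order: 5' window first, then 3' window
position_labels <- function(window) {
  c(as.character(seq_len(window)), as.character(-seq_len(window)))
}

# per-sequence nucleotide at signed position j (vectorized over sequences);
# j > 0 counts from the 5' end, j < 0 from the 3' end (-1 = last base)
chars_at <- function(seqs, j, lens = nchar(seqs)) {
  pos <- if (j > 0) rep.int(j, length(seqs)) else lens + 1L + j
  substr(seqs, pos, pos)
}

#' Build a position probability matrix over terminal windows
#'
#' For window `w`, positions 1..w index from the 5' end (1 = first base) and
#' -1..-w from the 3' end (-1 = last base). `probs[i, j]` is the fraction of
#' contributing sequences carrying nucleotide `i` at position `j`. Sequences
#' shorter than `w` are skipped (their count is reported); sequences shorter
#' than `2w` contribute the same base to an overlapping pair of positive and
#' negative positions, which is intentional: both windows are always fully
#' defined for every contributing sequence.
#'
#' @param x an `rna_set` whose sequences are over {A,C,G,U} (run
#'   [filter_ambiguous()] first).
#' @param window window width `w` (default 10, giving 2w = 20 positions).
#' @param pseudocount additive count per (nucleotide, position) cell
#'   (default 0: zero cells are handled downstream by the zero-score guard
#'   of [score_matrix()] instead of smoothing).
#' @return An object of class `ppm`: a 4 x 2w matrix (rows A,C,G,U; columns
#'   the signed positions) with attributes `window`, `n_sequences`
#'   (contributing count) and `n_skipped`.
#' @export
build_ppm <- function(x, window = 10L, pseudocount = 0) {
  stopifnot(inherits(x, "rna_set"), window >= 1L, pseudocount >= 0)
  lens <- nchar(x$seq)
  keep <- lens >= window
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " sequence(s) shorter than window ", window, " skipped")
  }
  seqs <- x$seq[keep]
  lens <- lens[keep]
  n <- length(seqs)
  if (n == 0L) stop("no sequences long enough for window ", window)

  labels <- position_labels(window)
  probs <- matrix(0, nrow = 4L, ncol = 2L * window,
                  dimnames = list(NUCS, labels))
  for (k in seq_along(labels)) {
    j <- as.integer(labels[k])
    ch <- chars_at(seqs, j, lens)
    cnt <- table(factor(ch, levels = NUCS))
    probs[, k] <- (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }
  structure(probs, window = as.integer(window), n_sequences = n,
            n_skipped = n_skipped, class = c("ppm", "matrix"))
}

#' Log2-odds score matrix from positive and negative PPMs
#'
#' `S(i, j) = log2(P_ij / N_ij)` where `P` and `N` are the positive- and
#' negative-class position probabilities. A zero score is assigned whenever
#' `P_ij` or `N_ij` is zero: a zero cell usually reflects limited sampling,
#' not infinite evidence, so the guard replaces +/-Inf by an uninformative 0.
#' `S` is also exactly 0 wherever `P_ij == N_ij`.
#'
#' @param pos `ppm` built from positive sequences.
#' @param neg `ppm` built from negative sequences, same window.
#' @return An object of class `score_matrix`: 4 x 2w numeric matrix with
#'   attribute `window`.
#' @export
score_matrix <- function(pos, neg) {
  stopifnot(inherits(pos, "ppm"), inherits(neg, "ppm"))
  if (attr(pos, "window") != attr(neg, "window")) {
    stop("window mismatch: ", attr(pos, "window"), " vs ", attr(neg, "window"))
  }
  s <- matrix(0, nrow = nrow(pos), ncol = ncol(pos), dimnames = dimnames(pos))
  ok <- pos > 0 & neg > 0
  s[ok] <- log2(pos[ok] / neg[ok])
  structure(s, window = attr(pos, "window"),
            class = c("score_matrix", "matrix"))
}

new_feature_matrix <- function(values, ids, labels, type) {
  structure(list(values = values, ids = ids, labels = labels, type = type),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d sequences x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$type))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Encode sequences as one-hot-masked PPM log-odds features
#'
#' Each sequence becomes an 8w-vector indexed by (nucleotide, position):
#' the entry for feature "jN" is `S(N, j)` if the sequence carries
#' nucleotide N at position j, and 0 otherwise — a one-hot encoding of the
#' terminal windows weighted by the discriminative score of the observed
#' base. With `binary = TRUE` the indicator itself (0/1) is used instead of
#' the score, for sensitivity analysis. Feature names follow the "jN"
#' convention: "1U", "10C", "-1A".
#'
#' @param x an `rna_set`; sequences shorter than the window are skipped
#'   (count reported via the `n_skipped` attribute and a message).
#' @param m a `score_matrix`.
#' @param binary use 0/1 indicators instead of score weights.
#' @return A `feature_matrix` with 8w columns; `labels` is +1/-1 filled from
#'   the set's label (NA for unlabeled sets).
#' @export
ppm_featurize <- function(x, m, binary = FALSE) {
  stopifnot(inherits(x, "rna_set"), inherits(m, "score_matrix"))
  window <- attr(m, "window")
  lens <- nchar(x$seq)
  keep <- lens >= window
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " sequence(s) shorter than window ", window, " skipped")
  }
  seqs <- x$seq[keep]
  lens <- lens[keep]
  plabels <- position_labels(window)
  fnames <- as.vector(vapply(plabels, function(p) paste0(p, NUCS),
                             character(4)))
  vals <- matrix(0, nrow = length(seqs), ncol = length(fnames),
                 dimnames = list(NULL, fnames))
  for (k in seq_along(plabels)) {
    j <- as.integer(plabels[k])
    ch <- chars_at(seqs, j, lens)
    for (n in seq_along(NUCS)) {
      hit <- ch == NUCS[n]
      col <- (k - 1L) * 4L + n
      vals[hit, col] <- if (binary) 1 else m[NUCS[n], k]
    }
  }
  lab <- switch(x$label, positive = 1L, negative = -1L, NA_integer_)
  out <- new_feature_matrix(vals, x$id[keep],
                            rep(lab, length(seqs)), type = "ppm")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Encode sequences as k-mer frequency features
#'
#' For each word size m in 1..kmax, the frequency of every m-mer over
#' {A,C,G,U} is the overlapping occurrence count divided by L - m + 1.
#' The dimension is sum over m of 4^m (1364 for kmax = 5).
#'
#' @param x an `rna_set` of unambiguous sequences, all of length >= kmax.
#' @param kmax largest word size (default 5).
#' @return A `feature_matrix` with the k-mer strings as feature names.
#' @export
kmer_featurize <- function(x, kmax = 5L) {
  stopifnot(inherits(x, "rna_set"), kmax >= 1L)
  if (length(x) == 0L) stop("empty sequence set")
  if (any(nchar(x$seq) < kmax)) {
    stop("all sequences must be at least kmax = ", kmax, " nt long")
  }
  rs <- Biostrings::RNAStringSet(x$seq)
  blocks <- lapply(seq_len(kmax), function(m) {
    cnt <- Biostrings::oligonucleotideFrequency(rs, width = m)
    cnt / (nchar(x$seq) - m + 1L)
  })
  vals <- do.call(cbind, blocks)
  lab <- switch(x$label, positive = 1L, negative = -1L, NA_integer_)
  new_feature_matrix(vals, x$id, rep(lab, length(x)), type = "kmer")
}

#' Column-wise combination of two feature matrices
#'
#' Concatenates the feature columns of two matrices built from the same
#' sequences in the same order; names are prefixed by feature class
#' ("ppm_", "kmer_") so they stay unique.
#'
#' @param a,b `feature_matrix` objects over identical sequences.
#' @return A combined `feature_matrix` of type "combined".
#' @export
combine_features <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (ncol(b$values) == 0L) return(a)
  if (ncol(a$values) == 0L) return(b)
  if (nrow(a$values) != nrow(b$values) || !identical(a$ids, b$ids)) {
    stop("feature matrices cover different sequences")
  }
  va <- a$values
  vb <- b$values
  colnames(va) <- paste0(a$type, "_", colnames(va))
  colnames(vb) <- paste0(b$type, "_", colnames(vb))
  new_feature_matrix(cbind(va, vb), a$ids, a$labels, type = "combined")
}

#' Stack feature matrices row-wise
#'
#' Row-binds matrices over the same feature columns (e.g. the featurized
#' positive and negative sets before F-score ranking or training).
#'
#' @param ... `feature_matrix` objects with identical feature names.
#' @param deparse.level unused (base signature).
#' @return A `feature_matrix` with the rows of all inputs.
#' @export
rbind.feature_matrix <- function(..., deparse.level = 1) {
  ms <- list(...)
  fn <- colnames(ms[[1]]$values)
  for (m in ms[-1]) {
    if (!identical(colnames(m$values), fn)) {
      stop("feature matrices have different feature columns")
    }
  }
  new_feature_matrix(do.call(base::rbind, lapply(ms, `[[`, "values")),
                     unlist(lapply(ms, `[[`, "ids")),
                     unlist(lapply(ms, `[[`, "labels")),
                     type = ms[[1]]$type)
}

#' Rank features by F-score
#'
#' The F-score of feature i is the squared separation of the class means
#' from the grand mean, divided by the summed within-class sample variances:
#' \deqn{F(i) = \frac{(\bar x_i^{+} - \bar x_i)^2 + (\bar x_i^{-} - \bar x_i)^2}
#'   {\frac{1}{n_+ - 1}\sum_k (x_{k,i}^{+} - \bar x_i^{+})^2 +
#'    \frac{1}{n_- - 1}\sum_k (x_{k,i}^{-} - \bar x_i^{-})^2}}
#' Larger F-scores indicate better discrimination. A zero denominator with a
#' positive numerator (perfect separation with zero within-class variance)
#' is flagged `Inf` and ranked first; 0/0 (a constant feature) gives F = 0.
#'
#' @param fm a labeled `feature_matrix` with at least 2 samples per class.
#' @return A data.frame sorted by decreasing F with columns `feature`, `F`,
#'   `mean_all`, `mean_pos`, `mean_neg`, `infinite` plus attributes `n_pos`,
#'   `n_neg`.
#' @export
fscore_rank <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  lab <- fm$labels
  if (anyNA(lab)) stop("feature matrix must be labeled")
  pos <- fm$values[lab == 1L, , drop = FALSE]
  neg <- fm$values[lab == -1L, , drop = FALSE]
  n_pos <- nrow(pos)
  n_neg <- nrow(neg)
  if (n_pos < 2L || n_neg < 2L) stop("need at least 2 samples per class")

  m_all <- colMeans(fm$values)
  m_pos <- colMeans(pos)
  m_neg <- colMeans(neg)
  num <- (m_pos - m_all)^2 + (m_neg - m_all)^2
  den <- apply(pos, 2, stats::var) + apply(neg, 2, stats::var)

  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  out <- data.frame(feature = colnames(fm$values), F = f,
                    mean_all = m_all, mean_pos = m_pos, mean_neg = m_neg,
                    infinite = is.infinite(f),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$F), ]
  rownames(out) <- NULL
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

#' Write a feature matrix as TSV
#'
#' Layout: first column `id`, second column `label` (+1/-1/NA), then the
#' named feature columns.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @param header optional provenance comment lines (written with a leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path, header = NULL) {
  df <- data.frame(id = fm$ids, label = fm$labels, fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix TSV written by [write_feature_tsv()]
#' @param path input path.
#' @return A `feature_matrix`.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  new_feature_matrix(vals, as.character(df$id), as.integer(df$label),
                     type = "loaded")
}

#' Write a score matrix as TSV (rows A,C,G,U; columns -w..-1, 1..w)
#' @param m a `score_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(m, path) {
  w <- attr(m, "window")
  ord <- c(as.character(-rev(seq_len(w))), as.character(seq_len(w)))
  df <- data.frame(nucleotide = rownames(m), m[, ord, drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
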