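#' Length histogram of a sequence set
#'
#' @param x an `rna_set`.
#' @return Named integer vector: names are lengths (nt), values are counts,
#'   sorted by length.
#' @export
length_histogram <- function(x) {
  stopifnot(inherits(x, "rna_set"))
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(nchar(x$seq))
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(as.integer(names(out)))]
}

as_length_histogram <- function(target) {
  if (is.null(names(target)) || any(!nzchar(names(target)))) {
    stop("a length histogram must be a named vector (names = lengths in nt)")
  }
  lens <- as.integer(names(target))
  counts <- as.integer(target)
  if (any(is.na(lens)) || any(lens < 1L)) stop("invalid lengths in histogram")
  if (any(is.na(counts)) || any(counts < 0L)) stop("invalid counts in histogram")
  stats::setNames(counts, lens)[order(lens)]
}

#' Fragment a sequence pool into non-overlapping segments
#'
#' Cuts each pool sequence left to right into contiguous, non-overlapping
#' segments whose lengths are drawn (seeded) from the lengths present in
#' `target`, with probability proportional to the remaining demand for each
#' length. Cutting stops when the demand is exhausted or no demanded length
#' fits the remainder of a sequence. With `oversample > 1` the demand is
#' inflated so downstream filtering and sampling have spare candidates; a
#' shortfall against the *original* target is still an error.
#'
#' Segment identifiers encode their origin as `sourceid:start-end`
#' (1-based, inclusive), so non-overlap is verifiable from the output.
#'
#' @param pool an `rna_set` of (typically long) source sequences.
#' @param target named integer vector: demanded count per length (nt).
#' @param seed integer seed; cutting is deterministic given the seed.
#' @param oversample demand inflation factor (default 1 = cut exactly the
#'   demanded counts when capacity allows).
#' @return An `rna_set` of segments with at least `target[l]` segments of
#'   every demanded length `l`.
#' @export
fragment_pool <- function(pool, target, seed, oversample = 1) {
  stopifnot(inherits(pool, "rna_set"))
  target <- as_length_histogram(target)
  target <- target[target > 0L]
  if (length(target) == 0L) {
    return(rna_set(character(), character(), label = "negative"))
  }
  lens <- as.integer(names(target))
  demand <- as.integer(ceiling(target * oversample))

  ids <- character(0)
  seqs <- character(0)
  withr::with_seed(seed, {
    for (s in seq_along(pool$seq)) {
      if (sum(demand) == 0L) break
      src <- pool$seq[s]
      L <- nchar(src)
      pos <- 1L
      repeat {
        remaining <- L - pos + 1L
        fit <- which(demand > 0L & lens <= remaining)
        if (length(fit) == 0L) break
        pick <- if (length(fit) == 1L) fit else {
          sample(fit, 1L, prob = demand[fit])
        }
        l <- lens[pick]
        ids <- c(ids, sprintf("%s:%d-%d", pool$id[s], pos, pos + l - 1L))
        seqs <- c(seqs, substr(src, pos, pos + l - 1L))
        demand[pick] <- demand[pick] - 1L
        pos <- pos + l
      }
    }
  })

  out <- rna_set(ids, seqs, label = "negative", normalize = FALSE)
  produced <- length_histogram(out)
  short <- target - ifelse(is.na(produced[names(target)]), 0L,
                           produced[names(target)])
  short[is.na(short)] <- target[is.na(short)]
  if (any(short > 0L)) {
    bad <- short[short > 0L]
    stop("pool cannot supply enough segments; deficient lengths: ",
         paste(sprintf("%s nt (missing %d)", names(bad), bad), collapse = ", "))
  }
  out
}

#' Shuffle each sequence of a set (composition-preserving)
#'
#' Each sequence is replaced by a uniformly random permutation of its own
#' characters, destroying positional and structural signal while preserving
#' the nucleotide multiset exactly. A single uniform permutation already
#' gives every arrangement equal probability; `rounds > 1` composes
#' additional independent permutations for literal reproduction of
#' repeated-shuffle protocols and does not change the distribution.
#'
#' @param x an `rna_set`.
#' @param seed integer seed.
#' @param rounds number of composed permutations per sequence (default 1).
#' @return An `rna_set` with shuffled sequences (ids and label preserved).
#' @export
shuffle_sequences <- function(x, seed, rounds = 1L) {
  stopifnot(inherits(x, "rna_set"), rounds >= 1L)
  withr::with_seed(seed, {
    shuffled <- vapply(x$seq, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (r in seq_len(rounds)) ch <- sample(ch)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  rna_set(x$id, shuffled, label = x$label, normalize = FALSE)
}

#' Sample candidates to match a target length histogram exactly
#'
#' For every length `l`, draws exactly `target[l]` candidate sequences of
#' length `l` uniformly at random without replacement. The output length
#' histogram equals `target` exactly; any deficit is an error.
#'
#' @param candidates an `rna_set`.
#' @param target named integer vector: demanded count per length.
#' @param seed integer seed.
#' @return An `rna_set` with histogram identical to `target`.
#' @export
sample_matched <- function(candidates, target, seed) {
  stopifnot(inherits(candidates, "rna_set"))
  target <- as_length_histogram(target)
  target <- target[target > 0L]
  if (length(target) == 0L) {
    return(rna_set(character(), character(), label = candidates$label))
  }
  cand_len <- nchar(candidates$seq)
  lens <- as.integer(names(target))
  avail <- vapply(lens, function(l) sum(cand_len == l), integer(1))
  if (any(avail < target)) {
    bad <- which(avail < target)
    stop("not enough candidates; deficient lengths: ",
         paste(sprintf("%d nt (need %d, have %d)",
                       lens[bad], target[bad], avail[bad]), collapse = ", "))
  }
  idx <- integer(0)
  withr::with_seed(seed, {
    for (k in seq_along(lens)) {
      pool_k <- which(cand_len == lens[k])
      take <- if (length(pool_k) == 1L) pool_k else {
        sample(pool_k, target[k])
      }
      idx <- c(idx, take[seq_len(target[k])])
    }
  })
  subset_set(candidates, sort(idx))
}

#' Build a shuffled, length-matched negative set ("random" background)
#'
#' Pipeline: fragment the pool into non-overlapping segments (with spare
#' capacity), shuffle every segment to destroy any functional structure,
#' discard any candidate identical to a positive sequence, then sample
#' without replacement so the negative length histogram equals the
#' positives' exactly. The result has the same size as `positives`.
#'
#' @param pool an `rna_set` of source non-coding RNA sequences.
#' @param positives the positive `rna_set` whose length distribution is
#'   matched.
#' @param seed integer seed controlling cutting, shuffling and sampling.
#' @param shuffle_rounds permutations composed per segment (default 1; see
#'   [shuffle_sequences()]).
#' @return A negative `rna_set` with `length()` equal to the positives'.
#' @export
build_random_negatives <- function(pool, positives, seed, shuffle_rounds = 1L) {
  target <- length_histogram(positives)
  cand <- fragment_pool(pool, target, seed = seed, oversample = 2)
  cand <- shuffle_sequences(cand, seed = seed + 1L, rounds = shuffle_rounds)
  cand <- subset_set(cand, !(cand$seq %in% positives$seq))
  cand$label <- "negative"
  sample_matched(cand, target, seed = seed + 2L)
}

#' Build an unshuffled, length-matched fragment negative set
#'
#' Same pipeline as [build_random_negatives()] but without the shuffling
#' step: segments are verbatim substrings of the pool sequences, emulating
#' degraded fragments of longer small RNAs.
#'
#' @inheritParams build_random_negatives
#' @return A negative `rna_set` with `length()` equal to the positives'.
#' @export
build_fragment_negatives <- function(pool, positives, seed) {
  target <- length_histogram(positives)
  cand <- fragment_pool(pool, target, seed = seed, oversample = 2)
  cand <- subset_set(cand, !(cand$seq %in% positives$seq))
  cand$label <- "negative"
  sample_matched(cand, target, seed = seed + 2L)
}
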