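#' Specification for the synthetic short-RNA generator
#'
#' The generator emulates the data shapes the classifier is designed for:
#' sequence lengths concentrated at 20-21 nt, a strong positive-class
#' preference for U at the first (5') position and A at the last (3')
#' position, and near-uniform background composition elsewhere and in the
#' negatives. The default signal strengths (0.8 / 0.7) are package choices
#' strong enough to separate classes reliably at n = 155 + 155; they are not
#' measured frequencies from any real dataset.
#'
#' @param n_pos,n_neg number of positive / negative sequences.
#' @param length_weights named probability vector over lengths (default
#'   20 and 21 nt, equal weight).
#' @param pos_first_U probability that a positive starts with U (else the
#'   first base is drawn from the background renormalized over {A,C,G}).
#' @param pos_last_A probability that a positive ends with A (else drawn
#'   from the background renormalized over {C,G,U}).
#' @param background named probability vector over A,C,G,U (default
#'   uniform).
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_pos = 155L, n_neg = 155L,
                           length_weights = c("20" = 0.5, "21" = 0.5),
                           pos_first_U = 0.8, pos_last_A = 0.7,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, U = 0.25)) {
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be probabilities summing to 1")
    }
  }
  if (n_pos < 0L || n_neg < 0L) stop("n_pos and n_neg must be >= 0")
  check_probs(length_weights, "length_weights")
  check_probs(background, "background")
  if (!identical(sort(names(background)), sort(NUCS))) {
    stop("background must be named over A, C, G, U")
  }
  for (p in c(pos_first_U, pos_last_A)) {
    if (p < 0 || p > 1) stop("positional preferences must be in [0, 1]")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_weights = length_weights,
                 pos_first_U = pos_first_U, pos_last_A = pos_last_A,
                 background = background[NUCS]),
            class = "generator_spec")
}

sample_background <- function(n, background) {
  sample(NUCS, n, replace = TRUE, prob = background)
}

#' Generate a labeled synthetic dataset
#'
#' Lengths are drawn from `spec$length_weights`. Negatives are i.i.d. from
#' the background at every position. Positives are i.i.d. from the
#' background except: position 1 is U with probability `pos_first_U`
#' (otherwise drawn from the background renormalized over {A,C,G}), and the
#' last position is A with probability `pos_last_A` (renormalized over
#' {C,G,U} otherwise). Deterministic given the seed.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed.
#' @return A list with elements `positives` and `negatives` (`rna_set`s).
#' @export
generate_dataset <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  bg <- spec$background
  lens_support <- as.integer(names(spec$length_weights))

  gen_one <- function(L, positive) {
    ch <- sample_background(L, bg)
    if (positive) {
      if (stats::runif(1) < spec$pos_first_U) {
        ch[1] <- "U"
      } else {
        alt <- bg[c("A", "C", "G")]
        ch[1] <- sample(c("A", "C", "G"), 1, prob = alt / sum(alt))
      }
      if (stats::runif(1) < spec$pos_last_A) {
        ch[L] <- "A"
      } else {
        alt <- bg[c("C", "G", "U")]
        ch[L] <- sample(c("C", "G", "U"), 1, prob = alt / sum(alt))
      }
    }
    paste(ch, collapse = "")
  }

  withr::with_seed(seed, {
    pos_lens <- if (spec$n_pos > 0) {
      sample(lens_support, spec$n_pos, replace = TRUE,
             prob = spec$length_weights)
    } else integer(0)
    neg_lens <- if (spec$n_neg > 0) {
      sample(lens_support, spec$n_neg, replace = TRUE,
             prob = spec$length_weights)
    } else integer(0)
    pos_seq <- vapply(pos_lens, gen_one, character(1), positive = TRUE)
    neg_seq <- vapply(neg_lens, gen_one, character(1), positive = FALSE)
  })

  list(
    positives = rna_set(sprintf("pos_%04d", seq_len(spec$n_pos)), pos_seq,
                        label = "positive", normalize = FALSE),
    negatives = rna_set(sprintf("neg_%04d", seq_len(spec$n_neg)), neg_seq,
                        label = "negative", normalize = FALSE)
  )
}

#' Generate a pool of long background sequences
#'
#' Convenience source material for [build_random_negatives()] and
#' [build_fragment_negatives()] when no real non-coding RNA pool is at hand:
#' `n` i.i.d. background sequences of the given length.
#'
#' @param n number of sequences.
#' @param length length of each sequence (nt).
#' @param background named probability vector over A,C,G,U.
#' @param seed integer seed.
#' @return An `rna_set`.
#' @export
generate_pool <- function(n = 10L, length = 1000L,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, U = 0.25),
                          seed = 1L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample_background(length, background[NUCS]), collapse = "")
    }, character(1))
  })
  rna_set(sprintf("pool_%03d", seq_len(n)), seqs, label = "unlabeled",
          normalize = FALSE)
}
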