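test_that("build_ppm counts terminal positions, with short-sequence overlap", {
  s <- rna_set(c("a", "b"), c("UA", "UG"))
  p <- build_ppm(s, window = 2)
  expect_equal(p["U", "1"], 1.0)
  expect_equal(p["A", "2"], 0.5)
  expect_equal(p["G", "2"], 0.5)
  expect_equal(p["A", "-1"], 0.5)  # j = 2 and j = -1 overlap at length 2
  expect_equal(p["U", "-2"], 1.0)
  expect_equal(attr(p, "n_sequences"), 2L)
})

test_that("PPM columns sum to 1 for random inputs", {
  for (seed in 1:5) {
    s <- random_rna_set(40, lens = 15:25, seed = seed)
    p <- build_ppm(s, window = 10)
    expect_equal(unname(colSums(p)), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("sequences shorter than the window are skipped, empty set errors", {
  s <- rna_set(c("short", "long"), c("ACGU", strrep("ACGU", 5)))
  expect_message(p <- build_ppm(s, window = 10), "1 sequence")
  expect_equal(attr(p, "n_skipped"), 1L)
  expect_equal(attr(p, "n_sequences"), 1L)
  expect_error(suppressMessages(build_ppm(s, window = 25)),
               "no sequences long enough")
})

test_that("pseudocounts smooth zero cells without breaking normalization", {
  s <- rna_set(c("a", "b"), c("UA", "UG"))
  p <- build_ppm(s, window = 2, pseudocount = 1)
  expect_gt(p["C", "1"], 0)
  expect_equal(unname(colSums(p)), rep(1, 4), tolerance = 1e-9)
})

test_that("score matrix is log2(P/N) with zero guards", {
  s1 <- rna_set(c("a", "b"), c("UA", "UG"))
  s2 <- rna_set(c("c", "d"), c("UA", "AG"))
  p <- build_ppm(s1, 2); n <- build_ppm(s2, 2)
  m <- score_matrix(p, n)
  expect_equal(m["U", "1"], log2(1 / 0.5))     # 1.0 = log2(2)
  expect_equal(m["A", "2"], 0)                 # P == N
  expect_equal(m["G", "1"], 0)                 # P = 0 -> guard
  expect_equal(m["C", "1"], 0)                 # both zero
  # self-comparison limit: identically zero
  expect_true(all(score_matrix(p, p) == 0))
  # window mismatch
  expect_error(score_matrix(p, build_ppm(s2, 1)), "window mismatch")
})

test_that("score matrix agrees with direct formula evaluation", {
  for (seed in 1:5) {
    pos <- build_ppm(random_rna_set(30, seed = seed, label = "positive"), 10)
    neg <- build_ppm(random_rna_set(30, seed = seed + 100,
                                    label = "negative"), 10)
    m <- score_matrix(pos, neg)
    manual <- ifelse(pos > 0 & neg > 0, log2(pos / neg), 0)
    expect_equal(unclass(m), unclass(manual),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ppm_featurize emits one-hot-masked scores named jN", {
  pos <- random_rna_set(30, lens = 20:21, seed = 1, label = "positive")
  neg <- random_rna_set(30, lens = 20:21, seed = 2, label = "negative")
  sm <- score_matrix(build_ppm(pos, 10), build_ppm(neg, 10))
  fm <- ppm_featurize(pos, sm)
  expect_equal(ncol(fm$values), 80L)
  expect_true(all(c("1U", "10C", "-1A") %in% colnames(fm$values)))
  expect_equal(fm$labels, rep(1L, 30))
  # at most one nonzero slot per position (scores can themselves be 0)
  for (p in c("1", "-1", "5", "-7")) {
    block <- fm$values[, paste0(p, c("A", "C", "G", "U"))]
    expect_true(all(rowSums(block != 0) <= 1))
  }
  # brute-force per-character lookup oracle
  expect_equal(unname(fm$values), unname(oracle_ppm_features(pos$seq, sm)),
               tolerance = 1e-12)
})

test_that("an all-zero score matrix featurizes to all zeros; binary mode to 0/1", {
  s <- random_rna_set(10, lens = 20:21, seed = 3, label = "positive")
  p <- build_ppm(s, 10)
  zero <- score_matrix(p, p)
  expect_true(all(ppm_featurize(s, zero)$values == 0))
  bin <- ppm_featurize(s, zero, binary = TRUE)
  expect_true(all(bin$values %in% c(0, 1)))
  expect_equal(unname(rowSums(bin$values)), rep(20, 10))  # one hit per position
})

test_that("kmer_featurize computes overlapping frequencies with L-m+1 denominators", {
  s <- rna_set("a", "ACGU", label = "unlabeled")
  fm <- kmer_featurize(s, kmax = 1)
  expect_equal(unname(fm$values[1, c("A", "C", "G", "U")]), rep(0.25, 4))
  # dimension: sum_{m=1..5} 4^m = 1364
  s2 <- random_rna_set(8, lens = 20:21, seed = 5)
  fm5 <- kmer_featurize(s2, kmax = 5)
  expect_equal(ncol(fm5$values), 1364L)
  # per-m frequencies sum to 1
  off <- 0L
  for (m in 1:5) {
    block <- fm5$values[, off + seq_len(4^m), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 8), tolerance = 1e-9)
    off <- off + 4L^m
  }
})

test_that("kmer frequencies match a sliding-window counting oracle", {
  s <- random_rna_set(5, lens = 15:18, seed = 6)
  fm <- kmer_featurize(s, kmax = 3)
  for (i in seq_along(s$seq)) {
    L <- nchar(s$seq[i])
    for (kmer in c("A", "GG", "ACG", "UUU")) {
      m <- nchar(kmer)
      cnt <- sum(vapply(seq_len(L - m + 1), function(p) {
        substr(s$seq[i], p, p + m - 1) == kmer
      }, logical(1)))
      expect_equal(unname(fm$values[i, kmer]), cnt / (L - m + 1))
    }
  }
})

test_that("F-score matches hand-computed and degenerate cases", {
  fm <- qirnapred:::new_feature_matrix(
    matrix(c(1, 0, 0, 0), ncol = 1, dimnames = list(NULL, "f")),
    ids = letters[1:4], labels = c(1L, 1L, -1L, -1L), type = "ppm")
  expect_equal(fscore_rank(fm)$F, 0.25)
  # constant feature: 0/0 -> 0
  fm$values[] <- 3
  expect_equal(fscore_rank(fm)$F, 0)
  # perfect separation, zero variance -> flagged infinite, ranked first
  fm$values[, 1] <- c(1, 1, 0, 0)
  out <- fscore_rank(fm)
  expect_true(is.infinite(out$F[1]) && out$infinite[1])
})

test_that("F-score agrees with a naive two-pass oracle on random matrices", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      np <- sample(5:25, 1); nn <- sample(5:25, 1); d <- sample(3:20, 1)
      vals <- matrix(rnorm((np + nn) * d), nrow = np + nn, ncol = d)
    })
    colnames(vals) <- sprintf("f%02d", seq_len(d))
    fm <- qirnapred:::new_feature_matrix(
      vals, ids = sprintf("s%d", 1:(np + nn)),
      labels = c(rep(1L, np), rep(-1L, nn)), type = "ppm")
    out <- fscore_rank(fm)
    for (j in seq_len(d)) {
      nm <- colnames(vals)[j]
      expect_equal(out$F[out$feature == nm],
                   oracle_fscore(vals[1:np, j], vals[np + 1:nn, j]),
                   tolerance = 1e-9)
    }
    expect_true(!is.unsorted(rev(out$F)))
    expect_equal(attr(out, "n_pos"), np)
  }
})

test_that("combine_features concatenates columns with unique prefixed names", {
  s <- random_rna_set(12, lens = 20:21, seed = 8, label = "positive")
  p <- build_ppm(s, 10)
  sm <- score_matrix(p, p)
  a <- ppm_featurize(s, sm)
  b <- kmer_featurize(s, kmax = 5)
  ab <- combine_features(a, b)
  expect_equal(ncol(ab$values), 80L + 1364L)
  expect_false(anyDuplicated(colnames(ab$values)) > 0)
  expect_true(all(startsWith(colnames(ab$values)[1:80], "ppm_")))
  # mismatched rows error
  expect_error(combine_features(a, kmer_featurize(subset_set(s, 1:5), 5)),
               "different sequences")
})

test_that("terminal-position features dominate the F-score ranking on signal data", {
  ds <- generate_dataset(generator_spec(), seed = 42)
  sm <- score_matrix(build_ppm(ds$positives, 10), build_ppm(ds$negatives, 10))
  fm <- rbind(ppm_featurize(ds$positives, sm), ppm_featurize(ds$negatives, sm))
  top5 <- fscore_rank(fm)$feature[1:5]
  expect_true("1U" %in% top5)
  expect_true("-1A" %in% top5)
})

test_that("feature matrix TSV round trip preserves values, ids and labels", {
  ds <- generate_dataset(generator_spec(n_pos = 10, n_neg = 10), seed = 3)
  sm <- score_matrix(build_ppm(ds$positives, 10), build_ppm(ds$negatives, 10))
  fm <- rbind(ppm_featurize(ds$positives, sm), ppm_featurize(ds$negatives, sm))
  f <- tempfile(fileext = ".tsv")
  write_feature_tsv(fm, f, header = "test")
  back <- read_feature_tsv(f)
  expect_equal(back$ids, fm$ids)
  expect_equal(back$labels, fm$labels)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-12)
  expect_equal(colnames(back$values), colnames(fm$values))
})
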