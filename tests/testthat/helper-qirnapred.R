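# shared test utilities: all fixtures are built in code

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# nucleotide composition of one sequence as a named count vector
base_composition <- function(seq) {
  table(factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "U")))
}

random_rna_set <- function(n, lens = 15:25, seed = 1, label = "unlabeled") {
  withr::with_seed(seed, {
    seqs <- vapply(sample(lens, n, replace = TRUE), function(L) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
  rna_set(sprintf("s%03d", seq_len(n)), seqs, label = label)
}

# brute-force per-character featurization oracle for ppm_featurize
oracle_ppm_features <- function(seqs, sm) {
  w <- attr(sm, "window")
  nucs <- c("A", "C", "G", "U")
  labs <- c(as.character(1:w), as.character(-(1:w)))
  fnames <- unlist(lapply(labs, function(p) paste0(p, nucs)))
  out <- matrix(0, length(seqs), length(fnames),
                dimnames = list(NULL, fnames))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in labs) {
      j <- as.integer(p)
      base <- if (j > 0) ch[j] else ch[length(ch) + 1 + j]
      out[i, paste0(p, base)] <- sm[base, p]
    }
  }
  out
}

# naive two-pass F-score oracle, one feature at a time
oracle_fscore <- function(xpos, xneg) {
  np <- length(xpos); nn <- length(xneg)
  m <- mean(c(xpos, xneg)); mp <- mean(xpos); mn <- mean(xneg)
  num <- (mp - m)^2 + (mn - m)^2
  den <- sum((xpos - mp)^2) / (np - 1) + sum((xneg - mn)^2) / (nn - 1)
  if (den > 0) num / den else if (num > 0) Inf else 0
}

# O(n^2) AUC oracle: concordant pairs, ties count 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
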