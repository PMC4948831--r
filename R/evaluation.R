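#' Confusion-matrix performance metrics
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)` and accuracy
#' `Ac = (TP+TN)/(TP+FP+TN+FN)` are returned as percentages; the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`
#' lies in [-1, 1]. When any MCC marginal is zero the coefficient is
#' undefined; it is reported as 0 with `mcc_flagged = TRUE`.
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts.
#' @return A list of class `metric_set` with elements `Sn`, `Sp`, `Ac`
#'   (percent), `MCC`, `mcc_flagged` and the four counts.
#' @export
metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all confusion counts are zero")
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  ac <- 100 * (tp + tn) / sum(counts)
  marg <- c(tp + fn, tn + fp, tp + fp, tn + fn)
  if (all(marg > 0)) {
    mcc <- (tp * tn - fn * fp) / sqrt(prod(marg))
    flagged <- FALSE
  } else {
    mcc <- 0
    flagged <- TRUE
  }
  structure(list(Sn = sn, Sp = sp, Ac = ac, MCC = mcc, mcc_flagged = flagged,
                 TP = tp, FP = fp, TN = tn, FN = fn),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn = %.2f%%  Sp = %.2f%%  Ac = %.2f%%  MCC = %.4f%s\n",
              x$Sn, x$Sp, x$Ac, x$MCC,
              if (x$mcc_flagged) " (flagged: zero marginal)" else ""))
  cat(sprintf("  TP = %d  FP = %d  TN = %d  FN = %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

confusion_counts <- function(scores, labels, cutoff) {
  pred <- classify(scores, cutoff)
  list(tp = sum(pred == 1L & labels == 1L),
       fp = sum(pred == 1L & labels == -1L),
       tn = sum(pred == -1L & labels == -1L),
       fn = sum(pred == -1L & labels == 1L))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct scores (predicting
#' positive at score >= threshold) and returns the resulting (FPR, TPR)
#' points, anchored at (0,0) and (1,1), with the AUC by the trapezoidal
#' rule. Tied scores move along a diagonal, so the AUC equals the
#' tie-corrected Mann-Whitney concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric vector.
#' @param labels vector in {+1, -1}, same length.
#' @return A list of class `roc_curve`: `points` (data.frame threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each distinct score (threshold = that score)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == -1L)[last]
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Build stratified cross-validation fold assignments
#'
#' Samples are partitioned into k folds; with stratification each class is
#' split as evenly as possible across folds (fold sizes within a class
#' differ by at most one). `k = n` gives leave-one-out.
#'
#' @param labels vector in {+1, -1}.
#' @param k number of folds (2..n), or the string "loo".
#' @param stratified stratify by class (default TRUE).
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(labels, k, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (identical(k, "loo")) k <- n
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be in 2..n")
  folds <- integer(n)
  withr::with_seed(seed, {
    if (stratified && k < n) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
  })
  folds
}

#' Cross-validated evaluation of the PPM / k-mer random-forest pipeline
#'
#' For each fold, position probability matrices and the log2-odds score
#' matrix are rebuilt from the training samples only (fold-local
#' featurization), both partitions are featurized with that matrix, a
#' random forest is trained on the training partition and the held-out
#' partition is scored. Held-out scores are pooled across folds into one
#' confusion matrix per cutoff (0.5 and the stringent 0.667) and one
#' ROC/AUC; per-fold accuracies are also reported. Leave-one-out is k-fold
#' with k equal to the sample count.
#'
#' `global_ppm = TRUE` reproduces the leaky variant in which the PPMs are
#' computed once from all samples; held-out statistics then contaminate the
#' features and the reported performance is optimistically biased — a
#' warning is issued.
#'
#' @param pos positive `rna_set`.
#' @param neg negative `rna_set`.
#' @param k folds (integer >= 2 or "loo").
#' @param features "ppm", "kmer" or "both".
#' @param window PPM window width (default 10).
#' @param kmax k-mer bound (default 5) when k-mer features are used.
#' @param n_trees,mtry forest size and per-split feature count.
#' @param seed integer seed driving fold assignment and per-fold training.
#' @param stratified stratify folds by class (default TRUE).
#' @param global_ppm compute PPMs from all data (leaky; default FALSE).
#' @param binary use binary one-hot PPM features.
#' @param cutoffs decision thresholds for the pooled confusion matrices.
#' @return A list of class `cv_report`: `scheme`, `k`, `n`, `scores`
#'   (pooled held-out data.frame id/label/score/fold), `metrics` (list per
#'   cutoff), `auc`, `roc`, `per_fold`.
#' @export
cross_validate <- function(pos, neg, k = 10L, features = c("ppm", "kmer", "both"),
                           window = 10L, kmax = 5L, n_trees = 500L,
                           mtry = NULL, seed = 1L, stratified = TRUE,
                           global_ppm = FALSE, binary = FALSE,
                           cutoffs = c(0.5, 0.667)) {
  stopifnot(inherits(pos, "rna_set"), inherits(neg, "rna_set"))
  features <- match.arg(features)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both positive and negative sets must be non-empty")
  }
  if (global_ppm) {
    warning("global_ppm = TRUE: held-out samples contribute to the PPMs; ",
            "reported performance is optimistically biased")
  }

  all_ids <- c(pos$id, neg$id)
  all_seq <- c(pos$seq, neg$seq)
  labels <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
  n <- length(labels)
  scheme <- if (identical(k, "loo") || identical(as.integer(k), n)) "loo"
            else paste0(k, "-fold")
  folds <- make_folds(labels, k, stratified = stratified, seed = seed)
  kk <- max(folds)

  build_fm <- function(idx, sm) {
    sp <- rna_set(all_ids[idx][labels[idx] == 1L],
                  all_seq[idx][labels[idx] == 1L],
                  label = "positive", normalize = FALSE)
    sn <- rna_set(all_ids[idx][labels[idx] == -1L],
                  all_seq[idx][labels[idx] == -1L],
                  label = "negative", normalize = FALSE)
    parts <- list()
    if (length(sp) > 0L) parts <- c(parts, list(featurize_one(sp, sm)))
    if (length(sn) > 0L) parts <- c(parts, list(featurize_one(sn, sm)))
    do.call(rbind, parts)
  }
  featurize_one <- function(s, sm) {
    switch(features,
      ppm = ppm_featurize(s, sm, binary = binary),
      kmer = kmer_featurize(s, kmax = kmax),
      both = combine_features(ppm_featurize(s, sm, binary = binary),
                              kmer_featurize(s, kmax = kmax)))
  }
  make_sm <- function(idx) {
    if (features == "kmer") return(NULL)
    ip <- idx[labels[idx] == 1L]
    in_ <- idx[labels[idx] == -1L]
    ppm_p <- build_ppm(rna_set(all_ids[ip], all_seq[ip],
                               label = "positive", normalize = FALSE), window)
    ppm_n <- build_ppm(rna_set(all_ids[in_], all_seq[in_],
                               label = "negative", normalize = FALSE), window)
    score_matrix(ppm_p, ppm_n)
  }

  sm_global <- if (global_ppm) make_sm(seq_len(n)) else NULL

  held <- vector("list", kk)
  per_fold <- vector("list", kk)
  for (f in seq_len(kk)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(labels[tr])) < 2L) {
      stop("fold ", f, " has a single class in training; ",
           "use stratified folds or fewer folds")
    }
    sm <- if (global_ppm) sm_global else make_sm(tr)
    fm_tr <- build_fm(tr, sm)
    fm_te <- build_fm(te, sm)
    model <- train_model(fm_tr, n_trees = n_trees, mtry = mtry,
                         seed = seed + f, score_mat = sm,
                         feature_type = features, kmax = kmax,
                         binary = binary)
    sc <- predict_scores(model, fm_te)
    held[[f]] <- data.frame(id = sc$id, label = fm_te$labels,
                            score = sc$score, fold = f,
                            stringsAsFactors = FALSE)
    acc <- mean(classify(sc$score, 0.5) == fm_te$labels)
    per_fold[[f]] <- data.frame(fold = f, n_test = length(te),
                                accuracy = acc)
  }
  pooled <- do.call(rbind, held)
  per_fold <- do.call(rbind, per_fold)

  mets <- lapply(cutoffs, function(ct) {
    cc <- confusion_counts(pooled$score, pooled$label, ct)
    metrics(cc$tp, cc$fp, cc$tn, cc$fn)
  })
  names(mets) <- sprintf("cutoff_%s", cutoffs)
  roc <- roc_auc(pooled$score, pooled$label)

  structure(list(scheme = scheme, k = kk, n = n, features = features,
                 window = window, seed = seed, scores = pooled,
                 metrics = mets, auc = roc$auc, roc = roc$points,
                 per_fold = per_fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation, %d samples, %s features, AUC = %.4f\n",
              x$scheme, x$n, x$features, x$auc))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %s: ", sub("cutoff_", "cutoff ", nm)))
    print(x$metrics[[nm]])
  }
  invisible(x)
}

#' Serialize a cv_report to JSON
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @param extra named list of provenance fields (seed, command, version)
#'   merged into the top level.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(report, path, extra = list()) {
  mets <- lapply(report$metrics, function(m) {
    m[c("Sn", "Sp", "Ac", "MCC", "TP", "FP", "TN", "FN")]
  })
  obj <- c(extra, list(
    scheme = report$scheme, k = report$k, n = report$n,
    features = report$features, window = report$window,
    seed = report$seed, auc = report$auc, metrics = mets,
    per_fold = report$per_fold,
    held_out = report$scores
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
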