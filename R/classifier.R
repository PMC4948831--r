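MODEL_VERSION <- 1L

#' Train a random-forest classifier on a feature matrix
#'
#' A bagged ensemble of decision trees with random feature subsets at each
#' split; class-probability scores are the fraction of trees voting
#' positive. The out-of-bag (OOB) accuracy — each tree's bootstrap leaves
#' about e^-1 of the training samples unused, which serve as an internal
#' test set — is recorded on the model. Training is deterministic given the
#' seed. The score matrix used to build the features (if any) is bundled so
#' novel sequences are featurized with the training-time PPM statistics,
#' never with statistics of the query set.
#'
#' @param fm a labeled `feature_matrix` with both classes present.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried at each split; default `floor(sqrt(d))`.
#' @param seed integer seed.
#' @param balanced if `TRUE`, downsample each bootstrap to the minority
#'   class size (default `FALSE`: no reweighting).
#' @param score_mat the `score_matrix` used to featurize `fm` (bundle it for
#'   any PPM-featurized model so prediction is self-consistent).
#' @param feature_type one of "ppm", "kmer", "combined" — how new sequences
#'   are featurized at prediction time.
#' @param kmax k-mer word size bound when `feature_type` is not "ppm".
#' @param binary whether PPM features were binary indicators.
#' @return An object of class `qirna_model`.
#' @export
train_model <- function(fm, n_trees = 500L, mtry = NULL, seed = 1L,
                        balanced = FALSE, score_mat = NULL,
                        feature_type = fm$type, kmax = 5L, binary = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  lab <- fm$labels
  if (anyNA(lab)) stop("feature matrix must be labeled")
  if (length(unique(lab)) < 2L) stop("training data contain a single class")
  y <- factor(ifelse(lab == 1L, "pos", "neg"), levels = c("neg", "pos"))
  d <- ncol(fm$values)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(d)))
  if (mtry > d) stop("mtry exceeds the feature count")

  sampsize <- if (balanced) rep(min(table(y)), 2L) else nrow(fm$values)
  forest <- withr::with_seed(seed, randomForest::randomForest(
    x = fm$values, y = y, ntree = n_trees, mtry = mtry,
    sampsize = sampsize, strata = if (balanced) y else NULL
  ))
  oob <- 1 - unname(forest$err.rate[n_trees, "OOB"])

  structure(list(
    forest = forest,
    feature_names = colnames(fm$values),
    score_mat = score_mat,
    window = if (!is.null(score_mat)) attr(score_mat, "window") else NULL,
    feature_type = feature_type,
    kmax = kmax,
    binary = binary,
    n_trees = n_trees,
    mtry = mtry,
    seed = seed,
    oob_accuracy = oob,
    version = MODEL_VERSION
  ), class = "qirna_model")
}

#' @export
print.qirna_model <- function(x, ...) {
  cat(sprintf(
    "qirna_model: %d trees, mtry %d, %d %s features, OOB accuracy %.4f\n",
    x$n_trees, x$mtry, length(x$feature_names), x$feature_type,
    x$oob_accuracy))
  invisible(x)
}

featurize_for_model <- function(model, x) {
  fm <- switch(model$feature_type,
    ppm = ppm_featurize(x, model$score_mat, binary = model$binary),
    kmer = kmer_featurize(x, kmax = model$kmax),
    combined = combine_features(
      ppm_featurize(x, model$score_mat, binary = model$binary),
      kmer_featurize(subset_set(x, nchar(x$seq) >= model$window),
                     kmax = model$kmax)),
    stop("unknown feature type: ", model$feature_type)
  )
  if (!identical(colnames(fm$values), model$feature_names)) {
    stop("feature names/order differ from the model's training features")
  }
  fm
}

#' Score sequences with a trained model
#'
#' The score of a sequence is the fraction of trees voting positive, in
#' [0, 1]. Featurization uses the model's bundled training-time score
#' matrix. Sequences shorter than the model window cannot be featurized;
#' they are skipped, reported with a message, and listed in the `skipped`
#' attribute of the result — never silently dropped.
#'
#' @param model a `qirna_model`.
#' @param x an `rna_set` (or an already-built `feature_matrix` whose columns
#'   match the model).
#' @return A data.frame with columns `id` and `score`, with attribute
#'   `skipped` (ids of too-short sequences).
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "qirna_model"))
  if (inherits(x, "feature_matrix")) {
    if (!identical(colnames(x$values), model$feature_names)) {
      stop("feature names/order differ from the model's training features")
    }
    fm <- x
    skipped <- character(0)
  } else {
    stopifnot(inherits(x, "rna_set"))
    minlen <- if (!is.null(model$window)) model$window else model$kmax
    short <- nchar(x$seq) < minlen
    skipped <- x$id[short]
    if (length(skipped) > 0) {
      message(length(skipped), " sequence(s) shorter than ", minlen,
              " nt skipped")
    }
    fm <- featurize_for_model(model, subset_set(x, !short))
  }
  p <- stats::predict(model$forest, fm$values, type = "prob")[, "pos"]
  out <- data.frame(id = fm$ids, score = unname(p), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Convert scores to class labels at a cutoff
#'
#' Label +1 iff score >= cutoff (ties go positive). The default cutoff is
#' 0.5; 0.667 is the documented stringent option that trades sensitivity for
#' specificity when nominating candidates for experimental follow-up.
#'
#' @param scores numeric vector of vote fractions in [0, 1].
#' @param cutoff decision threshold in [0, 1].
#' @return Integer vector of labels in {+1, -1}.
#' @export
classify <- function(scores, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single number in [0, 1]")
  }
  ifelse(scores >= cutoff, 1L, -1L)
}

#' Save a trained model to disk
#' @param model a `qirna_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qirna_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a trained model from disk
#'
#' Round trip preserves predictions bit-for-bit. Files that are not models
#' written by [save_model()], or models from an incompatible version, raise
#' an explicit error rather than returning garbage.
#'
#' @param path path written by [save_model()].
#' @return A `qirna_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!inherits(obj, "qirna_model")) {
    stop("file is not a qirna_model: ", path)
  }
  if (is.null(obj$version) || obj$version != MODEL_VERSION) {
    stop("model version mismatch: file has ", obj$version %||% "none",
         ", this package expects ", MODEL_VERSION)
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
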