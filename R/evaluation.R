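# Cross-validated model evaluation: fold assignment, the rank-sum AUC,
# 0%/10% training omission rates, the candidate feature x RM grid, and the
# multi-key model ranking.

#' Balanced random fold assignment
#'
#' Partitions presences into k folds whose sizes differ by at most one;
#' deterministic under a fixed seed. The background is not split: every fold
#' reuses the full background sample.
#'
#' @param occ an \linkS4class{OccurrenceSet} or an integer count of presences.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per presence
#' @export
makeFolds <- function(occ, k = 10L, seed = 1L) {
  n <- if (is(occ, "OccurrenceSet")) nOccurrences(occ) else as.integer(occ)
  if (k < 2L) stop("need k >= 2 folds")
  if (n < k) stop("fewer presences (", n, ") than folds (", k, ")")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  sample(rep(seq_len(k), length.out = n))
}

#' Rank-sum AUC
#'
#' Mann-Whitney estimator of the area under the ROC curve: the probability
#' that a random presence outscores a random background point, with ties
#' counted 0.5. Equals the trapezoidal area under the empirical ROC.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return AUC in [0, 1]
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  if (!length(presenceScores) || !length(backgroundScores))
    stop("empty score vector")
  m <- length(presenceScores); n <- length(backgroundScores)
  r <- rank(c(presenceScores, backgroundScores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Test omission rate at a training-percentile threshold
#'
#' The threshold is the \code{percentile} lower empirical quantile of the
#' training presence scores (0% = the training minimum; 10% = the smallest
#' order statistic at or above which 90% of training presences lie, i.e. the
#' ceiling(0.1 m)-th order statistic, no interpolation). The omission rate
#' is the fraction of test presences scoring strictly below the threshold.
#'
#' @param trainScores training presence scores.
#' @param testScores held-out presence scores.
#' @param percentile training percentile, 0 or 10 in standard use.
#' @return omission rate in [0, 1]
#' @export
omissionRate <- function(trainScores, testScores, percentile = 10) {
  if (!length(trainScores) || !length(testScores))
    stop("empty score vector")
  thr <- trainingThreshold(trainScores, percentile)
  mean(testScores < thr)
}

trainingThreshold <- function(trainScores, percentile) {
  stopifnot(percentile >= 0, percentile < 100)
  if (percentile == 0) return(min(trainScores))
  k <- ceiling(percentile / 100 * length(trainScores))
  sort(trainScores)[max(k, 1L)]
}

#' Cross-validate one candidate feature configuration
#'
#' For each fold: fit on the remaining folds' presences with the full
#' background, score the held-out presences and the background, and compute
#' the test AUC plus omission rates at the 0% and 10% training thresholds
#' (training scores come from the fold's own training presences). Returns
#' the per-fold means, the AUC standard deviation, and the pooled held-out
#' scores (used later for thresholding).
#'
#' @param presenceValues covariate matrix at presence points.
#' @param backgroundValues covariate matrix at background points.
#' @param config a \code{\link{makeFeatureConfig}}.
#' @param folds fold ids from \code{\link{makeFolds}}.
#' @param tol,maxit solver controls.
#' @return one-row data.frame (features, rm, auc_cv_mean, auc_cv_sd, or0,
#'   or10) with the pooled held-out scores in
#'   \code{attr(, "test_scores")} and background scores in
#'   \code{attr(, "background_scores")}
#' @export
crossValidate <- function(presenceValues, backgroundValues, config, folds,
                          tol = 1e-6, maxit = 50000L) {
  presenceValues <- as.matrix(presenceValues)
  stopifnot(length(folds) == nrow(presenceValues))
  ks <- sort(unique(folds))
  aucs <- or0s <- or10s <- numeric(length(ks))
  test_scores <- numeric(nrow(presenceValues))
  bg_scores_sum <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    hold <- folds == k
    model <- tryCatch(
      fitMaxent(presenceValues[!hold, , drop = FALSE], backgroundValues,
                config, tol = tol, maxit = maxit),
      error = function(e) stop("fold ", k, ": ", conditionMessage(e)))
    sc_train <- scoreValues(model, presenceValues[!hold, , drop = FALSE])
    sc_test <- scoreValues(model, presenceValues[hold, , drop = FALSE])
    sc_bg <- scoreValues(model, backgroundValues)
    aucs[i] <- aucScore(sc_test, sc_bg)
    or0s[i] <- omissionRate(sc_train, sc_test, 0)
    or10s[i] <- omissionRate(sc_train, sc_test, 10)
    test_scores[hold] <- sc_test
    bg_scores_sum <- if (is.null(bg_scores_sum)) sc_bg
                     else bg_scores_sum + sc_bg
  }
  class_order <- c("L", "Q", "P", "T", "H")
  rec <- data.frame(
    features = paste(class_order[sort(match(config$classes, class_order))],
                     collapse = ""),
    rm = config$rm,
    auc_cv_mean = mean(aucs), auc_cv_sd = sd(aucs),
    or0 = mean(or0s), or10 = mean(or10s),
    stringsAsFactors = FALSE)
  attr(rec, "test_scores") <- test_scores
  attr(rec, "background_scores") <- bg_scores_sum / length(ks)
  rec
}

#' Evaluate a grid of candidate models
#'
#' Cartesian product of feature-class sets and regularization multipliers,
#' all evaluated with the same shared fold assignment. The standard
#' full-scale candidate set is \code{featureSets = c("LQPH", "LQPTH",
#' "LQH", "LQP", "LH", "LQPT")} with \code{rms = c(1.0, 1.5, 2.0)}.
#'
#' @param presenceValues,backgroundValues covariate matrices.
#' @param featureSets character vector of feature-class strings.
#' @param rms numeric vector of regularization multipliers.
#' @param folds shared fold ids from \code{\link{makeFolds}}.
#' @param nHingeKnots,nThresholdKnots knot counts per candidate.
#' @param tol,maxit solver controls.
#' @return data.frame of evaluation records (unsorted), one per candidate,
#'   with per-candidate held-out scores in \code{attr(, "scores")}
#' @export
runCandidateGrid <- function(presenceValues, backgroundValues,
                             featureSets = c("LQPH", "LQPTH", "LQH", "LQP",
                                             "LH", "LQPT"),
                             rms = c(1.0, 1.5, 2.0),
                             folds,
                             nHingeKnots = 20L, nThresholdKnots = 20L,
                             tol = 1e-6, maxit = 50000L) {
  stopifnot(length(featureSets) >= 1, length(rms) >= 1)
  recs <- list()
  scores <- list()
  for (fs in featureSets) for (rm in rms) {
    cfg <- makeFeatureConfig(fs, rm, nHingeKnots, nThresholdKnots)
    rec <- crossValidate(presenceValues, backgroundValues, cfg, folds,
                         tol = tol, maxit = maxit)
    key <- paste0(rec$features, "_", format(rm))
    scores[[key]] <- list(test = attr(rec, "test_scores"),
                          background = attr(rec, "background_scores"))
    attr(rec, "test_scores") <- NULL
    attr(rec, "background_scores") <- NULL
    recs[[key]] <- rec
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}

#' Rank candidate models
#'
#' Stable sort by 10% training omission rate ascending, then 0% training
#' omission rate ascending, then cross-validated AUC descending — low
#' omission wins, AUC breaks remaining ties.
#'
#' @param records data.frame with columns or10, or0, auc_cv_mean (e.g. from
#'   \code{\link{runCandidateGrid}}).
#' @return the records, reordered, with a \code{rank} column prepended
#' @export
rankModels <- function(records) {
  stopifnot(nrow(records) >= 1)
  ord <- order(records$or10, records$or0, -records$auc_cv_mean)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Write evaluation records as CSV
#'
#' Columns mirror the usual candidate-comparison table: Features, RM, test
#' AUC with SD, omission rates at 0% and 10%, and rank if present.
#'
#' @param records data.frame of evaluation records.
#' @param path output CSV path.
#' @export
writeEvaluationRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
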