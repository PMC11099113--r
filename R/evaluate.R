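#' Split samples into training and test cohorts
#'
#' Deterministic under the seed.  By default the test-set size is
#' \code{floor((1 - trainFraction) * n)}; pass \code{nTest} to fix it
#' exactly (the study used 237 training / 100 test of 337).  Optional
#' stratification draws the test fraction within each stratum, keeping
#' per-stratum proportions within one sample of the global fraction.
#'
#' @param sampleIds character vector of sample ids.
#' @param trainFraction training fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @param stratifyBy optional factor (length of \code{sampleIds}) to
#'   stratify on, e.g. the outcome.
#' @param nTest optional explicit test-set size, overriding the fraction
#'   arithmetic.
#' @return list with \code{train} and \code{test} id vectors.
#' @export
splitCohort <- function(sampleIds, trainFraction = 0.7, seed = 1L,
                        stratifyBy = NULL, nTest = NULL) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  n <- length(sampleIds)
  set.seed(seed)
  if (!is.null(stratifyBy)) {
    stopifnot(length(stratifyBy) == n)
    testIdx <- unlist(lapply(split(seq_len(n), stratifyBy), function(ix) {
      k <- floor((1 - trainFraction) * length(ix))
      sample(ix, k)
    }), use.names = FALSE)
  } else {
    k <- if (!is.null(nTest)) nTest else floor((1 - trainFraction) * n)
    testIdx <- sample.int(n, k)
  }
  if (length(testIdx) == 0 || length(testIdx) == n)
    stop("split yields an empty cohort")
  list(train = sampleIds[-sort(testIdx)], test = sampleIds[sort(testIdx)])
}

#' Area under the ROC curve (percent)
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' outscores a random negative, ties contributing one half.  Requires both
#' classes present.
#'
#' @param scores numeric scores or probabilities.
#' @param labels binary labels (0/1); pairs with \code{NA} in either are
#'   dropped.
#' @return AUC as a percent in [0, 100].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))   # 100
#' @export
rocAuc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  U <- sum(r[labels == 1]) - npos * (npos + 1) / 2
  100 * U / (npos * nneg)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified percentile bootstrap: positives and negatives are resampled
#' separately (so no resample is degenerate), the AUC recomputed, and the
#' 2.5/97.5 percentiles returned.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param nBoot bootstrap replicates (default 2000, minimum 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return numeric \code{c(low, high)} in percent.
#' @export
aucCi <- function(scores, labels, nBoot = 2000, seed = 1L, level = 0.95) {
  if (nBoot < 100) stop("nBoot must be >= 100")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  set.seed(seed)
  stat <- vapply(seq_len(nBoot), function(b) {
    sp <- sample(pos, replace = TRUE)
    sn <- sample(neg, replace = TRUE)
    rocAuc(c(sp, sn), rep(c(1, 0), c(length(sp), length(sn))))
  }, 0)
  unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Confusion metrics and risk-group toxicity at a probability cutoff
#'
#' A sample is classified high-toxicity when its predicted probability is at
#' or above the cutoff.  Returns the confusion counts, percent accuracy,
#' sensitivity and specificity, and the observed toxicity proportion within
#' the predicted high- and low-risk groups.
#'
#' @param probabilities predicted probabilities in [0, 1].
#' @param labels binary outcomes (NA dropped pairwise).
#' @param cutoff probability cutoff, strictly inside (0, 1).
#' @return list with \code{confusion} (TP, FP, TN, FN), \code{accuracy},
#'   \code{sensitivity}, \code{specificity}, \code{high_group_toxicity},
#'   \code{low_group_toxicity} (percents), \code{n_used}, \code{cutoff}.
#' @export
confusionAtCutoff <- function(probabilities, labels, cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly inside (0, 1)")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must be in [0, 1]")
  ok <- !is.na(probabilities) & !is.na(labels)
  p <- probabilities[ok]; y <- labels[ok]
  pred <- as.integer(p >= cutoff)
  TP <- sum(pred == 1 & y == 1); FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0); FN <- sum(pred == 0 & y == 1)
  n <- TP + FP + TN + FN
  list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
       accuracy = 100 * (TP + TN) / n,
       sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
       high_group_toxicity = if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_,
       low_group_toxicity = if (TN + FN > 0) 100 * FN / (TN + FN) else NA_real_,
       n_used = n, cutoff = cutoff)
}

#' Choose a probability cutoff targeting a given accuracy
#'
#' Evaluates the accuracy at the midpoints between consecutive distinct
#' predicted probabilities (plus outer midpoints toward 0 and 1) and returns
#' the cutoff whose training accuracy is closest to the target; ties are
#' broken toward higher sensitivity, then toward the lower cutoff.
#'
#' @param probabilities training predicted probabilities.
#' @param labels training outcomes.
#' @param targetAccuracy target accuracy in (0, 1) (study setting: around
#'   0.80).
#' @return the chosen cutoff.
#' @export
chooseCutoff <- function(probabilities, labels, targetAccuracy = 0.8) {
  stopifnot(targetAccuracy > 0, targetAccuracy < 1)
  ok <- !is.na(probabilities) & !is.na(labels)
  if (!any(ok)) stop("no complete probability/label pairs")
  p <- probabilities[ok]; y <- labels[ok]
  u <- sort(unique(p))
  grid <- unique(c((head(u, -1) + u[-1]) / 2,
                   max(1e-6, u[1] / 2),
                   min(1 - 1e-6, (u[length(u)] + 1) / 2)))
  grid <- grid[grid > 0 & grid < 1]
  acc <- sens <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cm <- confusionAtCutoff(p, y, grid[i])
    acc[i] <- cm$accuracy
    sens[i] <- cm$sensitivity
  }
  dev <- abs(acc - 100 * targetAccuracy)
  cand <- which(dev == min(dev))
  cand <- cand[sens[cand] == max(sens[cand])]
  grid[min(cand)]
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p (delegates to \code{stats::t.test}).
#'
#' @param a,b numeric samples (each n \eqn{\ge} 2; at least one with
#'   nonzero variance).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) stop("zero variance in both groups")
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Full evaluation report for one cohort
#'
#' Computes AUC with bootstrap CI, the confusion metrics at a cutoff, and
#' the risk-group toxicity shares -- the per-cohort row of the performance
#' table.
#'
#' @param probabilities predicted probabilities.
#' @param labels observed outcomes (NA excluded).
#' @param cutoff probability cutoff.
#' @param nBoot,seed bootstrap settings for the CI.
#' @return list (an EvalReport): \code{auc}, \code{auc_ci}, plus all fields
#'   of \code{\link{confusionAtCutoff}}.
#' @export
evalReport <- function(probabilities, labels, cutoff, nBoot = 2000,
                       seed = 1L) {
  rep <- confusionAtCutoff(probabilities, labels, cutoff)
  rep$auc <- rocAuc(probabilities, labels)
  rep$auc_ci <- aucCi(probabilities, labels, nBoot = nBoot, seed = seed)
  rep
}

#' Accept or reject a validated model
#'
#' A model is accepted iff the training AUC strictly exceeds 80\% and the
#' held-out test AUC strictly exceeds 60\%.
#'
#' @param trainReport,testReport EvalReports (lists with an \code{auc}
#'   percent field).
#' @return \code{"accepted"} or \code{"rejected"}.
#' @export
acceptModel <- function(trainReport, testReport) {
  if (trainReport$auc > 80 && testReport$auc > 60) "accepted" else "rejected"
}
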