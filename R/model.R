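#' Drop exactly collinear design columns
#'
#' Greedy left-to-right screen: a column is kept iff it is not (numerically)
#' a linear combination of the columns kept before it, so exact duplicates
#' and constants collinear with the intercept lose their later copies.
#' Detection uses modified Gram-Schmidt with re-orthogonalization and a
#' relative tolerance of 1e-10 on the residual norm.
#'
#' @param X numeric design matrix whose first column is the intercept.
#' @param tol relative tolerance (default 1e-10).
#' @return list with \code{X} (reduced matrix, full column rank) and
#'   \code{dropped} (names of removed columns).
#' @export
removeSingularities <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(p))
  Qb <- matrix(0, n, 0)
  keep <- logical(p)
  for (j in seq_len(p)) {
    v <- X[, j]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    r <- v
    if (ncol(Qb) > 0) {
      r <- r - Qb %*% crossprod(Qb, r)
      r <- r - Qb %*% crossprod(Qb, r)   # second pass for stability
    }
    nr <- sqrt(sum(r^2))
    if (nr > tol * nv) {
      keep[j] <- TRUE
      Qb <- cbind(Qb, r / nr)
    }
  }
  list(X = X[, keep, drop = FALSE], dropped = colnames(X)[!keep])
}

## Build the model design for given samples: intercept + encoded SNVs +
## covariates.  snvs: data.frame(variant_id, coding).  impute: named numeric
## of per-variant fill values for missing genotypes (NULL -> leave NA).
.build_design <- function(cohort, snvs, covariates, samples = NULL,
                          impute = NULL) {
  d <- dosage(cohort)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  cols <- list(`(Intercept)` = rep(1, ncol(d)))
  for (k in seq_len(nrow(snvs))) {
    id <- snvs$variant_id[k]
    if (!id %in% rownames(d)) stop("variant not in cohort: ", id)
    g <- d[id, ]
    if (!is.null(impute) && id %in% names(impute))
      g[is.na(g)] <- impute[[id]]
    cols[[id]] <- recodeDosage(g, snvs$coding[k])
  }
  sd <- sampleData(cohort)
  if (!is.null(samples)) sd <- sd[samples, , drop = FALSE]
  for (cv in covariates) {
    if (!cv %in% names(sd)) stop("covariate not in colData: ", cv)
    cols[[cv]] <- as.numeric(sd[[cv]])
  }
  X <- do.call(cbind, cols)
  rownames(X) <- colnames(d)
  X
}

.as_snv_frame <- function(snvs) {
  if (is.character(snvs))
    snvs <- data.frame(variant_id = snvs,
                       coding = rep("additive", length(snvs)))
  if (is.null(snvs$coding)) snvs$coding <- "additive"
  snvs[, c("variant_id", "coding")]
}

#' Fit one staged prediction model
#'
#' Assembles \code{intercept + encoded SNVs + clinical covariates} on the
#' training samples, screens exact singularities, enforces the
#' events-per-variable guard, and fits the logistic model.  Samples with a
#' missing outcome are excluded; remaining missingness is complete-case.
#' Per-variant training mean dosages are stored so that
#' \code{\link{predictRisk}} can fill missing genotypes at prediction time.
#'
#' @param cohort a \linkS4class{TaxaneCohort} (training samples only --
#'   enforcing the train/test contract is the caller's or
#'   \code{\link{runPipeline}}'s job).
#' @param outcome name of the binary \code{colData} outcome column.
#' @param snvs character vector of variant ids (additive coding assumed,
#'   the panel convention) or a data.frame \code{(variant_id, coding)} with
#'   the scan's best codings.
#' @param covariates \code{colData} covariate columns (default the four
#'   clinical covariates present).
#' @param stage stage label stored on the fit (A1, B1, ... or free-form).
#' @param epvFloor minimum events per variable; more features than
#'   \code{events / epvFloor} is refused (default 1: never more features
#'   than events).
#' @param epvWarn warn when events per variable fall below this (default 5).
#' @return a \linkS4class{TipnFit}.
#' @export
buildStage <- function(cohort, outcome, snvs, covariates =
                         intersect(c("age", "bmi", "taxane", "diabetes"),
                                   names(sampleData(cohort))),
                       stage = "custom", epvFloor = 1, epvWarn = 5) {
  snvs <- .as_snv_frame(snvs)
  y <- sampleData(cohort)[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  hasY <- !is.na(y)
  sub <- cohort[, hasY]
  yy <- y[hasY]

  X <- .build_design(sub, snvs, covariates)
  rs <- removeSingularities(X)
  X <- rs$X
  nEvents <- min(sum(yy == 1, na.rm = TRUE), sum(yy == 0, na.rm = TRUE))
  nFeat <- ncol(X) - 1
  if (nFeat > nEvents / epvFloor)
    stop(sprintf(paste0("overfitting guard: %d features for %d events ",
                        "(events-per-variable floor %.2g)"),
                 nFeat, nEvents, epvFloor))
  if (nFeat > 0 && nEvents / nFeat < epvWarn)
    warning(sprintf("events per variable below %s (%.2f)", epvWarn,
                    nEvents / nFeat))

  fit <- fitLogistic(X, yy)
  featNames <- setdiff(colnames(X), "(Intercept)")
  kind <- ifelse(featNames %in% snvs$variant_id, "snv", "covariate")
  coding <- ifelse(kind == "snv",
                   snvs$coding[match(featNames, snvs$variant_id)], NA)
  vi <- abs(fit$z[featNames])
  vi[is.na(fit$se[featNames]) | fit$se[featNames] == 0] <- Inf
  features <- S4Vectors::DataFrame(
    feature = featNames, kind = kind, coding = coding,
    beta = unname(fit$beta[featNames]), se = unname(fit$se[featNames]),
    z = unname(fit$z[featNames]), vi = unname(vi))

  d <- dosage(sub)
  usedSnvs <- intersect(featNames, snvs$variant_id)
  impute <- if (length(usedSnvs))
    rowMeans(d[usedSnvs, , drop = FALSE], na.rm = TRUE)
  else setNames(numeric(), character())

  methods::new("TipnFit",
               stage = stage, outcome = outcome, features = features,
               intercept = unname(fit$beta["(Intercept)"]),
               dropped = rs$dropped,
               converged = fit$converged, separation = fit$separation,
               nUsed = as.integer(fit$nUsed), nEvents = as.integer(nEvents),
               trainProb = fit$fitted, imputeValues = impute)
}

#' Predicted toxicity probabilities for new samples
#'
#' Rebuilds the fitted model's design on a cohort (typically the held-out
#' test samples) and returns the logistic probabilities.  Missing genotypes
#' are filled with the variant's training mean dosage.
#'
#' @param fit a \linkS4class{TipnFit}.
#' @param cohort a \linkS4class{TaxaneCohort} containing the fit's variants
#'   and covariates.
#' @return named numeric vector of probabilities.
#' @export
predictRisk <- function(fit, cohort) {
  ft <- fit@features
  snvs <- data.frame(variant_id = ft$feature[ft$kind == "snv"],
                     coding = ft$coding[ft$kind == "snv"])
  covs <- ft$feature[ft$kind == "covariate"]
  X <- .build_design(cohort, snvs, covs, impute = fit@imputeValues)
  X <- X[, c("(Intercept)", ft$feature), drop = FALSE]
  beta <- c(fit@intercept, ft$beta)
  drop(plogis(X %*% beta))
}

#' Variable importance of a fitted model
#'
#' Defined as the absolute Wald z-statistic of each non-intercept
#' coefficient -- the standard model-based importance for a logistic fit.
#' A feature with an undefined standard error (separation) gets \code{Inf}.
#'
#' @param fit a \linkS4class{TipnFit}.
#' @return named numeric vector of importances (\eqn{\ge} 0).
#' @export
variableImportance <- function(fit) {
  setNames(fit@features$vi, fit@features$feature)
}

#' Prune a combined model by variable importance
#'
#' Keeps the features whose importance meets the threshold (boundary
#' inclusive) plus any forced covariates, yielding the feature specification
#' for the final-stage refit.
#'
#' @param fit the combined-stage \linkS4class{TipnFit} supplying the VI.
#' @param viThreshold importance threshold (the study tuned per-symptom
#'   values in 1.00-1.67).
#' @param forcedCovariates covariates retained regardless of importance.
#' @return list with \code{snvs} (data.frame \code{variant_id, coding}),
#'   \code{covariates}, \code{viThreshold}.
#' @export
pruneByVi <- function(fit, viThreshold, forcedCovariates = character()) {
  ft <- fit@features
  keep <- ft$vi >= viThreshold
  snvKeep <- keep & ft$kind == "snv"
  covKeep <- (keep & ft$kind == "covariate") |
    (ft$kind == "covariate" & ft$feature %in% forcedCovariates)
  if (!any(snvKeep) && !any(covKeep))
    stop("no features at or above the importance threshold")
  list(snvs = data.frame(variant_id = ft$feature[snvKeep],
                         coding = ft$coding[snvKeep]),
       covariates = ft$feature[covKeep],
       viThreshold = viThreshold)
}
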