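#' Per-variant logistic association scan under three inheritance codings
#'
#' For every variant, fits \code{outcome ~ intercept + encoded genotype} by
#' logistic regression under the additive (0/1/2), dominant (0/1/1) and
#' recessive (0/0/1) codings and reports the Wald test per coding.  The scan
#' is genotype-only (no covariates), matching a conventional association
#' scan; clinical covariates enter later at model building.  Samples with a
#' missing outcome are excluded; missing genotypes are handled complete-case
#' per variant.  A coding is skipped (p set to 1) when fewer than
#' \code{minCount} samples fall outside the modal encoded category, or when
#' the fit separates or fails to converge.  The best coding per variant is
#' the smallest p, ties broken additive > dominant > recessive.
#'
#' @param x a \linkS4class{TaxaneCohort} or a variants x samples dosage
#'   matrix.
#' @param outcome binary outcome vector (samples), or the name of a
#'   \code{colData} column when \code{x} is a cohort.
#' @param minCount minor-category floor per encoded column (default 5).
#' @return data.frame with one row per variant: \code{variant_id},
#'   \code{beta_/se_/z_/p_} for \code{additive}, \code{dominant},
#'   \code{recessive}, plus \code{best_coding} and \code{best_p}.
#' @export
snvScan <- function(x, outcome, minCount = 5) {
  d <- if (methods::is(x, "TaxaneCohort")) dosage(x) else x
  if (methods::is(x, "TaxaneCohort") && is.character(outcome) &&
      length(outcome) == 1)
    outcome <- sampleData(x)[[outcome]]
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L) | is.na(y)))
    stop("outcome must be binary 0/1 (NA allowed)")
  res <- .scan_engine(.as_int_matrix(d), y, as.integer(minCount))
  codings <- c("additive", "dominant", "recessive")
  out <- data.frame(variant_id = rownames(d))
  for (k in seq_along(codings)) {
    cc <- codings[k]
    out[[paste0("beta_", cc)]] <- res[, 4 * k - 3]
    out[[paste0("se_", cc)]] <- res[, 4 * k - 2]
    out[[paste0("z_", cc)]] <- res[, 4 * k - 1]
    out[[paste0("p_", cc)]] <- res[, 4 * k]
  }
  pm <- cbind(out$p_additive, out$p_dominant, out$p_recessive)
  best <- max.col(-pm, ties.method = "first")   # ties -> additive first
  out$best_coding <- codings[best]
  out$best_p <- pm[cbind(seq_len(nrow(pm)), best)]
  out
}

.as_int_matrix <- function(d) {
  if (!is.integer(d)) {
    storage.mode(d) <- "integer"
  }
  d
}

#' Permutation-based FDR curve for the association scan
#'
#' Permutes the outcome labels \code{nPerm} times (genotypes, and hence LD
#' structure, untouched), reruns the full three-coding scan per permutation,
#' and for each candidate threshold \eqn{t} estimates
#' \deqn{\mathrm{FDR}(t) = \min\!\left(1,\;
#'   \frac{\overline{\#\{\mathrm{best\_p}^{perm} \le t\}}}
#'        {\max(1, \#\{\mathrm{best\_p}^{obs} \le t\})}\right).}
#' The chosen threshold minimizes the estimated FDR, ties broken toward the
#' smallest threshold.
#'
#' @param x cohort or dosage matrix (as in \code{\link{snvScan}}).
#' @param outcome binary outcome vector or \code{colData} column name.
#' @param nPerm number of permutations (study setting: 1000).
#' @param thresholdGrid ascending p-value thresholds to evaluate (study
#'   window: 0.00001-0.005).
#' @param seed integer seed for the permutation draws.
#' @param minCount per-coding minor-category floor (default 5).
#' @return object of class \code{"FDRCurve"}: list with \code{thresholds},
#'   \code{observed_hits}, \code{mean_null_hits}, \code{fdr},
#'   \code{n_permutations}, \code{chosen_threshold}, \code{seed}.
#' @export
permutationFdr <- function(x, outcome, nPerm = 1000,
                           thresholdGrid = c(0.00001, 0.00005, 0.0001,
                                             0.00025, 0.0005, 0.00075,
                                             0.001, 0.0025, 0.005),
                           seed = 1L, minCount = 5) {
  if (length(thresholdGrid) == 0) stop("empty threshold grid")
  if (nPerm < 1) stop("nPerm must be >= 1")
  thresholdGrid <- sort(thresholdGrid)
  d <- if (methods::is(x, "TaxaneCohort")) dosage(x) else x
  if (methods::is(x, "TaxaneCohort") && is.character(outcome) &&
      length(outcome) == 1)
    outcome <- sampleData(x)[[outcome]]
  y <- as.integer(outcome)
  ## permute within the non-missing outcome rows only
  obs <- snvScan(d, y, minCount = minCount)
  okr <- which(!is.na(y))
  set.seed(seed)
  perms <- vapply(seq_len(nPerm), function(b) {
    yp <- y
    yp[okr] <- y[okr][sample.int(length(okr))]
    yp
  }, integer(length(y)))
  bp <- .scan_perm_best_p(.as_int_matrix(d), perms, as.integer(minCount))

  observed_hits <- vapply(thresholdGrid, function(t) sum(obs$best_p <= t), 0L)
  mean_null_hits <- vapply(thresholdGrid,
                           function(t) mean(colSums(bp <= t)), 0)
  fdr <- pmin(1, mean_null_hits / pmax(1, observed_hits))
  ## the chosen threshold must extract at least one variant to be usable
  ## downstream; restrict the argmin to thresholds with observed hits
  ## (falling back to the global argmin when no threshold has any)
  cand <- if (any(observed_hits > 0)) which(observed_hits > 0)
          else seq_along(thresholdGrid)
  chosen <- thresholdGrid[cand[which.min(fdr[cand])]]  # ties -> smallest t
  structure(list(thresholds = thresholdGrid,
                 observed_hits = observed_hits,
                 mean_null_hits = mean_null_hits,
                 fdr = fdr,
                 n_permutations = nPerm,
                 chosen_threshold = chosen,
                 seed = seed),
            class = "FDRCurve")
}

#' @export
print.FDRCurve <- function(x, ...) {
  cat("Permutation FDR curve (", x$n_permutations, " permutations)\n", sep = "")
  print(data.frame(threshold = x$thresholds, observed = x$observed_hits,
                   mean_null = round(x$mean_null_hits, 2),
                   fdr = round(x$fdr, 3)), row.names = FALSE)
  cat("chosen threshold:", format(x$chosen_threshold), "\n")
  invisible(x)
}

#' Select variants at a p-value threshold
#'
#' Returns the variants with best-coding p at or below the threshold, with
#' an optional deleteriousness-score sub-filter (CADD-style, keep score
#' \eqn{\ge} \code{minDeleteriousScore}).
#'
#' @param results scan results from \code{\link{snvScan}}.
#' @param threshold p-value threshold in (0, 1].
#' @param minDeleteriousScore optional score floor; requires a
#'   \code{deleterious_score} column in \code{results} or a separate named
#'   vector via \code{scores}.
#' @param scores optional named per-variant score vector.
#' @return character vector of variant ids.
#' @export
selectSnvs <- function(results, threshold, minDeleteriousScore = NULL,
                       scores = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- results$best_p <= threshold
  if (!is.null(minDeleteriousScore)) {
    sc <- if (!is.null(scores)) scores[results$variant_id]
          else results$deleterious_score
    if (is.null(sc)) stop("no deleteriousness scores available")
    keep <- keep & !is.na(sc) & sc >= minDeleteriousScore
  }
  results$variant_id[keep]
}
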