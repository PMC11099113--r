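#' @import methods
#' @importFrom stats glm.fit binomial plogis qlogis pchisq pnorm phyper
#'   rbinom rnorm runif uniroot sd qnorm t.test quantile setNames dbeta
#'   complete.cases rbeta rgamma
#' @importFrom utils head write.table read.table write.csv
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay rowData colData
#' @useDynLib tipnpred, .registration = TRUE
NULL

#' TaxaneCohort: genotypes, variant metadata and phenotypes for one cohort
#'
#' The central data container of the package.  It extends
#' \linkS4class{SummarizedExperiment}: the single \code{"dosage"} assay holds
#' the variants x samples genotype matrix coded 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) or \code{NA} (missing call);
#' \code{rowData} carries the per-variant record (locus, alleles, FILTER
#' label, mean coverage, gene annotation, optional deleteriousness score);
#' \code{colData} carries the per-sample covariates and the dichotomized
#' symptom outcomes (with per-item missingness as \code{NA}).
#'
#' Simulated cohorts additionally store the generating truth (causal variant
#' ids, effect sizes, codings, calibrated intercepts, seed) in
#' \code{metadata(x)$truth}.
#'
#' @slot .   inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{TaxaneCohort}} (constructor),
#'   \code{\link{readCohortVcf}}, \code{\link{simulateCohort}}
#' @export
setClass("TaxaneCohort", contains = "SummarizedExperiment")

setValidity("TaxaneCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && (any(bad < 0) || any(bad > 2)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "variant ids (rownames) are required")
  if (length(msg)) msg else TRUE
})

#' Construct a TaxaneCohort
#'
#' @param dosage integer matrix, variants in rows and samples in columns,
#'   values in \{0, 1, 2, NA\}.  Rownames are variant ids (rsID or
#'   \code{chrom:pos:ref:alt}), colnames are sample ids.
#' @param variantInfo \code{DataFrame} or data.frame of per-variant metadata,
#'   one row per dosage row.  Recognised columns include \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{filter_label},
#'   \code{mean_coverage}, \code{biallelic}, \code{genes} (a
#'   \code{CharacterList}), \code{deleterious_score}.
#' @param sampleData \code{DataFrame} or data.frame of per-sample covariates
#'   and binary symptom outcomes, one row per dosage column.
#' @param metadata optional list stored in \code{metadata()}.
#' @return A \linkS4class{TaxaneCohort}.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2", "s3")))
#' cohort <- TaxaneCohort(d)
#' dosage(cohort)
#' @export
TaxaneCohort <- function(dosage, variantInfo = NULL, sampleData = NULL,
                         metadata = list()) {
  if (is.null(rownames(dosage)))
    stop("dosage must have rownames (variant ids)")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%04d", seq_len(ncol(dosage)))
  if (is.null(variantInfo))
    variantInfo <- S4Vectors::DataFrame(row.names = rownames(dosage))
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = variantInfo,
    colData = sampleData,
    metadata = metadata)
  methods::new("TaxaneCohort", se)
}

#' @describeIn TaxaneCohort-class the variants x samples dosage matrix.
#' @param x a \code{TaxaneCohort}
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn TaxaneCohort-class per-variant metadata (\code{rowData}).
#' @export
variantInfo <- function(x) SummarizedExperiment::rowData(x)

#' @describeIn TaxaneCohort-class per-sample covariates/outcomes
#'   (\code{colData}).
#' @export
sampleData <- function(x) SummarizedExperiment::colData(x)

setMethod("show", "TaxaneCohort", function(object) {
  cat("TaxaneCohort:", nrow(object), "variants x", ncol(object), "samples\n")
  d <- dosage(object)
  cat(sprintf("  missing genotype calls: %.3f%%\n", 100 * mean(is.na(d))))
  cd <- names(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  sample fields:", paste(cd, collapse = ", "), "\n")
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulated cohort (truth stored in metadata(x)$truth)\n")
})

#' TipnFit: a fitted staged prediction model
#'
#' Result of \code{\link{buildStage}}.  Holds the feature table (variant ids
#' with their inheritance coding, plus clinical covariates) with coefficient,
#' standard error, Wald z and variable importance per feature, the columns
#' dropped as exact singularities, convergence/separation diagnostics and the
#' in-sample predicted probabilities.
#'
#' @slot stage model stage label (A1, A2, B1, B2, C1, C2 or free-form).
#' @slot outcome name of the symptom column modelled.
#' @slot features \code{DataFrame} with columns \code{feature}, \code{kind}
#'   ("snv" or "covariate"), \code{coding}, \code{beta}, \code{se}, \code{z},
#'   \code{vi}.
#' @slot intercept numeric intercept estimate.
#' @slot dropped character, features removed by singularity screening.
#' @slot converged,separation logical diagnostics from the IRLS fit.
#' @slot nUsed,nEvents samples and events (positives) in the fit.
#' @slot trainProb named numeric, fitted probabilities on the training rows.
#' @slot imputeValues named numeric, per-variant training mean dosage used to
#'   fill missing genotypes at prediction time.
#' @export
setClass("TipnFit", representation(
  stage = "character", outcome = "character", features = "DataFrame",
  intercept = "numeric", dropped = "character", converged = "logical",
  separation = "logical", nUsed = "integer", nEvents = "integer",
  trainProb = "numeric", imputeValues = "numeric"))

setMethod("show", "TipnFit", function(object) {
  ft <- object@features
  cat(sprintf("TipnFit stage %s for '%s': %d SNVs + %d covariates (n = %d, events = %d)\n",
              object@stage, object@outcome,
              sum(ft$kind == "snv"), sum(ft$kind == "covariate"),
              object@nUsed, object@nEvents))
  if (length(object@dropped))
    cat("  dropped singularities:", paste(object@dropped, collapse = ", "), "\n")
  if (!object@converged) cat("  WARNING: fit did not converge\n")
  if (object@separation) cat("  WARNING: separation detected\n")
})

#' @describeIn TipnFit-class feature table with estimates.
#' @param fit a \code{TipnFit}
#' @export
modelFeatures <- function(fit) fit@features
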