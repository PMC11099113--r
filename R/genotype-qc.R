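#' Read a multi-sample VCF into a TaxaneCohort
#'
#' Parses a VCF 4.x file (via \pkg{VariantAnnotation}) into the dosage
#' coding used throughout the package: reference homozygote 0, heterozygote
#' 1, alternate homozygote 2, missing call \code{NA}.  Multi-allelic rows are
#' kept but flagged (\code{biallelic = FALSE}); genotypes carrying an allele
#' index above 1 are recorded as missing.  Variant ids default to the VCF ID
#' (rsID) when present, else \code{chrom:pos:ref:alt}.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param coverageField INFO key holding the summed read depth across
#'   samples; the per-variant mean coverage is this value divided by the
#'   sample count.  Default \code{"DP"}.  If the key is absent a warning is
#'   raised and \code{mean_coverage} is \code{NA}.
#' @param phenotypes optional data.frame of per-sample covariates/outcomes,
#'   rownames matching the VCF sample names.
#' @return A \linkS4class{TaxaneCohort} whose \code{rowData} includes
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{filter_label},
#'   \code{mean_coverage}, \code{biallelic}, \code{genotyping_rate}.
#' @export
readCohortVcf <- function(path, coverageField = "DP", phenotypes = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  dos <- .gt_to_dosage(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  altc <- vapply(as.list(alt), function(a) paste(as.character(a), collapse = ","), "")
  refc <- as.character(VariantAnnotation::ref(vcf))
  ids <- rownames(vcf)
  fallback <- paste(as.character(GenomicRanges::seqnames(rr)),
                    GenomicRanges::start(rr), refc, altc, sep = ":")
  ## readVcf synthesizes "chrom:pos_ref/alt" names for rows without an ID;
  ## replace those (and empty ids) with the canonical chrom:pos:ref:alt form
  noid <- is.na(ids) | ids %in% c(".", "") | grepl(":[0-9]+_", ids)
  ids[noid] <- fallback[noid]
  rownames(dos) <- ids

  info <- VariantAnnotation::info(vcf)
  if (!is.null(coverageField) && coverageField %in% colnames(info)) {
    dp <- info[[coverageField]]
    meancov <- as.numeric(dp) / ncol(dos)
  } else {
    if (!is.null(coverageField))
      warning("INFO field '", coverageField,
              "' not found; mean coverage unknown")
    meancov <- rep(NA_real_, nrow(dos))
  }
  vi <- S4Vectors::DataFrame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = refc, alt = altc,
    filter_label = as.character(VariantAnnotation::filt(vcf)),
    mean_coverage = meancov,
    biallelic = nalt == 1L,
    genotyping_rate = rowMeans(!is.na(dos)),
    row.names = ids)
  sd <- NULL
  if (!is.null(phenotypes)) {
    miss <- setdiff(colnames(dos), rownames(phenotypes))
    if (length(miss)) stop("phenotype table lacks samples: ",
                           paste(head(miss), collapse = ", "))
    sd <- S4Vectors::DataFrame(phenotypes[colnames(dos), , drop = FALSE])
  }
  TaxaneCohort(dos, vi, sd)
}

## "0/1", "0|1", "./." etc -> 0/1/2/NA; any allele index > 1 -> NA
.gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  d <- map[gt]
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact conditional test on one-locus genotype counts: given the
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count.  Probabilities follow the Levene-Haldane distribution and are
#' evaluated with the mode-anchored ratio recurrence, so the computation is
#' O(number of admissible heterozygote counts) per table.  Monomorphic sites
#' return 1 by convention.  All three arguments are recycled.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative integers).
#' @return numeric vector of exact p-values in (0, 1].
#' @examples
#' hweExactP(57, 78, 28)
#' hweExactP(10, 0, 0)   # monomorphic -> 1
#' @export
hweExactP <- function(nHomRef, nHet, nHomAlt) {
  n <- max(length(nHomRef), length(nHet), length(nHomAlt))
  aa <- rep_len(as.integer(nHomRef), n)
  ab <- rep_len(as.integer(nHet), n)
  bb <- rep_len(as.integer(nHomAlt), n)
  if (any(aa < 0 | ab < 0 | bb < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  vapply(seq_len(n), function(i) .hwe_one(aa[i], ab[i], bb[i]), 0)
}

.hwe_one <- function(aa, ab, bb) {
  ntot <- aa + ab + bb
  if (ntot < 1) stop("at least one genotype required")
  nA <- 2L * aa + ab
  nB <- 2L * bb + ab
  rare <- min(nA, nB)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  ## unnormalized probs by recurrence from the lowest admissible het count:
  ## P(h+2)/P(h) = 4 * nAA(h) * nBB(h) / ((h+2)*(h+1))
  ## where nAA(h) = (nA - h)/2 (rare-allele homozygotes), nBB(h) accordingly.
  K <- length(hets)
  logw <- numeric(K)
  for (k in seq_len(K - 1L)) {
    h <- hets[k]
    hom_r <- (rare - h) / 2
    hom_c <- (max(nA, nB) - h) / 2
    logw[k + 1L] <- logw[k] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  obs <- prob[match(ab, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Minor allele frequency from a dosage vector or matrix
#'
#' Alternate-allele frequency folded to the minor side (\eqn{\le 0.5});
#' missing entries are excluded from the denominator.
#'
#' @param x dosage vector in \{0,1,2,NA\}, or a variants x samples matrix
#'   (one MAF per row).
#' @return numeric MAF(s) in [0, 0.5].
#' @export
computeMaf <- function(x) {
  if (is.matrix(x)) {
    nn <- rowSums(!is.na(x))
    if (any(nn == 0)) stop("all-missing dosage row")
    f <- rowSums(x, na.rm = TRUE) / (2 * nn)
  } else {
    nn <- sum(!is.na(x))
    if (nn == 0) stop("all-missing dosage column")
    f <- sum(x, na.rm = TRUE) / (2 * nn)
  }
  pmin(f, 1 - f)
}

#' Variant-level quality-control filtering
#'
#' Keeps a variant iff genotyping rate \eqn{\ge} \code{minGenotypingRate} AND
#' mean coverage \eqn{\ge} \code{minCoverage} AND Hardy-Weinberg exact
#' p \eqn{\ge} \code{minHweP} AND biallelic AND FILTER equals \code{"PASS"}.
#' Thresholds are removal conditions, so boundary values keep the variant.
#' Unknown mean coverage (\code{NA}) is not treated as low coverage.
#' Genotyping rate and HWE are recomputed from the dosage matrix; the filter
#' is idempotent.
#'
#' @param cohort a \linkS4class{TaxaneCohort}.
#' @param minGenotypingRate,minCoverage,minHweP removal thresholds
#'   (defaults 0.95, 10 reads, 1e-4).
#' @return list with \code{cohort} (the filtered \code{TaxaneCohort}, whose
#'   \code{rowData} gains \code{genotyping_rate}, \code{maf}, \code{hwe_p})
#'   and \code{log}, a data.frame \code{(variant_id, rule)} naming the first
#'   failing rule per removed variant.
#' @export
filterVariants <- function(cohort, minGenotypingRate = 0.95,
                           minCoverage = 10, minHweP = 1e-4) {
  d <- dosage(cohort)
  vi <- variantInfo(cohort)
  rate <- rowMeans(!is.na(d))
  nonmiss <- rowSums(!is.na(d))
  het <- rowSums(d == 1L, na.rm = TRUE)
  althom <- rowSums(d == 2L, na.rm = TRUE)
  refhom <- nonmiss - het - althom
  hwe <- rep(1, nrow(d))
  ok <- nonmiss > 0
  hwe[ok] <- hweExactP(refhom[ok], het[ok], althom[ok])
  maf <- rep(NA_real_, nrow(d))
  altfreq <- rowSums(d, na.rm = TRUE)[ok] / (2 * nonmiss[ok])
  maf[ok] <- pmin(altfreq, 1 - altfreq)

  cov <- if ("mean_coverage" %in% names(vi)) vi$mean_coverage else rep(NA_real_, nrow(d))
  bial <- if ("biallelic" %in% names(vi)) vi$biallelic else rep(TRUE, nrow(d))
  filt <- if ("filter_label" %in% names(vi)) vi$filter_label else rep("PASS", nrow(d))

  ## first failing rule, in a fixed order
  rule <- rep(NA_character_, nrow(d))
  rule[is.na(rule) & rate < minGenotypingRate] <- "genotyping_rate"
  rule[is.na(rule) & !is.na(cov) & cov < minCoverage] <- "mean_coverage"
  rule[is.na(rule) & hwe < minHweP] <- "hwe"
  rule[is.na(rule) & !bial] <- "not_biallelic"
  rule[is.na(rule) & filt != "PASS"] <- "filter_label"
  keep <- is.na(rule)

  out <- cohort[keep, ]
  nd <- SummarizedExperiment::rowData(out)
  nd$genotyping_rate <- rate[keep]
  nd$maf <- maf[keep]
  nd$hwe_p <- hwe[keep]
  SummarizedExperiment::rowData(out) <- nd
  list(cohort = out,
       log = data.frame(variant_id = rownames(d)[!keep],
                        rule = rule[!keep]))
}

#' Recode a dosage vector under an inheritance model
#'
#' Additive is the identity; dominant maps \{0,1,2\} to \{0,1,1\}; recessive
#' maps \{0,1,2\} to \{0,0,1\}.  Missing propagates.
#'
#' @param x dosage values in \{0,1,2,NA\}.
#' @param coding one of \code{"additive"}, \code{"dominant"},
#'   \code{"recessive"}.
#' @return numeric vector of encoded predictors.
#' @export
recodeDosage <- function(x, coding = c("additive", "dominant", "recessive")) {
  coding <- match.arg(coding)
  if (any(!is.na(x) & !(x %in% 0:2)))
    stop("dosage values must be 0, 1, 2 or NA")
  switch(coding,
         additive = as.numeric(x),
         dominant = as.numeric(x >= 1),
         recessive = as.numeric(x == 2))
}
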