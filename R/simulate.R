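#' Simulate a whole-exome genotype matrix
#'
#' Per-variant minor allele frequencies are drawn from a rare/common mixture
#' (by default 32\% common variants uniform on [0.01, 0.5] and 68\% rare
#' variants on [0.0005, 0.01], mirroring the common-variant share of a
#' filtered exome call set); dosages are two Bernoulli allele draws per
#' sample, so Hardy-Weinberg equilibrium holds marginally.  Optional linkage
#' blocks are induced by a Gaussian copula on the latent allele draws:
#' within a block every pair of variants shares a correlation \code{rho}
#' through a common factor.
#'
#' @param nSamples,nVariants cohort dimensions.
#' @param maf optional explicit per-variant MAF vector (recycled); when
#'   \code{NULL}, drawn from the mixture.
#' @param commonFraction probability a variant is common (default 0.32).
#' @param ldBlocks optional \code{list(size =, rho =)} linkage block spec.
#' @param nGenes number of genes tiled over the variants (consecutive
#'   blocks; every fifth boundary variant is annotated to both flanking
#'   genes, emulating overlapping gene regions).
#' @param genotypeMissingRate per-call missingness rate (default 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A \linkS4class{TaxaneCohort} with variant metadata (locus,
#'   alleles, PASS filter, mean coverage around 75x, CADD-like deleterious
#'   score, gene annotation in \code{rowData(x)$genes}).
#' @export
simulateGenotypes <- function(nSamples = 337, nVariants = 20000, maf = NULL,
                              commonFraction = 0.32, ldBlocks = NULL,
                              nGenes = max(2L, round(nVariants / 8)),
                              genotypeMissingRate = 0, seed = 1L) {
  set.seed(seed)
  m <- nVariants; n <- nSamples
  if (is.null(maf)) {
    common <- runif(m) < commonFraction
    maf <- ifelse(common, runif(m, 0.01, 0.5),
                  0.0005 + 0.0095 * rbeta(m, 0.8, 3))
  } else maf <- rep_len(maf, m)

  thr <- qnorm(maf)  # latent threshold per variant: allele is ALT iff z < thr
  drawAlleles <- function() {
    if (is.null(ldBlocks)) {
      z <- matrix(rnorm(m * n), nrow = m)
    } else {
      rho <- ldBlocks$rho
      bs <- ldBlocks$size
      block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
      f <- matrix(rnorm(max(block) * n), nrow = max(block))
      z <- sqrt(rho) * f[block, , drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(m * n), nrow = m)
    }
    z < thr
  }
  dos <- matrix(as.integer(drawAlleles()) + as.integer(drawAlleles()), nrow = m)
  if (genotypeMissingRate > 0)
    dos[matrix(runif(m * n) < genotypeMissingRate, nrow = m)] <- NA_integer_

  ids <- sprintf("rs%06d", seq_len(m))
  dimnames(dos) <- list(ids, sprintf("S%04d", seq_len(n)))

  chrom <- paste0("chr", sort(rep_len(1:22, m)))
  pos <- unlist(lapply(split(seq_len(m), chrom)[unique(chrom)],
                       function(ix) sort(sample.int(5e7, length(ix)))),
                use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  ## tile genes over consecutive variants, with occasional overlaps
  per <- ceiling(m / nGenes)
  gene_of <- rep(seq_len(nGenes), each = per)[seq_len(m)]
  gnames <- sprintf("GENE%04d", gene_of)
  genes <- as.list(gnames)
  boundary <- which(diff(gene_of) == 1L)
  overlap <- boundary[seq_along(boundary) %% 5L == 0L]
  for (b in overlap) genes[[b]] <- c(gnames[b], sprintf("GENE%04d", gene_of[b] + 1L))

  vi <- S4Vectors::DataFrame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    filter_label = "PASS",
    mean_coverage = pmax(1, rnorm(m, 74.7, 15)),
    biallelic = TRUE,
    deleterious_score = rgamma(m, shape = 2, scale = 5),
    maf_true = maf,
    genes = IRanges::CharacterList(genes),
    row.names = ids)
  TaxaneCohort(dos, vi, metadata = list(seed = seed))
}

#' Simulate correlated binary symptom phenotypes and clinical covariates
#'
#' For each symptom \eqn{s}, \eqn{P(y=1) = \mathrm{logit}^{-1}(\beta_{0s} +
#' \sum_j \beta_j \, \mathrm{code}(g_j) + \gamma' x)}.  The intercept
#' \eqn{\beta_{0s}} is calibrated by root-finding so the expected prevalence
#' over the realized linear predictors matches the target.  Covariates are
#' age (truncated normal, mean 62, sd 10, range 31-86 years), BMI (normal,
#' mean 26.9, sd 4.7 kg/m^2), paclitaxel treatment (Bernoulli 0.445) and
#' diabetes treatment (Bernoulli 0.047).  Symptom correlation arises only
#' through shared causal variants and covariates.  The generating truth is
#' stored in \code{metadata(cohort)$truth}.
#'
#' @param genotypes a \linkS4class{TaxaneCohort} from
#'   \code{\link{simulateGenotypes}}.
#' @param targetPrevalences named vector of symptom prevalences in (0,1);
#'   defaults to the five study symptoms (0.255 numbness in feet, 0.246
#'   tingling in feet, 0.276 cramps in feet, 0.261 difficulty opening a jar,
#'   0.121 difficulty climbing stairs).
#' @param nCausalPerSymptom causal variants per symptom (default 10), drawn
#'   among variants with MAF \eqn{\ge} 0.05; a shared pool induces
#'   between-symptom correlation.
#' @param effectSize log-odds magnitude per causal variant (default 0.8;
#'   recycled, sign kept positive).
#' @param codingProbs probabilities that a causal effect acts additively,
#'   dominantly or recessively (default 0.46/0.35/0.19).
#' @param covariateEffects named log-odds: per year of age and per BMI unit
#'   (centered at 62 and 26.9), and for paclitaxel and diabetes indicators.
#' @param sharedFraction fraction of each symptom's causal set drawn from the
#'   shared pool (default 0.3).
#' @param missingItemRate per-item response missingness (default 0.006,
#'   about 2 of 337).
#' @param seed integer seed.
#' @return the cohort with covariates and symptom columns added to
#'   \code{colData} and truth in \code{metadata(x)$truth}.
#' @export
simulatePhenotypes <- function(genotypes,
                               targetPrevalences = c(numbness_feet = 0.255,
                                                     tingling_feet = 0.246,
                                                     cramps_feet = 0.276,
                                                     open_jar = 0.261,
                                                     climb_stairs = 0.121),
                               nCausalPerSymptom = 10,
                               effectSize = 0.8,
                               codingProbs = c(additive = 0.46,
                                               dominant = 0.35,
                                               recessive = 0.19),
                               covariateEffects = c(age = 0.03, bmi = 0.05,
                                                    taxane = 0.5,
                                                    diabetes = 0.7),
                               sharedFraction = 0.3,
                               missingItemRate = 0.006,
                               seed = 1L) {
  stopifnot(all(targetPrevalences > 0 & targetPrevalences < 1))
  set.seed(seed + 1L)
  d <- dosage(genotypes)
  n <- ncol(d)
  if (nCausalPerSymptom > nrow(d))
    stop("more causal variants requested than variants available")

  ## clinical covariates (moments matched to the survivor characteristics)
  age <- qnorm(runif(n, pnorm(31, 62, 10), pnorm(86, 62, 10)), 62, 10)
  bmi <- rnorm(n, 26.9, 4.7)
  taxane <- rbinom(n, 1, 0.445)        # 1 = paclitaxel
  diabetes <- rbinom(n, 1, 0.047)
  covEta <- covariateEffects["age"] * (age - 62) +
    covariateEffects["bmi"] * (bmi - 26.9) +
    covariateEffects["taxane"] * taxane +
    covariateEffects["diabetes"] * diabetes

  maf <- computeMaf(d)
  eligible <- which(maf >= 0.05)
  if (length(eligible) < nCausalPerSymptom)
    eligible <- order(maf, decreasing = TRUE)[seq_len(min(nrow(d), 5 * nCausalPerSymptom))]
  nShared <- min(nCausalPerSymptom, ceiling(sharedFraction * nCausalPerSymptom))
  sharedPool <- sample(eligible, nShared)

  symptoms <- names(targetPrevalences)
  pheno <- S4Vectors::DataFrame(age = age, bmi = bmi, taxane = taxane,
                                diabetes = diabetes,
                                row.names = colnames(d))
  truth <- list(seed = seed, covariate_effects = covariateEffects,
                symptoms = list())
  for (s in symptoms) {
    own <- sample(setdiff(eligible, sharedPool),
                  nCausalPerSymptom - nShared)
    causal <- c(sharedPool, own)
    betas <- rep_len(abs(effectSize), length(causal))
    codings <- sample(names(codingProbs), length(causal), replace = TRUE,
                      prob = codingProbs)
    eta <- covEta
    for (k in seq_along(causal)) {
      g <- recodeDosage(d[causal[k], ], codings[k])
      g[is.na(g)] <- 0     # missing calls carry the reference liability
      eta <- eta + betas[k] * g
    }
    target <- targetPrevalences[[s]]
    b0 <- uniroot(function(b) mean(plogis(b + eta)) - target,
                  c(-30, 30), tol = 1e-10)$root
    y <- rbinom(n, 1, plogis(b0 + eta))
    if (missingItemRate > 0)
      y[runif(n) < missingItemRate] <- NA_integer_
    pheno[[s]] <- y
    truth$symptoms[[s]] <- list(
      causal = rownames(d)[causal], beta = betas, coding = codings,
      intercept = b0, target_prevalence = target)
  }
  SummarizedExperiment::colData(genotypes) <- pheno
  md <- S4Vectors::metadata(genotypes)
  md$truth <- truth
  md$symptoms <- symptoms
  S4Vectors::metadata(genotypes) <- md
  genotypes
}

#' One-call synthetic cohort
#'
#' Convenience wrapper chaining \code{\link{simulateGenotypes}} and
#' \code{\link{simulatePhenotypes}}; arguments are passed through.
#'
#' @param nSamples,nVariants cohort dimensions (defaults emulate the study:
#'   337 samples).
#' @param seed master seed for both steps.
#' @param ... forwarded to the two generators.
#' @return A \linkS4class{TaxaneCohort} with genotypes, covariates, symptom
#'   outcomes and stored truth.
#' @export
simulateCohort <- function(nSamples = 337, nVariants = 20000, seed = 1L, ...) {
  dots <- list(...)
  gArgs <- dots[names(dots) %in% names(formals(simulateGenotypes))]
  pArgs <- dots[names(dots) %in% names(formals(simulatePhenotypes))]
  g <- do.call(simulateGenotypes,
               c(list(nSamples = nSamples, nVariants = nVariants, seed = seed),
                 gArgs))
  do.call(simulatePhenotypes, c(list(genotypes = g, seed = seed), pArgs))
}

#' Build a literature SNV panel from a simulated cohort
#'
#' Emulates a meta-analysis panel (rsID, gene, reported p-value): a subset of
#' the cohort's causal variants enter with significant source p-values, the
#' remainder are random non-causal variants with p-values above 0.05.
#'
#' @param cohort a simulated \linkS4class{TaxaneCohort} carrying truth.
#' @param nPanel panel size (default 26, the exome-matched panel size).
#' @param nSignificant panel members given source p < 0.05 (default 8);
#'   causal variants are preferred for these slots.
#' @param seed integer seed.
#' @return data.frame \code{(rsid, gene, source_p)}.
#' @export
makeLiteraturePanel <- function(cohort, nPanel = 26, nSignificant = 8,
                                seed = 1L) {
  set.seed(seed + 2L)
  truth <- S4Vectors::metadata(cohort)$truth
  causal <- unique(unlist(lapply(truth$symptoms, `[[`, "causal")))
  maf <- computeMaf(dosage(cohort))
  common <- rownames(cohort)[maf >= 0.05]
  sig <- head(c(sample(causal), sample(setdiff(common, causal))), nSignificant)
  rest <- sample(setdiff(common, sig), nPanel - length(sig))
  ids <- c(sig, rest)
  gl <- variantInfo(cohort)$genes
  gene <- vapply(as.list(gl[match(ids, rownames(cohort))]),
                 function(g) g[1], "")
  data.frame(rsid = ids, gene = gene,
             source_p = c(runif(length(sig), 1e-5, 0.049),
                          runif(length(rest), 0.06, 0.9)))
}

#' Build gene-set definitions with one planted pathway
#'
#' Generates a GMT-style collection over the cohort's gene universe.  The
#' first set ("PLANTED_PATHWAY") contains the genes carrying the causal
#' variants plus random padding, so over-representation filtering has a
#' recoverable signal.
#'
#' @param cohort a simulated \linkS4class{TaxaneCohort}.
#' @param nSets number of gene sets (default 40).
#' @param setSize size range for random sets.
#' @param seed integer seed.
#' @return named list of gene symbol vectors (GMT semantics).
#' @export
makeGeneSets <- function(cohort, nSets = 40, setSize = c(10, 60), seed = 1L) {
  set.seed(seed + 3L)
  universe <- unique(unlist(as.list(variantInfo(cohort)$genes)))
  truth <- S4Vectors::metadata(cohort)$truth
  causalGenes <- character()
  if (!is.null(truth)) {
    causal <- unique(unlist(lapply(truth$symptoms, `[[`, "causal")))
    gl <- variantInfo(cohort)$genes
    causalGenes <- unique(unlist(as.list(gl[match(causal, rownames(cohort))])))
  }
  pad <- min(length(universe), max(0, 20 - length(causalGenes)))
  sets <- list(PLANTED_PATHWAY = unique(c(causalGenes,
                                          sample(universe, pad))))
  for (i in seq_len(nSets - 1)) {
    sz <- sample(seq(setSize[1], setSize[2]), 1)
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(universe, min(sz, length(universe)))
  }
  sets
}

#' Write a cohort to the pipeline's on-disk formats
#'
#' Emits the same formats the pipeline consumes: a VCF 4.x file (GT genotypes
#' plus an INFO DP field carrying summed depth), a phenotype/covariate CSV,
#' and, for simulated cohorts, a truth JSON (causal variants, effects, seed).
#'
#' @param cohort a \linkS4class{TaxaneCohort}.
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default "cohort").
#' @return named character vector of the files written.
#' @export
writeCohortVcf <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dosage(cohort)
  vi <- variantInfo(cohort)
  n <- ncol(d)

  rr <- GenomicRanges::GRanges(
    vi$chrom, IRanges::IRanges(vi$pos, width = nchar(vi$ref)))
  names(rr) <- rownames(d)
  cov <- vi$mean_coverage
  if (is.null(cov)) cov <- rep(NA_real_, nrow(d))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(vi$ref),
    ALT = Biostrings::DNAStringSetList(as.list(vi$alt)),
    QUAL = rep(100, nrow(d)),
    FILTER = vi$filter_label)
  info <- S4Vectors::DataFrame(DP = as.integer(round(cov * n)))
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), n, dimnames = dimnames(d))
  ok <- !is.na(d)
  gt[ok] <- gtmap[d[ok] + 1L]

  hdr <- VariantAnnotation::VCFHeader(
    samples = colnames(d),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      INFO = S4Vectors::DataFrame(
        Number = "1", Type = "Integer",
        Description = "Total read depth across samples",
        row.names = "DP"),
      FORMAT = S4Vectors::DataFrame(
        Number = "1", Type = "String", Description = "Genotype",
        row.names = "GT")))
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = S4Vectors::DataFrame(Samples = seq_len(n),
                                   row.names = colnames(d)),
    exptData = list(header = hdr),
    fixed = fixed, info = info,
    geno = S4Vectors::SimpleList(GT = gt))
  vcfPath <- file.path(dir, paste0(prefix, ".vcf"))
  VariantAnnotation::writeVcf(vcf, vcfPath)

  csvPath <- file.path(dir, paste0(prefix, "_phenotypes.csv"))
  ph <- as.data.frame(sampleData(cohort))
  utils::write.csv(cbind(sample_id = rownames(ph), ph), csvPath,
                   row.names = FALSE)
  out <- c(vcf = vcfPath, phenotypes = csvPath)

  truth <- S4Vectors::metadata(cohort)$truth
  if (!is.null(truth)) {
    truthPath <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
    out <- c(out, truth = truthPath)
  }
  out
}
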