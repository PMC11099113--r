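#' Dichotomize a 4-level symptom item
#'
#' Maps the questionnaire scale to the binary moderate-severe phenotype:
#' "quite a bit" / "very much" become 1, "not at all" / "a little" become 0,
#' missing stays missing.  Integer inputs 1-4 are read as the same scale in
#' order.
#'
#' @param responses character or integer item responses.
#' @return integer vector in \{0, 1, NA\}.
#' @export
dichotomizeSymptom <- function(responses) {
  lev <- c("not at all", "a little", "quite a bit", "very much")
  if (is.numeric(responses)) {
    if (any(!is.na(responses) & !(responses %in% 1:4)))
      stop("integer responses must be 1..4")
    r <- responses
  } else {
    r <- match(tolower(trimws(as.character(responses))), lev)
    if (any(is.na(r) & !is.na(responses)))
      stop("out-of-scale response: ",
           paste(unique(responses[is.na(r) & !is.na(responses)]),
                 collapse = ", "))
  }
  as.integer(r >= 3)
}

#' Pipeline configuration
#'
#' Collects every tunable of \code{\link{runPipeline}} with the study's
#' parameter windows as defaults.  With \code{paperMode = TRUE} the
#' constructor additionally checks each threshold lies inside its documented
#' window (permutation-FDR grid 0.00001-0.005, gene-test p 0.001, ORA
#' thresholds 0.0025-0.2, importance grid 1.00-1.67).
#'
#' @param symptoms symptom (outcome column) names.
#' @param trainFraction,nTest,splitSeed cohort split settings; \code{nTest}
#'   fixes the test-set size exactly (the study: 100 of 337).
#' @param nPerm permutations for the FDR curve (study: 1000).
#' @param fdrGrid candidate p-value thresholds for the permutation FDR.
#' @param genePThreshold gene/region test selection threshold.
#' @param oraThresholds candidate over-representation thresholds searched
#'   for the best training AUC.
#' @param viGrid candidate variable-importance thresholds for final pruning.
#' @param b2TopK rank cap on scan SNVs entering the wider-inclusion stage.
#' @param targetAccuracy cutoff tuning target (study: around 0.80).
#' @param minCount scan minor-category floor.
#' @param covariates clinical covariate columns.
#' @param forcedCovariates covariates kept through importance pruning
#'   regardless of importance.
#' @param mafMax rare-variant bound for the region tests.
#' @param epvFloor events-per-variable floor of the overfitting guard.
#' @param seed master seed; all stage randomness derives from it.
#' @param paperMode validate thresholds against the documented windows.
#' @return list of class \code{"TipnConfig"}.
#' @export
pipelineConfig <- function(symptoms = c("numbness_feet", "tingling_feet",
                                        "cramps_feet", "open_jar",
                                        "climb_stairs"),
                           trainFraction = 0.7, nTest = NULL, splitSeed = NULL,
                           nPerm = 1000,
                           fdrGrid = c(0.00001, 0.0001, 0.00025, 0.0005,
                                       0.00075, 0.001, 0.0025, 0.005),
                           genePThreshold = 0.001,
                           oraThresholds = c(0.0025, 0.005, 0.02, 0.05, 0.13),
                           viGrid = c(1, 1.25, 1.33, 1.5, 1.67),
                           b2TopK = 40,
                           targetAccuracy = 0.8,
                           minCount = 5,
                           covariates = c("age", "bmi", "taxane", "diabetes"),
                           forcedCovariates = c("taxane", "bmi"),
                           mafMax = 0.01,
                           epvFloor = 1,
                           seed = 1L,
                           paperMode = FALSE) {
  cfg <- list(symptoms = symptoms, trainFraction = trainFraction,
              nTest = nTest, splitSeed = splitSeed, nPerm = nPerm,
              fdrGrid = fdrGrid, genePThreshold = genePThreshold,
              oraThresholds = oraThresholds, viGrid = viGrid,
              b2TopK = b2TopK, targetAccuracy = targetAccuracy,
              minCount = minCount, covariates = covariates,
              forcedCovariates = forcedCovariates, mafMax = mafMax,
              epvFloor = epvFloor, seed = as.integer(seed),
              paperMode = paperMode)
  if (paperMode) {
    stopifnot(all(fdrGrid >= 0.00001 & fdrGrid <= 0.005),
              genePThreshold <= 0.001,
              all(oraThresholds >= 0.0025 & oraThresholds <= 0.2),
              all(viGrid >= 1 & viGrid <= 1.67))
  }
  class(cfg) <- "TipnConfig"
  cfg
}

.derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1009 + k * 9973) %% 2147483629)
}

#' Run the staged prediction pipeline
#'
#' Per symptom: split the samples, apply variant QC, fit and evaluate the
#' literature-panel model (A1), the scan + permutation-FDR model (B1), the
#' wider-inclusion + gene-test + over-representation model (B2), combine
#' with the significant literature SNVs (C1), prune by variable importance
#' and refit (C2), choose a cutoff targeting the configured accuracy, and
#' apply the acceptance rule (train AUC > 80\%, test AUC > 60\%).  All
#' selection and tuning happens on the training samples only; held-out
#' samples are touched exclusively in the final evaluation calls.
#'
#' A failing stage aborts that symptom's branch (the error is recorded) and
#' the remaining symptoms continue.
#'
#' @param cohort a \linkS4class{TaxaneCohort} with outcomes in
#'   \code{colData}.
#' @param panel literature panel data.frame \code{(rsid, gene, source_p)}.
#' @param geneSets named list of gene sets (see \code{\link{readGmt}},
#'   \code{\link{makeGeneSets}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of class \code{"TipnRun"}: per-symptom results (fits, FDR
#'   curve, thresholds chosen, evaluation reports, acceptance decision),
#'   the QC log, the split, and the config echo.
#' @export
runPipeline <- function(cohort, panel, geneSets,
                        config = pipelineConfig()) {
  stopifnot(inherits(config, "TipnConfig"))
  unknown <- setdiff(config$symptoms, names(sampleData(cohort)))
  if (length(unknown))
    stop("unknown symptom column(s): ", paste(unknown, collapse = ", "))

  splitSeed <- if (is.null(config$splitSeed))
    .derive_seed(config$seed, 1L) else config$splitSeed
  sp <- splitCohort(colnames(cohort), config$trainFraction,
                    seed = splitSeed, nTest = config$nTest)

  qc <- filterVariants(cohort)
  qcCohort <- qc$cohort
  train <- qcCohort[, sp$train]
  test <- qcCohort[, sp$test]
  geneMap <- mapVariantsToGenes(qcCohort)
  snvGeneDf <- {
    gl <- variantInfo(qcCohort)$genes
    data.frame(variant_id = rep(rownames(qcCohort),
                                S4Vectors::elementNROWS(gl)),
               gene = unlist(as.list(gl)))
  }
  genesOf <- function(ids)
    unique(snvGeneDf$gene[snvGeneDf$variant_id %in% ids])

  out <- list(split = sp, qc_log = qc$log, config = config,
              n_variants_qc = nrow(qcCohort), symptoms = list())

  for (s in config$symptoms) {
    out$symptoms[[s]] <- tryCatch(
      .run_symptom(s, train, test, panel, geneSets, geneMap, snvGeneDf,
                   genesOf, config),
      error = function(e) list(error = conditionMessage(e)))
  }
  class(out) <- "TipnRun"
  out
}

.run_symptom <- function(s, train, test, panel, geneSets, geneMap,
                         snvGeneDf, genesOf, config) {
  yTr <- setNames(sampleData(train)[[s]], colnames(train))
  yTe <- setNames(sampleData(test)[[s]], colnames(test))
  covs <- intersect(config$covariates, names(sampleData(train)))
  nEvents <- min(sum(yTr == 1, na.rm = TRUE), sum(yTr == 0, na.rm = TRUE))
  maxSnvs <- max(1L, floor(nEvents / config$epvFloor) - length(covs))
  res <- list()
  evalBoth <- function(fit, label) {
    cutoff <- chooseCutoff(fit@trainProb,
                           yTr[names(fit@trainProb)],
                           config$targetAccuracy)
    pTe <- predictRisk(fit, test)
    list(cutoff = cutoff,
         train = evalReport(fit@trainProb, yTr[names(fit@trainProb)], cutoff,
                            seed = .derive_seed(config$seed, 11L)),
         test = evalReport(pTe, yTe, cutoff,
                           seed = .derive_seed(config$seed, 12L)))
  }

  ## A1 -- literature panel, additive coding
  panelSnvs <- intersect(panel$rsid, rownames(train))
  fitA1 <- suppressWarnings(
    buildStage(train, s, panelSnvs, covs, stage = "A1",
               epvFloor = config$epvFloor))
  res$A1 <- c(list(fit = fitA1), evalBoth(fitA1, "A1"))

  ## B1 -- scan + permutation FDR threshold
  scan <- snvScan(train, s, minCount = config$minCount)
  fdr <- permutationFdr(train, s, nPerm = config$nPerm,
                        thresholdGrid = config$fdrGrid,
                        seed = .derive_seed(config$seed, 21L),
                        minCount = config$minCount)
  b1Ids <- selectSnvs(scan, fdr$chosen_threshold)
  b1 <- scan[match(b1Ids, scan$variant_id), c("variant_id", "best_coding")]
  names(b1)[2] <- "coding"
  b1 <- head(b1[order(scan$best_p[match(b1$variant_id, scan$variant_id)]), ],
             maxSnvs)
  res$B1 <- list(fdr = fdr, n_selected = length(b1Ids))
  if (nrow(b1) >= 1) {
    fitB1 <- suppressWarnings(
      buildStage(train, s, b1, covs, stage = "B1",
                 epvFloor = config$epvFloor))
    res$B1 <- c(res$B1, list(fit = fitB1), evalBoth(fitB1, "B1"))
  }

  ## B2 -- wider inclusion + gene tests + over-representation filter
  ord <- order(scan$best_p)
  wider <- scan[head(ord, config$b2TopK), c("variant_id", "best_coding")]
  names(wider)[2] <- "coding"
  gt <- regionScan(train, s, geneMap, covariates = covs,
                   mafMax = config$mafMax)
  gsel <- selectGenes(gt, config$genePThreshold)
  geneVars <- unique(unlist(geneMap[gsel$genes], use.names = FALSE))
  geneVars <- setdiff(geneVars, wider$variant_id)
  cand <- rbind(wider,
                if (length(geneVars))
                  data.frame(variant_id = geneVars, coding = "additive"))
  candGenes <- genesOf(cand$variant_id)
  universe <- unique(snvGeneDf$gene)

  bestB2 <- NULL
  for (thr in sort(config$oraThresholds)) {
    ef <- enrichAndFilter(candGenes, geneSets, universe = universe,
                          threshold = thr, snvGeneMap = snvGeneDf)
    ids <- intersect(cand$variant_id, ef$snvs)
    if (length(ids) < 1) next
    feats <- cand[cand$variant_id %in% ids, ]
    feats <- head(feats[order(match(feats$variant_id, cand$variant_id)), ],
                  maxSnvs)
    fit <- tryCatch(suppressWarnings(
      buildStage(train, s, feats, covs, stage = "B2",
                 epvFloor = config$epvFloor)),
      error = function(e) NULL)
    if (is.null(fit)) next
    auc <- rocAuc(fit@trainProb, yTr[names(fit@trainProb)])
    if (is.null(bestB2) || auc > bestB2$train_auc)
      bestB2 <- list(fit = fit, ora_threshold = thr, train_auc = auc,
                     enrichment = ef$table)
  }
  if (is.null(bestB2))
    stop("no over-representation threshold yields a fittable model")
  res$B2 <- c(bestB2, evalBoth(bestB2$fit, "B2"),
              list(genes_selected = gsel$genes, qq = gsel$qq))

  ## C1 -- add literature SNVs significant in the source meta-analysis
  litSig <- intersect(panel$rsid[panel$source_p < 0.05], rownames(train))
  b2feats <- modelFeatures(bestB2$fit)
  c1 <- data.frame(
    variant_id = b2feats$feature[b2feats$kind == "snv"],
    coding = b2feats$coding[b2feats$kind == "snv"])
  addLit <- setdiff(litSig, c1$variant_id)
  if (length(addLit))
    c1 <- rbind(c1, data.frame(variant_id = addLit, coding = "additive"))
  c1 <- head(c1, maxSnvs)
  fitC1 <- suppressWarnings(
    buildStage(train, s, c1, covs, stage = "C1",
               epvFloor = config$epvFloor))
  res$C1 <- list(fit = fitC1, literature_added = addLit)

  ## C2 -- variable-importance pruning, threshold tuned on training AUC
  forced <- intersect(config$forcedCovariates, covs)
  bestC2 <- NULL
  for (v in config$viGrid) {
    spec <- tryCatch(pruneByVi(fitC1, v, forced), error = function(e) NULL)
    if (is.null(spec) || nrow(spec$snvs) + length(spec$covariates) == 0) next
    fit <- tryCatch(suppressWarnings(
      buildStage(train, s, spec$snvs, spec$covariates, stage = "C2",
                 epvFloor = config$epvFloor)),
      error = function(e) NULL)
    if (is.null(fit)) next
    auc <- rocAuc(fit@trainProb, yTr[names(fit@trainProb)])
    if (is.null(bestC2) || auc > bestC2$train_auc)
      bestC2 <- list(fit = fit, vi_threshold = v, train_auc = auc)
  }
  if (is.null(bestC2))
    stop("importance pruning left no fittable model")
  res$C2 <- c(bestC2, evalBoth(bestC2$fit, "C2"))
  res$C2$decision <- acceptModel(res$C2$train, res$C2$test)
  res$selected_features <- modelFeatures(bestC2$fit)$feature
  res
}

#' @export
print.TipnRun <- function(x, ...) {
  cat("tipnpred pipeline run:", x$n_variants_qc, "variants after QC;",
      length(x$split$train), "train /", length(x$split$test), "test samples\n")
  for (s in names(x$symptoms)) {
    r <- x$symptoms[[s]]
    if (!is.null(r$error)) {
      cat(sprintf("  %-16s ERROR: %s\n", s, r$error))
    } else {
      cat(sprintf(
        "  %-16s C2: %d SNVs, train AUC %.2f%%, test AUC %.2f%% -> %s\n",
        s, sum(modelFeatures(r$C2$fit)$kind == "snv"),
        r$C2$train$auc, r$C2$test$auc, r$C2$decision))
    }
  }
  invisible(x)
}
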