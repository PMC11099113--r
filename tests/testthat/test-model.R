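test_that("singularity screening drops later duplicates until full rank", {
  set.seed(17)
  X <- cbind(`(Intercept)` = 1, a = rnorm(50), b = rnorm(50))
  X <- cbind(X, a_copy = X[, "a"], const = 2)
  rs <- removeSingularities(X)
  expect_setequal(rs$dropped, c("a_copy", "const"))
  expect_equal(colnames(rs$X), c("(Intercept)", "a", "b"))

  # random full-rank matrix: nothing dropped (rank checked independently)
  M <- cbind(1, matrix(rnorm(50 * 9), 50, 9))
  expect_equal(qr(M)$rank, 10)
  expect_length(removeSingularities(M)$dropped, 0)

  # exact linear combination of two predictors is caught
  Y <- cbind(`(Intercept)` = 1, u = rnorm(30), v = rnorm(30))
  Y <- cbind(Y, w = Y[, "u"] - 2 * Y[, "v"])
  expect_equal(removeSingularities(Y)$dropped, "w")
})

test_that("stage building fits, drops singular SNVs, and guards overfitting", {
  co <- simulateCohort(nSamples = 500, nVariants = 60, seed = 19,
                       commonFraction = 1, nCausalPerSymptom = 5,
                       missingItemRate = 0.01)
  ids <- rownames(co)[1:10]
  fit <- suppressWarnings(buildStage(co, "numbness_feet", ids, stage = "A1"))
  ft <- modelFeatures(fit)
  expect_s4_class(fit, "TipnFit")
  expect_equal(fit@stage, "A1")
  expect_setequal(ft$feature[ft$kind == "covariate"],
                  c("age", "bmi", "taxane", "diabetes"))
  expect_true(all(ft$vi >= 0))
  # missing outcomes excluded from the fit
  expect_equal(fit@nUsed,
               sum(!is.na(sampleData(co)$numbness_feet)))

  # duplicated SNV column: exactly one copy dropped, fit proceeds
  d2 <- rbind(dosage(co), dup = dosage(co)[ids[1], ])
  vi2 <- rbind(variantInfo(co), variantInfo(co)[ids[1], ])
  rownames(vi2)[nrow(vi2)] <- "dup"
  co2 <- TaxaneCohort(d2, vi2, sampleData(co))
  fit2 <- suppressWarnings(
    buildStage(co2, "numbness_feet", c(ids, "dup"), stage = "A1"))
  expect_true("dup" %in% fit2@dropped)

  # overfitting guard refuses more features than events allow
  expect_error(
    suppressWarnings(
      buildStage(co[, 1:100], "climb_stairs", rownames(co), stage = "B1")),
    "overfitting guard")
})

test_that("refitting a model on its own features reproduces the betas", {
  co <- simulateCohort(nSamples = 400, nVariants = 30, seed = 23,
                       commonFraction = 1, missingItemRate = 0)
  fit <- suppressWarnings(
    buildStage(co, "tingling_feet", rownames(co)[1:6]))
  ft <- modelFeatures(fit)
  snvs <- data.frame(variant_id = ft$feature[ft$kind == "snv"],
                     coding = ft$coding[ft$kind == "snv"])
  refit <- suppressWarnings(
    buildStage(co, "tingling_feet", snvs,
               ft$feature[ft$kind == "covariate"]))
  expect_equal(modelFeatures(refit)$beta, ft$beta, tolerance = 1e-8)
  expect_equal(refit@intercept, fit@intercept, tolerance = 1e-8)
})

test_that("variable importance is |Wald z| and pruning respects the boundary", {
  co <- simulateCohort(nSamples = 600, nVariants = 40, seed = 29,
                       commonFraction = 1, nCausalPerSymptom = 4,
                       effectSize = 1.2, missingItemRate = 0)
  fit <- suppressWarnings(
    buildStage(co, "numbness_feet", rownames(co)[1:12]))
  ft <- modelFeatures(fit)
  expect_equal(unname(variableImportance(fit)),
               abs(ft$beta / ft$se), tolerance = 1e-10)

  # vi = |beta|/se so beta 0.5, se 0.5 -> vi 1 (definition check on a row)
  expect_equal(ft$vi, abs(ft$z))

  # boundary inclusive: a feature at exactly the threshold is retained
  thr <- sort(ft$vi[ft$kind == "snv"], decreasing = TRUE)[3]
  spec <- pruneByVi(fit, thr, forcedCovariates = character())
  expect_true(sum(ft$vi[ft$kind == "snv"] >= thr) == nrow(spec$snvs))
  expect_true(all(spec$snvs$variant_id %in%
                    ft$feature[ft$vi >= thr & ft$kind == "snv"]))

  # threshold 0 keeps everything; +Inf with forced covariates keeps only them
  all_kept <- pruneByVi(fit, 0, forcedCovariates = character())
  expect_equal(nrow(all_kept$snvs), sum(ft$kind == "snv"))
  forced <- pruneByVi(fit, Inf, forcedCovariates = c("taxane", "bmi"))
  expect_equal(nrow(forced$snvs), 0)
  expect_setequal(forced$covariates, c("taxane", "bmi"))
  expect_error(pruneByVi(fit, Inf, forcedCovariates = character()),
               "no features")
})

test_that("importance is scale-free for rescaled genotype predictors", {
  set.seed(31)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g))
  f1 <- fitLogistic(cbind(1, g), y)
  f2 <- fitLogistic(cbind(1, g / 2), y)
  expect_equal(unname(abs(f1$z[2])), unname(abs(f2$z[2])), tolerance = 1e-6)
})

test_that("prediction on new samples uses stored codings and imputation", {
  co <- simulateCohort(nSamples = 300, nVariants = 25, seed = 37,
                       commonFraction = 1, missingItemRate = 0)
  tr <- co[, 1:200]
  te <- co[, 201:300]
  fit <- suppressWarnings(buildStage(tr, "cramps_feet", rownames(co)[1:5]))
  p <- predictRisk(fit, te)
  expect_length(p, 100)
  expect_true(all(p >= 0 & p <= 1))
  # prediction on the training cohort reproduces the fitted probabilities
  pin <- predictRisk(fit, tr)
  used <- names(fit@trainProb)
  expect_equal(unname(pin[used]), unname(fit@trainProb), tolerance = 1e-10)
})
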