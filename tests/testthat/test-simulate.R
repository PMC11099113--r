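test_that("genotype simulation hits its MAF targets and is reproducible", {
  co <- simulateGenotypes(nSamples = 4000, nVariants = 30, maf = 0.3, seed = 5)
  emp <- computeMaf(dosage(co))
  # binomial sampling bound on the max over 30 variants: 3.6 SD keeps the
  # familywise false-alarm rate near 1 percent
  bound <- 3.6 * sqrt(0.3 * 0.7 / (2 * 4000))
  expect_true(all(abs(emp - 0.3) < bound))

  again <- simulateGenotypes(nSamples = 4000, nVariants = 30, maf = 0.3,
                             seed = 5)
  expect_identical(dosage(co), dosage(again))
  other <- simulateGenotypes(nSamples = 4000, nVariants = 30, maf = 0.3,
                             seed = 6)
  expect_false(identical(dosage(co), dosage(other)))
})

test_that("unlinked variants have near-zero dosage correlation, linked ones do not", {
  co <- simulateGenotypes(nSamples = 2000, nVariants = 12, maf = 0.3, seed = 2,
                          ldBlocks = list(size = 3, rho = 0))
  cc <- cor(t(dosage(co)))
  off <- cc[upper.tri(cc)]
  expect_lt(max(abs(off)), 4 / sqrt(2000))

  ld <- simulateGenotypes(nSamples = 2000, nVariants = 12, maf = 0.3, seed = 2,
                          ldBlocks = list(size = 3, rho = 0.8))
  cl <- cor(t(dosage(ld)))
  within <- c(cl[1, 2], cl[1, 3], cl[4, 5], cl[7, 8])
  expect_gt(min(within), 0.3)
})

test_that("marginal genotype frequencies satisfy Hardy-Weinberg", {
  co <- simulateGenotypes(nSamples = 5000, nVariants = 40, seed = 9,
                          commonFraction = 1)
  d <- dosage(co)
  p <- hweExactP(rowSums(d == 0), rowSums(d == 1), rowSums(d == 2))
  expect_gt(min(p), 1e-4)   # no gross HWE violation among 40 variants
})

test_that("intercept calibration reproduces the target prevalences", {
  co <- simulateCohort(nSamples = 3000, nVariants = 60, seed = 3,
                       commonFraction = 1, nCausalPerSymptom = 5,
                       missingItemRate = 0)
  ph <- sampleData(co)
  for (s in S4Vectors::metadata(co)$symptoms) {
    target <- S4Vectors::metadata(co)$truth$symptoms[[s]]$target_prevalence
    emp <- mean(ph[[s]])
    expect_lt(abs(emp - target), 3 * sqrt(target * (1 - target) / 3000))
  }
})

test_that("covariate moments match the cohort characteristics emulated", {
  co <- simulateCohort(nSamples = 5000, nVariants = 20, seed = 8)
  ph <- sampleData(co)
  expect_lt(abs(mean(ph$age) - 62), 1)
  expect_true(all(ph$age >= 31 & ph$age <= 86))
  expect_lt(abs(mean(ph$bmi) - 26.9), 0.3)
  expect_lt(abs(mean(ph$taxane) - 0.445), 3 * sqrt(0.445 * 0.555 / 5000))
  expect_lt(abs(mean(ph$diabetes) - 0.047), 3 * sqrt(0.047 * 0.953 / 5000))
})

test_that("a planted strong effect is the top association at large n", {
  co <- simulateCohort(nSamples = 5000, nVariants = 50, seed = 12,
                       commonFraction = 1, nCausalPerSymptom = 1,
                       effectSize = 2,
                       codingProbs = c(additive = 1, dominant = 0,
                                       recessive = 0),
                       targetPrevalences = c(numbness_feet = 0.255),
                       missingItemRate = 0)
  truth <- S4Vectors::metadata(co)$truth$symptoms$numbness_feet
  sc <- snvScan(co, "numbness_feet")
  expect_equal(sc$variant_id[which.min(sc$best_p)], truth$causal)
})

test_that("null phenotypes are independent of genotypes and covariates", {
  # all genetic and covariate effects zero -> association chi-square flat
  reject <- 0
  for (s in 1:25) {
    co <- simulateCohort(nSamples = 400, nVariants = 10, seed = 100 + s,
                         effectSize = 0,
                         covariateEffects = c(age = 0, bmi = 0, taxane = 0,
                                              diabetes = 0),
                         targetPrevalences = c(numbness_feet = 0.255),
                         missingItemRate = 0)
    ph <- sampleData(co)
    p <- suppressWarnings(
      chisq.test(table(ph$numbness_feet, ph$taxane))$p.value)
    if (p < 0.05) reject <- reject + 1
  }
  expect_lte(reject, 4)   # >= 94% of seeds look independent at the 5% level
})

test_that("written cohort files round-trip through the VCF reader", {
  co <- simulateCohort(nSamples = 15, nVariants = 40, seed = 4,
                       genotypeMissingRate = 0.03)
  dir <- withr::local_tempdir()
  files <- writeCohortVcf(co, dir, "rt")
  expect_true(all(file.exists(files)))
  ph <- utils::read.csv(files["phenotypes"], row.names = 1)
  back <- readCohortVcf(files["vcf"], phenotypes = ph)
  expect_identical(dosage(back)[rownames(co), colnames(co)], dosage(co))
  expect_equal(sampleData(back)$age, sampleData(co)$age)
  truth <- jsonlite::read_json(files["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$symptoms$numbness_feet$causal),
               sort(S4Vectors::metadata(co)$truth$symptoms$numbness_feet$causal))
})
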