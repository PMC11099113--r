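test_that("logistic engine matches closed forms and the Newton oracle", {
  # intercept-only: beta0 = logit of the positive fraction
  y <- rep(c(1, 0), c(25, 75))
  f <- fitLogistic(matrix(1, 100, 1), y)
  expect_equal(unname(f$beta), log(0.25 / 0.75), tolerance = 1e-8)

  # 20-row fixture vs an independently coded Newton-Raphson fit
  set.seed(3)
  X <- cbind(1, rnorm(20), rbinom(20, 1, 0.5))
  y <- rbinom(20, 1, plogis(0.3 * X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  f <- fitLogistic(X, y)
  o <- nr_logistic_oracle(X, y)
  expect_equal(unname(f$beta), o$beta, tolerance = 1e-6)
  expect_equal(unname(f$se), o$se, tolerance = 1e-6)
  expect_true(f$converged)
  expect_false(f$separation)

  # perfectly separating predictor is flagged
  xs <- c(rep(0, 10), rep(1, 10))
  fs <- fitLogistic(cbind(1, xs), xs)
  expect_true(fs$separation)

  expect_error(fitLogistic(matrix(1, 10, 1), rep(1, 10)), "variance")
  expect_error(fitLogistic(cbind(1, 1:10, 1:10), rbinom(10, 1, .5)),
               "rank-deficient")
})

test_that("scan agrees with glm per coding and picks the best coding", {
  set.seed(21)
  n <- 300
  g <- sample(0:2, n, TRUE, prob = c(0.45, 0.4, 0.15))
  y <- rbinom(n, 1, plogis(-1 + 0.6 * (g >= 1)))
  d <- matrix(as.integer(g), 1, dimnames = list("v", NULL))
  sc <- snvScan(d, y)
  for (cod in c("additive", "dominant", "recessive")) {
    gl <- glm(y ~ recodeDosage(g, cod), family = binomial)
    cf <- summary(gl)$coefficients
    expect_equal(sc[[paste0("beta_", cod)]], cf[2, 1], tolerance = 1e-6)
    expect_equal(sc[[paste0("se_", cod)]], cf[2, 2], tolerance = 1e-5)
    expect_equal(sc[[paste0("p_", cod)]], cf[2, 4], tolerance = 1e-4)
  }
  expect_equal(sc$best_p,
               min(sc$p_additive, sc$p_dominant, sc$p_recessive))
  # additive-coding p equals a plain fit on the raw dosage
  fl <- fitLogistic(cbind(1, g), y)
  expect_equal(sc$p_additive, unname(fl$p[2]), tolerance = 1e-4)
})

test_that("scan skips degenerate codings and monomorphic variants", {
  n <- 100
  d <- rbind(mono = rep(0L, n),
             rare = c(rep(0L, n - 2), 1L, 1L))   # 2 carriers < minCount
  y <- rep(c(0L, 1L), n / 2)
  sc <- snvScan(d, y, minCount = 5)
  expect_equal(sc$best_p, c(1, 1))
  expect_true(all(is.na(sc$beta_additive)))
  # ties at p = 1 resolve to additive first
  expect_equal(sc$best_coding, c("additive", "additive"))
})

test_that("planted dominant effects are recovered with the right coding", {
  hits <- 0
  for (s in 1:25) {
    set.seed(700 + s)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-1.5 + 1.5 * (g >= 1)))
    d <- matrix(as.integer(g), 1, dimnames = list("v", NULL))
    sc <- snvScan(d, y)
    if (sc$best_coding == "dominant") hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= ~90 percent allowing for binomial noise at 25 seeds
})

test_that("null scan p-values are uniform", {
  ps <- c()
  for (s in 1:2) {
    co <- simulateGenotypes(nSamples = 400, nVariants = 500, seed = 800 + s,
                            commonFraction = 1)
    set.seed(900 + s)
    y <- rbinom(400, 1, 0.25)
    sc <- snvScan(co, y)
    ps <- c(ps, sc$p_additive[!is.na(sc$beta_additive)])
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation FDR curve is reproducible and re-derivable", {
  co <- simulateGenotypes(nSamples = 200, nVariants = 300, seed = 31,
                          commonFraction = 1)
  set.seed(55)
  y <- rbinom(200, 1, 0.3)
  f1 <- permutationFdr(co, y, nPerm = 50, seed = 7)
  f2 <- permutationFdr(co, y, nPerm = 50, seed = 7)
  expect_identical(f1, f2)
  # the curve is a pure function of its stored components
  expect_equal(f1$fdr,
               pmin(1, f1$mean_null_hits / pmax(1, f1$observed_hits)))
  # observed hits non-decreasing in the threshold
  expect_true(all(diff(f1$observed_hits) >= 0))
  expect_error(permutationFdr(co, y, nPerm = 50, thresholdGrid = numeric()),
               "empty")
})

test_that("zero observed hits cap the FDR at the mean null count", {
  # engineered: one strong variant only; at tiny thresholds no observed hits
  co <- simulateGenotypes(nSamples = 150, nVariants = 50, seed = 77,
                          commonFraction = 1)
  set.seed(78)
  y <- rbinom(150, 1, 0.3)
  f <- permutationFdr(co, y, nPerm = 30, seed = 9,
                      thresholdGrid = c(1e-10, 0.5))
  i <- which(f$observed_hits == 0)
  expect_true(length(i) >= 1)
  expect_equal(f$fdr[i], pmin(1, f$mean_null_hits[i]))
})

test_that("null FDR estimates concentrate near one with sampling-bounded dips", {
  # under a global null the true FDR is 1; the ratio estimator at k observed
  # hits carries ~1/sqrt(k) relative noise, so estimates concentrate near 1
  # and dips are bounded by a sampling envelope
  vals <- c(); ks <- c()
  for (s in 1:3) {
    co <- simulateGenotypes(nSamples = 300, nVariants = 800, seed = 1500 + s,
                            commonFraction = 1)
    set.seed(1600 + s)
    y <- rbinom(300, 1, 0.25)
    f <- permutationFdr(co, y, nPerm = 100, seed = 1700 + s)
    sel <- f$observed_hits >= 5
    vals <- c(vals, f$fdr[sel])
    ks <- c(ks, f$observed_hits[sel])
  }
  expect_gte(mean(vals), 0.8)
  expect_true(all(vals >= pmax(0.3, 1 - 3 / sqrt(ks))))
})

test_that("variant selection respects the threshold boundary and score filter", {
  res <- data.frame(variant_id = paste0("v", 1:10),
                    best_p = c(0.0001, 0.001, 0.00100001, 0.002, 0.5,
                               0.9, 1, 0.05, 0.01, 0.0005),
                    deleterious_score = c(20, 5, 20, 20, 20, 20, 20, 20, 20, 13))
  expect_setequal(selectSnvs(res, 0.001), c("v1", "v2", "v10"))
  expect_setequal(selectSnvs(res, 1), res$variant_id)
  expect_length(selectSnvs(res, 1e-6), 0)
  expect_setequal(selectSnvs(res, 0.001, minDeleteriousScore = 13),
                  c("v1", "v10"))
})
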