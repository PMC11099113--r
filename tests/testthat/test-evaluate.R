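test_that("cohort split honours sizes, determinism and stratification", {
  ids <- sprintf("S%03d", 1:337)
  sp <- splitCohort(ids, 0.7, seed = 1, nTest = 100)
  expect_length(sp$train, 237)
  expect_length(sp$test, 100)
  expect_length(intersect(sp$train, sp$test), 0)

  # default convention floors the test-set size
  sp2 <- splitCohort(ids, 0.7, seed = 1)
  expect_length(sp2$test, floor(0.3 * 337))

  expect_identical(splitCohort(ids, 0.7, seed = 5),
                   splitCohort(ids, 0.7, seed = 5))

  strat <- rep(c(0, 1), c(250, 87))
  sp3 <- splitCohort(ids, 0.7, seed = 2, stratifyBy = strat)
  for (g in 0:1) {
    inTest <- sum(ids[strat == g] %in% sp3$test)
    expect_lte(abs(inTest - 0.3 * sum(strat == g)), 1)
  }
  expect_error(splitCohort(ids[1:2], 0.9), "empty")
})

test_that("rank AUC equals pair counting, including ties", {
  expect_equal(rocAuc(c(.9, .8, .3, .2), c(1, 1, 0, 0)), 100)
  # 6-point fixture with a tie straddling the classes
  s <- c(0.1, 0.4, 0.4, 0.5, 0.7, 0.9)
  l <- c(0, 0, 1, 0, 1, 1)
  expect_equal(rocAuc(s, l), auc_pairs_oracle(s, l))
  set.seed(43)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb), auc_pairs_oracle(sc, lb))
    expect_equal(rocAuc(sc, lb) + rocAuc(-sc, lb), 100)
  }
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")

  # cross-check against an established ROC implementation
  set.seed(97)
  sc <- rnorm(200)
  lb <- rbinom(200, 1, plogis(sc))
  expect_equal(rocAuc(sc, lb),
               100 * as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUC near 50 for labels independent of scores", {
  set.seed(47)
  n <- 4000
  auc <- rocAuc(rnorm(n), rbinom(n, 1, 0.5))
  # 3 SE of the Mann-Whitney statistic under the null
  se <- 100 * sqrt((n / 2 + n / 2 + 1) / (12 * (n / 2) * (n / 2)))
  expect_lt(abs(auc - 50), 3 * se)
})

test_that("bootstrap CI is stratified, deterministic, and covers", {
  s <- c(rep(0.9, 10), rep(0.1, 10))
  l <- rep(c(1, 0), each = 10)
  ci <- aucCi(s, l, nBoot = 200, seed = 3)
  expect_equal(ci[2], 100)
  expect_identical(aucCi(s, l, nBoot = 200, seed = 3),
                   aucCi(s, l, nBoot = 200, seed = 3))
  expect_error(aucCi(s, l, nBoot = 50), "nBoot")

  # coverage: CI contains the point AUC in nearly all repeats
  set.seed(51)
  hit <- 0
  for (i in 1:60) {
    sc <- rnorm(120)
    lb <- rbinom(120, 1, plogis(sc))
    if (length(unique(lb)) < 2) next
    a <- rocAuc(sc, lb)
    ci <- aucCi(sc, lb, nBoot = 200, seed = i)
    if (a >= ci[1] && a <= ci[2]) hit <- hit + 1
  }
  expect_gte(hit, 56)
})

test_that("confusion metrics satisfy their identities at any cutoff", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(20:80, 1)
    p <- runif(n)
    y <- rbinom(n, 1, p)
    if (length(unique(y)) < 2) next
    cut <- runif(1, 0.05, 0.95)
    cm <- confusionAtCutoff(p, y, cut)
    cf <- cm$confusion
    expect_equal(cf[["TP"]] + cf[["FN"]], sum(y == 1))
    expect_equal(cf[["TN"]] + cf[["FP"]], sum(y == 0))
    expect_equal(cm$accuracy,
                 100 * (cf[["TP"]] + cf[["TN"]]) / n)
    expect_equal(cm$sensitivity, 100 * cf[["TP"]] / sum(y == 1))
    expect_equal(cm$specificity, 100 * cf[["TN"]] / sum(y == 0))
  }
  p <- c(0.2, 0.6, 0.7, 0.3)
  y <- c(0, 1, 1, 0)
  # near-zero cutoff: everything called positive
  cm0 <- confusionAtCutoff(p, y, 1e-9)
  expect_equal(cm0$sensitivity, 100)
  expect_equal(cm0$specificity, 0)
  expect_error(confusionAtCutoff(p, y, 0), "cutoff")
  expect_error(confusionAtCutoff(p, y, 1), "cutoff")
  expect_error(confusionAtCutoff(c(1.2, p[-1]), y, 0.5), "probabilities")
})

test_that("risk-group toxicity shares are the observed positive fractions", {
  p <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  y <- c(1, 1, 0, 1, 0, 0)
  cm <- confusionAtCutoff(p, y, 0.5)
  expect_equal(cm$high_group_toxicity, 100 * 2 / 3)
  expect_equal(cm$low_group_toxicity, 100 * 1 / 3)
})

test_that("cutoff choice targets the accuracy with the stated tie-breaks", {
  # perfectly separating model where 100 is the closest achievable accuracy
  p <- c(0.1, 0.9)
  y <- c(0, 1)
  cut <- chooseCutoff(p, y, 0.8)
  expect_equal(confusionAtCutoff(p, y, cut)$accuracy, 100)
  # ... but the rule minimizes |accuracy - target|: with intermediate
  # cutoffs achieving 75 percent, 75 beats 100 for a target of 80
  p2b <- c(0.1, 0.2, 0.8, 0.9)
  y2b <- c(0, 0, 1, 1)
  cut2b <- chooseCutoff(p2b, y2b, 0.8)
  expect_equal(confusionAtCutoff(p2b, y2b, cut2b)$accuracy, 75)

  # calibrated probabilities: achieved accuracy lands near the target
  set.seed(59)
  pp <- runif(500)
  yy <- rbinom(500, 1, pp)
  cut2 <- chooseCutoff(pp, yy, 0.8)
  acc <- confusionAtCutoff(pp, yy, cut2)$accuracy
  grid <- sort(unique(pp))
  best <- min(vapply((head(grid, -1) + grid[-1]) / 2,
                     function(ct) abs(confusionAtCutoff(pp, yy, ct)$accuracy - 80),
                     0))
  expect_equal(abs(acc - 80), best, tolerance = 1e-10)  # grid-optimal

  # tie on accuracy resolves toward higher sensitivity
  p3 <- c(0.1, 0.35, 0.65, 0.9)
  y3 <- c(1, 0, 1, 0)
  cut3 <- chooseCutoff(p3, y3, 0.5)
  cm3 <- confusionAtCutoff(p3, y3, cut3)
  expect_equal(cm3$accuracy, 50)
  expect_equal(cm3$sensitivity, 100)
})

test_that("Welch test matches the hand-computed fixture and calibrates", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  w <- welchT(a, b)
  va <- var(a) / 12; vb <- var(b) / 12
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 11 + vb^2 / 11)
  expect_equal(w$t, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  same <- c(1, 2, 3, 4)
  w0 <- welchT(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welchT(rep(1, 5), rep(1, 5)), "variance")

  set.seed(61)
  ps <- replicate(300, welchT(rnorm(15), rnorm(20, sd = 2))$p)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("acceptance rule applies strict AUC bounds on both cohorts", {
  mk <- function(a) list(auc = a)
  expect_equal(acceptModel(mk(88.87), mk(72.91)), "accepted")
  expect_equal(acceptModel(mk(85.69), mk(42.98)), "rejected")
  expect_equal(acceptModel(mk(80.00), mk(72.91)), "rejected")  # strict
  expect_equal(acceptModel(mk(90.00), mk(60.00)), "rejected")
})
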