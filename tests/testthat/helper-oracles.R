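# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Hardy-Weinberg exact p by direct log-factorial enumeration of the
# Levene-Haldane distribution (the package uses the mode-anchored recurrence).
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  nA <- 2 * aa + ab
  nB <- 2 * bb + ab
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(ab, hs)] * (1 + 1e-7)])
}

# Full-design Newton-Raphson logistic fit (analytic score/Hessian), no IRLS.
nr_logistic_oracle <- function(X, y, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * (mu * (1 - mu)))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(X, X * (mu * (1 - mu)))
  list(beta = beta, se = sqrt(diag(solve(H))))
}

# AUC by exhaustive pair counting (ties count one half).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  100 * mean(cmp)
}

# Upper-tail hypergeometric by explicit factorial sums.
hyper_tail_oracle <- function(k, K, N, m) {
  kk <- k:min(K, m)
  sum(exp(lchoose(K, kk) + lchoose(N - K, m - kk) - lchoose(N, m)))
}

# Small deterministic cohort for plumbing tests: 6 variants engineered so the
# QC filter removes exactly one per rule, plus one clean survivor.
make_qc_fixture <- function() {
  n <- 40
  ids <- c("v_lowrate", "v_lowcov", "v_hwe", "v_multi", "v_lowqual", "v_clean")
  d <- matrix(1L, nrow = 6, ncol = n,
              dimnames = list(ids, sprintf("S%02d", 1:n)))
  base <- rep(c(0L, 1L, 2L, 1L, 0L), length.out = n)   # HWE-compatible mix
  for (i in 1:6) d[i, ] <- base
  d["v_lowrate", 1:3] <- NA_integer_                   # rate 37/40 < 0.95
  d["v_hwe", ] <- rep(c(0L, 2L), length.out = n)       # no hets at all
  vi <- S4Vectors::DataFrame(
    chrom = "chr1", pos = 1:6 * 100L, ref = "A", alt = "G",
    filter_label = c("PASS", "PASS", "PASS", "PASS", "LowQual", "PASS"),
    mean_coverage = c(50, 5, 50, 50, 50, 50),
    biallelic = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    row.names = ids)
  TaxaneCohort(d, vi)
}
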