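#' Map variants to genes
#'
#' Builds the gene -> variant-id index used by the region tests.  Accepts
#' either a two-column data.frame (\code{variant_id}, \code{gene}) or a
#' cohort whose \code{rowData(x)$genes} is a \code{CharacterList}; a variant
#' lying in overlapping genes contributes to each of them.  Genes carrying
#' fewer than \code{minVariants} variants are excluded from testing (the
#' region statistic needs at least two variants to be a region).
#'
#' @param x a \linkS4class{TaxaneCohort} with gene annotation, or a
#'   data.frame \code{(variant_id, gene)}.
#' @param minVariants minimum variants per retained gene (default 2).
#' @return named list: gene -> character vector of variant ids.
#' @export
mapVariantsToGenes <- function(x, minVariants = 2) {
  if (methods::is(x, "TaxaneCohort")) {
    gl <- variantInfo(x)$genes
    if (is.null(gl)) stop("cohort has no rowData()$genes annotation")
    ids <- rep(rownames(x), S4Vectors::elementNROWS(gl))
    ann <- data.frame(variant_id = ids, gene = unlist(as.list(gl)))
  } else {
    ann <- x
    if (!all(c("variant_id", "gene") %in% names(ann)))
      stop("annotation needs columns variant_id and gene")
  }
  if (nrow(ann) == 0) return(list())
  sets <- split(ann$variant_id, ann$gene)
  sets <- lapply(sets, unique)
  sets[vapply(sets, length, 0L) >= minVariants]
}

#' Variance-component score test for a variant region
#'
#' Tests joint association of a set of (typically rare) variants with a
#' binary outcome.  With \eqn{\hat\mu} the fitted values of the null
#' logistic model \code{y ~ X} and \eqn{W = \mathrm{diag}(w_j)},
#' \deqn{Q = (y-\hat\mu)^\top G W^2 G^\top (y-\hat\mu),}
#' and the null distribution of \eqn{Q} is the usual mixture of
#' \eqn{\chi^2_1} variables whose weights are the eigenvalues of the
#' projected weighted kernel.  The p-value comes either from a three-moment
#' chi-square approximation to that mixture (matching \eqn{\sum\lambda^k},
#' k = 1..4) or, by default at small cohort sizes where the asymptotic
#' mixture is miscalibrated, from the exact conditional null obtained by
#' permuting the null-model residuals (see \code{pMethod}).
#'
#' Weights default to the Beta(1, 25) density evaluated at each variant's
#' MAF, the conventional rare-variant upweighting; pass
#' \code{weights = "flat"} for unit weights.  Missing genotypes are filled
#' with the variant mean dosage (the usual convention for kernel tests).
#'
#' @param G samples x variants dosage matrix for the region (\eqn{\ge} 2
#'   variants unless \code{allowSingle}).
#' @param y binary outcome.
#' @param X optional covariate matrix (no intercept column; one is added).
#' @param weights \code{"beta"} (default), \code{"flat"}, or a numeric
#'   vector of per-variant weights.
#' @param allowSingle allow a single-variant region (the statistic then
#'   reduces to the univariate score test).
#' @param pMethod \code{"auto"} (default), \code{"moment"} or
#'   \code{"permutation"}.  The eigenvalue mixture is an asymptotic null:
#'   with a binary outcome and rare, heavily upweighted variants its
#'   moment-matched tail is visibly miscalibrated at cohort sizes in the
#'   hundreds, so \code{"auto"} uses the exact conditional (permutation)
#'   null below 2000 usable samples and the moment approximation above.
#' @param nPerm permutations for the permutation null (default 1000).
#' @param seed seed for the permutation draws.
#' @return list with \code{Q}, \code{p}, \code{p_method} ("moment" or
#'   "permutation"), \code{n_variants}, \code{lambda}.
#' @export
regionScoreTest <- function(G, y, X = NULL, weights = "beta",
                            allowSingle = FALSE,
                            pMethod = c("auto", "moment", "permutation"),
                            nPerm = 1000, seed = 1L) {
  pMethod <- match.arg(pMethod)
  G <- as.matrix(G)
  if (ncol(G) < 2 && !allowSingle)
    stop("a region needs at least two variants")
  keep <- !is.na(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    keep <- keep & complete.cases(X)
    X1 <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  } else X1 <- matrix(1, sum(keep), 1)
  yk <- y[keep]
  Gk <- G[keep, , drop = FALSE]
  ## mean-impute missing genotypes within the region
  if (anyNA(Gk)) {
    cm <- colMeans(Gk, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    ix <- which(is.na(Gk), arr.ind = TRUE)
    Gk[ix] <- cm[ix[, 2]]
  }
  if (length(unique(yk)) < 2) stop("outcome has zero variance")

  nf <- fitLogistic(X1, yk)
  if (nf$separation) stop("null model separation")
  mu <- nf$fitted

  maf <- pmin(colMeans(Gk) / 2, 1 - colMeans(Gk) / 2)
  w <- if (is.numeric(weights)) rep_len(weights, ncol(Gk))
       else if (identical(weights, "flat")) rep(1, ncol(Gk))
       else dbeta(maf, 1, 25)
  Z <- sweep(Gk, 2, w, `*`)                 # G W
  r <- yk - mu
  Q <- drop(crossprod(crossprod(Z, r)))     # || (GW)' r ||^2

  v <- mu * (1 - mu)
  if (all(apply(Gk, 2, function(col) length(unique(col)) == 1)) || sum(w^2) == 0)
    return(list(Q = Q, p = 1, p_method = "moment",
                n_variants = ncol(Gk), lambda = numeric()))
  ## lambda: eigenvalues of W G' P G W with P = V - VX(X'VX)^{-1}X'V
  VZ <- Z * v
  VX <- X1 * v
  A <- crossprod(Z, VZ) -
    crossprod(Z, VX) %*% solve(crossprod(X1, VX), crossprod(VX, Z))
  A <- (A + t(A)) / 2
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (length(lambda) == 0)
    return(list(Q = Q, p = 1, p_method = "moment",
                n_variants = ncol(Gk), lambda = numeric()))
  if (pMethod == "auto")
    pMethod <- if (length(yk) >= 2000) "moment" else "permutation"
  if (pMethod == "moment") {
    p <- .liu_p(Q, lambda)
  } else {
    set.seed(seed)
    Qp <- .perm_Q(Z, yk - mu, nPerm)
    p <- (1 + sum(Qp >= Q)) / (nPerm + 1)
  }
  list(Q = Q, p = p, p_method = pMethod, n_variants = ncol(Gk),
       lambda = lambda)
}

## exact conditional null for Q: permute the null-model residual vector
## (for an intercept-only null this is identical to permuting the outcome)
.perm_Q <- function(Z, r, B) {
  n <- length(r)
  R <- matrix(r[vapply(seq_len(B), function(b) sample.int(n), integer(n))],
              nrow = n)
  colSums(crossprod(Z, R)^2)
}

## three-moment (Liu-type) chi-square approximation to P(sum lambda_i
## chi^2_1 > q); c_k = sum(lambda^k)
.liu_p <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s1^2
  }
  muQ <- c1
  sigmaQ <- sqrt(2 * c2)
  tstar <- (q - muQ) / sigmaQ
  muX <- l + delta
  sigmaX <- sqrt(2 * l + 4 * delta)
  pchisq(tstar * sigmaX + muX, df = l, ncp = delta, lower.tail = FALSE)
}

#' Region score tests over all annotated genes
#'
#' Runs \code{\link{regionScoreTest}} for every gene in a variant-to-gene
#' map, restricted to rare variants (MAF below \code{mafMax}); genes left
#' with fewer than two rare variants are skipped.
#'
#' @param cohort a \linkS4class{TaxaneCohort}.
#' @param outcome \code{colData} column name or outcome vector.
#' @param geneMap gene -> variant ids, from \code{\link{mapVariantsToGenes}}.
#' @param covariates character vector of \code{colData} covariate columns
#'   used in the null model (default the four clinical covariates when
#'   present).
#' @param mafMax rare-variant MAF bound (default 0.01).
#' @param pMethod,nPerm,seed,weights as in \code{\link{regionScoreTest}};
#'   under the permutation null the scan fits the null model once and shares
#'   one batch of residual permutations across all genes.
#' @return data.frame \code{(gene, n_variants, Q, p, p_method)}.
#' @export
regionScan <- function(cohort, outcome, geneMap,
                       covariates = intersect(c("age", "bmi", "taxane",
                                                "diabetes"),
                                              names(sampleData(cohort))),
                       mafMax = 0.01,
                       pMethod = c("auto", "moment", "permutation"),
                       nPerm = 1000, seed = 1L, weights = "beta") {
  pMethod <- match.arg(pMethod)
  d <- dosage(cohort)
  if (is.character(outcome) && length(outcome) == 1)
    outcome <- sampleData(cohort)[[outcome]]
  maf <- computeMaf(d)
  rare <- rownames(d)[!is.na(maf) & maf < mafMax & maf > 0]
  X <- if (length(covariates))
    as.matrix(as.data.frame(sampleData(cohort)[, covariates, drop = FALSE]))
  else NULL

  keep <- !is.na(outcome)
  if (!is.null(X)) keep <- keep & complete.cases(X)
  if (pMethod == "auto")
    pMethod <- if (sum(keep) >= 2000) "moment" else "permutation"

  if (pMethod == "permutation") {
    ## shared null fit and shared permutation batch
    yk <- outcome[keep]
    X1 <- if (is.null(X)) matrix(1, sum(keep), 1)
          else cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
    nf <- fitLogistic(X1, yk)
    r <- yk - nf$fitted
    n <- length(r)
    set.seed(seed)
    R <- matrix(r[vapply(seq_len(nPerm), function(b) sample.int(n),
                         integer(n))], nrow = n)
    rows <- lapply(names(geneMap), function(g) {
      vs <- intersect(geneMap[[g]], rare)
      if (length(vs) < 2) return(NULL)
      G <- t(d[vs, keep, drop = FALSE])
      if (anyNA(G)) {
        cm <- colMeans(G, na.rm = TRUE); cm[is.nan(cm)] <- 0
        ix <- which(is.na(G), arr.ind = TRUE); G[ix] <- cm[ix, 2]
      }
      fr <- colMeans(G) / 2
      w <- if (is.numeric(weights)) rep_len(weights, ncol(G))
           else if (identical(weights, "flat")) rep(1, ncol(G))
           else dbeta(pmin(fr, 1 - fr), 1, 25)
      Z <- sweep(G, 2, w, `*`)
      Q <- drop(crossprod(crossprod(Z, r)))
      Qp <- colSums(crossprod(Z, R)^2)
      data.frame(gene = g, n_variants = length(vs), Q = Q,
                 p = (1 + sum(Qp >= Q)) / (nPerm + 1),
                 p_method = "permutation")
    })
  } else {
    rows <- lapply(names(geneMap), function(g) {
      vs <- intersect(geneMap[[g]], rare)
      if (length(vs) < 2) return(NULL)
      res <- regionScoreTest(t(d[vs, , drop = FALSE]), outcome, X,
                             weights = weights, pMethod = "moment")
      data.frame(gene = g, n_variants = res$n_variants, Q = res$Q,
                 p = res$p, p_method = res$p_method)
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), n_variants = integer(),
                      Q = numeric(), p = numeric(), p_method = character())
  rownames(out) <- NULL
  out
}

#' Select genes from region-test results
#'
#' Genes with p at or below the threshold, plus quantile-quantile plot
#' coordinates (expected vs observed \eqn{-\log_{10} p}) for threshold
#' diagnosis.
#'
#' @param results data.frame from \code{\link{regionScan}}.
#' @param threshold p-value threshold (study setting: 0.001).
#' @return list with \code{genes} (character) and \code{qq} (data.frame
#'   \code{expected}, \code{observed}, \code{gene}).
#' @export
selectGenes <- function(results, threshold = 0.001) {
  ord <- order(results$p)
  n <- nrow(results)
  qq <- data.frame(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(results$p[ord]),
    gene = results$gene[ord])
  list(genes = results$gene[results$p <= threshold], qq = qq)
}
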