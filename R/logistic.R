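#' Maximum-likelihood logistic regression with diagnostics
#'
#' Thin wrapper around the binomial IRLS engine (\code{stats::glm.fit})
#' returning coefficient table, log-likelihood and convergence/separation
#' diagnostics in one flat list.  Rows with any missing value are dropped
#' (complete case).  The design matrix is expected to already contain an
#' intercept column and to be full rank (apply
#' \code{\link{removeSingularities}} first); a rank-deficient design is an
#' error here.
#'
#' @param X numeric design matrix (including intercept column).
#' @param y binary outcome (0/1), length \code{nrow(X)}.
#' @return list with \code{beta}, \code{se}, \code{z}, \code{p} (named per
#'   column), \code{loglik}, \code{converged}, \code{separation},
#'   \code{nUsed}, \code{fitted} (probabilities on the used rows, named),
#'   \code{used} (logical row mask).
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1, 2, 2))
#' y <- c(0, 0, 0, 1, 1, 1)
#' fitLogistic(X, y)$beta
#' @export
fitLogistic <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1) paste0("x", seq_len(ncol(X) - 1)))
  keep <- complete.cases(X) & !is.na(y)
  Xu <- X[keep, , drop = FALSE]
  yu <- y[keep]
  if (length(unique(yu)) < 2)
    stop("outcome has zero variance after complete-case filtering")

  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(Xu, yu, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("rank-deficient design; remove singularities before fitting")
  ## covariance from the weighted cross-product at the solution
  w <- fit$weights
  XtWX <- crossprod(Xu * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(beta)) else sqrt(diag(V))
  names(se) <- names(beta)
  z <- beta / se
  mu <- fit$fitted.values
  ll <- sum(yu * log(mu) + (1 - yu) * log1p(-mu))
  ## separation: divergent coefficients together with fitted probabilities
  ## pinned at the boundary (the IRLS warning is not always raised when the
  ## deviance converges to zero first)
  boundary <- any(mu > 1 - 1e-6) || any(mu < 1e-6)
  separation <- (sepWarn || boundary) && any(abs(beta) > 8)
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
       loglik = ll, converged = fit$converged, separation = separation,
       nUsed = sum(keep),
       fitted = setNames(mu, rownames(Xu)), used = keep)
}
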