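## Analytic power of the interaction score test, via the noncentral
## mixture-of-chi-square distribution of the score statistic.

#' Analytic power of the interaction-only test
#'
#' For a fixed design (covariates, exposure, gene dosages) and a common
#' per-variant interaction effect \code{gamma} (in residual-SD units per
#' dosage), computes the exact distribution of the score statistic under the
#' alternative - a noncentral weighted chi-square sum sharing the null's
#' eigenvalues - and returns the probability of falling beyond the critical
#' value at \code{threshold}.
#'
#' @param X covariate design (intercept included).
#' @param E binary exposure vector.
#' @param G dosage matrix of the gene.
#' @param gamma per-variant interaction effect in residual-SD units.
#' @param threshold significance threshold the test must beat.
#' @param weights variant weights (default Beta(1, 25) of the observed MAF).
#' @return power in [0, 1].
#' @export
interactionPowerAnalytic <- function(X, E, G, gamma, threshold,
                                     weights = NULL) {
    X <- as.matrix(X); G <- as.matrix(G); E <- as.numeric(E)
    if (is.null(weights)) {
        maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
        weights <- variantWeights(maf)
    }
    S <- G * E
    C <- sweep(S, 2L, sqrt(weights), "*")
    ## residual projector of the covariates-only null, unit residual variance
    XtXi <- chol2inv(chol(crossprod(X)))
    RC <- C - X %*% (XtXi %*% crossprod(X, C))
    M <- crossprod(C, RC)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    keep <- eg$values > .EIG_REL_TOL * max(eg$values)
    lam <- eg$values[keep]
    mu <- as.numeric(S %*% rep(gamma, ncol(S)))
    nu <- as.numeric(crossprod(C, mu - X %*% (XtXi %*% crossprod(X, mu))))
    b <- as.numeric(crossprod(eg$vectors[, keep, drop = FALSE], nu)) /
        sqrt(lam)
    delta <- b^2
    qcrit <- quadformQuantile(lam, threshold)
    quadformPowerTail(lam, delta, qcrit)
}

#' Interaction effect size for a target analytic power
#'
#' Smallest common per-variant interaction effect (residual-SD units per
#' dosage) giving at least \code{power} analytic power at \code{threshold}
#' on the supplied reference design.
#'
#' @inheritParams interactionPowerAnalytic
#' @param power target power (default 0.9).
#' @return the effect size gamma.
#' @export
chooseInteractionGamma <- function(X, E, G, threshold, power = 0.9,
                                   weights = NULL) {
    f <- function(g) interactionPowerAnalytic(X, E, G, g, threshold,
                                              weights) - power
    hi <- 0.25
    while (f(hi) < 0 && hi < 16) hi <- hi * 2
    uniroot(f, lower = 1e-3, upper = hi, tol = 1e-4)$root
}
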