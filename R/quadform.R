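## p-values for Q ~ sum_k lambda_k chi^2_1, the null distribution of the
## variance-component score statistics.

.EIG_REL_TOL <- 1e-10

.truncEigen <- function(lambda, relTol = .EIG_REL_TOL) {
    lambda <- lambda[lambda > 0]
    if (!length(lambda)) return(numeric())
    lambda[lambda > relTol * max(lambda)]
}

## Ruben-type series: F(q) = sum_k c_k P(chisq_{m + 2k} <= q / beta) with
## beta = min(lambda), all mixing weights c_k >= 0 summing to 1, so the
## truncated tail mass bounds the error. Upper-tail form keeps precision for
## small p.
.rubenP <- function(lambda, q, acc = 1e-12, maxTerms = 20000L) {
    m <- length(lambda)
    beta <- min(lambda)
    t <- 1 - beta / lambda              # in [0, 1)
    ## c_0 = prod (beta/lambda)^{1/2}; recursion via g_k = sum t^k / 2
    lc0 <- 0.5 * sum(log(beta / lambda))
    c0 <- exp(lc0)
    if (c0 == 0) return(NULL)           # spread too large for the series
    ck <- numeric(maxTerms + 1L)
    gk <- numeric(maxTerms)
    ck[1L] <- c0
    tpow <- rep(1, m)
    mass <- c0
    ptail <- c0 * pchisq(q / beta, df = m, lower.tail = FALSE)
    tc <- ptail
    massDone <- FALSE
    for (k in seq_len(maxTerms)) {
        tpow <- tpow * t
        gk[k] <- 0.5 * sum(tpow)
        ck[k + 1L] <- sum(gk[1:k] * ck[k:1]) / k
        mass <- mass + ck[k + 1L]
        tc <- ck[k + 1L] * pchisq(q / beta, df = m + 2 * k,
                                  lower.tail = FALSE)
        ptail <- ptail + tc
        massLeft <- max(1 - mass, 0)
        if (!massDone && (massLeft <= acc || massLeft <= 1e-15))
            massDone <- TRUE
        ## once the mass bound is met, keep adding terms until the series
        ## has also stabilised in relative terms (sharpens tiny p-values,
        ## whose rigorous absolute bound is limited by double precision)
        if (massDone && (tc <= 1e-9 * ptail || ptail == 0)) {
            return(list(p = ptail, err = max(massLeft, tc)))
        }
    }
    NULL
}

## Imhof characteristic-function inversion; also covers noncentral terms
## (used by the analytic power calculator).
.imhofP <- function(lambda, q, delta = NULL, absTol = 1e-10) {
    if (is.null(delta)) delta <- numeric(length(lambda))
    integrand <- function(u) {
        lu2 <- outer(lambda^2, u^2)
        th <- 0.5 * colSums(atan(outer(lambda, u)) +
                            outer(delta * lambda, u) / (1 + lu2)) -
              0.5 * q * u
        lrho <- 0.25 * colSums(log1p(lu2)) +
                0.5 * colSums(delta * lu2 / (1 + lu2))
        out <- sin(th) / (u * exp(lrho))
        out[u == 0] <- 0.5 * (sum(lambda * (1 + delta)) - q)
        out
    }
    val <- tryCatch(
        integrate(integrand, lower = 0, upper = Inf,
                  subdivisions = 10000L, rel.tol = 1e-12,
                  abs.tol = absTol, stop.on.error = FALSE),
        error = function(e) NULL)
    if (is.null(val) || !is.finite(val$value)) return(NULL)
    list(p = 0.5 + val$value / pi, err = val$abs.error / pi)
}

## Liu-Tang-Zhang four-moment chi-square match (fallback).
.liuP <- function(lambda, q) {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
        a <- 1 / (s1 - sqrt(s1^2 - s2))
        d <- s1 * a^3 - a^2
        l <- a^2 - 2 * d
    } else {
        a <- 1 / sqrt(s2); d <- 0; l <- 1 / s2
    }
    tstar <- (q - c1) / sqrt(2 * c2)
    pchisq(tstar * sqrt(2) * sqrt(l + 2 * d) + l + d, df = l, ncp = d,
           lower.tail = FALSE)
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_1 \ge q)}, the null tail
#' probability of the variance-component score statistics. The primary route
#' is an exact mixture-of-central-chi-square series with a rigorous truncation
#' bound; an exact characteristic-function (Imhof) quadrature is used when the
#' eigenvalue spread defeats the series, and a four-moment chi-square match is
#' the flagged last resort.
#'
#' @param lambda positive eigenvalues; entries below \code{1e-10 * max} are
#'   discarded.
#' @param q observed statistic (must be >= 0).
#' @param acc requested absolute accuracy of the exact routes.
#' @return the p-value, clipped to (1e-300, 1], with attribute
#'   \code{"method"} equal to \code{"exact-quadform"} or
#'   \code{"moment-match"}.
#' @examples
#' quadformPvalue(1, qchisq(0.95, 1))            # 0.05
#' quadformPvalue(c(1, 1), qchisq(0.95, 2))      # 0.05
#' @export
quadformPvalue <- function(lambda, q, acc = 1e-9) {
    if (q < 0) stop("q must be nonnegative")
    lambda <- .truncEigen(lambda)
    if (!length(lambda)) stop("no eigenvalue above tolerance")
    if (q == 0) return(structure(1, method = "exact-quadform"))
    ## all-equal eigenvalues: scaled chi-square, closed form
    if (max(lambda) - min(lambda) <= 1e-12 * max(lambda)) {
        p <- pchisq(q / lambda[1], df = length(lambda), lower.tail = FALSE)
        return(structure(max(min(p, 1), 1e-300), method = "exact-quadform"))
    }
    res <- .rubenP(lambda, q, acc = min(acc, 1e-12))
    okAcc <- function(r) !is.null(r) && is.finite(r$p) &&
        r$err <= max(acc, 1e-3 * max(r$p, 0)) && r$p > -acc && r$p < 1 + acc
    if (!okAcc(res)) {
        res <- .imhofP(lambda, q, absTol = acc)
        if (!okAcc(res)) res <- NULL
    }
    if (is.null(res))
        return(structure(max(min(.liuP(lambda, q), 1), 1e-300),
                         method = "moment-match"))
    structure(max(min(res$p, 1), 1e-300), method = "exact-quadform")
}

#' Upper quantile of a weighted sum of chi-square(1) variables
#'
#' Inverse of [quadformPvalue()]: the critical value q with
#' \eqn{P(\sum \lambda_k \chi^2_1 \ge q) = p}. Used by the analytic power
#' calculator.
#'
#' @param lambda positive eigenvalues.
#' @param p target upper-tail probability in (0, 1).
#' @return the quantile.
#' @export
quadformQuantile <- function(lambda, p) {
    stopifnot(p > 0, p < 1)
    lambda <- .truncEigen(lambda)
    f <- function(q) log(as.numeric(quadformPvalue(lambda, q))) - log(p)
    hi <- sum(lambda) * qchisq(p, df = 1, lower.tail = FALSE) + sum(lambda)
    while (f(hi) > 0) hi <- hi * 2
    uniroot(f, lower = 0, upper = hi, tol = 1e-10 * hi)$root
}

#' Tail probability of a noncentral weighted chi-square sum
#'
#' \eqn{P(\sum_k \lambda_k \chi^2_1(\delta_k) \ge q)} by Imhof quadrature;
#' the alternative distribution of the score statistics, used for analytic
#' power.
#'
#' @param lambda positive eigenvalues.
#' @param delta noncentrality parameters, one per eigenvalue.
#' @param q threshold.
#' @return the tail probability.
#' @export
quadformPowerTail <- function(lambda, delta, q) {
    keep <- lambda > .EIG_REL_TOL * max(lambda)
    res <- .imhofP(lambda[keep], q, delta = delta[keep], absTol = 1e-8)
    if (is.null(res)) stop("noncentral quadrature failed")
    max(min(res$p, 1), 0)
}
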