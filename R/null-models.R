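## REML machinery shared by the null models.
##
## Every null covariance here has the form V = sigma2 * (I + delta * A) with
## A = U diag(xi) U' (U orthonormal columns), so
## (I + delta A)^{-1} = I - U diag(delta*xi / (1 + delta*xi)) U'.
## The REML deviance is profiled down to the single ratio delta and minimised
## by bounded scalar optimisation on log(delta).

.remlProfile <- function(y, X, U, xi, logDeltaRange = c(-25, 15),
                         tol = 1e-8) {
    n <- length(y); q <- ncol(X)
    XX <- crossprod(X); Xy <- crossprod(X, y); yy <- sum(y^2)
    UX <- crossprod(U, X); Uy <- as.numeric(crossprod(U, y))
    dev <- function(logDelta) {
        delta <- exp(logDelta)
        cvec <- delta * xi / (1 + delta * xi)
        XHX <- XX - crossprod(UX, cvec * UX)
        XHy <- Xy - crossprod(UX, cvec * Uy)
        yHy <- yy - sum(cvec * Uy^2)
        ch <- tryCatch(chol(XHX), error = function(e) NULL)
        if (is.null(ch)) return(Inf)
        a <- backsolve(ch, forwardsolve(t(ch), XHy))
        rss <- yHy - sum(XHy * a)
        if (rss <= 0) return(Inf)
        (n - q) * log(rss / (n - q)) + sum(log1p(delta * xi)) +
            2 * sum(log(diag(ch)))
    }
    dev0 <- dev(-Inf)   # delta = 0 (exp(-Inf) = 0): ordinary regression
    opt <- tryCatch(
        optimize(dev, interval = logDeltaRange, tol = tol),
        error = function(e) NULL)
    notes <- character()
    if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= dev0) {
        delta <- 0
        if (is.null(opt)) notes <- "REML optimisation failed; tau set to 0"
        else notes <- "variance ratio at boundary 0"
    } else {
        delta <- exp(opt$minimum)
        if (opt$minimum > logDeltaRange[2] - 0.5)
            notes <- "variance ratio near upper search bound"
    }
    ## final GLS quantities at delta-hat
    cvec <- delta * xi / (1 + delta * xi)
    XHX <- XX - crossprod(UX, cvec * UX)
    XHy <- Xy - crossprod(UX, cvec * Uy)
    yHy <- yy - sum(cvec * Uy^2)
    ch <- chol(XHX)
    alpha <- as.numeric(backsolve(ch, forwardsolve(t(ch), XHy)))
    rss <- yHy - sum(XHy * alpha)
    sigma2 <- rss / (n - q)
    list(delta = delta, sigma2 = sigma2, alpha = alpha, cvec = cvec,
         notes = notes, converged = !is.null(opt))
}

.makeNullModel <- function(kind, y, X, U, fit, tau = 0, sigmaG2 = 0) {
    n <- length(y)
    applyHinv <- function(M) {
        if (ncol(U) == 0L || all(fit$cvec == 0)) return(M)
        M - U %*% (fit$cvec * crossprod(U, M))
    }
    res <- y - as.numeric(X %*% fit$alpha)
    ViX <- applyHinv(X) / fit$sigma2
    XtViX <- crossprod(X, ViX)
    Py <- as.numeric(applyHinv(res)) / fit$sigma2
    new("GxENullModel", kind = kind, alpha = fit$alpha, sigma2 = fit$sigma2,
        tau = tau, sigmaG2 = sigmaG2, delta = fit$delta,
        proj = list(U = U, cvec = fit$cvec, sigma2 = fit$sigma2),
        X = X, y = y, residuals = res, Py = Py, ViX = ViX, XtViX = XtViX,
        converged = fit$converged, notes = fit$notes)
}

## V^{-1} M for the fitted null
.vinvApply <- function(null, M) {
    U <- null@proj$U
    if (ncol(U) == 0L || all(null@proj$cvec == 0)) return(M / null@proj$sigma2)
    (M - U %*% (null@proj$cvec * crossprod(U, M))) / null@proj$sigma2
}

#' Apply the null-model projection
#'
#' Computes \eqn{\hat P M = (\hat V^{-1} - \hat V^{-1} X (X'\hat V^{-1}X)^{-1}
#' X'\hat V^{-1}) M}, the projection used by the score statistics.
#'
#' @param null a fitted \linkS4class{GxENullModel}.
#' @param M numeric vector or matrix with rows matching the samples.
#' @return the projected matrix.
#' @export
projectNull <- function(null, M) {
    M <- as.matrix(M)
    ViM <- .vinvApply(null, M)
    ViM - null@ViX %*% solve(null@XtViX, crossprod(null@X, ViM))
}

#' Fit the interaction-test null model
#'
#' Fits the linear mixed model \eqn{y = X\alpha + G\beta + \epsilon} with the
#' genetic main effects treated as random, \eqn{\beta \sim N(0, \tau W)} and
#' iid residuals, by REML profiled down to the variance ratio
#' \eqn{\delta = \tau/\sigma^2}. The null model absorbs the gene's main
#' effects so that [testInteraction()] scores the interaction terms only:
#' the returned projection eliminates the genotype columns exactly (they
#' enter the projection as adjustment covariates, in the \eqn{\hat V}
#' metric). Annihilating span(G) makes the interaction score's
#' mixture-of-chi-square null insensitive to the sampling noise of
#' \eqn{\hat\tau} — without it, the boundary noise of the variance component
#' rescales precisely the directions the interaction matrix lives in and
#' the test becomes conservative when main effects are absent.
#'
#' @param y transformed trait.
#' @param X full-rank covariate design (intercept, covariates, both smoking
#'   indicators).
#' @param G complete n x m dosage matrix of the gene's variants (m >= 2).
#' @param weights positive variant weights, the diagonal of W.
#' @return a \linkS4class{GxENullModel} of kind \code{INTERACTION_NULL}.
#' @seealso [testInteraction()], [fitNullJoint()]
#' @export
fitNullInteraction <- function(y, X, G, weights = NULL) {
    y <- as.numeric(y); X <- as.matrix(X); G <- as.matrix(G)
    stopifnot(length(y) == nrow(X), nrow(G) == length(y))
    if (is.null(weights)) {
        maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
        weights <- variantWeights(maf)
    }
    Gw <- sweep(G, 2L, sqrt(weights), "*")
    sv <- svd(Gw, nv = 0)
    keep <- sv$d^2 > 1e-12 * max(sv$d^2, 1e-300)
    U <- sv$u[, keep, drop = FALSE]
    xi <- sv$d[keep]^2
    if (!length(xi)) {                      # weighted genotypes all zero
        U <- matrix(0, length(y), 0); xi <- numeric()
    }
    fit <- .remlProfile(y, X, U, xi)
    ## adjust for the main effects exactly: the projection treats the
    ## (non-degenerate) genotype columns as covariates in the V-hat metric
    keepG <- apply(G, 2L, function(g) max(g) > min(g))
    Xaug <- .pruneCollinear(cbind(X, G[, keepG, drop = FALSE]),
                            "interaction null design")
    fitAug <- fit
    ## GLS coefficients of the augmented design at the fitted delta
    cvec <- fit$cvec
    applyHinv <- function(M) {
        if (ncol(U) == 0L || all(cvec == 0)) return(M)
        M - U %*% (cvec * crossprod(U, M))
    }
    XH <- applyHinv(Xaug)
    XtHX <- crossprod(Xaug, XH)
    fitAug$alpha <- as.numeric(solve(XtHX, crossprod(XH, y)))
    .makeNullModel("INTERACTION_NULL", y, Xaug, U, fitAug,
                   tau = fit$delta * fit$sigma2)
}

#' Fit the joint-test null model
#'
#' Without kinship this is the ordinary covariates-only linear regression
#' (\eqn{\hat V = \hat\sigma^2 I}). With a kinship matrix the null is the
#' linear mixed model with a polygenic random intercept,
#' \eqn{y = X\alpha + b + \epsilon}, \eqn{b \sim N(0, \sigma_g^2 A)} with A
#' the numerator relationship matrix, fitted by REML through the
#' eigendecomposition of A.
#'
#' @param y transformed trait.
#' @param X full-rank covariate design.
#' @param kinship optional symmetric PSD unit-diagonal matrix.
#' @param kinshipConvention \code{"numerator"}: the matrix is used as-is as
#'   A; \code{"kinship"}: off-diagonal entries are kinship coefficients
#'   relative to a unit diagonal and are doubled (A = 2K - I).
#' @return a \linkS4class{GxENullModel} of kind \code{JOINT_NULL} or
#'   \code{JOINT_NULL_KINSHIP}.
#' @export
fitNullJoint <- function(y, X, kinship = NULL,
                         kinshipConvention = c("numerator", "kinship")) {
    y <- as.numeric(y); X <- as.matrix(X)
    kinshipConvention <- match.arg(kinshipConvention)
    if (is.null(kinship)) {
        U <- matrix(0, length(y), 0)
        fit <- .remlProfile(y, X, U, numeric())
        return(.makeNullModel("JOINT_NULL", y, X, U, fit))
    }
    stopifnot(nrow(kinship) == length(y))
    A <- if (kinshipConvention == "kinship")
        2 * kinship - diag(nrow(kinship)) else kinship
    eg <- eigen(A, symmetric = TRUE)
    if (min(eg$values) < -1e-6 * max(abs(eg$values)))
        stop("kinship matrix is not positive semi-definite")
    xi <- pmax(eg$values, 0)
    fit <- .remlProfile(y, X, eg$vectors, xi)
    .makeNullModel("JOINT_NULL_KINSHIP", y, X, eg$vectors, fit,
                   sigmaG2 = fit$delta * fit$sigma2)
}
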