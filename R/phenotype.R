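## Phenotype preparation: smoking exposures, FEV1/FVC ratio, residual-outlier
## exclusion, rank-based inverse-normal transformation, covariate design.

SMOKING_LEVELS <- c("never", "past", "current")

#' Derive the two binary smoking exposures
#'
#' Ever-smoking contrasts ever (past or current) against never smokers;
#' current-smoking contrasts current smokers against past and never smokers
#' combined.
#'
#' @param smoking character/factor vector with levels never, past, current.
#' @return data.frame with columns \code{ever} and \code{current} (0/1).
#' @examples
#' deriveExposures(c("never", "past", "current"))
#' @export
deriveExposures <- function(smoking) {
    smoking <- as.character(smoking)
    bad <- which(!smoking %in% SMOKING_LEVELS & !is.na(smoking))
    if (length(bad))
        stop(sprintf("unknown smoking category '%s' at sample(s) %s",
                     smoking[bad[1]], paste(utils::head(bad, 5), collapse = ", ")))
    data.frame(ever = as.integer(smoking %in% c("past", "current")),
               current = as.integer(smoking == "current"))
}

#' FEV1/FVC ratio
#'
#' Elementwise ratio, computed before any transformation. Missing if either
#' input is missing; a zero FVC yields missing with a warning rather than an
#' error.
#'
#' @param fev1,fvc numeric vectors in mL.
#' @return numeric vector.
#' @export
computeRatio <- function(fev1, fvc) {
    stopifnot(length(fev1) == length(fvc))
    zero <- !is.na(fvc) & fvc == 0
    if (any(zero)) {
        warning(sprintf("%d sample(s) with FVC = 0 set to missing", sum(zero)))
        fvc[zero] <- NA
    }
    fev1 / fvc
}

#' Exclude residual outliers
#'
#' Regresses the raw trait on the covariates by ordinary least squares and
#' flags samples whose residual lies more than \code{kSd} standard deviations
#' from the residual mean. Flagged samples are excluded (set
#' \code{action = "flag"} to only record them).
#'
#' @param y raw trait vector (no missing values).
#' @param X covariate matrix (rank-deficient columns are pruned with a
#'   warning).
#' @param kSd exclusion threshold in residual standard deviations (default 4;
#'   \code{Inf} disables exclusion).
#' @param action \code{"exclude"} or \code{"flag"}.
#' @return list with \code{included} (integer indices kept) and \code{log}
#'   (data.frame: index, residual z-score, excluded flag).
#' @export
excludeResidualOutliers <- function(y, X, kSd = 4,
                                    action = c("exclude", "flag")) {
    action <- match.arg(action)
    y <- as.numeric(y); X <- as.matrix(X)
    stopifnot(!anyNA(y), !anyNA(X), nrow(X) == length(y))
    X <- .pruneCollinear(X, "outlier regression design")
    if (length(y) <= ncol(X))
        stop("need more samples than covariate columns")
    fit <- lm.fit(X, y)
    r <- fit$residuals
    s <- sd(r)
    ## an (essentially) perfect fit has no outliers; guard against rounding
    z <- if (s > 1e-10 * max(sd(y), .Machine$double.eps))
        (r - mean(r)) / s else rep(0, length(r))
    out <- abs(z) > kSd
    log <- data.frame(index = seq_along(y), residual_z = z, excluded = out)
    included <- if (action == "exclude") which(!out) else seq_along(y)
    list(included = included, log = log)
}

#' Rank-based inverse-normal transformation
#'
#' Replaces each value by \eqn{\Phi^{-1}((r_i - c)/(n - 2c + 1))} with r its
#' (average, for ties) rank among the non-missing values and c the Blom
#' offset 3/8 (configurable). Missing values are preserved.
#'
#' @param y numeric vector.
#' @param offset rank offset c; 3/8 (Blom, default) or 0.5 are common.
#' @return transformed vector, same length and missingness as the input.
#' @export
inverseNormalTransform <- function(y, offset = 3 / 8) {
    obs <- which(!is.na(y))
    if (length(obs) < 2) stop("need at least 2 non-missing values")
    v <- y[obs]
    if (max(v) == min(v))
        stop("all values identical; transform undefined")
    r <- rank(v, ties.method = "average")
    out <- y
    out[obs] <- qnorm((r - offset) / (length(obs) - 2 * offset + 1))
    out
}

.siteIndicators <- function(site) {
    site <- as.factor(site)
    if (nlevels(site) < 2) return(NULL)
    m <- stats::model.matrix(~site)[, -1, drop = FALSE]
    colnames(m) <- paste0("site", levels(site)[-1])
    m
}

#' Build the per-trait covariate design
#'
#' Assembles intercept, age, age-squared, sex, height, height-squared, weight
#' (FVC only, as it mainly reflects adiposity), site indicators (first level
#' dropped; single-site studies contribute no site columns), the leading
#' principal components and both smoking indicators.
#'
#' @param pheno per-sample data.frame with columns age, sex, height, weight,
#'   site, smoking and PC columns named \code{PC1}, \code{PC2}, ...
#' @param trait one of \code{"FEV1"}, \code{"FVC"}, \code{"RATIO"}.
#' @param nPcs number of principal components to include (default 10; capped
#'   at the number present).
#' @return numeric design matrix with named columns, intercept first.
#' @export
buildDesign <- function(pheno, trait = c("FEV1", "FVC", "RATIO"), nPcs = 10) {
    trait <- match.arg(trait)
    exp2 <- deriveExposures(pheno$smoking)
    X <- cbind(intercept = 1,
               age = pheno$age, age2 = pheno$age^2,
               sex = as.numeric(pheno$sex),
               height = pheno$height, height2 = pheno$height^2)
    if (trait == "FVC") X <- cbind(X, weight = pheno$weight)
    si <- .siteIndicators(pheno$site)
    if (!is.null(si)) X <- cbind(X, si)
    pcs <- grep("^PC[0-9]+$", names(pheno), value = TRUE)
    if (length(pcs)) {
        pcs <- pcs[order(as.integer(sub("PC", "", pcs)))]
        pcs <- utils::head(pcs, nPcs)
        X <- cbind(X, as.matrix(pheno[pcs]))
    }
    cbind(X, ever = exp2$ever, current = exp2$current)
}

#' Prepare one study for analysis
#'
#' End-to-end phenotype preparation for one trait/exposure pair: selects
#' samples with complete trait and covariates, computes the FEV1/FVC ratio
#' when needed (always before transformation), excludes residual outliers on
#' the raw trait, applies the inverse-normal transformation to the retained
#' samples, and returns the transformed trait with the matching design and
#' exposure vector.
#'
#' @param dataset a \linkS4class{StudyDataset} (or a plain phenotype
#'   data.frame).
#' @param trait \code{"FEV1"}, \code{"FVC"} or \code{"RATIO"}.
#' @param exposure tested exposure, \code{"EVER"} or \code{"CURRENT"}; both
#'   smoking indicators always remain covariates.
#' @param kSd residual-outlier threshold in SDs (default 4).
#' @param intOffset inverse-normal rank offset (default Blom 3/8).
#' @param outlierAction \code{"exclude"} (default) or \code{"flag"}.
#' @param nPcs principal components to adjust for (default 10).
#' @return object of class \code{PreparedStudy}: list with \code{yStar},
#'   \code{X}, \code{E}, \code{included} (row indices into the study's
#'   phenotype table), \code{exclusionLog}, \code{trait}, \code{exposure}.
#' @export
prepareStudy <- function(dataset, trait = c("FEV1", "FVC", "RATIO"),
                         exposure = c("EVER", "CURRENT"), kSd = 4,
                         intOffset = 3 / 8,
                         outlierAction = c("exclude", "flag"), nPcs = 10) {
    trait <- match.arg(trait)
    exposure <- match.arg(exposure)
    outlierAction <- match.arg(outlierAction)
    pheno <- if (is(dataset, "StudyDataset")) phenotypes(dataset) else dataset
    yRaw <- switch(trait,
                   FEV1 = pheno$fev1,
                   FVC = pheno$fvc,
                   RATIO = computeRatio(pheno$fev1, pheno$fvc))
    covNeeded <- c("age", "sex", "height", "site", "smoking",
                   if (trait == "FVC") "weight")
    pcCols <- grep("^PC[0-9]+$", names(pheno), value = TRUE)
    complete <- !is.na(yRaw) & complete.cases(pheno[c(covNeeded, pcCols)])
    idx <- which(complete)
    if (length(idx) < 10) stop("too few complete samples")
    X <- buildDesign(pheno[idx, , drop = FALSE], trait, nPcs)
    X <- .pruneCollinear(X, "covariate design")
    ol <- excludeResidualOutliers(yRaw[idx], X, kSd, outlierAction)
    kept <- ol$included
    exclusionLog <- data.frame(
        index = idx, residual_z = ol$log$residual_z,
        reason = ifelse(ol$log$excluded, "RESIDUAL_OUTLIER", ""))
    included <- idx[kept]
    yStar <- inverseNormalTransform(yRaw[included], offset = intOffset)
    Xk <- .pruneCollinear(X[kept, , drop = FALSE], "covariate design")
    E <- deriveExposures(pheno$smoking[included])
    E <- if (exposure == "EVER") E$ever else E$current
    structure(list(yStar = yStar, X = Xk, E = E, included = included,
                   exclusionLog = exclusionLog, trait = trait,
                   exposure = exposure),
              class = "PreparedStudy")
}

#' @export
print.PreparedStudy <- function(x, ...) {
    cat(sprintf("PreparedStudy: trait %s, exposure %s, n = %d (excluded %d), q = %d covariates\n",
                x$trait, x$exposure, length(x$yStar),
                sum(x$exclusionLog$reason != ""), ncol(x$X)))
    invisible(x)
}
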