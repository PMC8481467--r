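## Single-variant follow-up inside significant genes: 1-df Wald interaction
## tests, 2-df joint Wald tests of (main, interaction), conditional versions,
## and a local LD r-squared utility.

#' Single-variant interaction and joint tests
#'
#' Fits \eqn{y = X\alpha + g\beta + (g E)\gamma + \epsilon} by least squares
#' (optionally with conditioning dosages appended to the covariates) and
#' reports the 1-df Wald test of the interaction coefficient and the 2-df
#' Wald test of (main, interaction) using the joint covariance of the
#' estimates.
#'
#' @param y transformed trait.
#' @param X full-rank covariate design including both smoking indicators.
#' @param E tested binary exposure.
#' @param g dosage vector of the variant (must be non-constant).
#' @param conditioning optional vector/matrix of conditioning dosages;
#'   collinear columns are dropped with a warning.
#' @param variantId,gene,studyId,trait,exposure labels for the result row.
#' @return one-row data.frame: study_id, variant_id, gene, trait, exposure,
#'   maf, beta_main, se_main, beta_interaction, se_interaction,
#'   p_interaction, p_joint, conditioning_ids, notes. When no exposed
#'   carriers exist the interaction term is dropped: p_interaction is NA,
#'   p_joint is the 1-df main-effect test and a note records it.
#' @export
singleVariantTests <- function(y, X, E, g, conditioning = NULL,
                               variantId = "variant", gene = NA_character_,
                               studyId = "study", trait = "FEV1",
                               exposure = "EVER") {
    y <- as.numeric(y); X <- as.matrix(X)
    g <- as.numeric(g); E <- as.numeric(E)
    if (max(g) == min(g)) stop("NON_INFORMATIVE_VARIANT: dosage is constant")
    condIds <- character()
    if (!is.null(conditioning)) {
        Cd <- as.matrix(conditioning)
        if (any(colSums(abs(Cd - g)) == 0))
            stop("conditioning vector equals the tested variant")
        condIds <- colnames(Cd)
        if (is.null(condIds)) condIds <- sprintf("cond%d", seq_len(ncol(Cd)))
        colnames(Cd) <- condIds
        X <- .pruneCollinear(cbind(X, Cd), "conditioning design")
    }
    maf <- mean(g) / 2; maf <- min(maf, 1 - maf)
    gE <- g * E
    notes <- character()
    hasInteraction <- max(gE) > min(gE)
    A <- if (hasInteraction) cbind(X, g = g, gE = gE) else cbind(X, g = g)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) stop("design with variant terms is singular")
    n <- length(y); pdim <- ncol(A)
    fit <- lm.fit(A, y)
    sigma2 <- sum(fit$residuals^2) / (n - pdim)
    covB <- sigma2 * chol2inv(chol(crossprod(A)))
    dimnames(covB) <- list(colnames(A), colnames(A))
    coefs <- fit$coefficients
    iG <- which(names(coefs) == "g")
    betaMain <- coefs[iG]; seMain <- sqrt(covB[iG, iG])
    if (hasInteraction) {
        iS <- which(names(coefs) == "gE")
        betaInt <- coefs[iS]; seInt <- sqrt(covB[iS, iS])
        pInt <- pchisq((betaInt / seInt)^2, df = 1, lower.tail = FALSE)
        V2 <- covB[c(iG, iS), c(iG, iS)]
        w2 <- as.numeric(t(c(betaMain, betaInt)) %*%
                         solve(V2, c(betaMain, betaInt)))
        pJoint <- pchisq(w2, df = 2, lower.tail = FALSE)
    } else {
        notes <- "no exposed carriers; interaction term dropped"
        betaInt <- NA_real_; seInt <- NA_real_; pInt <- NA_real_
        pJoint <- pchisq((betaMain / seMain)^2, df = 1, lower.tail = FALSE)
    }
    data.frame(study_id = studyId, variant_id = variantId, gene = gene,
               trait = trait, exposure = exposure, maf = maf,
               beta_main = unname(betaMain), se_main = unname(seMain),
               beta_interaction = unname(betaInt),
               se_interaction = unname(seInt),
               p_interaction = unname(pInt), p_joint = unname(pJoint),
               conditioning_ids = paste(condIds, collapse = ","),
               notes = paste(notes, collapse = "; "),
               stringsAsFactors = FALSE)
}

#' Local LD r-squared between two variants
#'
#' Squared sample correlation of the dosage vectors (affine-invariant, so
#' allele flips do not change it).
#'
#' @param g1,g2 dosage vectors over the same samples.
#' @return r-squared in [0, 1].
#' @export
ldR2 <- function(g1, g2) {
    stopifnot(length(g1) == length(g2))
    ok <- !is.na(g1) & !is.na(g2)
    g1 <- g1[ok]; g2 <- g2[ok]
    if (max(g1) == min(g1) || max(g2) == min(g2))
        stop("dosage vector is constant; r2 undefined")
    cor(g1, g2)^2
}
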