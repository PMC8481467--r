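## Set-based variance-component score tests of gene-by-exposure interaction
## and of joint (main + interaction) effects, with mixture-of-chi-square
## p-values.

.dropConstantCols <- function(G, S, weights, mafs) {
    keep <- apply(G, 2L, function(g) max(g) > min(g))
    note <- NULL
    if (!all(keep))
        note <- sprintf("dropped %d constant variant column(s)", sum(!keep))
    list(G = G[, keep, drop = FALSE], S = S[, keep, drop = FALSE],
         weights = weights[keep], mafs = mafs[keep], note = note)
}

.scoreTest <- function(null, C, Py) {
    u <- as.numeric(crossprod(C, Py))
    q <- sum(u^2)
    M <- crossprod(C, projectNull(null, C))
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- .truncEigen(lam)
    if (!length(lam))
        return(list(q = 0, p = 1, method = "degenerate",
                    note = "no eigenvalue above tolerance"))
    p <- quadformPvalue(lam, q)
    list(q = q, p = as.numeric(p), method = attr(p, "method"), note = NULL)
}

#' Interaction-only score test
#'
#' Given the \code{INTERACTION_NULL} model fitted on the same data, computes
#' the variance-component score statistic
#' \eqn{Q = (y - X\hat\alpha)' \hat V^{-1} S W S' \hat V^{-1} (y - X\hat\alpha)}
#' for the interaction matrix S = G scaled row-wise by the exposure, and its
#' p-value from the \eqn{\sum_k \lambda_k \chi^2_1} null with
#' \eqn{\lambda_k} the eigenvalues of \eqn{W^{1/2} S' \hat P S W^{1/2}}.
#'
#' @param null a \linkS4class{GxENullModel} of kind \code{INTERACTION_NULL}
#'   fitted on the same (y, X, G, W).
#' @param model a \linkS4class{GxEModel}.
#' @return list with \code{q}, \code{p}, \code{method}
#'   (\code{"exact-quadform"} or \code{"moment-match"}) and \code{note}.
#' @export
setMethod("testInteraction", c("GxENullModel", "GxEModel"),
    function(null, model, ...) {
        if (null@kind != "INTERACTION_NULL")
            stop("testInteraction requires an INTERACTION_NULL model")
        d <- .dropConstantCols(model@G, model@S, model@weights, model@mafs)
        if (ncol(d$S) == 0L || all(d$S == 0))
            return(list(q = 0, p = 1, method = "degenerate",
                        note = "interaction matrix is zero"))
        C <- sweep(d$S, 2L, sqrt(d$weights), "*")
        out <- .scoreTest(null, C, null@Py)
        out$note <- paste(c(d$note, out$note), collapse = "; ")
        if (!nzchar(out$note)) out$note <- NULL
        out
    })

#' Joint main + interaction score test
#'
#' Computes
#' \eqn{Q = r' \hat V^{-1} (G W G' + S W S') \hat V^{-1} r} under the
#' covariates-only null (optionally with a polygenic kinship random
#' intercept), with the mixture-of-chi-square null built from
#' \eqn{B = [G W^{1/2} \mid S W^{1/2}]}.
#'
#' @param null a \linkS4class{GxENullModel} of kind \code{JOINT_NULL} or
#'   \code{JOINT_NULL_KINSHIP}.
#' @param model a \linkS4class{GxEModel}.
#' @return list as in [testInteraction()].
#' @export
setMethod("testJoint", c("GxENullModel", "GxEModel"),
    function(null, model, ...) {
        if (!null@kind %in% c("JOINT_NULL", "JOINT_NULL_KINSHIP"))
            stop("testJoint requires a JOINT_NULL(_KINSHIP) model")
        d <- .dropConstantCols(model@G, model@S, model@weights, model@mafs)
        if (ncol(d$G) == 0L)
            return(list(q = 0, p = 1, method = "degenerate",
                        note = "no informative variants"))
        sw <- sqrt(d$weights)
        B <- cbind(sweep(d$G, 2L, sw, "*"), sweep(d$S, 2L, sw, "*"))
        out <- .scoreTest(null, B, null@Py)
        out$note <- paste(c(d$note, out$note), collapse = "; ")
        if (!nzchar(out$note)) out$note <- NULL
        out
    })

.pruneCollinear <- function(X, warnPrefix = "design") {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        drop <- qrX$pivot[-seq_len(qrX$rank)]
        warning(sprintf("%s: dropped %d collinear column(s)", warnPrefix,
                        length(drop)), call. = FALSE)
        X <- X[, -drop, drop = FALSE]
    }
    X
}

#' Conditional gene-based test
#'
#' Re-runs the interaction and joint tests with known signal-driver dosages
#' added to the covariates (optionally together with their
#' exposure-interaction columns), the workflow used to ask whether a
#' gene-based signal is distinct from an established variant.
#'
#' @param model a \linkS4class{GxEModel}.
#' @param conditioningDosages numeric vector or n x c matrix of dosages to
#'   condition on. Columns identical to a tested variant are removed from G;
#'   columns collinear with the design are dropped with a warning.
#' @param includeInteractionCovariate also add dosage x exposure columns.
#' @param kinship,kinshipConvention optional, passed to [fitNullJoint()].
#' @return list with elements \code{interaction} and \code{joint}, each as
#'   returned by the test methods, plus \code{nVariants}.
#' @export
conditionalGeneTest <- function(model, conditioningDosages,
                                includeInteractionCovariate = FALSE,
                                kinship = NULL,
                                kinshipConvention = "numerator") {
    Cd <- as.matrix(conditioningDosages)
    stopifnot(nrow(Cd) == length(model@y))
    ## remove conditioning variants from the tested set
    keep <- rep(TRUE, ncol(model@G))
    for (j in seq_len(ncol(Cd)))
        keep <- keep & colSums(abs(model@G - Cd[, j])) > 0
    G <- model@G[, keep, drop = FALSE]
    w <- model@weights[keep]
    extra <- Cd
    colnames(extra) <- sprintf("cond%d", seq_len(ncol(extra)))
    if (includeInteractionCovariate) {
        ce <- Cd * model@E
        colnames(ce) <- sprintf("cond%d_x_E", seq_len(ncol(ce)))
        extra <- cbind(extra, ce)
    }
    X <- .pruneCollinear(cbind(model@X, extra), "conditional design")
    m2 <- gxeModel(model@y, X, model@E, G, weights = w)
    nullInt <- fitNullInteraction(model@y, X, G, w)
    nullJoint <- fitNullJoint(model@y, X, kinship, kinshipConvention)
    list(interaction = testInteraction(nullInt, m2),
         joint = testJoint(nullJoint, m2),
         nVariants = ncol(G))
}

#' Run the gene-based tests for one study, trait and exposure
#'
#' Fits the joint null once, then per retained gene fits the interaction null
#' and computes both score tests, returning one result row per gene.
#'
#' @param y transformed trait (analysis samples).
#' @param X full-rank covariate design.
#' @param E tested binary exposure.
#' @param genotypes complete (post-imputation) samples x variants dosage
#'   matrix restricted to the analysis samples.
#' @param geneGroups named list gene -> variant ids (post gene-level QC).
#' @param studyId,trait,exposure labels copied into the result rows.
#' @param kinship optional kinship matrix (analysis samples), used by the
#'   joint null.
#' @param kinshipConvention see [fitNullJoint()].
#' @param weightScheme,betaPars variant weights, see [variantWeights()].
#' @return data.frame with columns study_id, gene, trait, exposure,
#'   n_variants, cumulative_mac, q_interaction, p_interaction, q_joint,
#'   p_joint, pvalue_method, notes; rows ordered by gene.
#' @export
runGeneTests <- function(y, X, E, genotypes, geneGroups,
                         studyId = "study", trait = "FEV1",
                         exposure = "EVER", kinship = NULL,
                         kinshipConvention = "numerator",
                         weightScheme = "beta", betaPars = c(1, 25)) {
    stopifnot(is.list(geneGroups))
    if (!length(geneGroups))
        return(data.frame(study_id = character(), gene = character(),
                          trait = character(), exposure = character(),
                          n_variants = integer(), cumulative_mac = numeric(),
                          q_interaction = numeric(),
                          p_interaction = numeric(), q_joint = numeric(),
                          p_joint = numeric(), pvalue_method = character(),
                          notes = character(), stringsAsFactors = FALSE))
    stopifnot(!is.null(names(geneGroups)))
    nullJoint <- fitNullJoint(y, X, kinship, kinshipConvention)
    genes <- sort(names(geneGroups))
    rows <- lapply(genes, function(g) {
        ids <- intersect(geneGroups[[g]], colnames(genotypes))
        G <- genotypes[, ids, drop = FALSE]
        mac <- sum(pmin(colSums(G), 2 * nrow(G) - colSums(G)))
        model <- gxeModel(y, X, E, G, weightScheme = weightScheme,
                          betaPars = betaPars)
        nullInt <- fitNullInteraction(y, X, G, model@weights)
        ti <- testInteraction(nullInt, model)
        tj <- testJoint(nullJoint, model)
        notes <- c(nullInt@notes, ti$note, nullJoint@notes, tj$note)
        data.frame(study_id = studyId, gene = g, trait = trait,
                   exposure = exposure, n_variants = ncol(G),
                   cumulative_mac = mac,
                   q_interaction = ti$q, p_interaction = ti$p,
                   q_joint = tj$q, p_joint = tj$p,
                   pvalue_method = paste(unique(c(ti$method, tj$method)),
                                         collapse = "+"),
                   notes = paste(notes, collapse = "; "),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
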