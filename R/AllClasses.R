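#' @include AllGenerics.R
#' @import methods
#' @importFrom stats dbeta qnorm pnorm qchisq pchisq rnorm rbinom runif
#'   median complete.cases lm.fit optimize uniroot integrate rchisq sd var
#'   cor setNames ecdf ks.test
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

MISSING_DOSAGE <- NA_real_

#' Container for one cohort's analysis inputs
#'
#' A \code{StudyDataset} bundles everything one cohort contributes to the
#' discovery analysis: the rare-variant dosage matrix, per-variant metadata
#' (chromosome, position, alleles, nonsynonymous flag), the per-sample
#' phenotype/covariate table (FEV1, FVC, smoking category, age, sex, height,
#' weight, site, principal components), the gene-to-variant grouping used by
#' the set-based tests and, optionally, a kinship matrix for family cohorts.
#'
#' The class extends \linkS4class{SummarizedExperiment} with variants as rows
#' and samples as columns; the single assay \code{"dosage"} holds minor-allele
#' dosages in \{0, 1, 2\} with \code{NA} marking missing genotypes.
#'
#' @slot .  See \linkS4class{SummarizedExperiment}; \code{metadata()} carries
#'   \code{studyId}, \code{kinship}, \code{kinshipConvention} and
#'   \code{geneGroups}.
#' @aliases StudyDataset-class
#' @seealso [StudyDataset()] for the constructor, [generateCohorts()] for the
#'   synthetic-data generator that produces these objects.
#' @export
setClass("StudyDataset", contains = "SummarizedExperiment")

.validStudyDataset <- function(object) {
    msg <- character()
    if (!"dosage" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0, 1, 2)))
            msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
    }
    rd <- rowData(object)
    need <- c("chrom", "pos", "nonsyn")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, sprintf("rowData must contain columns: %s",
                              paste(need, collapse = ", ")))
    K <- metadata(object)$kinship
    if (!is.null(K)) {
        if (!is.matrix(K) || nrow(K) != ncol(K))
            msg <- c(msg, "kinship must be a square matrix")
        else {
            if (nrow(K) != ncol(object))
                msg <- c(msg, "kinship dimension must match sample count")
            if (max(abs(K - t(K))) > 1e-8)
                msg <- c(msg, "kinship must be symmetric")
            if (max(abs(diag(K) - 1)) > 1e-8)
                msg <- c(msg, "kinship must have unit diagonal")
        }
    }
    gg <- metadata(object)$geneGroups
    if (!is.null(gg) && length(gg)) {
        ids <- rownames(object)
        unknown <- setdiff(unique(unlist(gg)), ids)
        if (length(unknown))
            msg <- c(msg, sprintf("gene groups reference unknown variants: %s",
                                  paste(utils::head(unknown, 3), collapse = ", ")))
        dup <- vapply(gg, function(v) anyDuplicated(v) > 0, logical(1))
        if (any(dup))
            msg <- c(msg, "gene groups must not contain duplicated variant ids")
    }
    if (length(msg)) msg else TRUE
}

setValidity("StudyDataset", .validStudyDataset)

#' Construct a StudyDataset
#'
#' @param genotypes numeric samples x variants matrix of minor-allele dosages
#'   (0/1/2, \code{NA} = missing). Column names are variant ids, row names
#'   sample ids.
#' @param variants data.frame with one row per variant: columns \code{id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{nonsyn}.
#' @param phenotypes data.frame with one row per sample (see
#'   \linkS4class{StudyDataset}).
#' @param geneGroups named list mapping gene symbol to a character vector of
#'   member variant ids.
#' @param kinship optional symmetric unit-diagonal relatedness matrix.
#' @param kinshipConvention \code{"numerator"} (unit diagonal, 0.5 full sibs)
#'   or \code{"kinship"} (a kinship-coefficient matrix rescaled to unit
#'   diagonal; it is doubled off-diagonal before model fitting).
#' @param studyId single string naming the cohort.
#' @return a \linkS4class{StudyDataset}.
#' @examples
#' g <- matrix(rbinom(20, 2, 0.1), 10, 2,
#'             dimnames = list(paste0("s", 1:10), c("v1", "v2")))
#' v <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
#'                 ref = "A", alt = "G", nonsyn = TRUE)
#' p <- data.frame(sample_id = paste0("s", 1:10), fev1 = rnorm(10, 3000, 500))
#' sd1 <- StudyDataset(g, v, p, geneGroups = list(GENE1 = c("v1", "v2")),
#'                     studyId = "toy")
#' @export
StudyDataset <- function(genotypes, variants, phenotypes,
                         geneGroups = list(), kinship = NULL,
                         kinshipConvention = c("numerator", "kinship"),
                         studyId = "study") {
    kinshipConvention <- match.arg(kinshipConvention)
    genotypes <- as.matrix(genotypes)
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- variants$id
    stopifnot(nrow(genotypes) == nrow(phenotypes),
              ncol(genotypes) == nrow(variants),
              identical(colnames(genotypes), as.character(variants$id)))
    if (is.null(rownames(genotypes))) {
        sid <- if ("sample_id" %in% names(phenotypes))
            as.character(phenotypes$sample_id)
        else sprintf("%s_s%04d", studyId, seq_len(nrow(phenotypes)))
        rownames(genotypes) <- sid
    }
    rd <- DataFrame(variants)
    rownames(rd) <- as.character(variants$id)
    cd <- DataFrame(phenotypes)
    rownames(cd) <- rownames(genotypes)
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = t(genotypes)),
        rowData = rd, colData = cd,
        metadata = list(studyId = studyId, kinship = kinship,
                        kinshipConvention = kinshipConvention,
                        geneGroups = geneGroups))
    new("StudyDataset", se)
}

#' Fitted null model for the variance-component score tests
#'
#' Holds the covariate effects, variance components and projection machinery
#' of a fitted null model, reused across genes. Kinds: \code{INTERACTION_NULL}
#' (genetic main effects absorbed as a random effect with variance
#' \code{tau} * W), \code{JOINT_NULL} (covariates-only linear model) and
#' \code{JOINT_NULL_KINSHIP} (covariates plus a polygenic random intercept
#' with covariance \code{sigmaG2} times the numerator relationship matrix).
#'
#' @slot kind character, one of the three kinds above.
#' @slot alpha fitted covariate coefficients (GLS under the null covariance).
#' @slot sigma2 residual variance estimate.
#' @slot tau variance component of the random genetic main effects
#'   (INTERACTION_NULL only; 0 otherwise).
#' @slot sigmaG2 polygenic variance component (kinship null only).
#' @slot proj list with the whitening representation of V-inverse.
#' @slot X design matrix the null was fitted on.
#' @slot y response the null was fitted on.
#' @slot residuals y - X alpha.
#' @slot Py the projected response P y used by the score statistics.
#' @slot ViX V^{-1} X, cached.
#' @slot XtViX X' V^{-1} X, cached.
#' @slot converged logical, REML convergence.
#' @slot notes character vector of fitting notes (boundary hits, fallbacks).
#' @export
setClass("GxENullModel",
    representation(kind = "character", alpha = "numeric", sigma2 = "numeric",
                   tau = "numeric", sigmaG2 = "numeric", delta = "numeric",
                   proj = "list", X = "matrix", y = "numeric",
                   residuals = "numeric", Py = "numeric", ViX = "matrix",
                   XtViX = "matrix", converged = "logical",
                   notes = "character"))

#' Per-gene model inputs for the set-based tests
#'
#' Bundles the trait, covariates, tested binary exposure, the gene's dosage
#' matrix G, the interaction matrix S = G scaled row-wise by the exposure,
#' and the diagonal variant weights.
#'
#' @slot y transformed trait vector.
#' @slot X covariate design (intercept, covariates, both smoking indicators).
#' @slot E tested binary exposure (0/1).
#' @slot G n x m dosage matrix, complete (post-imputation), MAF < 0.05.
#' @slot S n x m interaction matrix, S[i, j] = G[i, j] * E[i].
#' @slot weights length-m positive variant weights (diagonal of W).
#' @slot mafs per-variant minor allele frequencies.
#' @export
setClass("GxEModel",
    representation(y = "numeric", X = "matrix", E = "numeric", G = "matrix",
                   S = "matrix", weights = "numeric", mafs = "numeric"))

.validGxEModel <- function(object) {
    msg <- character()
    n <- length(object@y)
    if (nrow(object@X) != n || nrow(object@G) != n || length(object@E) != n)
        msg <- c(msg, "row dimensions of y, X, E, G must agree")
    if (!all(object@E %in% c(0, 1)))
        msg <- c(msg, "E must be binary 0/1")
    if (!identical(dim(object@S), dim(object@G)) ||
        max(abs(object@S - object@G * object@E)) > 0)
        msg <- c(msg, "S must equal G scaled row-wise by E")
    if (length(object@weights) != ncol(object@G) || any(object@weights <= 0))
        msg <- c(msg, "weights must be positive, one per variant")
    if (length(msg)) msg else TRUE
}
setValidity("GxEModel", .validGxEModel)

#' Beta-density variant weights
#'
#' Standard rare-variant weighting: \code{w_j = dbeta(MAF_j, a1, a2)} with the
#' default (1, 25) up-weighting the rarest variants; \code{"flat"} gives unit
#' weights.
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @param scheme \code{"beta"} or \code{"flat"}.
#' @param betaPars shape parameters of the Beta density.
#' @return positive numeric vector of weights.
#' @export
variantWeights <- function(maf, scheme = c("beta", "flat"),
                           betaPars = c(1, 25)) {
    scheme <- match.arg(scheme)
    stopifnot(all(maf >= 0 & maf <= 0.5))
    if (scheme == "flat") return(rep(1, length(maf)))
    dbeta(pmin(pmax(maf, 1e-6), 1 - 1e-6), betaPars[1], betaPars[2])
}

#' Construct a GxEModel
#'
#' @param y transformed trait.
#' @param X covariate design matrix including intercept and both smoking
#'   indicators.
#' @param E tested binary exposure.
#' @param G complete dosage matrix for the gene's variants.
#' @param weights optional explicit weights; if \code{NULL} they are computed
#'   from the observed MAFs via [variantWeights()].
#' @param weightScheme,betaPars passed to [variantWeights()].
#' @return a \linkS4class{GxEModel}.
#' @export
gxeModel <- function(y, X, E, G, weights = NULL,
                     weightScheme = c("beta", "flat"), betaPars = c(1, 25)) {
    G <- as.matrix(G)
    X <- as.matrix(X)
    if (anyNA(G)) stop("G must be complete; run imputeMissingGenotypes first")
    maf <- colMeans(G) / 2
    maf <- pmin(maf, 1 - maf)
    if (is.null(weights))
        weights <- variantWeights(maf, match.arg(weightScheme), betaPars)
    new("GxEModel", y = as.numeric(y), X = X, E = as.numeric(E), G = G,
        S = G * as.numeric(E), weights = weights, mafs = maf)
}

## ---- accessors ----

#' @describeIn StudyDataset cohort label
#' @param x a StudyDataset
#' @export
setMethod("studyId", "StudyDataset", function(x) metadata(x)$studyId)

#' @describeIn StudyDataset samples x variants dosage matrix
#' @param withDimnames passed through
#' @export
setMethod("genotypes", "StudyDataset", function(x, ...)
    t(SummarizedExperiment::assay(x, "dosage")))

#' @describeIn StudyDataset per-variant metadata as a data.frame
#' @export
setMethod("variantInfo", "StudyDataset", function(x)
    as.data.frame(rowData(x)))

#' @describeIn StudyDataset per-sample phenotype/covariate table
#' @export
setMethod("phenotypes", "StudyDataset", function(x)
    as.data.frame(colData(x)))

#' @describeIn StudyDataset optional kinship matrix (NULL if absent)
#' @export
setMethod("kinshipMatrix", "StudyDataset", function(x) metadata(x)$kinship)

#' @describeIn StudyDataset self-kinship convention of the stored matrix
#' @export
setMethod("kinshipConvention", "StudyDataset", function(x)
    metadata(x)$kinshipConvention)

#' @describeIn StudyDataset named list gene -> variant ids
#' @export
setMethod("geneGroups", "StudyDataset", function(x) metadata(x)$geneGroups)

#' @describeIn StudyDataset replace the gene grouping
#' @param value named list gene -> variant ids
#' @export
setMethod("geneGroups<-", "StudyDataset", function(x, value) {
    metadata(x)$geneGroups <- value
    validObject(x)
    x
})

#' @export
setMethod("show", "StudyDataset", function(object) {
    cat("StudyDataset '", studyId(object), "': ",
        ncol(object), " samples x ", nrow(object), " variants, ",
        length(geneGroups(object)), " gene groups",
        if (!is.null(kinshipMatrix(object))) ", with kinship" else "",
        "\n", sep = "")
    d <- SummarizedExperiment::assay(object, "dosage")
    cat(sprintf("  missing dosage rate: %.3f\n", mean(is.na(d))))
})

#' @export
setMethod("show", "GxENullModel", function(object) {
    cat("GxENullModel [", object@kind, "]\n", sep = "")
    cat(sprintf("  n = %d, q = %d covariates\n",
                length(object@y), ncol(object@X)))
    cat(sprintf("  sigma2 = %.4g", object@sigma2))
    if (object@kind == "INTERACTION_NULL")
        cat(sprintf(", tau = %.4g", object@tau))
    if (object@kind == "JOINT_NULL_KINSHIP")
        cat(sprintf(", sigmaG2 = %.4g", object@sigmaG2))
    cat("\n")
    if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
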