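## Synthetic multi-cohort generator: rare-variant genotypes under
## Hardy-Weinberg, smoking exposures, covariates, pulmonary-function
## phenotypes with configurable genetic main and gene-by-smoking interaction
## effects, and optional sibship-structured relatedness.

.substreamSeed <- function(seed, study, stage) {
    as.integer((as.numeric(seed) * 100003 + study * 1009 + stage) %%
               2147483647L)
}

.checkRange <- function(x, lo, hi, field, loOpen = FALSE, hiOpen = FALSE) {
    bad <- if (loOpen) any(x <= lo) else any(x < lo)
    bad <- bad || if (hiOpen) any(x >= hi) else any(x > hi)
    if (bad) stop(sprintf("simConfig: field '%s' out of range", field))
}

#' Simulation configuration
#'
#' Validated configuration for [generateCohorts()]. Defaults emulate the
#' scale and structure of a multi-cohort exome-chip discovery analysis:
#' several cohorts of unequal size, ever-smoking prevalence spanning roughly
#' 30-61% and current-smoking 6-25%, a rare MAF spectrum (log-uniform below
#' 5%), 2-25 variants per gene, Hardy-Weinberg genotypes with sparse
#' missingness, and mL-scale spirometric traits driven by age, sex, height,
#' weight, site and principal components.
#'
#' @param nStudies number of cohorts.
#' @param nSamplesPerStudy integer vector of cohort sizes (recycled to
#'   \code{nStudies}).
#' @param nGenes number of genes in the panel.
#' @param variantsPerGene length-2 integer range of variants per gene.
#' @param mafRange length-2 MAF range in (0, 0.05]; MAFs are drawn
#'   log-uniformly to over-represent the rarest variants.
#' @param missingRate genotype missingness (completely at random), in
#'   [0, 0.05].
#' @param exposurePrevalence data.frame with per-study columns \code{ever}
#'   and \code{current} (current <= ever); the default spaces studies over
#'   ever 0.30-0.61 and current 0.06-0.25.
#' @param covariateSpec list: ageMean, ageSd, pMale, heightMean, heightSd,
#'   weightMean, weightSd, nSites, nPcs.
#' @param effectSpec list: \code{beta}, \code{gamma} (named per-gene
#'   per-variant effect sizes in residual-SD units per dosage; unnamed genes
#'   are 0), \code{interactionExposure} (\code{"ever"} or \code{"current"}:
#'   the exposure gamma acts on), \code{alpha} (covariate effects on the mL
#'   scale) and \code{exposureEver}/\code{exposureCurrent} (mL).
#' @param residualSd residual SD of FEV1 in mL (default 600, Table-1-like).
#' @param familySpec optional list(sibshipSize, polygenicShare) switching on
#'   sibship-structured relatedness with the given share of the residual
#'   variance assigned to a polygenic random intercept.
#' @param seed master integer seed; per-study, per-stage substreams are
#'   derived from it deterministically.
#' @param panelSeed optional separate seed for the shared variant panel
#'   (gene sizes, MAFs, positions). Defaults to \code{seed}; fixing it while
#'   varying \code{seed} yields replicate cohort draws over one genome.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nStudies = 3,
                      nSamplesPerStudy = c(1500, 1000, 800),
                      nGenes = 50,
                      variantsPerGene = c(2L, 25L),
                      mafRange = c(0.001, 0.05),
                      missingRate = 0.01,
                      exposurePrevalence = NULL,
                      covariateSpec = list(),
                      effectSpec = list(),
                      residualSd = 600,
                      familySpec = NULL,
                      seed = 1L,
                      panelSeed = NULL) {
    nSamplesPerStudy <- rep_len(as.integer(nSamplesPerStudy), nStudies)
    if (any(nSamplesPerStudy < 50))
        stop("simConfig: field 'nSamplesPerStudy' must be >= 50")
    .checkRange(nGenes, 1, Inf, "nGenes")
    if (length(variantsPerGene) != 2 || variantsPerGene[1] < 1 ||
        diff(variantsPerGene) < 0)
        stop("simConfig: field 'variantsPerGene' must be an increasing range")
    .checkRange(mafRange, 0, 0.05, "mafRange", loOpen = TRUE)
    if (diff(mafRange) < 0)
        stop("simConfig: field 'mafRange' must be increasing")
    .checkRange(missingRate, 0, 0.05, "missingRate")
    if (is.null(exposurePrevalence)) {
        ever <- seq(0.30, 0.61, length.out = nStudies)
        current <- seq(0.06, 0.25, length.out = nStudies)
        exposurePrevalence <- data.frame(ever = ever, current = current)
    }
    exposurePrevalence <- as.data.frame(exposurePrevalence)
    if (nrow(exposurePrevalence) == 1)
        exposurePrevalence <- exposurePrevalence[rep(1, nStudies), ]
    .checkRange(exposurePrevalence$ever, 0, 1, "exposurePrevalence$ever",
                loOpen = TRUE, hiOpen = TRUE)
    .checkRange(exposurePrevalence$current, 0, 1,
                "exposurePrevalence$current", loOpen = TRUE, hiOpen = TRUE)
    if (any(exposurePrevalence$current > exposurePrevalence$ever))
        stop("simConfig: field 'exposurePrevalence' requires current <= ever")
    cs <- utils::modifyList(
        list(ageMean = 55, ageSd = 10, pMale = 0.5, heightMean = 168,
             heightSd = 9, weightMean = 78, weightSd = 14, nSites = 2L,
             nPcs = 10L), covariateSpec)
    es <- utils::modifyList(
        list(beta = numeric(), gamma = numeric(),
             alpha = c(age = -25, sex = 400, height = 25, weight = -5,
                       site = 50, pc = 15),
             exposureEver = -120, exposureCurrent = -180,
             interactionExposure = "ever"), effectSpec)
    .checkRange(residualSd, 0, Inf, "residualSd", loOpen = TRUE)
    if (!is.null(familySpec)) {
        familySpec <- utils::modifyList(
            list(sibshipSize = 4L, polygenicShare = 0.4), familySpec)
        .checkRange(familySpec$polygenicShare, 0, 1, "polygenicShare",
                    hiOpen = TRUE)
    }
    structure(list(nStudies = nStudies, nSamplesPerStudy = nSamplesPerStudy,
                   nGenes = nGenes,
                   variantsPerGene = as.integer(variantsPerGene),
                   mafRange = mafRange, missingRate = missingRate,
                   exposurePrevalence = exposurePrevalence,
                   covariateSpec = cs, effectSpec = es,
                   residualSd = residualSd, familySpec = familySpec,
                   seed = as.integer(seed),
                   panelSeed = as.integer(panelSeed %||% seed)),
              class = "SimConfig")
}

#' Sibship kinship structure
#'
#' Builds a block-diagonal relatedness matrix of independent sibships, unit
#' diagonal with the within-sibship coefficient set by the convention:
#' 0.5 for full sibs under the numerator-relationship convention (default),
#' 0.25 under the kinship-coefficient convention.
#'
#' @param nSamples total samples.
#' @param sibshipSizes either a single integer (all sibships that size) or an
#'   integer vector sampled from uniformly; sizes are drawn until
#'   \code{nSamples} is reached (last sibship truncated).
#' @param convention \code{"numerator"} or \code{"kinship"}.
#' @param seed optional seed for the size draws.
#' @return list: \code{kinship} (dense matrix), \code{family} (integer
#'   labels), \code{convention}.
#' @export
generateFamilyStructure <- function(nSamples, sibshipSizes = 4L,
                                    convention = c("numerator", "kinship"),
                                    seed = NULL) {
    stopifnot(nSamples > 0)
    convention <- match.arg(convention)
    if (!is.null(seed)) set.seed(seed)
    sizes <- integer()
    while (sum(sizes) < nSamples) {
        s <- if (length(sibshipSizes) == 1L) sibshipSizes
             else sample(sibshipSizes, 1L)
        sizes <- c(sizes, as.integer(s))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - nSamples)
    sizes <- sizes[sizes > 0]
    fam <- rep(seq_along(sizes), sizes)
    off <- if (convention == "numerator") 0.5 else 0.25
    K <- matrix(0, nSamples, nSamples)
    start <- 1L
    for (s in sizes) {
        idx <- start:(start + s - 1L)
        K[idx, idx] <- off
        start <- start + s
    }
    diag(K) <- 1
    list(kinship = K, family = fam, convention = convention)
}

.drawSmoking <- function(n, ever, current) {
    p <- c(never = 1 - ever, past = ever - current, current = current)
    sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate synthetic cohorts
#'
#' Draws a shared variant panel (gene assignments, positions, log-uniform
#' MAFs), then per study: Hardy-Weinberg genotypes Binomial(2, MAF) with
#' completely-at-random missingness, smoking categories at the configured
#' prevalences, covariates, an optional sibship polygenic intercept, and
#' mL-scale FEV1/FVC built as covariate effects + exposure effect + genetic
#' main effects + gene-by-exposure interaction effects + noise. Genetic
#' effect sizes are per-dosage increments in residual-SD units; FVC is FEV1
#' rescaled towards a plausible FEV1/FVC ratio plus weight effects and
#' independent noise.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return list of \linkS4class{StudyDataset}, one per cohort, each carrying
#'   the shared gene grouping and (if configured) its kinship matrix.
#' @export
generateCohorts <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    ## ---- shared variant panel (stage 0) ----
    set.seed(.substreamSeed(config$panelSeed, 0L, 0L))
    nGenes <- config$nGenes
    mPerGene <- if (config$variantsPerGene[1] == config$variantsPerGene[2])
        rep(config$variantsPerGene[1], nGenes)
    else sample(config$variantsPerGene[1]:config$variantsPerGene[2],
                nGenes, replace = TRUE)
    geneNames <- sprintf("GENE%04d", seq_len(nGenes))
    geneOf <- rep(geneNames, mPerGene)
    nVar <- length(geneOf)
    variantIds <- sprintf("var%05d", seq_len(nVar))
    lmaf <- runif(nVar, log(config$mafRange[1]), log(config$mafRange[2]))
    mafs <- exp(lmaf)
    variants <- data.frame(
        id = variantIds,
        chrom = as.character(rep_len(1:22, nGenes))[match(geneOf, geneNames)],
        pos = seq_len(nVar) * 1000L,
        ref = "A", alt = "T", nonsyn = TRUE,
        maf_generative = mafs,
        stringsAsFactors = FALSE)
    groups <- split(variantIds, geneOf)[geneNames]
    es <- config$effectSpec
    betaOf <- function(g) if (g %in% names(es$beta)) es$beta[[g]] else 0
    gammaOf <- function(g) if (g %in% names(es$gamma)) es$gamma[[g]] else 0
    betaVec <- vapply(geneOf, betaOf, 0)
    gammaVec <- vapply(geneOf, gammaOf, 0)
    cs <- config$covariateSpec
    prev <- config$exposurePrevalence
    lapply(seq_len(config$nStudies), function(i) {
        sid <- sprintf("STUDY%02d", i)
        n <- config$nSamplesPerStudy[i]
        ## genotypes (stage 1)
        set.seed(.substreamSeed(config$seed, i, 1L))
        G <- matrix(rbinom(n * nVar, 2L, rep(mafs, each = n)), n, nVar,
                    dimnames = list(sprintf("%s_s%05d", sid, seq_len(n)),
                                    variantIds))
        if (config$missingRate > 0) {
            miss <- runif(n * nVar) < config$missingRate
            G[miss] <- NA
        }
        ## covariates & smoking (stage 2)
        set.seed(.substreamSeed(config$seed, i, 2L))
        pheno <- data.frame(
            sample_id = rownames(G),
            smoking = .drawSmoking(n, prev$ever[i], prev$current[i]),
            age = rnorm(n, cs$ageMean, cs$ageSd),
            sex = rbinom(n, 1L, cs$pMale),
            height = rnorm(n, cs$heightMean, cs$heightSd),
            weight = rnorm(n, cs$weightMean, cs$weightSd),
            site = if (cs$nSites > 1)
                sample(sprintf("site%d", seq_len(cs$nSites)), n, TRUE)
            else "site1",
            stringsAsFactors = FALSE)
        if (cs$nPcs > 0) {
            pcs <- matrix(rnorm(n * cs$nPcs), n, cs$nPcs,
                          dimnames = list(NULL, paste0("PC", seq_len(cs$nPcs))))
            pheno <- cbind(pheno, pcs)
        }
        ## kinship + phenotype (stage 3)
        set.seed(.substreamSeed(config$seed, i, 3L))
        kin <- NULL; b <- 0
        sdE <- config$residualSd
        if (!is.null(config$familySpec)) {
            fs <- generateFamilyStructure(n, config$familySpec$sibshipSize)
            kin <- fs$kinship
            phi <- config$familySpec$polygenicShare
            sdG <- config$residualSd * sqrt(phi)
            sdE <- config$residualSd * sqrt(1 - phi)
            ## A = 0.5 * J + 0.5 * I within sibships: shared + individual part
            uFam <- rnorm(max(fs$family))
            b <- sdG * (sqrt(0.5) * uFam[fs$family] + sqrt(0.5) * rnorm(n))
        }
        exps <- deriveExposures(pheno$smoking)
        Gc <- G; Gc[is.na(Gc)] <- 0   # missing dosages carry no effect
        E <- if (identical(es$interactionExposure, "current"))
            exps$current else exps$ever
        genet <- config$residualSd *
            (as.numeric(Gc %*% betaVec) + as.numeric((Gc * E) %*% gammaVec))
        alpha <- es$alpha
        siteNum <- as.integer(factor(pheno$site))
        covPart <- alpha[["age"]] * (pheno$age - cs$ageMean) +
            alpha[["sex"]] * pheno$sex +
            alpha[["height"]] * (pheno$height - cs$heightMean) +
            alpha[["site"]] * (siteNum - 1) +
            if (cs$nPcs > 0) as.numeric(as.matrix(
                pheno[paste0("PC", seq_len(cs$nPcs))]) %*%
                rep(alpha[["pc"]], cs$nPcs)) else 0
        smoke <- es$exposureEver * exps$ever +
            es$exposureCurrent * exps$current
        fev1 <- 3300 + covPart + smoke + genet + b + rnorm(n, 0, sdE)
        fvc <- 4300 + 1.2 * (covPart + smoke + genet + b) +
            alpha[["weight"]] * (pheno$weight - cs$weightMean) +
            rnorm(n, 0, 250)
        pheno$fev1 <- fev1
        pheno$fvc <- fvc
        StudyDataset(G, variants, pheno, geneGroups = groups,
                     kinship = kin, kinshipConvention = "numerator",
                     studyId = sid)
    })
}
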