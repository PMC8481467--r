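## Variant- and gene-level genotype QC and binomial imputation of missing
## genotypes.

SEX_CHROMS <- c("X", "Y", "23", "24", "chrX", "chrY")

.variantStats <- function(dosage) {
    obs <- !is.na(dosage)
    n <- sum(obs)
    if (n == 0)
        return(list(maf = 0, miss = 1, mac = 0, mono = TRUE))
    ac <- sum(dosage[obs])
    p <- ac / (2 * n)
    maf <- min(p, 1 - p)
    list(maf = maf, miss = 1 - n / length(dosage),
         mac = min(ac, 2 * n - ac), mono = maf == 0)
}

#' Variant-level QC filters
#'
#' Retains autosomal, nonsynonymous-flagged, polymorphic variants with
#' MAF strictly below \code{mafMax} (computed on non-missing dosages,
#' minor-allele oriented) and missing rate at most \code{missMax}. Variants
#' with all genotypes missing count as monomorphic.
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param mafMax MAF exclusion bound (default 0.05; the bound is strict,
#'   MAF must be < mafMax).
#' @param missMax maximum tolerated missing rate (default 0.05; variants
#'   with missing rate > missMax are excluded).
#' @return list with \code{retained} (character vector of variant ids) and
#'   \code{report}, a data.frame (variant_id, maf, missing_rate, mac,
#'   filters_failed) with one row per variant.
#' @export
filterVariants <- function(dataset, mafMax = 0.05, missMax = 0.05) {
    geno <- genotypes(dataset)
    vi <- variantInfo(dataset)
    st <- apply(geno, 2L, .variantStats)
    rep <- data.frame(
        variant_id = colnames(geno),
        maf = vapply(st, `[[`, 0, "maf"),
        missing_rate = vapply(st, `[[`, 0, "miss"),
        mac = vapply(st, `[[`, 0, "mac"),
        stringsAsFactors = FALSE)
    fails <- mapply(function(s, chrom, nonsyn) {
        f <- character()
        if (s$mono) f <- c(f, "MONOMORPHIC")
        if (s$miss > missMax) f <- c(f, "MISSING_GT_5PCT")
        if (s$maf >= mafMax) f <- c(f, "MAF_GE_5PCT")
        if (as.character(chrom) %in% SEX_CHROMS) f <- c(f, "SEX_CHROM")
        if (!isTRUE(as.logical(nonsyn))) f <- c(f, "NOT_NONSYNONYMOUS")
        paste(f, collapse = ",")
    }, st, vi$chrom, vi$nonsyn)
    rep$filters_failed <- unname(fails)
    rownames(rep) <- NULL
    list(retained = rep$variant_id[rep$filters_failed == ""], report = rep)
}

#' Binomial imputation of missing genotypes
#'
#' Each missing dosage is replaced by an independent draw from
#' Binomial(2, MAF), with the MAF estimated from the non-missing dosages of
#' the same variant and oriented to the minor allele (draws are flipped back
#' to the stored allele orientation). Observed dosages are never changed.
#'
#' @param genotypes samples x variants dosage matrix (or a single numeric
#'   vector) with \code{NA} marking missing entries.
#' @param maf optional known minor allele frequency (vector input only);
#'   estimated from the data when \code{NULL}.
#' @param seed optional integer seed for a reproducible imputation stream.
#' @return completed matrix (or vector) of the same shape.
#' @export
imputeMissingGenotypes <- function(genotypes, maf = NULL, seed = NULL) {
    if (!is.null(seed)) {
        old <- globalenv()$.Random.seed
        on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                          envir = globalenv()))
        set.seed(seed)
    }
    impVec <- function(g, p = NULL) {
        miss <- is.na(g)
        if (!any(miss)) return(g)
        obs <- g[!miss]
        if (is.null(p)) {
            pAlt <- if (length(obs)) mean(obs) / 2 else 0
        } else {
            pAlt <- p
        }
        flip <- pAlt > 0.5
        pm <- if (flip) 1 - pAlt else pAlt
        draws <- rbinom(sum(miss), 2L, pm)
        g[miss] <- if (flip) 2 - draws else draws
        g
    }
    if (is.matrix(genotypes)) {
        if (!is.null(maf)) stop("explicit maf only supported for vector input")
        for (j in seq_len(ncol(genotypes)))
            genotypes[, j] <- impVec(genotypes[, j])
        genotypes
    } else {
        if (!is.null(maf)) stopifnot(maf >= 0, maf <= 0.5)
        impVec(as.numeric(genotypes), maf)
    }
}

#' Gene-level QC filters
#'
#' Intersects each gene's membership with the retained variants and excludes
#' genes with fewer than \code{minVariants} retained variants or cumulative
#' minor allele count (summed over member variants, computed on the completed
#' post-imputation dosages) below \code{cmacMin}.
#'
#' @param geneGroups named list gene -> variant ids.
#' @param retained character vector of variant ids that passed variant QC.
#' @param genotypes complete samples x variants dosage matrix.
#' @param cmacMin minimum cumulative MAC (default 20; strict less-than
#'   excludes).
#' @param minVariants minimum retained variants per gene (default 2).
#' @return list with \code{groups} (the retained, intersected gene list) and
#'   \code{report} data.frame (gene, n_variants_retained, cumulative_mac,
#'   excluded, reason).
#' @export
applyGeneFilters <- function(geneGroups, retained, genotypes,
                             cmacMin = 20, minVariants = 2) {
    stopifnot(!anyNA(genotypes))
    n <- nrow(genotypes)
    macOf <- function(ids) {
        ac <- colSums(genotypes[, ids, drop = FALSE])
        sum(pmin(ac, 2 * n - ac))
    }
    genes <- names(geneGroups)
    rows <- lapply(genes, function(g) {
        ids <- intersect(geneGroups[[g]], intersect(retained,
                                                    colnames(genotypes)))
        m <- length(ids)
        cmac <- if (m) macOf(ids) else 0
        reason <- if (m < minVariants) "TOO_FEW_VARIANTS"
                  else if (cmac < cmacMin) "CMAC_LT_20"
                  else "none"
        data.frame(gene = g, n_variants_retained = m, cumulative_mac = cmac,
                   excluded = reason != "none", reason = reason,
                   stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
    keep <- report$gene[!report$excluded]
    groups <- lapply(setNames(keep, keep), function(g)
        intersect(geneGroups[[g]], intersect(retained, colnames(genotypes))))
    list(groups = groups, report = report)
}

#' Full genotype QC for one study
#'
#' Convenience wrapper running variant filters, binomial imputation of the
#' retained variants and gene-level filters in the package's canonical order
#' (cumulative MAC is computed on the completed data, so the filter and the
#' tested matrix agree).
#'
#' @param dataset a \linkS4class{StudyDataset}.
#' @param mafMax,missMax see [filterVariants()].
#' @param cmacMin,minVariants see [applyGeneFilters()].
#' @param seed integer seed for the imputation stream.
#' @return list: \code{genotypes} (complete matrix, retained variants only),
#'   \code{groups}, \code{variantReport}, \code{geneReport}.
#' @export
qcStudy <- function(dataset, mafMax = 0.05, missMax = 0.05, cmacMin = 20,
                    minVariants = 2, seed = NULL) {
    fv <- filterVariants(dataset, mafMax, missMax)
    geno <- genotypes(dataset)[, fv$retained, drop = FALSE]
    geno <- imputeMissingGenotypes(geno, seed = seed)
    gf <- applyGeneFilters(geneGroups(dataset), fv$retained, geno,
                           cmacMin, minVariants)
    list(genotypes = geno, groups = gf$groups,
         variantReport = fv$report, geneReport = gf$report)
}
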