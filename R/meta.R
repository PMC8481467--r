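## Stouffer weighted-Z meta-analysis, genomic-control screening, Bonferroni
## threshold and gene ranking.

.CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

#' Stouffer's weighted Z-score combination
#'
#' Transforms per-study p-values to z-values by the Gaussian inverse CDF,
#' \eqn{Z_i = \Phi^{-1}(P_i)}, combines them with square-root-of-sample-size
#' weights, \eqn{Z = \sum w_i Z_i / \sqrt{\sum w_i^2}} with
#' \eqn{w_i = \sqrt{N_i}}, and returns \eqn{P = \Phi(Z)} (lower tail: small
#' study p-values give negative Z and a small combined P). Extreme inputs are
#' handled in log space so the combined p-value never underflows to zero.
#'
#' @param pvalues per-study p-values in (0, 1); exact 0/1 are clipped to the
#'   open interval with a warning.
#' @param sampleSizes per-study analyzed sample sizes (> 0).
#' @return list with \code{Z} and \code{P}.
#' @examples
#' stoufferCombine(c(0.05, 0.05), c(1000, 1000))$P   # ~0.0100
#' @export
stoufferCombine <- function(pvalues, sampleSizes) {
    stopifnot(length(pvalues) == length(sampleSizes), length(pvalues) >= 1,
              all(sampleSizes > 0), all(!is.na(pvalues)))
    if (any(pvalues <= 0 | pvalues >= 1)) {
        warning("p-values at 0 or 1 clipped to the open unit interval")
        pvalues <- pmin(pmax(pvalues, 1e-300), 1 - 1e-16)
    }
    z <- qnorm(pvalues)
    w <- sqrt(sampleSizes)
    Z <- sum(w * z) / sqrt(sum(w^2))
    P <- exp(pnorm(Z, log.p = TRUE))
    list(Z = Z, P = max(P, 1e-300))
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to its 1-df chi-square statistic and divides the
#' median by the chi-square(1) median (0.4549364): \eqn{\lambda = 1} under
#' the null, \eqn{\lambda \gg 1} under systematic inflation.
#'
#' @param pvalues vector of p-values (a warning is issued below 50, where the
#'   median is noisy).
#' @return the inflation factor.
#' @export
genomicLambda <- function(pvalues) {
    pvalues <- pvalues[!is.na(pvalues)]
    if (!length(pvalues)) stop("no p-values supplied")
    if (length(pvalues) < 50)
        warning("fewer than 50 p-values; lambda estimate is noisy")
    stats <- qchisq(pvalues, df = 1, lower.tail = FALSE)
    median(stats) / .CHISQ1_MEDIAN
}

#' Screen studies by inflation factor
#'
#' Excludes a study from the meta-analysis of one test family (trait x
#' exposure x test type) when its genomic-control lambda for that family
#' exceeds the threshold; exclusion is per family, never global, and the
#' bound is strict (lambda exactly at the threshold is kept).
#'
#' @param lambdas data.frame with columns study_id, trait, exposure, test,
#'   lambda.
#' @param threshold exclusion bound (default 1.5).
#' @return the input with an added logical column \code{excluded} and a
#'   character column \code{reason}.
#' @export
screenStudies <- function(lambdas, threshold = 1.5) {
    stopifnot(all(c("study_id", "lambda") %in% names(lambdas)))
    lambdas$excluded <- lambdas$lambda > threshold
    lambdas$reason <- ifelse(lambdas$excluded, "LAMBDA_GT_1.5", "")
    lambdas
}

#' Bonferroni significance threshold
#'
#' \code{alpha / (nGenes * nCombinations)}; with the genome-wide gene count
#' and the six trait-by-smoking combinations this gives the study-wide
#' threshold 5.7e-07.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param nGenes number of genes tested.
#' @param nCombinations number of trait x exposure combinations (default 6).
#' @return the per-test significance threshold.
#' @examples
#' bonferroniThreshold(0.05, 14591, 6)
#' @export
bonferroniThreshold <- function(alpha = 0.05, nGenes, nCombinations = 6) {
    stopifnot(alpha > 0, nGenes > 0, nCombinations > 0)
    alpha / (nGenes * nCombinations)
}

#' Meta-analyze per-study gene-based results
#'
#' Stacks per-study result tables (as produced by [runGeneTests()]),
#' computes each study's genomic-control lambda per test family from its own
#' genome-wide p-values, excludes inflated studies per family, combines the
#' remaining p-values per gene by Stouffer's weighted Z, and flags
#' significance against the Bonferroni threshold.
#'
#' @param results data.frame rbind of per-study gene test tables.
#' @param sampleSizes named numeric vector study_id -> analyzed sample size.
#' @param alpha,nCombinations Bonferroni inputs; \code{nGenes} is the number
#'   of distinct genes in \code{results}. \code{nCombinations = NULL} uses
#'   the number of trait x exposure pairs present times the two test types'
#'   shared combination count (i.e. the number of distinct trait-exposure
#'   pairs).
#' @param lambdaThreshold genomic-control screening bound (default 1.5).
#' @param minLambdaGenes minimum number of gene-level p-values a study must
#'   contribute before its lambda is trusted for screening (default 50, the
#'   same bound below which [genomicLambda()] warns that the median-based
#'   estimate is noise); smaller families report lambda but are never
#'   excluded by it.
#' @return list with \code{meta} (gene, trait, exposure, test, n_studies,
#'   total_n, Z, P, significant, excluded_studies), \code{lambdaReport} and
#'   \code{threshold}.
#' @export
metaAnalyze <- function(results, sampleSizes, alpha = 0.05,
                        nCombinations = NULL, lambdaThreshold = 1.5,
                        minLambdaGenes = 50) {
    stopifnot(all(c("study_id", "gene", "trait", "exposure", "p_interaction",
                    "p_joint") %in% names(results)))
    if (!nrow(results))
        stop("no gene-based results to meta-analyze (all genes filtered?)")
    long <- rbind(
        data.frame(results[c("study_id", "gene", "trait", "exposure")],
                   test = "interaction", p = results$p_interaction),
        data.frame(results[c("study_id", "gene", "trait", "exposure")],
                   test = "joint", p = results$p_joint))
    long <- long[!is.na(long$p), ]
    fam <- interaction(long$trait, long$exposure, long$test, drop = TRUE)
    key <- interaction(long$study_id, fam, drop = TRUE)
    lam <- do.call(rbind, lapply(split(long, key), function(d) {
        data.frame(study_id = d$study_id[1], trait = d$trait[1],
                   exposure = d$exposure[1], test = d$test[1],
                   n_pvalues = nrow(d),
                   lambda = suppressWarnings(genomicLambda(d$p)),
                   stringsAsFactors = FALSE)
    }))
    rownames(lam) <- NULL
    lam <- screenStudies(lam, lambdaThreshold)
    tooFew <- lam$n_pvalues < minLambdaGenes
    lam$excluded[tooFew] <- FALSE
    lam$reason[tooFew] <- ""
    nGenes <- length(unique(results$gene))
    if (is.null(nCombinations))
        nCombinations <- nrow(unique(results[c("trait", "exposure")]))
    threshold <- bonferroniThreshold(alpha, nGenes, nCombinations)
    excludedKey <- with(lam[lam$excluded, , drop = FALSE],
                        paste(study_id, trait, exposure, test))
    metaRows <- lapply(split(long, interaction(long$gene, fam, drop = TRUE)),
        function(d) {
            drop <- paste(d$study_id, d$trait, d$exposure, d$test) %in%
                excludedKey
            kept <- d[!drop, , drop = FALSE]
            exc <- unique(d$study_id[drop])
            if (!nrow(kept)) {
                return(data.frame(
                    gene = d$gene[1], trait = d$trait[1],
                    exposure = d$exposure[1], test = d$test[1],
                    n_studies = 0L, total_n = 0, Z = NA_real_, P = NA_real_,
                    significant = FALSE,
                    excluded_studies = paste(sort(exc), collapse = ","),
                    stringsAsFactors = FALSE))
            }
            N <- sampleSizes[as.character(kept$study_id)]
            sc <- stoufferCombine(kept$p, N)
            data.frame(
                gene = d$gene[1], trait = d$trait[1],
                exposure = d$exposure[1], test = d$test[1],
                n_studies = nrow(kept), total_n = sum(N),
                Z = sc$Z, P = sc$P, significant = sc$P < threshold,
                excluded_studies = paste(sort(exc), collapse = ","),
                stringsAsFactors = FALSE)
        })
    meta <- do.call(rbind, metaRows)
    meta <- meta[order(meta$trait, meta$exposure, meta$test, meta$gene), ]
    rownames(meta) <- NULL
    list(meta = meta, lambdaReport = lam, threshold = threshold)
}

#' Top genes per test family
#'
#' The k smallest combined p-values per (trait, exposure, test), ties broken
#' by gene symbol.
#'
#' @param meta the \code{meta} data.frame from [metaAnalyze()].
#' @param k genes to keep per family (default 5).
#' @return data.frame with an added \code{rank} column.
#' @export
rankTopGenes <- function(meta, k = 5) {
    fam <- interaction(meta$trait, meta$exposure, meta$test, drop = TRUE)
    out <- do.call(rbind, lapply(split(meta, fam), function(d) {
        d <- d[order(d$P, d$gene), , drop = FALSE]
        d <- utils::head(d, k)
        d$rank <- seq_len(nrow(d))
        d
    }))
    rownames(out) <- NULL
    out
}
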