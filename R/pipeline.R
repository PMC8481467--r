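## Orchestration: simulate -> prepare -> QC -> gene tests -> meta -> report,
## from a single configuration with derived seeds and a run manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the discovery workflow in one validated object;
#' stage functions receive all thresholds from here, never from literals of
#' their own. The defaults are the analysis defaults throughout the package:
#' MAF < 0.05, missing rate <= 0.05, cumulative MAC >= 20, >= 2 variants per
#' gene, 4-SD residual-outlier exclusion, Beta(1, 25) variant weights,
#' lambda screening at 1.5 and a Bonferroni threshold over genes x the six
#' trait-exposure combinations.
#'
#' @param sim a \code{SimConfig} ([simConfig()]), or \code{NULL} when
#'   \code{studyDirs} provide the data.
#' @param studyDirs optional character vector of directories readable by
#'   [readStudyDataset()]; overrides \code{sim}.
#' @param traits,exposures trait and exposure sets to analyze (default all
#'   3 x 2 = 6 combinations).
#' @param qc list: mafMax, missMax, cmacMin, minVariants, outlierSd.
#' @param test list: weightScheme, betaPars, useKinship.
#' @param meta list: alpha, lambdaThreshold, nCombinations (NULL = number of
#'   trait-exposure pairs analyzed).
#' @param intOffset inverse-normal rank offset.
#' @param seed master seed (also passed to \code{sim} when it has none).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), studyDirs = NULL,
                           traits = c("FEV1", "FVC", "RATIO"),
                           exposures = c("EVER", "CURRENT"),
                           qc = list(), test = list(), meta = list(),
                           intOffset = 3 / 8, seed = 1L) {
    qc <- utils::modifyList(list(mafMax = 0.05, missMax = 0.05, cmacMin = 20,
                                 minVariants = 2, outlierSd = 4), qc)
    test <- utils::modifyList(list(weightScheme = "beta",
                                   betaPars = c(1, 25), useKinship = TRUE),
                              test)
    meta <- utils::modifyList(list(alpha = 0.05, lambdaThreshold = 1.5,
                                   nCombinations = NULL,
                                   minLambdaGenes = 50), meta)
    stopifnot(all(traits %in% c("FEV1", "FVC", "RATIO")),
              all(exposures %in% c("EVER", "CURRENT")))
    structure(list(sim = sim, studyDirs = studyDirs, traits = traits,
                   exposures = exposures, qc = qc, test = test, meta = meta,
                   intOffset = intOffset, seed = as.integer(seed)),
              class = "PipelineConfig")
}

.configFingerprint <- function(config) {
    ## FNV-1a over the serialized configuration; stable across runs of the
    ## same R version so reruns are comparable.
    bytes <- serialize(config, NULL, version = 2)
    h <- 216613626L
    for (b in as.integer(bytes)) {
        h <- bitwXor(h, b)
        h <- as.integer((as.numeric(h) * 16777619) %% 2147483629)
    }
    sprintf("%08x", h)
}

#' Run the discovery pipeline
#'
#' Executes, per study: phenotype preparation for every configured trait and
#' exposure, genotype QC (variant filters, binomial imputation, gene
#' filters) and the gene-based interaction and joint tests; then combines
#' studies per test family by Stouffer's weighted Z with genomic-control
#' screening. All stage outputs are TSV files under \code{outDir} and a YAML
#' manifest records configuration, seeds and per-stage row counts.
#'
#' @param config a \code{PipelineConfig}.
#' @param outDir output directory (created).
#' @return invisibly, a list with \code{results} (stacked gene-test rows),
#'   \code{meta}, \code{lambdaReport}, \code{threshold}, \code{manifest}.
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outDir, "results"), showWarnings = FALSE)
    datasets <- if (!is.null(config$studyDirs))
        lapply(config$studyDirs, readStudyDataset)
    else {
        sim <- config$sim
        if (is.null(sim)) stop("either sim or studyDirs must be provided")
        generateCohorts(sim)
    }
    manifest <- list(config_fingerprint = .configFingerprint(config),
                     seed = config$seed, stages = list())
    allResults <- list()
    sampleSizes <- numeric()
    for (ds in datasets) {
        sid <- studyId(ds)
        qcRes <- tryCatch(
            qcStudy(ds, config$qc$mafMax, config$qc$missMax,
                    config$qc$cmacMin, config$qc$minVariants,
                    seed = .substreamSeed(config$seed,
                                          match(sid, vapply(datasets, studyId,
                                                            "")), 9L)),
            error = function(e) stop(sprintf("stage qc failed for %s: %s",
                                             sid, conditionMessage(e))))
        .fwrite(qcRes$variantReport,
                file.path(outDir, "results",
                          sprintf("variant_qc_%s.tsv", sid)))
        .fwrite(qcRes$geneReport,
                file.path(outDir, "results",
                          sprintf("gene_qc_%s.tsv", sid)))
        studyRows <- list()
        for (tr in config$traits) for (ex in config$exposures) {
            prep <- tryCatch(
                prepareStudy(ds, tr, ex, kSd = config$qc$outlierSd,
                             intOffset = config$intOffset),
                error = function(e)
                    stop(sprintf("stage prepare failed for %s (%s/%s): %s",
                                 sid, tr, ex, conditionMessage(e))))
            geno <- qcRes$genotypes[prep$included, , drop = FALSE]
            kin <- if (config$test$useKinship) kinshipMatrix(ds) else NULL
            if (!is.null(kin))
                kin <- kin[prep$included, prep$included, drop = FALSE]
            res <- tryCatch(
                runGeneTests(prep$yStar, prep$X, prep$E, geno, qcRes$groups,
                             studyId = sid, trait = tr, exposure = ex,
                             kinship = kin,
                             kinshipConvention =
                                 kinshipConvention(ds) %||% "numerator",
                             weightScheme = config$test$weightScheme,
                             betaPars = config$test$betaPars),
                error = function(e)
                    stop(sprintf("stage test-genes failed for %s (%s/%s): %s",
                                 sid, tr, ex, conditionMessage(e))))
            studyRows[[paste(tr, ex)]] <- res
        }
        studyResults <- do.call(rbind, studyRows)
        writeGeneTestResults(studyResults,
                             file.path(outDir, "results",
                                       sprintf("gene_tests_%s.tsv", sid)))
        manifest$stages[[sid]] <- list(
            n_samples = ncol(ds),
            n_variants_retained = ncol(qcRes$genotypes),
            n_genes_retained = length(qcRes$groups),
            n_result_rows = nrow(studyResults))
        allResults[[sid]] <- studyResults
        ## meta weights use the per-study total analyzed sample size
        sampleSizes[sid] <- ncol(ds)
    }
    results <- do.call(rbind, allResults)
    rownames(results) <- NULL
    mt <- metaAnalyze(results, sampleSizes, alpha = config$meta$alpha,
                      nCombinations = config$meta$nCombinations,
                      lambdaThreshold = config$meta$lambdaThreshold,
                      minLambdaGenes = config$meta$minLambdaGenes)
    .fwrite(mt$meta, file.path(outDir, "results", "meta.tsv"))
    .fwrite(mt$lambdaReport,
            file.path(outDir, "results", "lambda_report.tsv"))
    manifest$meta <- list(threshold = mt$threshold,
                          n_meta_rows = nrow(mt$meta),
                          n_significant = sum(mt$meta$significant,
                                              na.rm = TRUE))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(list(results = results, meta = mt$meta,
                   lambdaReport = mt$lambdaReport,
                   threshold = mt$threshold, manifest = manifest))
}

#' Summaries and QQ diagnostics for a completed run
#'
#' Reads the meta-analysis and lambda tables written by [runPipeline()] and
#' produces, per test family, a QQ plot of -log10 p with the lambda
#' annotation, a top-genes table and an exclusion summary.
#'
#' @param runDir directory written by [runPipeline()].
#' @param k top genes per family (default 5).
#' @return invisibly, list with \code{topGenes}, \code{exclusions} and the
#'   QQ plot file paths.
#' @export
makeReport <- function(runDir, k = 5) {
    metaPath <- file.path(runDir, "results", "meta.tsv")
    if (!file.exists(metaPath))
        stop(sprintf("no pipeline results under '%s'", runDir))
    meta <- as.data.frame(data.table::fread(metaPath))
    lam <- as.data.frame(data.table::fread(
        file.path(runDir, "results", "lambda_report.tsv")))
    repDir <- file.path(runDir, "report")
    dir.create(repDir, showWarnings = FALSE)
    top <- rankTopGenes(meta, k)
    .fwrite(top, file.path(repDir, "top_genes.tsv"))
    excl <- lam[lam$excluded, , drop = FALSE]
    .fwrite(excl, file.path(repDir, "excluded_studies.tsv"))
    fams <- unique(meta[c("trait", "exposure", "test")])
    paths <- character()
    for (i in seq_len(nrow(fams))) {
        d <- merge(meta, fams[i, , drop = FALSE])
        d <- d[!is.na(d$P), ]
        if (!nrow(d)) next
        d <- d[order(d$P), ]
        d$expected <- -log10(stats::ppoints(nrow(d)))
        d$observed <- -log10(d$P)
        lamMeta <- suppressWarnings(genomicLambda(d$P))
        lab <- sprintf("%s_%s_%s", fams$trait[i], fams$exposure[i],
                       fams$test[i])
        gp <- ggplot2::ggplot(d, ggplot2::aes(x = expected, y = observed)) +
            ggplot2::geom_abline(slope = 1, intercept = 0,
                                 linetype = "dashed", colour = "grey50") +
            ggplot2::geom_point(size = 0.8) +
            ggplot2::labs(
                title = sprintf("QQ: %s (meta lambda = %.2f)", lab, lamMeta),
                x = "expected -log10(p)", y = "observed -log10(p)") +
            ggplot2::theme_bw()
        f <- file.path(repDir, sprintf("qq_%s.pdf", lab))
        suppressMessages(ggplot2::ggsave(f, gp, width = 4, height = 4))
        paths <- c(paths, f)
    }
    invisible(list(topGenes = top, exclusions = excl, qqPlots = paths))
}
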