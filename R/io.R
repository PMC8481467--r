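## Plain-text readers/writers: TSV dosage matrices, gene set files,
## phenotype and kinship tables, GT-based VCF, result tables, YAML manifests.

.fwrite <- function(d, path) {
    data.table::fwrite(d, path, sep = "\t", quote = FALSE, na = "NA")
}

#' @rdname studyIO
#' @export
writeDosageTsv <- function(dataset, path) {
    g <- if (is(dataset, "StudyDataset")) genotypes(dataset) else dataset
    d <- data.table::data.table(sample_id = rownames(g))
    d <- cbind(d, data.table::as.data.table(g))
    .fwrite(d, path)
    invisible(path)
}

#' @rdname studyIO
#' @export
readDosageTsv <- function(path) {
    d <- data.table::fread(path, sep = "\t")
    m <- as.matrix(d[, -1])
    rownames(m) <- d[[1]]
    m
}

#' @rdname studyIO
#' @export
writeGeneSetFile <- function(geneGroups, path) {
    d <- data.table::data.table(
        gene = rep(names(geneGroups), lengths(geneGroups)),
        variant_id = unlist(geneGroups, use.names = FALSE))
    data.table::fwrite(d, path, sep = "\t", quote = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname studyIO
#' @export
readGeneSetFile <- function(path) {
    d <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "variant_id"))
    split(d$variant_id, d$gene)
}

#' @rdname studyIO
#' @export
writePhenotypeTsv <- function(dataset, path) {
    p <- if (is(dataset, "StudyDataset")) phenotypes(dataset) else dataset
    .fwrite(p, path)
    invisible(path)
}

#' @rdname studyIO
#' @export
readPhenotypeTsv <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname studyIO
#' @export
writeKinshipTsv <- function(kinship, path) {
    d <- data.table::data.table(sample_id = rownames(kinship))
    d <- cbind(d, data.table::as.data.table(kinship))
    .fwrite(d, path)
    invisible(path)
}

#' @rdname studyIO
#' @export
readKinshipTsv <- function(path) {
    d <- data.table::fread(path, sep = "\t")
    m <- as.matrix(d[, -1])
    rownames(m) <- d[[1]]
    m
}

.GT_CODES <- c("0/0", "0/1", "1/1")

#' Study dataset I/O
#'
#' Writers and readers for the plain-text exchange formats: a TSV dosage
#' matrix (samples in rows), a two-column \code{gene<TAB>variant_id} set
#' file, phenotype and kinship TSVs, a GT-based VCF 4.2 sites file (missing
#' genotypes as \code{./.}), and a whole-study directory with a YAML
#' manifest.
#'
#' @param dataset a \linkS4class{StudyDataset} (writers also accept the bare
#'   matrix/data.frame).
#' @param geneGroups named list gene -> variant ids.
#' @param kinship labelled square matrix.
#' @param path,dir file or directory path.
#' @name studyIO
#' @export
writeStudyVcf <- function(dataset, path) {
    stopifnot(is(dataset, "StudyDataset"))
    g <- genotypes(dataset)
    vi <- variantInfo(dataset)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(g)),
                       collapse = "\t")), con)
    for (j in seq_len(ncol(g))) {
        gt <- ifelse(is.na(g[, j]), "./.", .GT_CODES[g[, j] + 1])
        writeLines(paste(c(vi$chrom[j], vi$pos[j], vi$id[j], vi$ref[j],
                           vi$alt[j], ".", "PASS",
                           paste0("NS=", sum(!is.na(g[, j]))), "GT", gt),
                         collapse = "\t"), con)
    }
    invisible(path)
}

#' @rdname studyIO
#' @export
readVcfDosages <- function(path) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("VariantAnnotation is required to read VCF files")
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt %in% c("0/0", "0|0")] <- 0
    dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    dos[gt %in% c("1/1", "1|1")] <- 2
    t(dos)
}

#' @rdname studyIO
#' @export
writeStudyDataset <- function(dataset, dir) {
    stopifnot(is(dataset, "StudyDataset"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeDosageTsv(dataset, file.path(dir, "dosages.tsv"))
    writeGeneSetFile(geneGroups(dataset), file.path(dir, "gene_sets.tsv"))
    writePhenotypeTsv(dataset, file.path(dir, "phenotypes.tsv"))
    vi <- variantInfo(dataset)
    .fwrite(vi, file.path(dir, "variants.tsv"))
    K <- kinshipMatrix(dataset)
    if (!is.null(K)) {
        rownames(K) <- rownames(genotypes(dataset))
        colnames(K) <- rownames(K)
        writeKinshipTsv(K, file.path(dir, "kinship.tsv"))
    }
    yaml::write_yaml(list(study_id = studyId(dataset),
                          n_samples = ncol(dataset),
                          n_variants = nrow(dataset),
                          kinship = !is.null(K),
                          kinship_convention = kinshipConvention(dataset)),
                     file.path(dir, "study.yaml"))
    invisible(dir)
}

#' @rdname studyIO
#' @export
readStudyDataset <- function(dir) {
    info <- yaml::read_yaml(file.path(dir, "study.yaml"))
    g <- readDosageTsv(file.path(dir, "dosages.tsv"))
    vi <- as.data.frame(data.table::fread(file.path(dir, "variants.tsv")))
    ph <- readPhenotypeTsv(file.path(dir, "phenotypes.tsv"))
    gg <- readGeneSetFile(file.path(dir, "gene_sets.tsv"))
    kf <- file.path(dir, "kinship.tsv")
    K <- if (file.exists(kf)) readKinshipTsv(kf) else NULL
    StudyDataset(g, vi, ph, geneGroups = gg, kinship = K,
                 kinshipConvention = info$kinship_convention %||% "numerator",
                 studyId = info$study_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read gene-based test results
#'
#' TSV with one row per study x gene x trait x exposure, rows ordered by
#' (study_id, gene) so output is deterministic.
#'
#' @param results data.frame from [runGeneTests()].
#' @param path file path.
#' @name resultIO
#' @export
writeGeneTestResults <- function(results, path) {
    results <- results[order(results$study_id, results$gene), ]
    .fwrite(results, path)
    invisible(path)
}

#' @rdname resultIO
#' @export
readGeneTestResults <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t"))
}
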