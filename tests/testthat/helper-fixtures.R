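# Shared fixture builders; everything is generated in code.

# small design with intercept, one continuous and one binary covariate plus
# the exposure as covariate (as in the analysis models)
smallDesign <- function(n, prevalence = 0.2) {
    X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
    E <- rbinom(n, 1, prevalence)
    list(X = cbind(X, E = E), E = E)
}

# rare-variant dosage matrix under Hardy-Weinberg
rareG <- function(n, m, mafRange = c(0.005, 0.05)) {
    maf <- exp(runif(m, log(mafRange[1]), log(mafRange[2])))
    matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
           dimnames = list(NULL, sprintf("v%02d", seq_len(m))))
}

# minimal StudyDataset with controllable variant metadata
toyStudy <- function(n = 60, geno = NULL, variants = NULL, kinship = NULL,
                     groups = NULL, seed = 42) {
    set.seed(seed)
    if (is.null(geno)) geno <- rareG(n, 4, c(0.02, 0.05))
    m <- ncol(geno)
    if (is.null(variants))
        variants <- data.frame(id = colnames(geno), chrom = "1",
                               pos = seq_len(m) * 100L, ref = "A", alt = "T",
                               nonsyn = TRUE)
    colnames(geno) <- variants$id
    pheno <- data.frame(
        sample_id = sprintf("s%03d", seq_len(n)),
        smoking = sample(c("never", "past", "current"), n, TRUE,
                         prob = c(0.5, 0.3, 0.2)),
        age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5),
        height = rnorm(n, 168, 9), weight = rnorm(n, 78, 12),
        site = "site1",
        PC1 = rnorm(n), PC2 = rnorm(n))
    pheno$fev1 <- 3300 - 20 * (pheno$age - 55) + 300 * pheno$sex +
        rnorm(n, 0, 500)
    pheno$fvc <- pheno$fev1 / 0.76 + rnorm(n, 0, 200)
    if (is.null(groups))
        groups <- list(GENEA = variants$id[seq_len(min(2, m))],
                       GENEB = variants$id)
    StudyDataset(geno, variants, pheno, geneGroups = groups,
                 kinship = kinship, studyId = "TOY")
}
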