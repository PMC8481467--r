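mkStudy <- function(geno, chrom = "1", nonsyn = TRUE) {
    m <- ncol(geno)
    variants <- data.frame(id = colnames(geno),
                           chrom = rep_len(chrom, m),
                           pos = seq_len(m) * 10L, ref = "A", alt = "T",
                           nonsyn = rep_len(nonsyn, m))
    toyStudy(n = nrow(geno), geno = geno, variants = variants,
             groups = list(G1 = colnames(geno)))
}

test_that("variant filters implement the strict QC bounds", {
    n <- 200
    set.seed(2)
    g <- cbind(mono = rep(0, n),                       # monomorphic
               maf5 = rbinom(n, 2, 0.3),               # high frequency
               ok = rbinom(n, 2, 0.02),
               gap = rbinom(n, 2, 0.02),
               allmiss = rep(NA_real_, n))
    ## make maf5 exactly 5%: 20 alt alleles in 200 samples
    g[, "maf5"] <- 0; g[1:20, "maf5"] <- 1
    ## 6% missing on gap
    g[1:12, "gap"] <- NA
    ds <- mkStudy(g)
    fv <- filterVariants(ds)
    rep <- fv$report
    expect_setequal(fv$retained, "ok")
    expect_match(rep$filters_failed[rep$variant_id == "mono"], "MONOMORPHIC")
    expect_match(rep$filters_failed[rep$variant_id == "maf5"], "MAF_GE_5PCT")
    expect_match(rep$filters_failed[rep$variant_id == "gap"],
                 "MISSING_GT_5PCT")
    expect_match(rep$filters_failed[rep$variant_id == "allmiss"],
                 "MONOMORPHIC")
    ## MAF just under the bound is kept
    g2 <- g; g2[, "maf5"] <- 0; g2[1:19, "maf5"] <- 1
    fv2 <- filterVariants(mkStudy(g2))
    expect_true("maf5" %in% fv2$retained)
})

test_that("sex-chromosome and annotation filters apply", {
    set.seed(3)
    g <- cbind(a = rbinom(100, 2, 0.03), b = rbinom(100, 2, 0.03))
    dsx <- mkStudy(g, chrom = c("chrX", "1"))
    expect_setequal(filterVariants(dsx)$retained, "b")
    dsn <- mkStudy(g, nonsyn = c(FALSE, TRUE))
    fv <- filterVariants(dsn)
    expect_setequal(fv$retained, "b")
    expect_match(fv$report$filters_failed[1], "NOT_NONSYNONYMOUS")
})

test_that("binomial imputation fills only missing entries at the right rate", {
    set.seed(4)
    g <- rbinom(5000, 2, 0.25)
    expect_identical(imputeMissingGenotypes(g), as.numeric(g))
    gm <- g; gm[sample(5000, 2000)] <- NA
    done <- imputeMissingGenotypes(gm, seed = 7)
    expect_false(anyNA(done))
    expect_identical(done[!is.na(gm)], as.numeric(gm[!is.na(gm)]))
    expect_identical(done, imputeMissingGenotypes(gm, seed = 7))
    ## imputed mean ~ 2 * maf within 3 binomial SEs
    mafHat <- mean(gm, na.rm = TRUE) / 2
    imp <- done[is.na(gm)]
    se <- sqrt(2 * mafHat * (1 - mafHat) / length(imp))
    expect_lt(abs(mean(imp) - 2 * mafHat), 3 * se)
    ## maf = 0 fills zeros
    expect_equal(imputeMissingGenotypes(c(0, NA, 0), maf = 0), c(0, 0, 0))
    ## major-allele-oriented input is flipped for the draw and back
    gmaj <- c(rep(2, 900), rep(1, 100), rep(NA, 200))
    impMaj <- imputeMissingGenotypes(gmaj, seed = 9)[1001:1200]
    expect_gt(mean(impMaj), 1.7)   # draws follow the common allele
})

test_that("gene filters enforce the variant-count and cumulative-MAC rules", {
    n <- 100
    mk <- function(mac) { v <- rep(0, n); v[seq_len(mac)] <- 1; v }
    geno <- cbind(a = mk(10), b = mk(9), c = mk(11), d = mk(500 %% 90),
                  e = mk(60))
    groups <- list(LOW = c("a", "b"),      # cmac 19
                   OK = c("a", "c"),       # cmac 21
                   SOLO = "e")             # 1 variant, big mac
    gf <- applyGeneFilters(groups, colnames(geno), geno)
    rep <- gf$report
    expect_true(rep$excluded[rep$gene == "LOW"])
    expect_equal(rep$reason[rep$gene == "LOW"], "CMAC_LT_20")
    expect_false(rep$excluded[rep$gene == "OK"])
    expect_true(rep$excluded[rep$gene == "SOLO"])
    expect_equal(rep$reason[rep$gene == "SOLO"], "TOO_FEW_VARIANTS")
    expect_setequal(names(gf$groups), "OK")
    ## boundary: cmac exactly 20 is retained
    gb <- applyGeneFilters(list(EDGE = c("b", "c")), colnames(geno), geno)
    expect_false(gb$report$excluded)
    ## unknown variants count as absent
    gu <- applyGeneFilters(list(GHOST = c("zz", "zy")), colnames(geno), geno)
    expect_equal(gu$report$reason, "TOO_FEW_VARIANTS")
})

test_that("QC is idempotent", {
    set.seed(6)
    ds <- toyStudy(150, geno = rareG(150, 6, c(0.02, 0.05)))
    qc1 <- qcStudy(ds, seed = 1)
    ## re-filter the already-clean data
    gf2 <- applyGeneFilters(qc1$groups, colnames(qc1$genotypes),
                            qc1$genotypes)
    expect_identical(gf2$groups, qc1$groups)
    expect_identical(imputeMissingGenotypes(qc1$genotypes), qc1$genotypes)
})
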