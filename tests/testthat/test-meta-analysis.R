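test_that("Stouffer combination reproduces its closed forms", {
    expect_equal(stoufferCombine(0.037, 1234)$P, 0.037, tolerance = 1e-12)
    two <- stoufferCombine(c(0.5, 0.5), c(1000, 1000))
    expect_equal(two$Z, 0, tolerance = 1e-12)
    expect_equal(two$P, 0.5, tolerance = 1e-12)
    eq <- stoufferCombine(c(0.05, 0.05), c(2500, 2500))
    expect_equal(eq$P, pnorm(sqrt(2) * qnorm(0.05)), tolerance = 1e-12)
    expect_lt(abs(eq$P - 0.0100), 5e-5)
})

test_that("Stouffer combination is symmetric, monotone and replication-sensitive", {
    p <- c(0.01, 0.2, 0.6); N <- c(900, 2500, 400)
    expect_equal(stoufferCombine(p, N)$P,
                 stoufferCombine(p[c(3, 1, 2)], N[c(3, 1, 2)])$P,
                 tolerance = 1e-14)
    ## monotone in each input p
    base <- stoufferCombine(c(0.05, 0.3), c(1000, 1000))$P
    up <- stoufferCombine(c(0.07, 0.3), c(1000, 1000))$P
    expect_gt(up, base)
    ## replicating a study sharpens evidence on its side of 0.5
    expect_lt(stoufferCombine(c(0.05, 0.05), c(1000, 1000))$P,
              stoufferCombine(0.05, 1000)$P)
    expect_gt(stoufferCombine(c(0.9, 0.9), c(1000, 1000))$P,
              stoufferCombine(0.9, 1000)$P)
    ## extreme p-values stay positive via log-space
    tiny <- stoufferCombine(c(1e-280, 1e-290), c(5000, 5000))$P
    expect_gt(tiny, 0)
    expect_lt(tiny, 1e-250)
    expect_warning(stoufferCombine(c(0, 0.5), c(100, 100)), "clipped")
})

test_that("combined p-values are uniform under a global null", {
    set.seed(41)
    reps <- 5000
    P <- vapply(seq_len(reps), function(i)
        stoufferCombine(runif(4), c(800, 1500, 400, 2000))$P, 0)
    expect_gt(ks.test(P, "punif")$p.value, 0.01)
})

test_that("genomic lambda matches its definition and null behaviour", {
    expect_equal(suppressWarnings(genomicLambda(rep(0.5, 10))), 1,
                 tolerance = 1e-12)
    set.seed(42)
    expect_equal(genomicLambda(runif(10000)), 1, tolerance = 0.03)
    expect_error(genomicLambda(numeric()), "no p-values")
    expect_warning(genomicLambda(runif(10)), "fewer than 50")
})

test_that("lambda screening excludes inflated studies per family only", {
    set.seed(43)
    pInfl <- pchisq(1.6 * rchisq(5000, 1), 1, lower.tail = FALSE)
    lamInfl <- genomicLambda(pInfl)
    expect_gt(lamInfl, 1.5); expect_lt(lamInfl, 1.7)
    tab <- data.frame(
        study_id = c("A", "A", "B"),
        trait = c("FEV1", "FEV1", "FEV1"),
        exposure = c("CURRENT", "EVER", "CURRENT"),
        test = "interaction",
        lambda = c(lamInfl, 1.02, 1.5))       # B sits exactly at the bound
    sc <- screenStudies(tab)
    expect_equal(sc$excluded, c(TRUE, FALSE, FALSE))
    expect_equal(sc$reason[1], "LAMBDA_GT_1.5")
})

test_that("Bonferroni threshold arithmetic matches the study-wide constant", {
    expect_equal(bonferroniThreshold(0.05, 14591, 6), 5.712e-07,
                 tolerance = 1e-4)
    expect_equal(signif(bonferroniThreshold(0.05, 14591, 6), 2), 5.7e-07)
    expect_equal(bonferroniThreshold(0.05, 1, 1), 0.05)
    expect_equal(bonferroniThreshold(0.05, 10, 2), 2.5e-3)
})

test_that("top-gene ranking respects k and lexicographic ties", {
    meta <- data.frame(
        gene = c("B", "A", "C"), trait = "FEV1", exposure = "EVER",
        test = "interaction", P = c(0.01, 0.01, 0.5))
    top <- rankTopGenes(meta, k = 5)
    expect_equal(top$gene, c("A", "B", "C"))   # all returned, tie A before B
    expect_equal(top$rank, 1:3)
    expect_equal(nrow(rankTopGenes(meta, k = 2)), 2)
})

test_that("metaAnalyze screens, combines and flags per family", {
    set.seed(44)
    ng <- 300
    genes <- sprintf("G%03d", seq_len(ng))
    mk <- function(sid, pI, pJ)
        data.frame(study_id = sid, gene = genes, trait = "FEV1",
                   exposure = "CURRENT", p_interaction = pI, p_joint = pJ)
    ## study C has chi-square-inflated interaction p-values
    res <- rbind(
        mk("A", runif(ng), runif(ng)),
        mk("B", runif(ng), runif(ng)),
        mk("C", pchisq(2.0 * rchisq(ng, 1), 1, lower.tail = FALSE),
           runif(ng)))
    mt <- metaAnalyze(res, c(A = 1000, B = 800, C = 600), alpha = 0.05,
                      nCombinations = 6)
    lamC <- mt$lambdaReport[mt$lambdaReport$study_id == "C", ]
    expect_true(lamC$excluded[lamC$test == "interaction"])
    expect_false(lamC$excluded[lamC$test == "joint"])
    intRows <- mt$meta[mt$meta$test == "interaction", ]
    expect_true(all(intRows$n_studies == 2))
    expect_true(all(intRows$excluded_studies == "C"))
    jointRows <- mt$meta[mt$meta$test == "joint", ]
    expect_true(all(jointRows$n_studies == 3))
    expect_equal(mt$threshold, 0.05 / (ng * 6))
    expect_true(all(mt$meta$P > 0 & mt$meta$P <= 1))
})
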