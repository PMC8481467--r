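test_that("generation is reproducible and respects configured ranges", {
    cfg <- simConfig(nStudies = 2, nSamplesPerStudy = c(300, 200),
                     nGenes = 6, variantsPerGene = c(2, 8), seed = 11)
    d1 <- generateCohorts(cfg)
    d2 <- generateCohorts(cfg)
    expect_length(d1, 2)
    expect_identical(genotypes(d1[[1]]), genotypes(d2[[1]]))
    expect_identical(phenotypes(d1[[2]]), phenotypes(d2[[2]]))
    vi <- variantInfo(d1[[1]])
    expect_true(all(vi$maf_generative > 0 & vi$maf_generative < 0.05))
    g <- genotypes(d1[[1]])
    expect_true(all(g[!is.na(g)] %in% 0:2))
    ev <- deriveExposures(phenotypes(d1[[1]])$smoking)
    expect_true(all(ev$current <= ev$ever))
})

test_that("invalid configurations are rejected with the offending field named", {
    expect_error(simConfig(mafRange = c(0, 0.05)), "mafRange")
    expect_error(simConfig(missingRate = 0.2), "missingRate")
    expect_error(simConfig(
        exposurePrevalence = data.frame(ever = 0.2, current = 0.5)),
        "exposurePrevalence")
    expect_error(simConfig(variantsPerGene = c(5, 2)), "variantsPerGene")
})

test_that("sample MAF converges to the configured MAF", {
    cfg <- simConfig(nStudies = 1, nSamplesPerStudy = 4000, nGenes = 4,
                     variantsPerGene = c(5, 5), mafRange = c(0.01, 0.05),
                     missingRate = 0, seed = 3)
    ds <- generateCohorts(cfg)[[1]]
    g <- genotypes(ds)
    mafHat <- colMeans(g) / 2
    maf <- variantInfo(ds)$maf_generative
    se <- sqrt(maf * (1 - maf) / (2 * nrow(g)))
    expect_true(all(abs(mafHat - maf) < 4 * se))
})

test_that("an interaction effect shifts exposed carriers by the configured amount", {
    cfg <- simConfig(nStudies = 1, nSamplesPerStudy = 8000, nGenes = 3,
                     variantsPerGene = c(4, 4), mafRange = c(0.02, 0.05),
                     missingRate = 0,
                     effectSpec = list(gamma = c(GENE0002 = 0.5),
                                       interactionExposure = "ever",
                                       alpha = c(age = 0, sex = 0, height = 0,
                                                 weight = 0, site = 0, pc = 0),
                                       exposureEver = 0, exposureCurrent = 0),
                     seed = 21)
    ds <- generateCohorts(cfg)[[1]]
    g <- genotypes(ds)
    ids <- geneGroups(ds)$GENE0002
    burden <- rowSums(g[, ids])
    ev <- deriveExposures(phenotypes(ds)$smoking)$ever
    y <- phenotypes(ds)$fev1 / 600          # residual-SD units
    carrier <- burden > 0
    obsDiff <- mean(y[carrier & ev == 1]) - mean(y[carrier & ev == 0])
    expDiff <- 0.5 * mean(burden[carrier & ev == 1])
    expect_equal(obsDiff, expDiff, tolerance = 0.1)
})

test_that("sibship kinship structure matches its definition", {
    f1 <- generateFamilyStructure(5, 1L)
    expect_equal(f1$kinship, diag(5))
    f2 <- generateFamilyStructure(2, 2L)
    expect_equal(f2$kinship[1, 2], 0.5)
    f2k <- generateFamilyStructure(2, 2L, convention = "kinship")
    expect_equal(f2k$kinship[1, 2], 0.25)
    f3 <- generateFamilyStructure(300, 3L)
    expect_equal(nrow(f3$kinship), 300)
    offDiag <- f3$kinship; diag(offDiag) <- 0
    expect_equal(sum(offDiag != 0), 600)   # 3 pairs x 2 entries x 100 sibships
})

test_that("polygenic variance induces within-sibship phenotype correlation", {
    cfg <- simConfig(nStudies = 1, nSamplesPerStudy = 2000, nGenes = 2,
                     variantsPerGene = c(2, 2), missingRate = 0,
                     familySpec = list(sibshipSize = 4, polygenicShare = 0.5),
                     seed = 8)
    ds <- generateCohorts(cfg)[[1]]
    K <- kinshipMatrix(ds)
    expect_true(isSymmetric(K))
    expect_equal(diag(K), rep(1, 2000), ignore_attr = TRUE)
    ## residualize the trait on the main covariates, then compare sib pairs
    ph <- phenotypes(ds)
    X <- buildDesign(ph, "FEV1", nPcs = 10)
    r <- lm.fit(X, ph$fev1)$residuals
    fam <- rep(seq_len(500), each = 4)
    sibPairs <- do.call(rbind, lapply(split(seq_along(r), fam), function(i)
        cbind(r[i[1]], r[i[2]])))
    shufPairs <- cbind(sibPairs[, 1], sibPairs[sample(nrow(sibPairs)), 2])
    expect_gt(cor(sibPairs[, 1], sibPairs[, 2]),
              cor(shufPairs[, 1], shufPairs[, 2]) + 0.1)
})

test_that("pure-null generation leaves the phenotype independent of genotype", {
    cfg <- simConfig(nStudies = 1, nSamplesPerStudy = 3000, nGenes = 5,
                     variantsPerGene = c(3, 3), missingRate = 0, seed = 17)
    ds <- generateCohorts(cfg)[[1]]
    g <- genotypes(ds)
    ph <- phenotypes(ds)
    X <- buildDesign(ph, "FEV1", nPcs = 10)
    r <- lm.fit(X, ph$fev1)$residuals
    cors <- abs(cor(r, g))
    expect_lt(max(cors), 4.5 / sqrt(nrow(g)))
})
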