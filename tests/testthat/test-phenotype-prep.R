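test_that("smoking exposures follow the ever/current definitions", {
    e <- deriveExposures(c("never", "past", "current"))
    expect_equal(e$ever, c(0, 1, 1))
    expect_equal(e$current, c(0, 0, 1))
    expect_error(deriveExposures(c("never", "quit")), "quit")
})

test_that("FEV1/FVC ratio is elementwise with missing propagation", {
    expect_equal(computeRatio(3000, 4000), 0.75)
    expect_equal(computeRatio(2935.4, 3977.2), 0.738057, tolerance = 1e-6)
    expect_true(is.na(computeRatio(NA, 4000)))
    expect_warning(r0 <- computeRatio(3000, 0), "FVC = 0")
    expect_true(is.na(r0))
})

test_that("residual-outlier exclusion flags only genuine outliers", {
    set.seed(5)
    n <- 1000
    X <- cbind(1, rnorm(n))
    y <- 2 + 3 * X[, 2]
    expect_length(excludeResidualOutliers(y, X)$included, n)  # zero residuals
    y2 <- y + rnorm(n)
    y2[17] <- y[17] + 10 * sd(rnorm(n))
    out <- excludeResidualOutliers(y2, X, kSd = 4)
    expect_false(17 %in% out$included)
    expect_length(out$included, n - 1)
    expect_length(excludeResidualOutliers(y2, X, kSd = Inf)$included, n)
    ## affine invariance of the exclusion set
    out2 <- excludeResidualOutliers(1000 + 250 * y2, X, kSd = 4)
    expect_identical(out$included, out2$included)
    ## flag-only mode keeps everyone but records the flag
    fl <- excludeResidualOutliers(y2, X, kSd = 4, action = "flag")
    expect_length(fl$included, n)
    expect_true(fl$log$excluded[17])
})

test_that("inverse-normal transform uses Blom scores with average ranks", {
    y <- c(10, 3, 7)
    z <- inverseNormalTransform(y)
    q <- qnorm((3 - 3 / 8) / (3 - 2 * 3 / 8 + 1))
    expect_equal(sort(z), c(-q, 0, q))
    expect_equal(rank(z), rank(y))
    set.seed(1)
    v <- rexp(500)
    v[c(3, 9)] <- NA
    z1 <- inverseNormalTransform(v)
    expect_true(all(is.na(z1[c(3, 9)])))
    expect_equal(inverseNormalTransform(z1), z1, tolerance = 1e-12)
    expect_equal(mean(z1, na.rm = TRUE), 0, tolerance = 1e-3)
    expect_equal(var(z1[!is.na(z1)]), 1, tolerance = 0.02)
    ## ties share the transformed value
    zt <- inverseNormalTransform(c(1, 2, 2, 5))
    expect_equal(zt[2], zt[3])
    expect_error(inverseNormalTransform(rep(4, 10)), "identical")
})

test_that("trait-specific designs include weight only for FVC", {
    ds <- toyStudy(80)
    ph <- phenotypes(ds)
    Xfev1 <- buildDesign(ph, "FEV1")
    Xfvc <- buildDesign(ph, "FVC")
    Xratio <- buildDesign(ph, "RATIO")
    expect_false("weight" %in% colnames(Xfev1))
    expect_true("weight" %in% colnames(Xfvc))
    expect_false("weight" %in% colnames(Xratio))
    expect_true(all(c("ever", "current") %in% colnames(Xfev1)))
    ## single-site study contributes no site columns
    expect_false(any(grepl("^site", colnames(Xfev1))))
})

test_that("prepareStudy transforms the ratio itself and wires the exposure", {
    ds <- toyStudy(120)
    prep <- prepareStudy(ds, "RATIO", "CURRENT", kSd = Inf)
    ph <- phenotypes(ds)
    direct <- inverseNormalTransform(
        computeRatio(ph$fev1, ph$fvc)[prep$included])
    expect_equal(prep$yStar, direct)
    expect_equal(prep$E,
                 deriveExposures(ph$smoking[prep$included])$current)
    expect_equal(mean(prep$yStar), 0, tolerance = 5e-3)
    ## samples with missing covariates are dropped
    ph2 <- ph; ph2$height[3] <- NA
    prep2 <- prepareStudy(ph2, "FEV1", "EVER")
    expect_false(3 %in% prep2$included)
})
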