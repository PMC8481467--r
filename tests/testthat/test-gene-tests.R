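test_that("no exposed samples degenerates the interaction test", {
    set.seed(21)
    n <- 120
    X <- cbind(1, rnorm(n))
    E <- rep(0, n)
    G <- rareG(n, 3)
    y <- rnorm(n)
    model <- gxeModel(y, X, E, G)
    null <- fitNullInteraction(y, X, G, model@weights)
    res <- testInteraction(null, model)
    expect_equal(res$p, 1)
    expect_equal(res$q, 0)
    ## joint test reduces to the main-effect-only variance-component statistic
    nj <- fitNullJoint(y, X)
    tj <- testJoint(nj, model)
    C <- sweep(G, 2, sqrt(model@weights), "*")
    Py <- nj@Py
    qMain <- sum(as.numeric(crossprod(C, Py))^2)
    expect_equal(tj$q, qMain, tolerance = 1e-10)
})

test_that("score statistics are invariant to design reparameterization and variant order", {
    set.seed(22)
    n <- 200
    d <- smallDesign(n)
    G <- rareG(n, 4)
    y <- rnorm(n) + 0.3 * rowSums(G)
    model <- gxeModel(y, d$X, d$E, G)
    ## invertible affine recombination of the covariate columns
    A <- matrix(c(1, 0, 0, 0,  2, 3, 0, 0,  1, -1, 0.5, 0,  0, 1, 1, 2), 4, 4)
    X2 <- d$X %*% A
    m2 <- gxeModel(y, X2, d$E, G, weights = model@weights)
    n1 <- fitNullInteraction(y, d$X, G, model@weights)
    n2 <- fitNullInteraction(y, X2, G, model@weights)
    t1 <- testInteraction(n1, model); t2 <- testInteraction(n2, m2)
    expect_equal(t1$q, t2$q, tolerance = 1e-8)
    expect_equal(t1$p, t2$p, tolerance = 1e-8)
    ## permuting variants leaves both tests unchanged
    perm <- c(3, 1, 4, 2)
    mp <- gxeModel(y, d$X, d$E, G[, perm], weights = model@weights[perm])
    np <- fitNullInteraction(y, d$X, G[, perm], model@weights[perm])
    tp <- testInteraction(np, mp)
    expect_equal(t1$p, tp$p, tolerance = 1e-8)
    j1 <- testJoint(fitNullJoint(y, d$X), model)
    jp <- testJoint(fitNullJoint(y, d$X), mp)
    expect_equal(j1$p, jp$p, tolerance = 1e-8)
})

test_that("score p-value matches a Monte-Carlo oracle on a small instance", {
    set.seed(23)
    n <- 60; m <- 3
    d <- smallDesign(n, prevalence = 0.4)
    G <- rareG(n, m, c(0.05, 0.05))
    y <- rnorm(n)
    model <- gxeModel(y, d$X, d$E, G)
    null <- fitNullInteraction(y, d$X, G, model@weights)
    res <- testInteraction(null, model)
    ## oracle: draw the mixture with the instance's own eigenvalues
    C <- sweep(model@S, 2, sqrt(model@weights), "*")
    M <- crossprod(C, projectNull(null, C))
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam)]
    nmc <- 1e6
    draws <- colSums(lam * matrix(rchisq(nmc * length(lam), 1), length(lam)))
    phat <- mean(draws >= res$q)
    se <- sqrt(phat * (1 - phat) / nmc)
    expect_lt(abs(res$p - phat), 3 * se + 1e-10)
})

test_that("single-pseudo-variant joint test tracks the 2-df single-variant test", {
    set.seed(24)
    diffs <- replicate(10, {
        n <- 1500
        d <- smallDesign(n, prevalence = 0.4)
        g <- rbinom(n, 2, 0.2)
        y <- rnorm(n)                      # null data: score ~ Wald at O(1/n)
        model <- gxeModel(y, d$X, d$E, matrix(g, ncol = 1),
                          weights = 1)
        null <- fitNullJoint(y, d$X)
        tj <- testJoint(null, model)
        ## identity: Q is the squared norm of the 2-df score vector
        B <- cbind(g, g * d$E)
        u <- as.numeric(crossprod(B, null@Py))
        expect_equal(tj$q, sum(u^2), tolerance = 1e-10)
        ## normalising by the score covariance recovers the 2-df chi-square
        ## test, which tracks the single-variant Wald test
        M <- crossprod(B, projectNull(null, B))
        p2df <- pchisq(sum(u * solve(M, u)), df = 2, lower.tail = FALSE)
        pWald <- singleVariantTests(y, d$X, d$E, g)$p_joint
        abs(p2df - pWald)
    })
    expect_lt(max(diffs), 0.02)
})

test_that("conditional testing matches its contracts", {
    set.seed(25)
    n <- 300
    d <- smallDesign(n, prevalence = 0.3)
    G <- rareG(n, 4)
    y <- rnorm(n) + 0.5 * G[, 1] + 0.4 * G[, 1] * d$E
    model <- gxeModel(y, d$X, d$E, G)
    base <- list(
        interaction = testInteraction(
            fitNullInteraction(y, d$X, G, model@weights), model),
        joint = testJoint(fitNullJoint(y, d$X), model))
    ## conditioning on a zero vector changes nothing (column is dropped)
    suppressWarnings(
        c0 <- conditionalGeneTest(model, rep(0, n)))
    expect_equal(c0$joint$p, base$joint$p, tolerance = 1e-8)
    expect_equal(c0$interaction$p, base$interaction$p, tolerance = 1e-8)
    ## duplicated conditioning vector: second copy dropped, same answer
    cond <- rbinom(n, 2, 0.2)
    c1 <- conditionalGeneTest(model, cbind(cond))
    suppressWarnings(c2 <- conditionalGeneTest(model, cbind(cond, cond)))
    expect_equal(c1$joint$p, c2$joint$p, tolerance = 1e-8)
    expect_warning(conditionalGeneTest(model, cbind(cond, cond)), "collinear")
    ## conditioning on the causal variant attenuates the signal
    cc <- conditionalGeneTest(model, G[, 1],
                              includeInteractionCovariate = TRUE)
    expect_equal(cc$nVariants, 3)   # causal column removed from the set
    expect_gt(cc$joint$p, base$joint$p)
})

test_that("conditioning on the causal variant restores null behaviour on average", {
    set.seed(26)
    ps <- replicate(25, {
        n <- 400
        d <- smallDesign(n, prevalence = 0.3)
        G <- rareG(n, 3, c(0.03, 0.05))
        y <- rnorm(n) + 0.8 * G[, 1]
        model <- gxeModel(y, d$X, d$E, G)
        cc <- conditionalGeneTest(model, G[, 1])
        cc$joint$p
    })
    ## roughly uniform: mean near 0.5, no pile-up at 0
    expect_gt(mean(ps), 0.32)
    expect_gt(min(ps), 1e-4)
})

test_that("joint test power increases with the interaction effect", {
    set.seed(27)
    n <- 600
    rejRate <- vapply(c(0, 0.3, 0.6), function(gam) {
        mean(replicate(30, {
            d <- smallDesign(n, prevalence = 0.3)
            G <- rareG(n, 4, c(0.02, 0.05))
            y <- rnorm(n) + gam * rowSums(G) * d$E
            model <- gxeModel(y, d$X, d$E, G)
            testJoint(fitNullJoint(y, d$X), model)$p <= 0.05
        }))
    }, 0)
    expect_lte(rejRate[1], 0.2)
    expect_gt(rejRate[3], rejRate[1] + 0.2)
    expect_gte(rejRate[3], rejRate[2] - 0.1)
})

test_that("per-gene result tables are complete and deterministically ordered", {
    ds <- toyStudy(150, seed = 77)
    qc <- qcStudy(ds, cmacMin = 1, minVariants = 1, seed = 3)
    prep <- prepareStudy(ds, "FEV1", "EVER", kSd = Inf)
    res <- runGeneTests(prep$yStar, prep$X, prep$E,
                        qc$genotypes[prep$included, , drop = FALSE],
                        qc$groups, studyId = "TOY", trait = "FEV1",
                        exposure = "EVER")
    expect_equal(res$gene, sort(names(qc$groups)))
    expect_true(all(res$p_interaction > 0 & res$p_interaction <= 1))
    expect_true(all(res$p_joint > 0 & res$p_joint <= 1))
    expect_true(all(res$n_variants >= 1))
    expect_true(all(c("study_id", "cumulative_mac", "pvalue_method")
                    %in% names(res)))
})
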