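designWithExposure <- function(n, seed) {
    d <- generateDesign(n, seed = seed)
    ex <- generateExposures(d, seed = seed)
    list(d = as.data.frame(d), x = visitExposure(d, ex, "NO2"))
}

test_that("GLS with identity covariance matches ordinary least squares", {
    de <- designWithExposure(100, 1)
    set.seed(2)
    y <- 5 + 0.01 * de$x + rnorm(nrow(de$d))   # Sigma = I, independent errors
    fit <- fitMvnFeature(y, de$d, de$x)
    ols <- lm(y ~ x + age + sex + group + bmi,
              data = transform(de$d, x = de$x))
    expect_lt(abs(fit$beta - coef(ols)[["x"]]), 1e-4)
    # every coefficient agrees well within one OLS standard error
    se <- sqrt(diag(vcov(ols)))
    expect_true(all(abs(fit$coefficients - coef(ols)) < 0.5 * se))
})

test_that("REML estimates agree with the generalized least squares oracle", {
    skip_if_not_installed("nlme")
    de <- designWithExposure(25, 3)
    set.seed(4)
    u <- rnorm(25)[match(de$d$participant, unique(de$d$participant))]
    y <- 8 + 0.01 * de$x + 0.02 * de$d$age + u + rnorm(150, sd = 0.8)
    fit <- fitMvnFeature(y, de$d, de$x)
    dd <- transform(de$d, y = y, x = de$x, occ = as.integer(occasion),
                    id = participant)
    g <- nlme::gls(y ~ x + age + sex + group + bmi, data = dd,
                   correlation = nlme::corSymm(form = ~occ | id),
                   weights = nlme::varIdent(form = ~1 | occ),
                   method = "REML",
                   control = nlme::glsControl(maxIter = 200,
                                              msMaxIter = 200,
                                              returnObject = TRUE))
    expect_lt(abs(fit$beta - coef(g)[["x"]]), 1e-5)
    expect_lt(abs(fit$se - sqrt(vcov(g)["x", "x"])), 1e-5)
})

test_that("effect recovery is unbiased over simulation replicates", {
    # true beta = 0.5 per unit exposure; moderate within-person correlation
    nRep <- 60
    de <- designWithExposure(100, 5)
    xs <- scale(de$x)[, 1]   # unit-scale exposure so beta = 0.5 is plain
    betas <- ses <- numeric(nRep)
    for (r in seq_len(nRep)) {
        set.seed(1000 + r)
        u <- rnorm(100, 0, 1)[match(de$d$participant,
                                    unique(de$d$participant))]
        y <- 10 + 0.5 * xs + u + rnorm(600, sd = 1)
        f <- fitMvnFeature(y, de$d, xs)
        betas[r] <- f$beta
        ses[r] <- f$se
    }
    mcse <- sd(betas) / sqrt(nRep)
    expect_lt(abs(mean(betas) - 0.5), 3 * mcse)
    covered <- mean(abs(betas - 0.5) <= 1.96 * ses)
    expect_gte(covered, 0.9)
})

test_that("permuted exposure gives approximately uniform p-values", {
    de <- designWithExposure(40, 7)
    set.seed(8)
    u <- rnorm(40)[match(de$d$participant, unique(de$d$participant))]
    y <- 10 + u + rnorm(240)
    ps <- vapply(1:80, function(r) {
        set.seed(r)
        # permute the visit-level exposure across participants
        xp <- de$x[order(rep(sample(40), each = 6))]
        fitMvnFeature(y, de$d, xp)$p
    }, 0)
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("unstructured covariance nests compound symmetry in REML", {
    de <- designWithExposure(20, 9)
    set.seed(10)
    u <- rnorm(20, 0, 0.7)[match(de$d$participant,
                                 unique(de$d$participant))]
    y <- 10 + u + rnorm(120, sd = 0.6)
    un <- fitMvnFeature(y, de$d, de$x, covStruct = "unstructured")
    cs <- fitMvnFeature(y, de$d, de$x, covStruct = "compoundSymmetry")
    expect_gte(un$logLikREML, cs$logLikREML - 1e-4)
    expect_identical(cs$model, "compoundSymmetry")
})

test_that("identifiability violations are reported", {
    de <- designWithExposure(12, 11)
    y <- rnorm(72)
    expect_error(fitMvnFeature(y, de$d, rep(1, 72)), "identifiability")
    # collinear covariate (bmi duplicated into age) -> singular design
    d2 <- de$d
    d2$age <- d2$bmi
    d2$bmi <- NULL
    expect_error(fitMvnFeature(y, transform(d2, bmi = age), de$x),
                 "identifiability")
})

test_that("participants with missing occasions contribute sub-vectors", {
    de <- designWithExposure(30, 13)
    set.seed(14)
    u <- rnorm(30)[match(de$d$participant, unique(de$d$participant))]
    y <- 9 + 0.01 * de$x + u + rnorm(180, sd = 0.5)
    drop <- c(3, 50, 97)      # three occasions from three participants
    y2 <- y
    y2[drop] <- NA
    f <- fitMvnFeature(y2, de$d, de$x)
    expect_true(is.finite(f$p))
    full <- fitMvnFeature(y, de$d, de$x)
    expect_lt(abs(f$beta - full$beta), 0.05 * max(abs(full$beta), 0.01))
})

test_that("ENT equals the exact spectral count", {
    # rank-3 noiseless data: 3 independent signals duplicated many times
    set.seed(15)
    sig <- matrix(rnorm(60), 20, 3)
    m <- t(sig[, rep(1:3, each = 10)])   # 30 features, 20 samples
    expect_equal(effectiveNumberOfTests(m), 3)
    # 100 iid features on 20 samples: centering leaves rank 19
    set.seed(16)
    m2 <- matrix(rnorm(100 * 20), 100, 20)
    expect_equal(effectiveNumberOfTests(m2), 19)
    # single feature
    expect_equal(effectiveNumberOfTests(matrix(rnorm(20), 1)), 1)
    # duplication invariance
    expect_equal(effectiveNumberOfTests(rbind(m, m[1, ])), 3)
    expect_equal(effectiveNumberOfTests(rbind(m2, m2[5, ])), 19)
    expect_warning(effectiveNumberOfTests(rbind(m, 0)), "zero-variance")
})

test_that("Bonferroni flags follow strict per-test thresholds", {
    tab <- data.frame(feature = paste0("F", 1:4), exposure = "NO2",
                      beta = 0, se = 1, stat = 0,
                      p = c(0.04 / 284, 0.05, 0.049 / 284, 1))
    r <- applyCorrections(tab, ent = 284, nFeatures = 6040)
    d <- as.data.frame(r)
    expect_true(d$significantENT[1])        # p = 0.04/284 < 0.05/284
    expect_false(d$significantENT[2])
    expect_true(d$significantENT[3])
    expect_false(d$significantFull[3])      # full correction more stringent
    expect_true(all(!d$significantFull | d$significantENT))
    # p exactly at the threshold is not significant (strict inequality)
    r2 <- applyCorrections(data.frame(feature = "F1", exposure = "e",
                                      beta = 0, se = 1, stat = 0, p = 0.05),
                           ent = 1, nFeatures = 1)
    expect_false(as.data.frame(r2)$significantENT)
    # ent = nFeatures makes the two flags identical
    r3 <- applyCorrections(tab, ent = 4, nFeatures = 4)
    expect_identical(as.data.frame(r3)$significantENT,
                     as.data.frame(r3)$significantFull)
    expect_error(applyCorrections(tab, ent = 0), "ent")
    expect_error(applyCorrections(tab, ent = 10, nFeatures = 4), "exceeds")
})

test_that("association summary recovers a planted sharing partition", {
    # 10 features significant for NO2 only, 5 for both NO2 and BC
    tab <- expand.grid(feature = paste0("F", 1:20),
                       exposure = c("NO2", "BC"),
                       stringsAsFactors = FALSE)
    tab$beta <- 0; tab$se <- 1; tab$stat <- 0
    tab$p <- 1
    tab$p[tab$exposure == "NO2" & tab$feature %in% paste0("F", 1:15)] <- 1e-8
    tab$p[tab$exposure == "BC" & tab$feature %in% paste0("F", 11:15)] <- 1e-8
    r <- applyCorrections(tab, ent = 10, nFeatures = 20)
    s <- associationSummary(r)
    expect_equal(unname(s$perExposure["NO2"]), 15L)
    expect_equal(unname(s$perExposure["BC"]), 5L)
    expect_equal(s$uniqueSignificant, 15)
    expect_equal(s$combinations$nFeatures[s$combinations$pattern == "NO2"],
                 10L)
    expect_equal(s$combinations$nFeatures[
        s$combinations$pattern == "BC+NO2"], 5L)
    # empty case
    tab$p <- 1
    s0 <- associationSummary(applyCorrections(tab, 10, 20))
    expect_equal(s0$uniqueSignificant, 0)
    expect_true(all(s0$perExposure == 0))
})

test_that("matrix-level association testing flags the affected features", {
    sim <- simulateStudy(nParticipants = 25, nFeatures = 30, nAffected = 6,
                         beta = 0.05, batchSd = 0, censorFraction = 0,
                         seed = 21)
    os <- log2Transform(sim$omics)
    res <- associateExposures(os, sim$exposures, pollutants = "NO2")
    tab <- as.data.frame(res)
    expect_equal(nrow(tab), 30)
    hits <- which(rownames(os) %in% tab$feature[tab$significantENT])
    expect_gte(length(intersect(hits, sim$truth$affected)), 5)
    expect_lte(length(setdiff(hits, sim$truth$affected)), 1)
})
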