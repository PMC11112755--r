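makeRawSet <- function(m, design = NULL) {
    OmicsSet(m, colData = design, scale = "raw")
}

test_that("missingness filter removes features at the threshold, inclusive", {
    # 10 features with per-sample missing fractions 0.0, 0.1, ..., 0.9 over
    # 10 participants (one sample each)
    d <- S4Vectors::DataFrame(participant = paste0("P", 1:10),
                              row.names = paste0("S", 1:10))
    m <- matrix(2, 10, 10, dimnames = list(paste0("F", 1:10),
                                           paste0("S", 1:10)))
    for (i in 1:10) if (i > 1) m[i, seq_len(i - 1L)] <- NA
    os <- makeRawSet(m, d)
    kept <- filterMissingness(os, 0.40)
    expect_equal(nrow(kept), 4)                   # 0.0 .. 0.3 retained
    expect_equal(S4Vectors::metadata(kept)$removed$feature,
                 paste0("F", 5:10))
    # fully observed matrix is untouched
    full <- makeRawSet(matrix(1:20, 4, 5), NULL)
    expect_equal(nrow(filterMissingness(full, 0.4)), 4)
    expect_warning(filterMissingness(os[-1, ], 0.05),
                   "all features removed")
    # participant-level counting: observed in any sample of a participant
    d2 <- S4Vectors::DataFrame(participant = rep(c("P1", "P2"), each = 2),
                               row.names = paste0("S", 1:4))
    m2 <- matrix(c(NA, 1, 1, 1), 1, 4,
                 dimnames = list("F1", paste0("S", 1:4)))
    expect_equal(nrow(filterMissingness(makeRawSet(m2, d2), 0.4)), 1)
})

test_that("log2 transform flips the scale flag and validates inputs", {
    m <- matrix(c(8, 1, 4, NA), 2, 2, dimnames = list(c("A", "B"), NULL))
    os <- makeRawSet(m)
    tr <- log2Transform(os)
    expect_identical(omicsScale(tr), "log2")
    expect_equal(intensities(tr)[1, 1], 3)
    expect_equal(intensities(tr)[2, 1], 0)
    expect_identical(missingMask(tr), missingMask(os))
    # round trip
    expect_equal(2^intensities(tr), intensities(os))
    expect_error(log2Transform(tr), "raw")
    bad <- makeRawSet(matrix(c(1, 0, 2, 3), 2, 2,
                             dimnames = list(c("A", "B"), c("s1", "s2"))))
    expect_error(log2Transform(bad), "'B'.*'s1'")
})

test_that("QRILC recovers the latent normal under 20% left-censoring", {
    set.seed(31)
    n <- 500
    latent <- rnorm(n, 10, 1)
    thr <- quantile(latent, 0.2)
    col <- ifelse(latent < thr, NA, latent)
    m <- matrix(col, n, 1, dimnames = list(paste0("F", 1:n), "S1"))
    os <- OmicsSet(m, scale = "log2")
    imp <- imputeQRILC(os, seed = 3)
    est <- S4Vectors::metadata(imp)$qrilc
    expect_lt(abs(est["S1", "mu"] - 10), 0.15)
    expect_lt(abs(est["S1", "sigma"] - 1), 0.15)
    # imputed values respect the truncation bound (tuneSigma <= 1):
    # never above the estimated censoring quantile, i.e. near the
    # observed minimum
    imputed <- intensities(imp)[is.na(col), 1]
    bound <- est["S1", "mu"] + est["S1", "sigma"] * qnorm(0.2)
    expect_lte(max(imputed), bound + 1e-8)
    expect_lte(max(imputed), min(col, na.rm = TRUE) + 0.1)
    expect_equal(sum(is.na(intensities(imp))), 0)
    # no missing values -> identity
    os2 <- OmicsSet(matrix(rnorm(20), 4, 5), scale = "log2")
    expect_equal(intensities(imputeQRILC(os2, seed = 1)), intensities(os2))
    # determinism under a fixed seed
    imp2 <- imputeQRILC(os, seed = 3)
    expect_identical(intensities(imp), intensities(imp2))
    # < 4 observed values in a column -> half-minimum fallback with warning
    sparse <- OmicsSet(matrix(c(5, 6, NA, NA, NA, NA), 6, 1,
                              dimnames = list(paste0("F", 1:6), "S1")),
                       scale = "log2")
    expect_warning(impS <- imputeQRILC(sparse, seed = 1), "half-minimum")
    expect_equal(unname(intensities(impS)[3, 1]), 4)
    expect_error(imputeQRILC(makeRawSet(matrix(1, 2, 2))), "log2")
})

test_that("PCA outlier flags fire on spiked samples, not on clean data", {
    set.seed(17)
    m <- matrix(rnorm(100 * 60), 100, 60,
                dimnames = list(paste0("F", 1:100), paste0("S", 1:60)))
    os <- OmicsSet(m, scale = "log2")
    clean <- flagPCAOutliers(os, nComponents = 3, madMultiplier = 5)
    expect_lt(mean(clean), 0.01)
    # a +50 SD shift on 30% of features must be flagged
    spiked <- m
    spiked[1:30, 7] <- spiked[1:30, 7] + 50
    fs <- flagPCAOutliers(OmicsSet(spiked, scale = "log2"))
    expect_true(fs[["S7"]])
    expect_lte(sum(fs), 2)
    # infinite multiplier -> no flags
    expect_equal(sum(flagPCAOutliers(os, madMultiplier = Inf)), 0)
    expect_error(flagPCAOutliers(os, nComponents = 1000), "invalid config")
})

test_that("technical denoising removes between-batch variance", {
    set.seed(23)
    nLev <- 6; per <- 20
    batch <- factor(rep(paste0("b", seq_len(nLev)), each = per))
    d <- S4Vectors::DataFrame(plate = batch,
                              box = factor(rep(c("x", "y"),
                                               length.out = nLev * per)))
    offsets <- rnorm(nLev, 0, 2)
    y <- 10 + offsets[as.integer(batch)] + rnorm(nLev * per, 0, 0.5)
    os <- OmicsSet(matrix(y, 1, dimnames = list("F1", NULL)),
                   colData = d, scale = "log2")
    den <- denoiseTechnical(os, factors = c("plate", "box"))
    z <- intensities(den)[1, ]
    betweenShare <- function(v) {
        gm <- tapply(v, batch, mean)
        sum(tabulate(batch) * (gm - mean(v))^2) / sum((v - mean(v))^2)
    }
    expect_gt(betweenShare(y), 0.5)       # raw data dominated by batch
    expect_lt(betweenShare(z), 0.05)      # < 5% after BLUP subtraction
    expect_equal(mean(z), mean(y), tolerance = 0.2)  # grand mean retained
    # single-level factor contributes nothing and is dropped with warning
    d1 <- S4Vectors::DataFrame(plate = batch,
                               box = factor(rep("only", nLev * per)))
    os1 <- OmicsSet(matrix(y, 1, dimnames = list("F1", NULL)),
                    colData = d1, scale = "log2")
    expect_warning(den1 <- denoiseTechnical(os1), "single-level")
    expect_equal(intensities(denoiseTechnical(os, factors = "plate")),
                 intensities(den1))
})

test_that("denoising is near-identity when there is no batch signal", {
    set.seed(29)
    n <- 240
    d <- S4Vectors::DataFrame(plate = factor(rep(1:4, length.out = n)),
                              box = factor(rep(1:6, length.out = n)))
    y <- rnorm(n, 12, 1)
    os <- OmicsSet(matrix(y, 1, dimnames = list("F1", NULL)),
                   colData = d, scale = "log2")
    den <- denoiseTechnical(os)
    expect_lt(max(abs(intensities(den)[1, ] - y)), 0.25)
})

test_that("denoising reduces the technical intraclass correlation", {
    set.seed(41)
    sim <- simulateStudy(nParticipants = 8, nFeatures = 10, batchSd = 1,
                         censorFraction = 0, seed = 8)
    os <- denoiseTechnical(log2Transform(sim$omics))
    icc <- function(v, f) {
        gm <- tapply(v, f, mean)
        sum(tabulate(f) * (gm - mean(v))^2) / sum((v - mean(v))^2)
    }
    plate <- colData(os)$plate
    before <- intensities(log2Transform(sim$omics))
    after <- intensities(os)
    for (i in seq_len(nrow(os)))
        expect_lte(icc(after[i, ], plate), icc(before[i, ], plate) + 0.02)
})
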