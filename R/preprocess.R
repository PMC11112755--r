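#' @importFrom stats lm qnorm runif prcomp median mad coef sd var
NULL

#' Remove features with excessive missingness
#'
#' A feature is removed when its missing fraction is at or above
#' `maxMissingFrac` (threshold inclusive: a feature missing in exactly 40%
#' of participants is dropped at the 0.40 default). By default the fraction
#' is computed over participants — a feature observed in any sample of a
#' participant counts as observed for that participant; set
#' `by = "sample"` for a plain per-sample fraction.
#'
#' @param m an [OmicsSet-class].
#' @param maxMissingFrac removal threshold in (0, 1\]; default 0.40.
#' @param by `"participant"` (default) or `"sample"`.
#' @return the filtered `OmicsSet`; the removal log (feature id + missing
#'   fraction of every removed feature) is appended to `metadata()$removed`.
#' @export
filterMissingness <- function(m, maxMissingFrac = 0.40,
                              by = c("participant", "sample")) {
    by <- match.arg(by)
    if (maxMissingFrac <= 0 || maxMissingFrac > 1)
        stop("maxMissingFrac must lie in (0, 1]")
    miss <- missingMask(m)
    if (by == "participant" && "participant" %in% colnames(colData(m))) {
        pid <- as.character(colData(m)$participant)
        obsByPid <- vapply(split(seq_len(ncol(m)), pid),
                           function(ix) rowSums(!miss[, ix, drop = FALSE]) > 0,
                           logical(nrow(m)))
        if (is.null(dim(obsByPid)))               # single-feature input
            obsByPid <- matrix(obsByPid, nrow = nrow(m))
        frac <- 1 - rowMeans(obsByPid)
    } else {
        frac <- rowMeans(miss)
    }
    drop <- frac >= maxMissingFrac
    if (all(drop))
        warning("all features removed by the missingness filter")
    out <- m[!drop, ]
    metadata(out)$removed <- data.frame(feature = rownames(m)[drop],
                                        missingFrac = frac[drop],
                                        row.names = NULL)
    out
}

#' Log2-transform raw intensities
#'
#' @param m an [OmicsSet-class] on the raw scale; every observed intensity
#'   must be strictly positive.
#' @return the `OmicsSet` on the log2 scale; the missing mask is unchanged.
#' @export
log2Transform <- function(m) {
    if (omicsScale(m) != "raw")
        stop("log2Transform expects raw-scale intensities")
    a <- intensities(m)
    bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-positive intensity at feature '%s', sample '%s'",
                     rownames(a)[bad[1L, 1L]], colnames(a)[bad[1L, 2L]]))
    setIntensities(m, log2(a), scale = "log2")
}

# QRILC core for a single column: fit the latent normal by regressing the
# observed order statistics on standard-normal quantiles at plotting
# positions spanning (f, 1), then draw the missing values from
# N(mu, tuneSigma * sigma) truncated above at the censoring quantile
# mu + sigma * qnorm(f).
qrilcColumn <- function(x, tuneSigma) {
    miss <- is.na(x)
    nMiss <- sum(miss)
    if (nMiss == 0L) return(list(x = x, mu = NA_real_, sigma = NA_real_))
    obs <- sort(x[!miss])
    nObs <- length(obs)
    f <- nMiss / length(x)
    if (nObs < 4L) {
        x[miss] <- min(obs) - 1  # half-minimum on the log2 scale
        return(list(x = x, mu = NA_real_, sigma = NA_real_,
                    fallback = TRUE))
    }
    pp <- f + (1 - f) * (seq_len(nObs) - 0.5) / nObs
    z <- qnorm(pp)
    fit <- lm.fit(cbind(1, z), obs)
    mu <- fit$coefficients[[1L]]
    sigma <- max(fit$coefficients[[2L]], 1e-8)
    upper <- mu + sigma * qnorm(f)
    sdd <- tuneSigma * sigma
    pUpper <- pnorm((upper - mu) / sdd)
    u <- runif(nMiss, 0, pUpper)
    x[miss] <- mu + sdd * qnorm(pmax(u, 1e-12))
    list(x = x, mu = mu, sigma = sigma)
}

#' Impute left-censored missing values (QRILC)
#'
#' Quantile-regression imputation of left-censored data, applied per sample
#' (column): the observed upper tail of each sample's intensity
#' distribution is regressed on standard-normal quantiles to recover the
#' mean and SD of the latent complete distribution, and each missing value
#' is drawn from that normal — variance shrunk by `tuneSigma` — truncated
#' above at the estimated censoring quantile. Columns with fewer than 4
#' observed values fall back to half-minimum imputation with a warning.
#'
#' @param m an [OmicsSet-class] on the log2 scale.
#' @param tuneSigma multiplier (in (0, 1\]) on the estimated SD of the
#'   imputation distribution; default 1.
#' @param seed integer seed making the draws reproducible.
#' @return the `OmicsSet` with no missing values; per-column estimates
#'   `(mu, sigma)` in `metadata()$qrilc`.
#' @export
imputeQRILC <- function(m, tuneSigma = 1, seed = 1) {
    if (omicsScale(m) != "log2")
        stop("imputeQRILC expects log2-scale intensities (impute after log2Transform)")
    if (tuneSigma <= 0) stop("tuneSigma must be positive")
    a <- intensities(m)
    set.seed(stageSeed(seed, "qrilc"))
    est <- matrix(NA_real_, ncol(a), 2L,
                  dimnames = list(colnames(a), c("mu", "sigma")))
    nFallback <- 0L
    for (j in seq_len(ncol(a))) {
        r <- qrilcColumn(a[, j], tuneSigma)
        a[, j] <- r$x
        est[j, ] <- c(r$mu, r$sigma)
        if (isTRUE(r$fallback)) nFallback <- nFallback + 1L
    }
    if (nFallback)
        warning(sprintf(
            "%d column(s) had < 4 observed values; half-minimum fallback used",
            nFallback))
    out <- setIntensities(m, a)
    metadata(out)$qrilc <- est
    out
}

#' Flag outlying samples on leading principal components
#'
#' Computes PCA scores of the standardized features and flags samples whose
#' score on any of the first `nComponents` axes deviates from the median by
#' more than `madMultiplier` robust SDs (MAD with the usual 1.4826
#' consistency constant). A programmatic stand-in for visual PCA screening;
#' the caller decides what to remove.
#'
#' @param m an imputed, log2-scale [OmicsSet-class].
#' @param nComponents number of leading axes inspected (default 3).
#' @param madMultiplier robust-SD multiplier (default 5).
#' @return logical vector, one flag per sample; per-sample worst
#'   standardized deviation in `attr(, "score")`.
#' @export
flagPCAOutliers <- function(m, nComponents = 3, madMultiplier = 5) {
    a <- intensities(m)
    if (anyNA(a)) stop("flagPCAOutliers expects an imputed matrix")
    if (nComponents > min(dim(a)))
        stop("invalid config: nComponents exceeds matrix rank bound")
    v <- apply(a, 1L, var)
    a <- a[v > 0, , drop = FALSE]
    pc <- prcomp(t(a), center = TRUE, scale. = TRUE)
    k <- min(nComponents, ncol(pc$x))
    dev <- vapply(seq_len(k), function(i) {
        s <- pc$x[, i]
        md <- mad(s)
        if (md < 1e-12) md <- sd(s)
        abs(s - median(s)) / md
    }, numeric(ncol(a)))
    worst <- apply(dev, 1L, max)
    flag <- worst > madMultiplier
    names(flag) <- colnames(a)
    attr(flag, "score") <- worst
    flag
}

#' Remove technical batch variation by mixed-model BLUP subtraction
#'
#' For each feature, fits an intercept-only linear mixed model with one
#' random intercept per technical factor (crossed; REML via
#' [lme4::lmer()]) and subtracts each sample's predicted random effects
#' (BLUPs) from its value, retaining the fixed-effect mean. Factors with a
#' single level contribute nothing and are dropped with a warning; a
#' feature whose joint fit fails falls back to sequential one-factor fits
#' with a warning.
#'
#' @param m an imputed [OmicsSet-class].
#' @param factors character vector of technical-factor columns in
#'   `colData(m)` (default `c("plate", "box")`).
#' @return the denoised `OmicsSet`; estimated variance components per
#'   feature in `metadata()$denoise`.
#' @export
denoiseTechnical <- function(m, factors = c("plate", "box")) {
    a <- intensities(m)
    if (anyNA(a)) stop("denoiseTechnical expects an imputed matrix")
    cd <- colData(m)
    missing <- setdiff(factors, colnames(cd))
    if (length(missing))
        stop("unknown technical factor(s): ", paste(missing, collapse = ", "))
    lev <- vapply(factors, function(f) length(unique(cd[[f]])), 0L)
    if (any(lev < 2L)) {
        warning("dropping single-level technical factor(s): ",
                paste(factors[lev < 2L], collapse = ", "))
        factors <- factors[lev >= 2L]
    }
    if (!length(factors)) return(m)
    df <- data.frame(lapply(as.data.frame(cd[, factors, drop = FALSE]),
                            factor))
    form <- stats::as.formula(paste("y ~ 1 +",
        paste(sprintf("(1 | %s)", factors), collapse = " + ")))
    vc <- matrix(NA_real_, nrow(a), length(factors) + 1L,
                 dimnames = list(rownames(a), c(factors, "residual")))
    out <- a
    nFallback <- 0L
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    for (i in seq_len(nrow(a))) {
        df$y <- a[i, ]
        fit <- tryCatch(
            suppressMessages(lme4::lmer(form, data = df, REML = TRUE,
                                        control = ctrl)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            re <- lme4::ranef(fit)
            adj <- 0
            for (f in factors)
                adj <- adj + re[[f]][as.character(df[[f]]), 1L]
            out[i, ] <- a[i, ] - adj
            v <- as.data.frame(lme4::VarCorr(fit))
            vc[i, factors] <- v$vcov[match(factors, v$grp)]
            vc[i, "residual"] <- v$vcov[v$grp == "Residual"]
        } else {
            # sequential one-factor-at-a-time fallback
            nFallback <- nFallback + 1L
            y <- a[i, ]
            for (f in factors) {
                f1 <- tryCatch(
                    suppressMessages(lme4::lmer(
                        stats::as.formula(sprintf("y ~ 1 + (1 | %s)", f)),
                        data = transform(df, y = y), REML = TRUE,
                        control = ctrl)),
                    error = function(e) NULL)
                if (is.null(f1)) next
                y <- y - lme4::ranef(f1)[[f]][as.character(df[[f]]), 1L]
            }
            out[i, ] <- y
        }
    }
    if (nFallback)
        warning(sprintf(
            "joint mixed model failed for %d feature(s); sequential one-factor fits used",
            nFallback))
    res <- setIntensities(m, out)
    metadata(res)$denoise <- vc
    res
}
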