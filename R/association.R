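#' @importFrom stats pnorm pt optim model.matrix complete.cases
NULL

# ---------------------------------------------------------------------------
# Internal machinery for the repeated-measures multivariate-normal (GLS) fit
#
# Model per feature: the vector of a participant's (up to) six occasion
# values is MVN(X beta, Sigma) with Sigma = D R D shared across
# participants; R unstructured 6x6 correlation, D occasion-specific SDs.
# Estimation is REML: beta is profiled out by GLS and Sigma maximizes the
# restricted likelihood. Participants with missing occasions contribute
# their observed sub-vector with the corresponding sub-covariance.
# ---------------------------------------------------------------------------

# Group participants by missingness pattern and precompute the per-pattern
# cross-product arrays so each REML iteration costs a handful of 6x6 and
# q x q operations regardless of the number of participants.
mvnPrep <- function(y, X, participant, occasion) {
    occ <- as.integer(occasion)
    nOcc <- nlevels(occasion)
    pid <- factor(participant)
    N <- nlevels(pid)
    q <- ncol(X)
    Yw <- matrix(NA_real_, N, nOcc)
    Xw <- array(NA_real_, c(N, nOcc, q))
    idx <- cbind(as.integer(pid), occ)
    Yw[idx] <- y
    for (k in seq_len(q))
        Xw[cbind(idx, k)] <- X[, k]
    obsPat <- !is.na(Yw)
    key <- apply(obsPat, 1L, paste, collapse = "")
    patterns <- lapply(split(seq_len(N), key), function(ids) {
        o <- which(obsPat[ids[1L], ])
        Xs <- lapply(o, function(s) Xw[ids, s, , drop = FALSE][, 1L, ])
        if (length(ids) == 1L) Xs <- lapply(Xs, function(m) matrix(m, 1L))
        names(Xs) <- o
        C <- lapply(seq_along(o), function(a)
            lapply(seq_along(o), function(b) crossprod(Xs[[a]], Xs[[b]])))
        Y <- Yw[ids, o, drop = FALSE]
        d <- lapply(seq_along(o), function(a)
            lapply(seq_along(o), function(b) crossprod(Xs[[a]], Y[, b])))
        list(ids = ids, o = o, n = length(ids), Y = Y, Xs = Xs, C = C,
             d = d)
    })
    list(patterns = patterns, N = N, nOcc = nOcc, q = q,
         nObs = sum(obsPat), colnamesX = colnames(X), idx = idx)
}

# swap in a new response sharing the same missingness pattern and design
# (used when testing many features against one exposure): only the
# response-side cross-products change.
mvnUpdateY <- function(prep, y) {
    Yw <- matrix(NA_real_, prep$N, prep$nOcc)
    Yw[prep$idx] <- y
    prep$patterns <- lapply(prep$patterns, function(pp) {
        pp$Y <- Yw[pp$ids, pp$o, drop = FALSE]
        pp$d <- lapply(seq_along(pp$o), function(a)
            lapply(seq_along(pp$o), function(b)
                crossprod(pp$Xs[[a]], pp$Y[, b])))
        pp
    })
    prep
}

# Evaluate the restricted log-likelihood at a fixed Sigma, profiling beta
# by GLS; optionally return the EM-update matrix T (expected residual
# cross-products plus the beta-uncertainty correction) so the caller can
# set Sigma <- T / N.
remlEval <- function(prep, Sigma, wantT = FALSE) {
    q <- prep$q
    A <- matrix(0, q, q)
    b <- numeric(q)
    pats <- prep$patterns
    cache <- vector("list", length(pats))
    for (g in seq_along(pats)) {
        pp <- pats[[g]]
        V <- Sigma[pp$o, pp$o, drop = FALSE]
        ch <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(ch)) return(NULL)
        Vinv <- chol2inv(ch)
        logdetV <- 2 * sum(log(diag(ch)))
        for (a in seq_along(pp$o)) for (bb in seq_along(pp$o)) {
            w <- Vinv[a, bb]
            if (w == 0) next
            A <- A + w * pp$C[[a]][[bb]]
            b <- b + w * pp$d[[a]][[bb]]
        }
        cache[[g]] <- list(Vinv = Vinv, logdetV = logdetV)
    }
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(NULL)
    Ainv <- chol2inv(chA)
    beta <- drop(Ainv %*% b)
    rll <- -sum(log(diag(chA)))      # -0.5 * logdet(A)
    Tm <- if (wantT) matrix(0, prep$nOcc, prep$nOcc) else NULL
    for (g in seq_along(pats)) {
        pp <- pats[[g]]
        Vinv <- cache[[g]]$Vinv
        R <- pp$Y
        for (a in seq_along(pp$o))
            R[, a] <- R[, a] - drop(pp$Xs[[a]] %*% beta)
        M <- crossprod(R)
        rll <- rll - 0.5 * (pp$n * cache[[g]]$logdetV + sum(Vinv * M))
        if (wantT) {
            o <- pp$o
            B <- matrix(0, length(o), length(o))
            for (a in seq_along(o)) for (bb in seq_along(o))
                B[a, bb] <- sum(Ainv * pp$C[[a]][[bb]])
            Tm[o, o] <- Tm[o, o] + M + B
            mm <- setdiff(seq_len(prep$nOcc), o)
            if (length(mm)) {
                P <- Sigma[mm, o, drop = FALSE] %*% Vinv
                Rm <- R %*% t(P)
                fill <- Sigma[mm, mm, drop = FALSE] -
                    P %*% Sigma[o, mm, drop = FALSE]
                Tm[mm, mm] <- Tm[mm, mm] + crossprod(Rm) + pp$n * fill
                Tm[mm, o] <- Tm[mm, o] + crossprod(Rm, R)
                Tm[o, mm] <- t(Tm[mm, o, drop = FALSE])
            }
        }
    }
    list(beta = beta, Ainv = Ainv, rll = rll, T = Tm)
}

csSigma <- function(logs2, z, nOcc, lower = -1 / (6 - 1) + 0.01) {
    rho <- lower + (1 - lower) * stats::plogis(z)
    s2 <- exp(logs2)
    s2 * ((1 - rho) * diag(nOcc) + rho)
}

fitCovCS <- function(prep, init = c(0, 0)) {
    obj <- function(par) {
        e <- remlEval(prep, csSigma(par[1L], par[2L], prep$nOcc))
        if (is.null(e)) return(1e10)
        -e$rll
    }
    opt <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    Sigma <- csSigma(opt$par[1L], opt$par[2L], prep$nOcc)
    list(Sigma = Sigma, eval = remlEval(prep, Sigma), model = "compoundSymmetry")
}

fitCovUnstructured <- function(prep, Sigma0, tol = 1e-8, maxit = 500) {
    Sigma <- Sigma0
    best <- NULL
    rllOld <- -Inf
    for (it in seq_len(maxit)) {
        e <- remlEval(prep, Sigma, wantT = TRUE)
        if (is.null(e)) return(NULL)
        if (is.null(best) || e$rll >= best$eval$rll)
            best <- list(Sigma = Sigma, eval = e)
        if (is.finite(rllOld) && abs(e$rll - rllOld) < tol) break
        rllOld <- e$rll
        Sigma <- (e$T + t(e$T)) / (2 * prep$N)   # symmetrize vs roundoff
        diag(Sigma) <- pmax(diag(Sigma), 1e-10)
    }
    best$model <- "unstructured"
    best$iterations <- it
    best$converged <- it < maxit
    best
}

# ---------------------------------------------------------------------------
# Public fitting interface
# ---------------------------------------------------------------------------

#' Repeated-measures multivariate-normal association test for one feature
#'
#' Fits, by restricted maximum likelihood, the model in which a
#' participant's six occasion values (site x time point) are multivariate
#' normal with mean `X beta` — intercept, exposure, and the adjustment
#' covariates — and a shared unstructured 6 x 6 covariance (free
#' correlation matrix, occasion-specific variances). Individuals thereby
#' act as their own controls: the within-person covariance carries the
#' crossover contrast. The exposure coefficient is tested by a Wald
#' statistic against the standard-normal reference (a t reference with
#' residual degrees of freedom is available).
#'
#' @param y numeric feature values, one per sample (profile).
#' @param meta sample metadata (rows aligned with `y`): `participant`,
#'   `occasion` (factor, 6 levels = site x time), `post`, plus covariates.
#' @param exposure numeric exposure per sample (visit-level value repeated
#'   over the visit's occasions).
#' @param covariates adjustment columns of `meta`; defaults to age, sex,
#'   health group and BMI (columns absent from `meta` are skipped).
#' @param effectMode `"main"` tests the visit-level exposure main effect
#'   (default); `"postInteraction"` adds an exposure x post-walk term and
#'   tests it.
#' @param covStruct `"unstructured"` (default) or `"compoundSymmetry"`.
#' @param reference `"normal"` (default) or `"t"` for the Wald p-value.
#' @param tol REML convergence tolerance on the restricted log-likelihood.
#' @param maxit maximum REML iterations.
#' @return list: `beta`, `se`, `stat`, `p` for the tested exposure
#'   coefficient; `coefficients` (all fixed effects), `Sigma`, `R`
#'   (correlation), `D` (occasion SDs), `logLikREML`, `model`,
#'   `converged`, `nParticipants`.
#' @examples
#' d <- generateDesign(12, seed = 3)
#' ex <- generateExposures(d, seed = 3)
#' x <- ex$NO2[match(paste(d$participant, d$visit),
#'                   paste(ex$participant, ex$visit))]
#' y <- rnorm(nrow(d)) + 0.02 * x
#' fitMvnFeature(y, d, x)$p
#' @export
fitMvnFeature <- function(y, meta, exposure,
                          covariates = c("age", "sex", "group", "bmi"),
                          effectMode = c("main", "postInteraction"),
                          covStruct = c("unstructured", "compoundSymmetry"),
                          reference = c("normal", "t"),
                          tol = 1e-8, maxit = 500) {
    effectMode <- match.arg(effectMode)
    covStruct <- match.arg(covStruct)
    reference <- match.arg(reference)
    meta <- as.data.frame(meta)
    if (!"occasion" %in% colnames(meta))
        meta$occasion <- factor(paste(meta$site, meta$time, sep = ":"))
    stopifnot(length(y) == nrow(meta), length(exposure) == nrow(meta))
    if (sd(exposure) < 1e-12)
        stop("identifiability error: exposure is constant")
    keep <- !is.na(y) & !is.na(exposure)
    y <- y[keep]; meta <- meta[keep, , drop = FALSE]
    exposure <- exposure[keep]
    nPart <- length(unique(meta$participant))
    if (nPart < 10)
        warning("fewer than 10 participants; estimates will be unstable")

    covariates <- intersect(covariates, colnames(meta))
    df <- meta[, covariates, drop = FALSE]
    df$exposure <- exposure
    form <- if (effectMode == "postInteraction") {
        df$post <- as.logical(meta$post)
        ~ exposure + exposure:post + .
    } else ~ exposure + .
    X <- model.matrix(form, data = df)
    if (qr(X)$rank < ncol(X))
        stop("identifiability error: singular design matrix")
    target <- if (effectMode == "postInteraction")
        grep("^exposure:", colnames(X), value = TRUE)[1L] else "exposure"

    prep <- mvnPrep(y, X, meta$participant, droplevels(factor(meta$occasion)))
    fitMvnCore(prep, y, X, target, covStruct, reference, tol, maxit, nPart)
}

# shared back-end: REML fit + Wald test given a prepared design
fitMvnCore <- function(prep, y, X, target, covStruct, reference, tol,
                       maxit, nPart) {
    ols <- lm.fit(X, y)   # moment start: OLS residual variance on the diagonal
    s2 <- sum(ols$residuals^2) / max(length(y) - ncol(X), 1L)
    Sigma0 <- diag(rep(s2, prep$nOcc))

    downgraded <- FALSE
    if (covStruct == "compoundSymmetry") {
        fit <- fitCovCS(prep, init = c(log(s2), 0))
    } else {
        fit <- fitCovUnstructured(prep, Sigma0, tol = tol, maxit = maxit)
        if (is.null(fit)) # multiple starts: restart from an inflated diagonal
            fit <- fitCovUnstructured(prep, Sigma0 * 4, tol = tol,
                                      maxit = maxit)
        if (is.null(fit)) {
            fit <- fitCovCS(prep, init = c(log(s2), 0))
            downgraded <- TRUE
        }
    }
    e <- fit$eval
    beta <- setNames(e$beta, prep$colnamesX)
    se <- sqrt(diag(e$Ainv))
    names(se) <- prep$colnamesX
    stat <- beta[[target]] / se[[target]]
    p <- if (reference == "t")
        2 * pt(-abs(stat), df = prep$nObs - prep$q)
    else 2 * pnorm(-abs(stat))
    D <- sqrt(diag(fit$Sigma))
    list(beta = beta[[target]], se = se[[target]], stat = stat,
         p = max(p, .Machine$double.xmin),
         coefficients = beta, se.all = se, vcov = e$Ainv,
         Sigma = fit$Sigma, R = fit$Sigma / tcrossprod(D), D = D,
         logLikREML = e$rll, model = fit$model, downgraded = downgraded,
         converged = isTRUE(fit$converged) || fit$model == "compoundSymmetry",
         nParticipants = nPart)
}

#' Effective number of tests from principal components
#'
#' The effective number of tests (ENT) is the smallest number of principal
#' components of the standardized feature matrix explaining strictly more
#' than `varThreshold` of total variance — a spectral alternative to
#' permutation-based ENT, used as the Bonferroni denominator.
#'
#' @param m an imputed [OmicsSet-class] (features x samples) or a numeric
#'   matrix in the same orientation.
#' @param varThreshold variance fraction to exceed (default 0.99).
#' @return integer ENT.
#' @examples
#' sig <- matrix(rnorm(60), 20, 3)
#' effectiveNumberOfTests(t(sig[, c(1, 1, 2, 2, 3, 3)]))  # rank 3 -> 3
#' @export
effectiveNumberOfTests <- function(m, varThreshold = 0.99) {
    a <- if (is(m, "OmicsSet")) intensities(m) else as.matrix(m)
    if (anyNA(a)) stop("effectiveNumberOfTests expects a complete matrix")
    v <- apply(a, 1L, var)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance feature(s) dropped before PCA")
        a <- a[v > 0, , drop = FALSE]
    }
    x <- t(scale(t(a)))            # standardize features
    x <- scale(t(x), scale = FALSE) # center over samples for the PCA
    d2 <- svd(x, nu = 0, nv = 0)$d^2
    cum <- cumsum(d2) / sum(d2)
    as.integer(which(cum > varThreshold)[1L])
}

#' Flag significance under ENT-based and full Bonferroni corrections
#'
#' Per-test level is `fwer / ent` for the ENT flag and `fwer / nFeatures`
#' for the full flag (strict inequality); the full correction is at least
#' as stringent since `ent <= nFeatures`.
#'
#' @param results an [AssociationResults-class] or a data.frame with a `p`
#'   column.
#' @param ent effective number of tests (>= 1).
#' @param nFeatures total number of features tested (defaults to the
#'   distinct features in `results`).
#' @param fwer target family-wise error rate (default 0.05).
#' @return the input with `significantENT` / `significantFull` columns set.
#' @export
applyCorrections <- function(results, ent, nFeatures = NULL, fwer = 0.05) {
    if (ent < 1) stop("invalid: ent must be >= 1")
    tab <- if (is(results, "AssociationResults")) results@table
           else DataFrame(results)
    if (is.null(nFeatures)) nFeatures <- length(unique(tab$feature))
    if (ent > nFeatures) stop("invalid: ent exceeds the number of features")
    tab$significantENT <- tab$p < fwer / ent
    tab$significantFull <- tab$p < fwer / nFeatures
    if (is(results, "AssociationResults")) {
        initialize(results, table = tab, ent = as.integer(ent),
                   nFeatures = as.integer(nFeatures), fwer = fwer)
    } else {
        new("AssociationResults", table = tab, ent = as.integer(ent),
            nFeatures = as.integer(nFeatures), fwer = fwer)
    }
}

#' Association tests for every feature and exposure
#'
#' Runs [fitMvnFeature()] per (feature, exposure) pair, computes the ENT on
#' the tested matrix and applies both Bonferroni corrections.
#'
#' @param m an imputed, denoised [OmicsSet-class]; `colData` must carry the
#'   design (participant, occasion, post, covariates).
#' @param exposures per-visit exposure table from [generateExposures()] (or
#'   any data.frame with `participant`, `visit` and pollutant columns).
#' @param pollutants exposure columns to test (default: all five TRAP
#'   pollutants present).
#' @param covariates,effectMode,reference passed to [fitMvnFeature()].
#' @param ent effective number of tests; computed from `m` when `NULL`.
#' @param fwer family-wise error rate for both corrections.
#' @param varThreshold passed to [effectiveNumberOfTests()].
#' @return an [AssociationResults-class].
#' @export
associateExposures <- function(m, exposures,
                               pollutants = intersect(
                                   c("PM10", "PM2.5", "NO2", "BC", "PCNT"),
                                   colnames(exposures)),
                               covariates = c("age", "sex", "group", "bmi"),
                               effectMode = "main", reference = "normal",
                               ent = NULL, fwer = 0.05,
                               varThreshold = 0.99) {
    a <- intensities(m)
    meta <- colData(m)
    key <- paste(meta$participant, meta$visit)
    ekey <- paste(exposures$participant, exposures$visit)
    if (is.null(ent)) ent <- effectiveNumberOfTests(m, varThreshold)
    meta <- as.data.frame(meta)
    if (!"occasion" %in% colnames(meta))
        meta$occasion <- factor(paste(meta$site, meta$time, sep = ":"))
    complete <- !anyNA(a)
    covs <- intersect(covariates, colnames(meta))
    rows <- vector("list", nrow(a) * length(pollutants))
    k <- 0L
    for (pol in pollutants) {
        x <- exposures[[pol]][match(key, ekey)]
        prep <- NULL
        if (complete && !anyNA(x)) {
            # design and missingness pattern are shared: prepare once and
            # swap the response per feature
            df <- meta[, covs, drop = FALSE]
            df$exposure <- x
            form <- if (effectMode == "postInteraction") {
                df$post <- as.logical(meta$post)
                ~ exposure + exposure:post + .
            } else ~ exposure + .
            X <- model.matrix(form, data = df)
            target <- if (effectMode == "postInteraction")
                grep("^exposure:", colnames(X), value = TRUE)[1L]
            else "exposure"
            if (qr(X)$rank == ncol(X))
                prep <- mvnPrep(a[1L, ], X, meta$participant,
                                droplevels(factor(meta$occasion)))
        }
        for (i in seq_len(nrow(a))) {
            fit <- if (!is.null(prep))
                fitMvnCore(mvnUpdateY(prep, a[i, ]), a[i, ], X, target,
                           "unstructured", reference, 1e-8, 500,
                           length(unique(meta$participant)))
            else fitMvnFeature(a[i, ], meta, x, covariates = covariates,
                               effectMode = effectMode,
                               reference = reference)
            k <- k + 1L
            rows[[k]] <- data.frame(feature = rownames(a)[i], exposure = pol,
                                    beta = fit$beta, se = fit$se,
                                    stat = fit$stat, p = fit$p,
                                    model = fit$model,
                                    stringsAsFactors = FALSE)
        }
    }
    tab <- do.call(rbind, rows)
    applyCorrections(tab, ent = ent, nFeatures = nrow(a), fwer = fwer)
}

#' Summarize significant features across exposures
#'
#' Upset-style breakdown: per-exposure significant counts, counts per
#' exposure combination (exclusive patterns), and the number of unique
#' features significant for at least one exposure.
#'
#' @param results an [AssociationResults-class].
#' @param flag which correction to summarize: `"ENT"` (default) or
#'   `"full"`.
#' @return list with `perExposure` (named counts), `combinations`
#'   (data.frame of exclusive patterns), `uniqueSignificant`, and
#'   `exclusive` / `shared` unique-feature counts.
#' @export
associationSummary <- function(results, flag = c("ENT", "full")) {
    flag <- match.arg(flag)
    tab <- as.data.frame(results@table)
    sigCol <- if (flag == "ENT") "significantENT" else "significantFull"
    if (!sigCol %in% colnames(tab))
        stop("apply corrections before summarizing")
    exposures <- sort(unique(tab$exposure))
    sig <- tab[tab[[sigCol]], , drop = FALSE]
    perExposure <- vapply(exposures, function(e)
        length(unique(sig$feature[sig$exposure == e])), 0L)
    pat <- vapply(split(sig$exposure, sig$feature), function(e)
        paste(sort(unique(e)), collapse = "+"), "")
    comb <- if (length(pat)) {
        tb <- table(pat)
        data.frame(pattern = names(tb), nFeatures = as.integer(tb),
                   stringsAsFactors = FALSE)
    } else data.frame(pattern = character(), nFeatures = integer(),
                      stringsAsFactors = FALSE)
    comb <- comb[order(-comb$nFeatures), , drop = FALSE]
    rownames(comb) <- NULL
    nUnique <- length(unique(sig$feature))
    nExclusive <- sum(comb$nFeatures[!grepl("\\+", comb$pattern)])
    list(perExposure = perExposure, combinations = comb,
         uniqueSignificant = nUnique, exclusive = nExclusive,
         shared = nUnique - nExclusive)
}
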