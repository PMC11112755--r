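#' @importFrom stats rnorm runif rbinom quantile setNames
NULL

# ---------------------------------------------------------------------------
# Design
# ---------------------------------------------------------------------------

#' Simulate the sample sheet of a two-site crossover exposure study
#'
#' Each participant walks once at each of two sites (visit order randomized
#' per participant) and gives a blood sample at three occasions per visit:
#' 2 h before, 2 h after and 24 h after the walk — six profiles per
#' participant. Demographics (age, sex, BMI) and a three-level health group
#' are drawn per participant; two crossed technical factors (plate, box) are
#' assigned round-robin over samples.
#'
#' @param nParticipants number of participants (default 50, giving 300
#'   profiles).
#' @param groupProportions named fractions per health group; must sum to 1.
#'   Default 18/50, 18/50, 14/50 for Healthy/COPD/IHD.
#' @param sites ordered pair of site labels; the first is the high-exposure
#'   site.
#' @param timePoints ordered triple of occasion labels.
#' @param nPlates,nBoxes numbers of levels of the two technical factors.
#' @param ageMean,ageSd,maleFraction,bmiMean,bmiSd demographic distributions.
#' @param seed integer seed fixing all randomness.
#' @return A [S4Vectors::DataFrame] with one row per profile: `sample`,
#'   `participant`, `visit`, `site`, `time`, `occasion`, `post`, `plate`,
#'   `box`, `age`, `sex`, `group`, `bmi`.
#' @examples
#' d <- generateDesign(5, seed = 1)
#' nrow(d)  # 30 profiles
#' @export
generateDesign <- function(nParticipants = 50,
                           groupProportions = c(Healthy = 0.36, COPD = 0.36,
                                                IHD = 0.28),
                           sites = c("A", "B"),
                           timePoints = c("pre", "post2h", "post24h"),
                           nPlates = 4, nBoxes = 7,
                           ageMean = 65.5, ageSd = 6,
                           maleFraction = 0.64,
                           bmiMean = 27, bmiSd = 4,
                           seed = 1) {
    if (nParticipants < 1)
        stop("invalid config: nParticipants must be >= 1")
    if (abs(sum(groupProportions) - 1) > 1e-8)
        stop("invalid config: group proportions must sum to 1")
    if (length(sites) != 2L || length(timePoints) != 3L)
        stop("invalid config: exactly 2 sites and 3 time points required")
    set.seed(stageSeed(seed, "design"))
    pid <- sprintf("P%03d", seq_len(nParticipants))
    firstSite <- ifelse(rbinom(nParticipants, 1L, 0.5) == 1L,
                        sites[1L], sites[2L])
    age <- rnorm(nParticipants, ageMean, ageSd)
    sex <- ifelse(runif(nParticipants) < maleFraction, "male", "female")
    bmi <- rnorm(nParticipants, bmiMean, bmiSd)
    grp <- sample(names(groupProportions), nParticipants, replace = TRUE,
                  prob = groupProportions)
    rows <- expand.grid(time = timePoints, visit = 1:2, participant = pid,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[, c("participant", "visit", "time")]
    i <- match(rows$participant, pid)
    rows$site <- ifelse(rows$visit == 1L, firstSite[i],
                        ifelse(firstSite[i] == sites[1L], sites[2L],
                               sites[1L]))
    n <- nrow(rows)
    rows$sample <- sprintf("%s_v%d_%s", rows$participant, rows$visit,
                           rows$time)
    rows$occasion <- factor(paste(rows$site, rows$time, sep = ":"),
                            levels = as.vector(outer(timePoints, sites,
                                function(t, s) paste(s, t, sep = ":"))))
    rows$post <- rows$time != timePoints[1L]
    rows$plate <- factor(sprintf("plate%d", (seq_len(n) - 1L) %% nPlates + 1L))
    rows$box <- factor(sprintf("box%d", (seq_len(n) - 1L) %% nBoxes + 1L))
    rows$age <- age[i]
    rows$sex <- factor(sex[i], levels = c("female", "male"))
    rows$group <- factor(grp[i], levels = names(groupProportions))
    rows$bmi <- bmi[i]
    out <- DataFrame(rows[, c("sample", "participant", "visit", "site",
                              "time", "occasion", "post", "plate", "box",
                              "age", "sex", "group", "bmi")])
    rownames(out) <- rows$sample
    metadata(out) <- list(sites = sites, timePoints = timePoints, seed = seed)
    out
}

# ---------------------------------------------------------------------------
# Exposures
# ---------------------------------------------------------------------------

#' Default exposure model: five TRAP pollutants, site-specific means
#'
#' Means and between-visit SDs for PM10, PM2.5, NO2, black carbon and
#' ultrafine particle counts; the high-exposure site mean strictly exceeds
#' the low-exposure site mean for every pollutant.
#'
#' @param pollutants pollutant names.
#' @param meanHigh,meanLow site-specific means (high-exposure site first
#'   element of the design's `sites`).
#' @param sd within-site, between-visit noise SD per pollutant.
#' @return a data.frame with one row per pollutant.
#' @export
exposureModel <- function(pollutants = c("PM10", "PM2.5", "NO2", "BC",
                                         "PCNT"),
                          meanHigh = c(70, 30, 90, 12, 35000),
                          meanLow = c(30, 15, 35, 2, 12000),
                          sd = c(15, 6, 18, 2, 6000)) {
    if (any(sd < 0)) stop("invalid config: negative exposure SD")
    if (any(meanHigh <= meanLow))
        stop("invalid config: high-site mean must exceed low-site mean")
    data.frame(pollutant = pollutants, meanHigh = meanHigh,
               meanLow = meanLow, sd = sd, stringsAsFactors = FALSE)
}

#' Simulate per-visit pollutant exposures
#'
#' One exposure value per (participant, visit) and pollutant, drawn from the
#' site mean plus visit-level Gaussian noise and floored at zero; the value
#' is constant across the three occasions of the visit (the walk is the
#' exposure event).
#'
#' @param design sample sheet from [generateDesign()].
#' @param model exposure model from [exposureModel()].
#' @param seed integer seed.
#' @return data.frame with `participant`, `visit`, `site` and one column per
#'   pollutant.
#' @export
generateExposures <- function(design, model = exposureModel(), seed = 1) {
    if (any(model$sd < 0)) stop("invalid config: negative exposure SD")
    sites <- metadata(design)$sites
    if (is.null(sites)) sites <- unique(design$site)
    visits <- unique(as.data.frame(design[, c("participant", "visit",
                                              "site")]))
    visits <- visits[order(visits$participant, visits$visit), ]
    rownames(visits) <- NULL
    set.seed(stageSeed(seed, "exposures"))
    for (k in seq_len(nrow(model))) {
        mu <- ifelse(visits$site == sites[1L], model$meanHigh[k],
                     model$meanLow[k])
        visits[[model$pollutant[k]]] <-
            pmax(0, mu + rnorm(nrow(visits), 0, model$sd[k]))
    }
    visits
}

# ---------------------------------------------------------------------------
# Precision matrix (ground truth for network recovery)
# ---------------------------------------------------------------------------

#' Simulate a sparse symmetric positive-definite precision matrix
#'
#' Ground truth for conditional-independence network recovery: edges are
#' drawn independently with the given density, off-diagonal entries get a
#' random sign and a magnitude uniform in `magnitudeRange`, and the diagonal
#' is set to the row-wise absolute sum plus `margin` (diagonal dominance,
#' hence positive definite). Zero off-diagonals are exactly off the drawn
#' support.
#'
#' @param p dimension (>= 2).
#' @param density edge probability in \[0, 1\].
#' @param magnitudeRange range of absolute off-diagonal values.
#' @param margin diagonal dominance margin (> 0).
#' @param seed integer seed.
#' @param maxTries retries if a draw fails the positive-definiteness check.
#' @return list with `precision` (p x p matrix), `edges` (2-column index
#'   matrix, rows j < k) and `support` (logical p x p).
#' @export
generatePrecisionMatrix <- function(p, density = 0.1,
                                    magnitudeRange = c(0.2, 0.4),
                                    margin = 0.1, seed = 1,
                                    maxTries = 10) {
    if (p < 2) stop("invalid config: p must be >= 2")
    if (density < 0 || density > 1)
        stop("invalid config: density must lie in [0, 1]")
    if (margin <= 0) stop("invalid config: margin must be positive")
    set.seed(stageSeed(seed, "precision"))
    nPairs <- p * (p - 1L) / 2L
    for (try in seq_len(maxTries)) {
        on <- runif(nPairs) < density
        val <- numeric(nPairs)
        val[on] <- runif(sum(on), magnitudeRange[1L], magnitudeRange[2L]) *
            sample(c(-1, 1), sum(on), replace = TRUE)
        theta <- symFromUpper(val, p)
        diag(theta) <- rowSums(abs(theta)) + margin
        if (min(eigen(theta, symmetric = TRUE,
                      only.values = TRUE)$values) > 0) {
            support <- theta != 0
            diag(support) <- FALSE
            edges <- which(upper.tri(theta) & support, arr.ind = TRUE)
            colnames(edges) <- c("j", "k")
            return(list(precision = theta, edges = edges, support = support))
        }
    }
    stop("precision generation failed: could not reach positive definiteness")
}

# ---------------------------------------------------------------------------
# Effects and omics intensities
# ---------------------------------------------------------------------------

#' Specify sparse exposure effects on features
#'
#' @param features integer indices of affected features.
#' @param beta effect per unit exposure on the log2 scale (scalar or one per
#'   affected feature).
#' @param pollutant name of the driving pollutant.
#' @param mode `"post"` (effect enters on the two post-walk occasions only,
#'   the default — the within-person contrast the repeated-measures model
#'   exploits) or `"all"` (visit-level main effect on all three occasions).
#' @return list of class `effectSpec`.
#' @export
effectSpec <- function(features = integer(), beta = 0.01,
                       pollutant = "NO2", mode = c("post", "all")) {
    mode <- match.arg(mode)
    if (any(!is.finite(beta))) stop("invalid config: beta must be finite")
    beta <- rep_len(beta, length(features))
    structure(list(features = as.integer(features), beta = beta,
                   pollutant = pollutant, mode = mode),
              class = "effectSpec")
}

#' Simulate a feature-by-sample intensity matrix for the crossover design
#'
#' Per profile, a feature vector is drawn from a multivariate normal on the
#' log2 scale with covariance equal to the inverse of the supplied precision
#' matrix; a per-(participant, feature) random intercept induces
#' within-person correlation across the six occasions; exposure effects are
#' added per [effectSpec()]; additive (log2-scale) batch offsets are drawn
#' per feature and technical-factor level; finally the lowest
#' `censorFraction` quantile of each feature is set missing (left-censored,
#' missing-not-at-random) and intensities are returned on the raw scale
#' (2^log2).
#'
#' @param design sample sheet from [generateDesign()].
#' @param exposures per-visit exposure table from [generateExposures()].
#' @param precision output of [generatePrecisionMatrix()] (or a precision
#'   matrix).
#' @param effects an [effectSpec()]; empty by default.
#' @param batchSd SD of the additive batch offsets (log2 units) for each of
#'   the two technical factors.
#' @param censorFraction fraction of each feature's values censored, in
#'   \[0, 0.5\].
#' @param participantSd SD of the per-participant random intercept.
#' @param baselineRange range of per-feature baseline means (log2 units).
#' @param groupEffects optional named additive offsets per health group
#'   (default all zero).
#' @param seed integer seed.
#' @return an [OmicsSet-class] on the raw scale with `mz` and `rt` feature
#'   metadata; `metadata()` holds the latent (uncensored, log2) matrix, the
#'   censoring mask and the drawn batch offsets for testing.
#' @export
generateOmics <- function(design, exposures, precision,
                          effects = effectSpec(),
                          batchSd = 0.3, censorFraction = 0.1,
                          participantSd = 0.5,
                          baselineRange = c(8, 16),
                          groupEffects = NULL, seed = 1) {
    if (censorFraction < 0 || censorFraction > 0.5)
        stop("invalid config: censorFraction must lie in [0, 0.5]")
    if (batchSd < 0) stop("invalid config: batchSd must be >= 0")
    theta <- if (is.list(precision)) precision$precision else precision
    p <- nrow(theta)
    n <- nrow(design)
    if (length(effects$features) && max(effects$features) > p)
        stop("dimension error: affected feature index exceeds feature count")
    key <- paste(design$participant, design$visit)
    ekey <- paste(exposures$participant, exposures$visit)
    if (!all(key %in% ekey))
        stop("dimension error: design visits missing from exposure table")
    set.seed(stageSeed(seed, "omics"))

    sigma <- solve(theta)
    cholS <- chol(sigma)
    latent <- t(matrix(rnorm(n * p), n, p) %*% cholS)  # p x n, MVN(0, sigma)
    baseline <- runif(p, baselineRange[1L], baselineRange[2L])
    latent <- latent + baseline

    pid <- unique(design$participant)
    ranef <- matrix(rnorm(p * length(pid), 0, participantSd), p,
                    dimnames = list(NULL, pid))
    latent <- latent + ranef[, match(design$participant, pid)]

    if (!is.null(groupEffects)) {
        ge <- groupEffects[as.character(design$group)]
        ge[is.na(ge)] <- 0
        latent <- latent + rep(ge, each = p)
    }

    if (length(effects$features)) {
        x <- exposures[[effects$pollutant]][match(key, ekey)]
        w <- if (effects$mode == "post") as.numeric(design$post) else 1
        for (a in seq_along(effects$features))
            latent[effects$features[a], ] <-
                latent[effects$features[a], ] + effects$beta[a] * x * w
    }

    batch <- list()
    for (f in c("plate", "box")) {
        lev <- levels(design[[f]])
        off <- matrix(rnorm(p * length(lev), 0, batchSd), p,
                      dimnames = list(NULL, lev))
        latent <- latent + off[, as.integer(design[[f]])]
        batch[[f]] <- off
    }

    censored <- matrix(FALSE, p, n)
    if (censorFraction > 0) {
        thr <- apply(latent, 1L, quantile, probs = censorFraction,
                     names = FALSE)
        censored <- latent < thr
    }
    raw <- 2^latent
    raw[censored] <- NA_real_

    fid <- sprintf("F%04d", seq_len(p))
    dimnames(raw) <- list(fid, design$sample)
    featureMeta <- DataFrame(mz = runif(p, 80, 1000),
                             rt = runif(p, 0.5, 12), row.names = fid)
    os <- OmicsSet(raw, rowData = featureMeta, colData = design,
                   scale = "raw")
    metadata(os) <- list(latent = `dimnames<-`(latent, dimnames(raw)),
                         censored = censored, batch = batch,
                         effects = effects, seed = seed)
    os
}

# ---------------------------------------------------------------------------
# Whole-study convenience wrapper and writers
# ---------------------------------------------------------------------------

#' Simulate a complete synthetic crossover study
#'
#' Bundles [generateDesign()], [generateExposures()],
#' [generatePrecisionMatrix()], [effectSpec()] and [generateOmics()] under a
#' single seed, with defaults matching the emulated study: 50 participants,
#' 2 sites, 3 time points (300 profiles), five pollutants higher at one
#' site, features correlated through a sparse precision matrix, additive
#' batch effects on two crossed technical factors and 10% left-censoring.
#'
#' @param nParticipants participants (default 50).
#' @param nFeatures features in the main omic block (default 500).
#' @param edgeDensity density of the true conditional-independence graph.
#' @param nAffected number of features carrying a true exposure effect.
#' @param beta true effect size (log2 units per exposure unit).
#' @param pollutant the driving pollutant for true effects.
#' @param batchSd,censorFraction passed to [generateOmics()].
#' @param effectMode passed to [effectSpec()].
#' @param seed master seed; stage streams are derived from it.
#' @return list with `omics` ([OmicsSet-class]), `design`, `exposures`, and
#'   `truth` (affected features, true betas, true edge set, precision).
#' @examples
#' sim <- simulateStudy(nParticipants = 6, nFeatures = 20, seed = 1)
#' dim(intensities(sim$omics))
#' @export
simulateStudy <- function(nParticipants = 50, nFeatures = 500,
                          edgeDensity = 0.02, nAffected = 50,
                          beta = 0.01, pollutant = "NO2",
                          batchSd = 0.3, censorFraction = 0.1,
                          effectMode = "post", seed = 1) {
    design <- generateDesign(nParticipants, seed = seed)
    exposures <- generateExposures(design, seed = seed)
    prec <- generatePrecisionMatrix(nFeatures, density = edgeDensity,
                                    seed = seed)
    set.seed(stageSeed(seed, "effects"))
    affected <- sort(sample.int(nFeatures, min(nAffected, nFeatures)))
    eff <- effectSpec(affected, beta = beta, pollutant = pollutant,
                      mode = effectMode)
    omics <- generateOmics(design, exposures, prec, eff, batchSd = batchSd,
                           censorFraction = censorFraction, seed = seed)
    list(omics = omics, design = design, exposures = exposures,
         truth = list(affected = affected, beta = eff$beta,
                      pollutant = pollutant, edges = prec$edges,
                      support = prec$support, precision = prec$precision))
}

#' Write a simulated study to disk
#'
#' Emits the plain-text dialect shared with the preprocessing module:
#' `features.tsv` (rows = features, columns = sample IDs, blank cell =
#' missing), `samples.tsv`, `exposures.tsv` and `truth.json`.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- intensities(sim$omics)
    feat <- data.frame(feature = rownames(m),
                       as.data.frame(rowData(sim$omics)), m,
                       check.names = FALSE)
    writeTsv(feat, file.path(dir, "features.tsv"))
    writeTsv(as.data.frame(sim$design), file.path(dir, "samples.tsv"))
    writeTsv(sim$exposures, file.path(dir, "exposures.tsv"))
    jsonlite::write_json(list(affected = sim$truth$affected,
                              beta = sim$truth$beta,
                              pollutant = sim$truth$pollutant,
                              edges = as.data.frame(sim$truth$edges)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(dir)
}

#' Read a feature table written by [writeStudy()]
#'
#' @param dir directory holding `features.tsv` and `samples.tsv`.
#' @return an [OmicsSet-class] on the raw scale.
#' @export
readStudy <- function(dir) {
    feat <- utils::read.delim(file.path(dir, "features.tsv"),
                              check.names = FALSE)
    samp <- utils::read.delim(file.path(dir, "samples.tsv"))
    meta <- intersect(c("mz", "rt", "symbol"), colnames(feat))
    m <- as.matrix(feat[, setdiff(colnames(feat), c("feature", meta)),
                        drop = FALSE])
    rownames(m) <- feat$feature
    rownames(samp) <- samp$sample
    for (f in c("plate", "box", "occasion", "sex", "group"))
        if (f %in% colnames(samp)) samp[[f]] <- factor(samp[[f]])
    OmicsSet(m, rowData = feat[, meta, drop = FALSE],
             colData = samp[colnames(m), , drop = FALSE], scale = "raw")
}
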