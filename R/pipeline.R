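#' @importFrom utils modifyList write.table
NULL

#' Assemble a pipeline run configuration
#'
#' Returns the fully resolved configuration for [runPipeline()], with every
#' default explicit so the run manifest can record it. Any nested field can
#' be overridden by passing a list with the same shape.
#'
#' @param outDir output directory.
#' @param seed master seed; each stage derives its own stream from it, so
#'   toggling one stage does not perturb another's randomness.
#' @param overrides nested list overriding any default below.
#' @return the configuration list.
#' @export
runConfig <- function(outDir = tempfile("crossomix_run"), seed = 1,
                      overrides = list()) {
    cfg <- list(
        outDir = outDir,
        seed = seed,
        stages = c("simulate", "preprocess", "associate", "cluster",
                   "network", "enrich"),
        simulate = list(nParticipants = 50, nFeatures = 500, nMrna = 40,
                        edgeDensity = 0.02, nAffected = 50, beta = 0.01,
                        pollutant = "NO2", batchSd = 0.3,
                        censorFraction = 0.1, effectMode = "post"),
        preprocess = list(maxMissingFrac = 0.40, tuneSigma = 1,
                          nComponents = 3, madMultiplier = 5,
                          factors = c("plate", "box")),
        association = list(pollutants = c("PM10", "PM2.5", "NO2", "BC",
                                          "PCNT"),
                           covariates = c("age", "sex", "group", "bmi"),
                           effectMode = "main", fwer = 0.05,
                           varThreshold = 0.99),
        clustering = list(Ggrid = 2:10, nSubsamples = 100,
                          subsampleFrac = 0.8, maxClusterInput = 60),
        network = list(K = 100, frac = 0.8, nLambda = 15,
                       lambdaMinRatio = 0.05,
                       multiblockGridSize = 4,
                       timePoints = c("pre", "post2h", "post24h")),
        enrichment = list(tolPpm = 8, nPathways = 5,
                          annotatedFraction = 0.6,
                          thresholds = as.list(oraThresholds()))
    )
    utils::modifyList(cfg, overrides)
}

readRunConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    runConfig(overrides = cfg)
}

pipelineStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> preprocess -> associate -> cluster -> network
#' -> enrich under a single master seed, writing every stage's outputs as
#' TSV plus a `manifest.json` recording all resolved parameters, and a
#' `report.md` with the headline counts. Re-running with the same
#' configuration reproduces all outputs bit-identically. Stages can be
#' disabled through `cfg$stages` (e.g. dropping `"network"` leaves
#' association outputs only); a stage failure aborts with the stage name,
#' preserving the outputs already written.
#'
#' @param cfg configuration from [runConfig()] (or a path to a JSON file
#'   of overrides).
#' @return invisibly, a list with the output directory and the in-memory
#'   stage results.
#' @export
runPipeline <- function(cfg = runConfig()) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    res <- list(dir = cfg$outDir)
    on <- function(s) s %in% cfg$stages

    ## -- simulate ----------------------------------------------------------
    sim <- pipelineStage("simulate", {
        s <- do.call(simulateStudy, c(cfg$simulate[
            setdiff(names(cfg$simulate), "nMrna")], list(seed = cfg$seed)))
        writeStudy(s, cfg$outDir)
        s
    })
    mrna <- NULL
    if (cfg$simulate$nMrna >= 2) mrna <- pipelineStage("simulate", {
        precM <- generatePrecisionMatrix(cfg$simulate$nMrna, density = 0.05,
                                         seed = stageSeed(cfg$seed, "mrna"))
        set.seed(stageSeed(cfg$seed, "mrnaEffects"))
        affected <- sort(sample.int(cfg$simulate$nMrna,
                                    max(1L, cfg$simulate$nMrna %/% 5L)))
        eff <- effectSpec(affected, beta = cfg$simulate$beta,
                          pollutant = cfg$simulate$pollutant,
                          mode = cfg$simulate$effectMode)
        g <- generateOmics(sim$design, sim$exposures, precM, eff,
                           batchSd = cfg$simulate$batchSd,
                           censorFraction = 0,
                           seed = stageSeed(cfg$seed, "mrna"))
        rownames(g) <- sprintf("T%04d", seq_len(nrow(g)))
        rowData(g)$symbol <- sprintf("GENE%04d", seq_len(nrow(g)))
        g
    })
    res$sim <- sim

    ## -- preprocess --------------------------------------------------------
    prep <- function(os, label) {
        pc <- cfg$preprocess
        os <- filterMissingness(os, pc$maxMissingFrac)
        os <- log2Transform(os)
        os <- imputeQRILC(os, tuneSigma = pc$tuneSigma,
                          seed = stageSeed(cfg$seed, paste0("impute.", label)))
        flags <- flagPCAOutliers(os, pc$nComponents, pc$madMultiplier)
        os <- denoiseTechnical(os[, !flags], factors = pc$factors)
        metadata(os)$outliers <- names(flags)[flags]
        os
    }
    omics <- mrnaClean <- NULL
    if (on("preprocess")) {
        omics <- pipelineStage("preprocess", prep(sim$omics, "metab"))
        if (!is.null(mrna))
            mrnaClean <- pipelineStage("preprocess", prep(mrna, "mrna"))
        writeTsv(data.frame(feature = rownames(omics),
                            as.data.frame(rowData(omics)),
                            intensities(omics), check.names = FALSE),
                 file.path(cfg$outDir, "denoised.tsv"))
        res$omics <- omics
        res$mrna <- mrnaClean
    }

    ## -- associate ---------------------------------------------------------
    assoc <- assocM <- NULL
    if (on("associate") && !is.null(omics)) {
        ac <- cfg$association
        assoc <- pipelineStage("associate",
            associateExposures(omics, sim$exposures,
                               pollutants = ac$pollutants,
                               covariates = ac$covariates,
                               effectMode = ac$effectMode, fwer = ac$fwer,
                               varThreshold = ac$varThreshold))
        writeTsv(as.data.frame(assoc), file.path(cfg$outDir,
                                                 "associations.tsv"))
        rt <- rowData(omics)$rt
        man <- as.data.frame(assoc)
        man$rt <- rt[match(man$feature, rownames(omics))]
        man$mz <- rowData(omics)$mz[match(man$feature, rownames(omics))]
        writeTsv(man[order(man$rt), c("feature", "rt", "mz", "exposure",
                                      "beta", "p", "significantENT")],
                 file.path(cfg$outDir, "manhattan.tsv"))
        if (!is.null(mrnaClean))
            assocM <- pipelineStage("associate",
                associateExposures(mrnaClean, sim$exposures,
                                   pollutants = ac$pollutants,
                                   covariates = ac$covariates,
                                   effectMode = ac$effectMode,
                                   fwer = ac$fwer))
        res$assoc <- assoc
        res$assocMrna <- assocM
    }

    ## -- cluster -----------------------------------------------------------
    clus <- NULL
    if (on("cluster") && !is.null(assoc)) {
        cc <- cfg$clustering
        tab <- as.data.frame(assoc)
        sig <- unique(tab$feature[tab$significantENT])
        if (length(sig) < 3) {  # too few hits: cluster the strongest signals
            byp <- sort(vapply(split(tab$p, tab$feature), min, 0))
            sig <- names(byp)[seq_len(min(20L, length(byp)))]
        }
        if (length(sig) > cc$maxClusterInput) {
            byp <- vapply(split(tab$p[tab$feature %in% sig],
                                tab$feature[tab$feature %in% sig]), min, 0)
            sig <- names(sort(byp))[seq_len(cc$maxClusterInput)]
        }
        clus <- pipelineStage("cluster",
            consensusCluster(omics[sig, ], Ggrid = cc$Ggrid,
                             nSubsamples = cc$nSubsamples,
                             subsampleFrac = cc$subsampleFrac,
                             seed = stageSeed(cfg$seed, "cluster")))
        writeTsv(data.frame(feature = names(clusterLabels(clus)),
                            cluster = clusterLabels(clus),
                            isMedoid = names(clusterLabels(clus)) %in%
                                medoids(clus)),
                 file.path(cfg$outDir, "clusters.tsv"))
        writeTsv(as.data.frame(comembership(clus)),
                 file.path(cfg$outDir, "comembership.tsv"))
        res$clusters <- clus
    }

    ## -- network -----------------------------------------------------------
    nets <- rewiring <- multiNets <- NULL
    if (on("network") && !is.null(clus)) {
        nc <- cfg$network
        med <- medoids(clus)
        sigM <- if (!is.null(assocM)) {
            tm <- as.data.frame(assocM)
            s <- unique(tm$feature[tm$significantENT])
            if (length(s) < 2)
                s <- names(sort(vapply(split(tm$p, tm$feature), min,
                                       0)))[seq_len(min(5L,
                                           length(unique(tm$feature))))]
            s
        } else character()
        nets <- list()
        multiNets <- list()
        for (tp in nc$timePoints) nets[[tp]] <- pipelineStage("network", {
            sel <- colData(omics)$time == tp
            x <- scale(t(intensities(omics[med, sel])))
            stabilityNetwork(x, ids = colData(omics)$participant[sel],
                             nLambda = nc$nLambda,
                             lambdaMinRatio = nc$lambdaMinRatio,
                             K = nc$K, frac = nc$frac,
                             seed = stageSeed(cfg$seed,
                                              paste0("net.", tp)))
        })
        if (length(sigM) >= 2 && !is.null(mrnaClean)) {
            for (tp in nc$timePoints) multiNets[[tp]] <-
                pipelineStage("network", {
                    sel <- colData(omics)$time == tp
                    selM <- colData(mrnaClean)$time == tp
                    common <- intersect(colnames(omics)[sel],
                                        colnames(mrnaClean)[selM])
                    x <- cbind(scale(t(intensities(
                             omics[med, common]))),
                         scale(t(intensities(mrnaClean[sigM, common]))))
                    blocks <- rep(c("metab", "mrna"),
                                  c(length(med), length(sigM)))
                    lamMax <- max(abs(upperVec(cor(x))))
                    grid <- exp(seq(log(lamMax), log(lamMax * 0.1),
                                    length.out = nc$multiblockGridSize))
                    multiblockNetwork(x, blocks, lambdaGrids = grid,
                        ids = colData(omics)[common, "participant"],
                        K = nc$K, frac = nc$frac,
                        seed = stageSeed(cfg$seed, paste0("mnet.", tp)))
                })
        }
        for (tp in names(nets))
            exportNetwork(nets[[tp]],
                          tsv = file.path(cfg$outDir,
                                          sprintf("network_%s.tsv", tp)),
                          graphml = file.path(cfg$outDir,
                                          sprintf("network_%s.graphml", tp)))
        rewiring <- pipelineStage("network",
            compareNetworks(nets[[1L]], nets[[2L]], nets[[3L]]))
        writeTsv(rewiring$edges, file.path(cfg$outDir, "rewiring.tsv"))
        res$networks <- nets
        res$multiomicNetworks <- multiNets
        res$rewiring <- rewiring
    }

    ## -- enrich ------------------------------------------------------------
    ora <- NULL
    if (on("enrich") && !is.null(assoc)) {
        ec <- cfg$enrichment
        ora <- pipelineStage("enrich", {
            mz <- setNames(rowData(omics)$mz, rownames(omics))
            ref <- generateReferenceSet(mz, nPathways = ec$nPathways,
                                        annotatedFraction =
                                            ec$annotatedFraction,
                                        seed = stageSeed(cfg$seed, "enrich"))
            tab <- as.data.frame(assoc)
            thr <- unlist(ec$thresholds)
            keep <- tab$p < thr[tab$exposure]
            sigFeat <- unique(tab$feature[!is.na(keep) & keep])
            hits <- matchMz(mz[sigFeat], ref$referenceMasses,
                            tolPpm = ec$tolPpm)
            selected <- intersect(unique(hits$compound),
                                  names(ref$referenceMasses))
            out <- oraFisher(selected, ref$pathways,
                             universe = names(ref$referenceMasses))
            writeTsv(out, file.path(cfg$outDir, "ora.tsv"))
            list(table = out, matches = hits, reference = ref)
        })
        res$ora <- ora
    }

    ## -- manifest and report ----------------------------------------------
    manifest <- list(config = cfg,
                     package = as.character(utils::packageVersion(
                         "crossomix")),
                     stages = cfg$stages)
    if (!is.null(omics))
        manifest$preprocess <- list(
            featuresKept = nrow(omics),
            outliersRemoved = metadata(omics)$outliers)
    if (!is.null(assoc))
        manifest$association <- list(ent = assoc@ent,
                                     nFeatures = assoc@nFeatures)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    rpt <- c("# crossomix run summary", "")
    if (!is.null(assoc)) {
        s <- associationSummary(assoc)
        rpt <- c(rpt, sprintf("- ENT = %d (of %d features)", assoc@ent,
                              assoc@nFeatures),
                 sprintf("- unique features significant for >= 1 exposure (ENT correction): %d",
                         s$uniqueSignificant),
                 sprintf("- per exposure: %s",
                         paste(sprintf("%s=%d", names(s$perExposure),
                                       s$perExposure), collapse = ", ")))
    }
    if (!is.null(clus))
        rpt <- c(rpt, sprintf("- consensus clusters: G = %d (threshold %.2f)",
                              clus@G, clus@threshold))
    if (!is.null(rewiring))
        rpt <- c(rpt, sprintf("- network edge classes: %s",
                 paste(sprintf("%s=%d", names(rewiring$counts),
                               as.integer(rewiring$counts)),
                       collapse = ", ")))
    if (!is.null(ora))
        rpt <- c(rpt, sprintf("- top pathway: %s (p = %.3g)",
                              ora$table$pathway[1L], ora$table$p[1L]))
    writeLines(rpt, file.path(cfg$outDir, "report.md"))
    invisible(res)
}
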