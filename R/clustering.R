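#' @importFrom stats hclust cutree as.dist cor cophenetic
NULL

# agglomerate the features of one connected component on 1 - comembership
# (average linkage) and return the merge heights, so components can be
# split at their weakest comemberships first.
splitComponent <- function(cm, members, nSplit) {
    if (length(members) <= 1L || nSplit <= 1L)
        return(rep(1L, length(members)))
    d <- as.dist(1 - cm[members, members, drop = FALSE])
    hc <- hclust(d, method = "average")
    cutree(hc, k = min(nSplit, length(members)))
}

#' Stability-calibrated consensus clustering of features
#'
#' For each candidate number of clusters G and each of `nSubsamples`
#' subsamples of the samples (without replacement, fraction
#' `subsampleFrac`), the base clusterer — hierarchical clustering with Ward
#' linkage on the correlation distance 1 - |Pearson r| — partitions the
#' features; pairwise comembership proportions are accumulated across
#' subsamples. The pair (G, pi) is calibrated by maximizing the same
#' binomial-null stability score used for network calibration, applied to
#' comembership counts ([stabilityScore()]). The final partition cuts the
#' comembership graph at the calibrated threshold and, if fewer than G
#' components result, splits components at their weakest comemberships.
#'
#' @param m an [OmicsSet-class] (features x samples) or numeric matrix in
#'   that orientation; typically the exposure-associated feature subset.
#' @param Ggrid candidate cluster numbers (default 2..10; trimmed with a
#'   warning if it exceeds the feature count).
#' @param nSubsamples number of subsamples (default 500).
#' @param subsampleFrac fraction of samples per subsample (default 0.8).
#' @param piGrid comembership thresholds scanned (default 0.51..0.99).
#' @param seed integer seed.
#' @return a [ClusterAssignment-class].
#' @examples
#' x <- matrix(rnorm(300), 6, 50)   # 6 features, 50 samples
#' x[4:6, ] <- x[4:6, ] + rep(rnorm(50, sd = 2), each = 3)
#' consensusCluster(x, Ggrid = 2:4, nSubsamples = 50, seed = 1)
#' @export
consensusCluster <- function(m, Ggrid = 2:10, nSubsamples = 500,
                             subsampleFrac = 0.8,
                             piGrid = seq(0.51, 0.99, by = 0.01),
                             seed = 1) {
    a <- if (is(m, "OmicsSet")) intensities(m) else as.matrix(m)
    p <- nrow(a)
    n <- ncol(a)
    if (p < 3L) stop("consensus clustering needs at least 3 features")
    if (any(Ggrid >= p)) {
        warning("Ggrid trimmed to the number of features")
        Ggrid <- Ggrid[Ggrid < p]
    }
    Ggrid <- sort(unique(as.integer(Ggrid)))
    fid <- rownames(a)
    if (is.null(fid)) fid <- paste0("F", seq_len(p))
    nSub <- max(2L, floor(subsampleFrac * n))
    set.seed(stageSeed(seed, "consensus"))
    subs <- lapply(seq_len(nSubsamples), function(k) sample.int(n, nSub))
    nPairs <- p * (p - 1L) / 2L
    counts <- matrix(0, nPairs, length(Ggrid))
    for (k in seq_len(nSubsamples)) {
        x <- a[, subs[[k]], drop = FALSE]
        cc <- abs(cor(t(x)))
        cc[!is.finite(cc)] <- 0
        hc <- hclust(as.dist(1 - cc), method = "ward.D2")
        for (gi in seq_along(Ggrid)) {
            lab <- cutree(hc, k = Ggrid[gi])
            counts[, gi] <- counts[, gi] + upperVec(outer(lab, lab, "=="))
        }
    }
    # joint calibration of (G, pi) by the binomial-null stability score
    best <- list(score = -Inf)
    scores <- matrix(NA_real_, length(Ggrid), length(piGrid),
                     dimnames = list(paste0("G", Ggrid), piGrid))
    for (gi in seq_along(Ggrid)) for (pj in seq_along(piGrid)) {
        s <- stabilityScore(counts[, gi], K = nSubsamples, pi = piGrid[pj])
        scores[gi, pj] <- s
        if (is.finite(s) && s > best$score)
            best <- list(score = s, gi = gi, pi = piGrid[pj])
    }
    if (!is.finite(best$score))
        stop("stability score degenerate on the whole (G, pi) grid")
    G <- Ggrid[best$gi]
    cm <- symFromUpper(counts[, best$gi] / nSubsamples, p,
                       dimnames = list(fid, fid))
    diag(cm) <- 1
    # consensus partition: threshold, components, split weak components
    comp <- graphComponents(cm >= best$pi)
    labels <- comp
    if (max(comp) < G) {
        # split components at their weakest comemberships until G reached
        repeat {
            nNow <- max(labels)
            if (nNow >= G) break
            sizes <- tabulate(labels)
            # candidate: the component with the lowest mean comembership
            cand <- which(sizes > 1L)
            if (!length(cand)) break
            coh <- vapply(cand, function(g) {
                ix <- which(labels == g)
                mean(cm[ix, ix][upper.tri(matrix(0, length(ix),
                                                 length(ix)))])
            }, 0)
            g <- cand[which.min(coh)]
            ix <- which(labels == g)
            sub <- splitComponent(cm, ix, 2L)
            labels[ix[sub == 2L]] <- nNow + 1L
        }
    }
    # relabel clusters in order of first appearance
    labels <- as.integer(factor(labels, levels = unique(labels)))
    names(labels) <- fid
    ass <- new("ClusterAssignment", labels = labels, comembership = cm,
               G = as.integer(max(labels)), threshold = best$pi,
               medoids = character(), score = best$score)
    ass@medoids <- clusterMedoids(ass, a)
    validObject(ass)
    ass
}

#' Medoid feature of each cluster
#'
#' The medoid is the member with the highest summed absolute Pearson
#' correlation to its co-members (equivalently, lowest total correlation
#' dissimilarity); singleton clusters are their own medoid; ties break to
#' the lowest feature index. Medoid intensity vectors are the cluster
#' representatives used for network estimation.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param m the matrix (features x samples) or [OmicsSet-class] the
#'   assignment was computed on.
#' @return character vector of medoid feature ids, one per cluster.
#' @export
clusterMedoids <- function(assignment, m) {
    a <- if (is(m, "OmicsSet")) intensities(m) else as.matrix(m)
    labels <- if (is(assignment, "ClusterAssignment"))
        clusterLabels(assignment) else assignment
    stopifnot(length(labels) == nrow(a))
    vapply(seq_len(max(labels)), function(g) {
        ix <- which(labels == g)
        stopifnot(length(ix) > 0L)     # empty cluster impossible by construction
        if (length(ix) == 1L) return(names(labels)[ix])
        cc <- abs(cor(t(a[ix, , drop = FALSE])))
        diag(cc) <- 0
        tot <- rowSums(cc)
        names(labels)[ix[which.max(tot)]]  # which.max takes the first = lowest index
    }, "")
}

#' Retention-time coherence of clusters
#'
#' Features clustered together often stem from the same compound and then
#' share a retention time; this report (not an assertion) gives the
#' within-cluster retention-time spread for inspection.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param rt numeric retention times named by feature.
#' @return data.frame: cluster, size, rtMedian, rtIQR.
#' @export
clusterRtCoherence <- function(assignment, rt) {
    labels <- clusterLabels(assignment)
    rt <- rt[names(labels)]
    do.call(rbind, lapply(seq_len(max(labels)), function(g) {
        v <- rt[labels == g]
        data.frame(cluster = g, size = length(v),
                   rtMedian = stats::median(v, na.rm = TRUE),
                   rtIQR = stats::IQR(v, na.rm = TRUE))
    }))
}
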