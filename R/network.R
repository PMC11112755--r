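#' @importFrom stats pbinom cor
#' @useDynLib crossomix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sparse inverse-covariance estimation (graphical LASSO)
#'
#' Maximizes `log det(Theta) - tr(S Theta) - sum_(j != k) lambda_jk
#' |Theta_jk|` by block coordinate descent over columns, each column's
#' lasso subproblem solved by cyclic coordinate descent with
#' soft-thresholding. The diagonal is unpenalized and the input is
#' expected to be a correlation matrix. Zero entries of the estimate
#' encode conditional independence.
#'
#' @param S symmetric correlation (or covariance) matrix with unit
#'   diagonal expected.
#' @param lambda penalty: a non-negative scalar, or a p x p matrix for
#'   block-specific penalties (diagonal ignored).
#' @param tol convergence tolerance, relative to the average absolute
#'   off-diagonal of `S`.
#' @param maxIter maximum outer sweeps.
#' @return list: `theta` (precision estimate), `w` (its inverse, the
#'   covariance estimate), `adjacency` (logical, zero diagonal), `edges`
#'   (2-column index matrix, j < k), `lambda`, `iterations`, `converged`.
#' @examples
#' S <- cor(matrix(rnorm(200), 50, 4))
#' g <- graphicalLasso(S, 0.2)
#' g$edges
#' @export
graphicalLasso <- function(S, lambda, tol = 1e-6, maxIter = 200) {
    S <- as.matrix(S)
    p <- nrow(S)
    stopifnot(p == ncol(S))
    if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
    Lambda <- if (is.matrix(lambda)) {
        stopifnot(all(dim(lambda) == p))
        lambda
    } else matrix(lambda, p, p)
    diag(Lambda) <- 0
    if (any(Lambda < 0)) stop("penalties must be non-negative")
    if (any(upperVec(Lambda) == 0)) {
        ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
        if (!ok)
            stop("regularization error: S is singular; a penalty lambda > 0 is required")
    }
    r <- .glassoCpp(S, Lambda, tol = tol, maxIter = as.integer(maxIter))
    adj <- matrix(as.logical(r$adjacency), p, p,
                  dimnames = dimnames(S))
    theta <- r$theta
    dimnames(theta) <- dimnames(S)
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    colnames(edges) <- c("j", "k")
    list(theta = theta, w = r$w, adjacency = adj, edges = edges,
         lambda = Lambda, iterations = r$iterations,
         converged = r$converged)
}

#' Penalized Gaussian log-likelihood of a precision matrix
#'
#' The graphical-LASSO objective `log det(Theta) - tr(S Theta) -
#' sum_(j != k) lambda_jk |Theta_jk|`; used to verify solver optimality
#' against generic numerical maximization.
#'
#' @param theta precision matrix.
#' @param S empirical correlation matrix.
#' @param lambda scalar or matrix penalty.
#' @return the objective value.
#' @export
glassoObjective <- function(theta, S, lambda) {
    Lambda <- if (is.matrix(lambda)) lambda else matrix(lambda, nrow(S),
                                                        ncol(S))
    diag(Lambda) <- 0
    determinant(theta, logarithm = TRUE)$modulus[1L] - sum(S * theta) -
        sum(Lambda * abs(theta))    # diag(Lambda) = 0: diagonal unpenalized
}

#' Likelihood-based stability score for selection proportions
#'
#' Contrasts the observed bimodality of edge (or comembership) selection
#' counts against an exchangeable null in which every pair is selected
#' independently with the average selection probability `q`: with
#' `B ~ Binomial(K, q)`, a pair selected in a fraction `>= pi` of
#' subsamples contributes `log P(B >= ceiling(K pi))`, one selected in
#' `<= 1 - pi` contributes `log P(B <= floor(K (1 - pi)))`, and the rest
#' contribute the log-probability of the middle range. The score is minus
#' the summed contributions: the higher it is, the less compatible the
#' selection pattern is with exchangeable instability. Maximized jointly
#' over the penalty and `pi` during calibration.
#'
#' @param counts integer selection counts per pair, in \[0, K\].
#' @param K number of subsamples.
#' @param pi selection-proportion threshold, in (0.5, 1).
#' @param q average selection probability; computed from `counts` when
#'   `NULL`.
#' @return the score; `-Inf` when `q` is 0 or 1 (degenerate penalty,
#'   excluded from calibration).
#' @export
stabilityScore <- function(counts, K, pi, q = NULL) {
    if (pi <= 0.5 || pi >= 1) stop("pi must lie in (0.5, 1)")
    if (any(counts < 0 | counts > K)) stop("counts must lie in [0, K]")
    if (is.null(q)) q <- sum(counts) / (K * length(counts))
    if (q <= 0 || q >= 1) return(-Inf)
    thrHi <- ceiling(K * pi)
    thrLo <- floor(K * (1 - pi))
    logHi <- pbinom(thrHi - 1, K, q, lower.tail = FALSE, log.p = TRUE)
    logLo <- pbinom(thrLo, K, q, log.p = TRUE)
    # middle probability from whichever tail avoids cancellation
    pMid <- max(pbinom(thrHi - 1, K, q) - pbinom(thrLo, K, q),
                pbinom(thrLo, K, q, lower.tail = FALSE) -
                    pbinom(thrHi - 1, K, q, lower.tail = FALSE),
                1e-300)
    prop <- counts / K
    contrib <- ifelse(prop >= pi, logHi,
                      ifelse(prop <= 1 - pi, logLo, log(pMid)))
    -sum(contrib)
}

# shared core: run the glasso over K subsamples for a list of penalty
# matrices, accumulate per-pair selection counts, and calibrate
# (penalty, pi) by the stability score.
stabilityCore <- function(x, ids, LambdaList, comboTab, piGrid, K, frac,
                          seed, blocks = factor(), tol = 1e-6) {
    x <- as.matrix(x)
    p <- ncol(x)
    if (is.null(ids)) ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    units <- sort(unique(as.character(ids)))
    nSub <- max(2L, floor(frac * length(units)))
    set.seed(stageSeed(seed, "stabsel"))
    subUnits <- lapply(seq_len(K), function(k) sample(units, nSub))
    rowsOf <- split(seq_len(nrow(x)), as.character(ids))
    nPairs <- p * (p - 1L) / 2L
    counts <- matrix(0, nPairs, length(LambdaList))
    warned <- FALSE
    for (k in seq_len(K)) {
        rows <- unlist(rowsOf[subUnits[[k]]], use.names = FALSE)
        if (length(rows) < p && !warned) {
            warning("subsample size below dimension; correlation is singular, ",
                    "penalties must stay positive")
            warned <- TRUE
        }
        Ssub <- cor(x[rows, , drop = FALSE])
        Ssub[!is.finite(Ssub)] <- 0
        diag(Ssub) <- 1
        for (li in seq_along(LambdaList)) {
            g <- graphicalLasso(Ssub, LambdaList[[li]], tol = tol)
            counts[, li] <- counts[, li] + upperVec(g$adjacency)
        }
    }
    best <- list(score = -Inf, li = NA_integer_, pi = NA_real_)
    for (li in seq_along(LambdaList)) {
        q <- sum(counts[, li]) / (K * nPairs)
        for (pi in piGrid) {
            s <- stabilityScore(counts[, li], K, pi, q = q)
            if (is.finite(s) && s > best$score)
                best <- list(score = s, li = li, pi = pi)
        }
    }
    if (!is.finite(best$score))
        stop("stability calibration degenerate: all penalties give empty or ",
             "complete graphs")
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("V", seq_len(p))
    prop <- symFromUpper(counts[, best$li] / K, p, dimnames = list(nm, nm))
    adj <- prop >= best$pi
    diag(adj) <- FALSE
    lambdaStar <- unlist(comboTab[best$li, , drop = FALSE])
    new("StabilityNetwork", proportions = prop, adjacency = adj,
        lambda = lambdaStar, pi = best$pi, score = best$score,
        K = as.integer(K), frac = frac,
        blocks = if (length(blocks)) factor(blocks) else factor())
}

#' Stability-calibrated conditional-independence network
#'
#' Applies the graphical LASSO to `K` subsamples (fraction `frac`, drawn
#' without replacement — by participant when `ids` is given, the default
#' resampling unit of the study design) for each penalty in a grid, counts
#' how often each edge is selected, and calibrates the penalty and the
#' selection-proportion threshold jointly by maximizing the
#' [stabilityScore()]. The stable network keeps edges whose selection
#' proportion reaches the calibrated threshold.
#'
#' @param x samples x variables matrix (e.g. transposed, standardized
#'   medoid intensities at one time point), or an [OmicsSet-class] (its
#'   features become the variables).
#' @param ids resampling-unit label per row (participants); `NULL` uses
#'   row names, falling back to row indices.
#' @param lambdaGrid penalty grid; default 25 log-spaced values from the
#'   smallest penalty giving an empty graph (`max |off-diagonal
#'   correlation|`) down to `lambdaMinRatio` times it.
#' @param nLambda,lambdaMinRatio default grid shape.
#' @param piGrid thresholds scanned, within (0.5, 1); default 0.51 to 0.99
#'   by 0.01.
#' @param K number of subsamples (default 500; at least 50 required for a
#'   meaningful calibration).
#' @param frac subsample fraction (default 0.8).
#' @param seed integer seed.
#' @param tol passed to [graphicalLasso()].
#' @return a [StabilityNetwork-class].
#' @export
stabilityNetwork <- function(x, ids = NULL, lambdaGrid = NULL,
                             nLambda = 25, lambdaMinRatio = 0.01,
                             piGrid = seq(0.51, 0.99, by = 0.01),
                             K = 500, frac = 0.8, seed = 1, tol = 1e-6) {
    if (is(x, "OmicsSet")) x <- t(intensities(x))
    x <- as.matrix(x)
    if (K < 50)
        stop("K subsamples below 50: selection proportions are too coarse ",
             "to calibrate; use K >= 50")
    if (is.null(lambdaGrid)) {
        S <- cor(x)
        lamMax <- max(abs(upperVec(S)))
        lambdaGrid <- exp(seq(log(lamMax), log(lamMax * lambdaMinRatio),
                              length.out = nLambda))
    }
    p <- ncol(x)
    LambdaList <- lapply(lambdaGrid, function(l) matrix(l, p, p))
    comboTab <- data.frame(lambda = lambdaGrid)
    stabilityCore(x, ids, LambdaList, comboTab, piGrid, K, frac, seed,
                  tol = tol)
}

#' Multiomic stability network with block-specific penalties
#'
#' Joint conditional-independence estimation over two omic blocks (e.g.
#' metabolite-cluster medoids and gene-mapped transcripts) with three
#' penalty groups — within block 1, within block 2 and cross-block —
#' applied elementwise in the graphical-LASSO objective. All penalty
#' combinations from the per-group grids are calibrated jointly with the
#' threshold by the same stability score summed over all variable pairs;
#' a block with fewer than 2 variables has no within-block pair and its
#' penalty group is dropped.
#'
#' @param x samples x variables matrix spanning both blocks.
#' @param blocks factor (2 levels) assigning each column to a block.
#' @param lambdaGrids named list of penalty grids for `within1`, `within2`
#'   and `cross`; a single unnamed grid is recycled to all three groups.
#' @param expand if `TRUE` (default) calibrate over the full grid product;
#'   if `FALSE`, couple the grids position-by-position (all groups share
#'   one penalty axis), which reduces exactly to [stabilityNetwork()] when
#'   the grids are identical.
#' @param ids,piGrid,K,frac,seed,tol as in [stabilityNetwork()].
#' @return a [StabilityNetwork-class] with the `blocks` slot set; cross-
#'   omic edges are flagged through `edgeList()`'s `blockPair` column.
#' @export
multiblockNetwork <- function(x, blocks, lambdaGrids, ids = NULL,
                              piGrid = seq(0.51, 0.99, by = 0.01),
                              K = 500, frac = 0.8, seed = 1,
                              expand = TRUE, tol = 1e-6) {
    if (is(x, "OmicsSet")) x <- t(intensities(x))
    x <- as.matrix(x)
    blocks <- factor(blocks)
    stopifnot(ncol(x) == length(blocks), nlevels(blocks) == 2L)
    if (K < 50)
        stop("K subsamples below 50: use K >= 50")
    groups <- c("within1", "within2", "cross")
    if (!is.list(lambdaGrids))
        lambdaGrids <- setNames(rep(list(lambdaGrids), 3L), groups)
    if (is.null(names(lambdaGrids)))
        names(lambdaGrids) <- groups[seq_along(lambdaGrids)]
    sizes <- table(blocks)
    active <- c(sizes[1L] >= 2L, sizes[2L] >= 2L, TRUE)
    names(active) <- groups
    use <- groups[active]
    if (!all(active))
        message("block with < 2 variables: penalty group(s) ",
                paste(groups[!active], collapse = ", "), " dropped")
    grids <- lambdaGrids[use]
    comboTab <- if (expand) expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    else {
        len <- unique(lengths(grids))
        if (length(len) != 1L)
            stop("coupled grids (expand = FALSE) must have equal lengths")
        as.data.frame(grids)
    }
    b <- as.integer(blocks)
    groupOf <- outer(b, b, function(i, j)
        ifelse(i != j, "cross", ifelse(i == 1L, "within1", "within2")))
    LambdaList <- lapply(seq_len(nrow(comboTab)), function(r) {
        L <- matrix(0, ncol(x), ncol(x))
        for (g in use)
            L[groupOf == g] <- comboTab[r, g]
        # inactive within-groups inherit the cross penalty (no pairs anyway)
        L[groupOf %in% groups[!active]] <- comboTab[r, "cross"]
        L
    })
    stabilityCore(x, ids, LambdaList, comboTab, piGrid, K, frac, seed,
                  blocks = blocks, tol = tol)
}

#' Classify network rewiring across the three occasions
#'
#' Compares the networks estimated before the exposure, 2 h after and
#' 24 h after, classifying every edge present in at least one of them:
#' `stable` (all three), `baselineOnly` (before only), `acute` (+2 h
#' only), `persistent` (+2 h and +24 h, not before), `lagged` (+24 h
#' only), `attenuated` (before and +2 h, gone by +24 h), `recurrent`
#' (before and +24 h, absent at +2 h — correlation patterns reverting to
#' their pre-exposure state).
#'
#' @param netBefore,netAfter2h,netAfter24h [StabilityNetwork-class]
#'   objects or logical adjacency matrices on the same node set.
#' @return list: `edges` (data.frame node1, node2, presence flags, class)
#'   and `counts` (table per class).
#' @export
compareNetworks <- function(netBefore, netAfter2h, netAfter24h) {
    getAdj <- function(z) if (is(z, "StabilityNetwork")) adjacency(z)
                          else as.matrix(z)
    A <- lapply(list(before = netBefore, after2h = netAfter2h,
                     after24h = netAfter24h), getAdj)
    nodes <- rownames(A[[1L]])
    for (nm in names(A)) {
        nd <- rownames(A[[nm]])
        if (!setequal(nd, nodes) || is.null(nd)) {
            miss <- c(setdiff(nodes, nd), setdiff(nd, nodes))
            stop("alignment error: node sets differ; missing/extra nodes: ",
                 paste(unique(miss), collapse = ", "))
        }
        A[[nm]] <- A[[nm]][nodes, nodes]
    }
    ut <- upper.tri(A[[1L]])
    keep <- which(ut & (A$before | A$after2h | A$after24h), arr.ind = TRUE)
    pres <- cbind(before = A$before[keep], after2h = A$after2h[keep],
                  after24h = A$after24h[keep])
    cls <- apply(pres, 1L, function(v) {
        if (all(v)) "stable"
        else if (v[1L] && !v[2L] && !v[3L]) "baselineOnly"
        else if (!v[1L] && v[2L] && !v[3L]) "acute"
        else if (!v[1L] && v[2L] && v[3L]) "persistent"
        else if (!v[1L] && !v[2L] && v[3L]) "lagged"
        else if (v[1L] && v[2L] && !v[3L]) "attenuated"
        else "recurrent"
    })
    lev <- c("stable", "baselineOnly", "acute", "persistent", "lagged",
             "attenuated", "recurrent")
    edges <- data.frame(node1 = nodes[keep[, 1L]], node2 = nodes[keep[, 2L]],
                        pres, class = factor(cls, levels = lev),
                        stringsAsFactors = FALSE)
    list(edges = edges, counts = table(edges$class))
}

#' Write a network as an edge-list TSV and a GraphML file
#'
#' @param net a [StabilityNetwork-class].
#' @param tsv,graphml output paths (`NULL` skips either).
#' @return the edge list, invisibly.
#' @export
exportNetwork <- function(net, tsv = NULL, graphml = NULL) {
    el <- edgeList(net)
    if (!is.null(tsv)) writeTsv(el, tsv)
    if (!is.null(graphml)) {
        nodes <- rownames(selectionProportions(net))
        con <- file(graphml, "w")
        on.exit(close(con))
        writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
            '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
            '<key id="w" for="edge" attr.name="proportion" attr.type="double"/>',
            '<graph edgedefault="undirected">'), con)
        writeLines(sprintf('<node id="%s"/>', nodes), con)
        st <- el[el$stable, , drop = FALSE]
        if (nrow(st))
            writeLines(sprintf(
                '<edge source="%s" target="%s"><data key="w">%g</data></edge>',
                st$node1, st$node2, st$proportion), con)
        writeLines(c("</graph>", "</graphml>"), con)
    }
    invisible(el)
}
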