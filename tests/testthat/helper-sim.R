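# Shared fixture builders (all generated in code; no stored data).

# exposure vector aligned to the design rows
visitExposure <- function(design, exposures, pollutant = "NO2") {
    exposures[[pollutant]][match(paste(design$participant, design$visit),
                                 paste(exposures$participant,
                                       exposures$visit))]
}

# samples x p draws from N(0, solve(precision)), named rows
mvnDraws <- function(n, precision, seed = 1) {
    set.seed(seed)
    x <- matrix(rnorm(n * nrow(precision)), n) %*% chol(solve(precision))
    dimnames(x) <- list(paste0("s", seq_len(n)),
                        paste0("V", seq_len(ncol(x))))
    x
}

# features x samples matrix with 3 planted correlation blocks
# (within-block correlation ~rho, between-block 0)
blockMatrix <- function(sizes = c(6, 6, 6), n = 100, rho = 0.9, seed = 5) {
    set.seed(seed)
    z <- matrix(rnorm(n * length(sizes)), n)
    x <- do.call(rbind, lapply(seq_along(sizes), function(k)
        matrix(rep(sqrt(rho) * z[, k], sizes[k]), sizes[k], n,
               byrow = TRUE) +
            sqrt(1 - rho) * matrix(rnorm(sizes[k] * n), sizes[k], n)))
    rownames(x) <- paste0("f", seq_len(nrow(x)))
    x
}

edgeF1 <- function(adjEst, adjTrue) {
    ut <- upper.tri(adjEst)
    tp <- sum(adjEst[ut] & adjTrue[ut])
    fp <- sum(adjEst[ut] & !adjTrue[ut])
    fn <- sum(!adjEst[ut] & adjTrue[ut])
    if (2 * tp + fp + fn == 0) return(1)
    2 * tp / (2 * tp + fp + fn)
}

countEdges <- function(net) {
    a <- adjacency(net)
    sum(a[upper.tri(a)])
}

# proximal-gradient (ISTA) maximizer of the penalized log-likelihood:
# an independent oracle for the coordinate-descent glasso solver
istaGlasso <- function(S, lambda, step = 0.02, iters = 40000) {
    p <- nrow(S)
    L <- matrix(lambda, p, p); diag(L) <- 0
    Th <- diag(p)
    for (i in seq_len(iters)) {
        G <- solve(Th) - S            # gradient of the smooth part
        Z <- Th + step * G
        Th <- sign(Z) * pmax(abs(Z) - step * L, 0)
        Th <- (Th + t(Th)) / 2
    }
    Th
}
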