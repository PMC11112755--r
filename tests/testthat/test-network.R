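test_that("glasso matches direct inversion at lambda = 0", {
    set.seed(1)
    S <- cor(matrix(rnorm(400), 100, 4))
    g <- graphicalLasso(S, 0)
    expect_lt(max(abs(g$theta - solve(S))), 1e-6)
})

test_that("a penalty above max |S| gives the diagonal solution", {
    set.seed(2)
    S <- cor(matrix(rnorm(300), 60, 5))
    lamMax <- max(abs(S[upper.tri(S)]))
    g <- graphicalLasso(S, lamMax + 1e-12)
    expect_equal(nrow(g$edges), 0)
    expect_equal(diag(g$theta), 1 / diag(S))
})

test_that("glasso agrees with a proximal-gradient oracle at p = 4", {
    set.seed(3)
    for (rep in 1:3) {
        S <- cor(matrix(rnorm(4 * 80), 80, 4))
        lam <- c(0.05, 0.1, 0.2)[rep]
        g <- graphicalLasso(S, lam, tol = 1e-9)
        oracle <- istaGlasso(S, lam)
        expect_lt(max(abs(g$theta - oracle)), 1e-5)
        expect_gte(glassoObjective(g$theta, S, lam),
                   glassoObjective(oracle, S, lam) - 1e-8)
    }
})

test_that("solutions satisfy the subgradient optimality conditions", {
    set.seed(4)
    for (p in c(4, 8, 15)) {
        S <- cor(matrix(rnorm(p * 60), 60, p))
        lam <- 0.15
        g <- graphicalLasso(S, lam, tol = 1e-8)
        W <- solve(g$theta)
        D <- W - S
        off <- !diag(p)
        zero <- off & g$theta == 0
        nz <- off & g$theta != 0
        expect_true(all(abs(D[zero]) <= lam + 1e-5))
        if (any(nz))
            expect_lt(max(abs(D[nz] - lam * sign(g$theta[nz]))), 1e-5)
    }
})

test_that("edge count is non-increasing in the penalty", {
    set.seed(5)
    S <- cor(mvnDraws(80, generatePrecisionMatrix(10, 0.3,
                                                  seed = 6)$precision))
    lams <- exp(seq(log(0.6), log(0.01), length.out = 12))
    ne <- vapply(lams, function(l) nrow(graphicalLasso(S, l)$edges), 0L)
    expect_true(all(diff(ne) >= 0))     # lams decreasing -> edges grow
})

test_that("singular S without penalty is refused with advice", {
    x <- matrix(rnorm(20), 4, 5)        # n < p: singular correlation
    S <- cor(x)
    expect_error(graphicalLasso(S, 0), "lambda > 0")
    expect_silent(graphicalLasso(S, 0.3))
})

test_that("stability score separates bimodal from uniform selection", {
    K <- 10
    # all counts at K/2: minimal score among configurations with equal q
    mid <- rep(5, 3)
    q <- sum(mid) / (K * 3)
    sMid <- stabilityScore(mid, K, pi = 0.8, q = q)
    # enumerate every configuration of 3 edges with the same total count
    confs <- expand.grid(0:K, 0:K, 0:K)
    confs <- confs[rowSums(confs) == sum(mid), ]
    scores <- apply(confs, 1L, function(cc)
        stabilityScore(as.numeric(cc), K, pi = 0.8, q = q))
    expect_equal(min(scores), sMid, tolerance = 1e-12)
    # extreme 0/K counts: maximal score at equal q
    ext <- c(0, 5, 10)  # same total; contains the most extreme values
    sExt <- stabilityScore(c(10, 5, 0), K, pi = 0.8, q = q)
    expect_equal(max(scores), sExt, tolerance = 1e-12)
    expect_gt(sExt, sMid)
    # degenerate q
    expect_identical(stabilityScore(c(2, 2), K = 2, pi = 0.9, q = 1), -Inf)
    expect_identical(stabilityScore(rep(2L, 3), K = 2, pi = 0.9), -Inf)
    expect_error(stabilityScore(c(1, 2), K = 10, pi = 0.4), "pi")
    expect_error(stabilityScore(c(11, 2), K = 10, pi = 0.9), "counts")
})

test_that("stability selection recovers a planted sparse graph", {
    pr <- generatePrecisionMatrix(20, 0.1, seed = 42)
    x <- mvnDraws(300, pr$precision, seed = 11)
    net <- stabilityNetwork(x, K = 100, seed = 1)
    expect_gte(edgeF1(adjacency(net), pr$support), 0.8)
    expect_gt(net@pi, 0.5)
    expect_lt(net@pi, 1)
    # adjacency consistent with proportions and threshold
    expect_true(all(selectionProportions(net)[adjacency(net)] >= net@pi))
})

test_that("selection proportions are invariant to sample order", {
    pr <- generatePrecisionMatrix(10, 0.2, seed = 7)
    x <- mvnDraws(100, pr$precision, seed = 8)
    shuffle <- sample(nrow(x))
    n1 <- stabilityNetwork(x, K = 60, seed = 5)
    n2 <- stabilityNetwork(x[shuffle, ], K = 60, seed = 5)
    expect_identical(selectionProportions(n1), selectionProportions(n2))
})

test_that("K = 1 subsampling is rejected with advice", {
    x <- mvnDraws(50, diag(5), seed = 9)
    expect_error(stabilityNetwork(x, K = 1, seed = 1), "K >= 50")
})

test_that("multiblock penalties control cross-omic edges", {
    pr <- generatePrecisionMatrix(12, 0.25, seed = 13)
    x <- mvnDraws(150, pr$precision, seed = 14)
    blocks <- rep(c("A", "B"), c(7, 5))
    # infinite-like cross penalty: no cross-omic edges survive
    net <- multiblockNetwork(x, blocks,
                             lambdaGrids = list(within1 = 0.2,
                                                within2 = 0.2, cross = 10),
                             K = 60, seed = 2)
    el <- edgeList(net)
    expect_false(any(el$blockPair[el$stable] == "A:B"))
})

test_that("coupled identical grids reduce multiblock to single-block", {
    pr <- generatePrecisionMatrix(10, 0.2, seed = 17)
    x <- mvnDraws(120, pr$precision, seed = 18)
    grid <- c(0.4, 0.25, 0.15, 0.08)
    single <- stabilityNetwork(x, lambdaGrid = grid, K = 60, seed = 3)
    multi <- multiblockNetwork(x, rep(c("A", "B"), each = 5),
                               lambdaGrids = list(within1 = grid,
                                                  within2 = grid,
                                                  cross = grid),
                               expand = FALSE, K = 60, seed = 3)
    expect_identical(selectionProportions(multi),
                     selectionProportions(single))
    expect_identical(adjacency(multi), adjacency(single))
    expect_identical(multi@pi, single@pi)
})

test_that("planted cross-block edges are recovered", {
    # block-structured precision with 4 planted cross-block edges
    set.seed(19)
    p1 <- 15; p2 <- 10; p <- p1 + p2
    theta <- diag(p)
    cross <- cbind(1:4, p1 + (1:4))
    for (r in 1:4) {
        theta[cross[r, 1], cross[r, 2]] <- 0.35
        theta[cross[r, 2], cross[r, 1]] <- 0.35
    }
    within <- rbind(cbind(c(5, 7, 9), c(6, 8, 10)),
                    cbind(p1 + c(5, 7), p1 + c(6, 8)))
    for (r in seq_len(nrow(within))) {
        theta[within[r, 1], within[r, 2]] <- 0.35
        theta[within[r, 2], within[r, 1]] <- 0.35
    }
    diag(theta) <- rowSums(abs(theta)) + 0.1
    x <- mvnDraws(400, theta, seed = 20)
    grid <- exp(seq(log(0.5), log(0.05), length.out = 5))
    net <- multiblockNetwork(x, rep(c("A", "B"), c(p1, p2)),
                             lambdaGrids = list(within1 = grid,
                                                within2 = grid,
                                                cross = grid),
                             expand = FALSE, K = 60, seed = 4)
    adj <- adjacency(net)
    found <- sum(vapply(1:4, function(r) adj[cross[r, 1], cross[r, 2]],
                        TRUE))
    expect_gte(found, 3)
})

test_that("rewiring classes follow the three-occasion presence patterns", {
    nodes <- paste0("n", 1:5)
    adj <- function(pairs) {
        a <- matrix(FALSE, 5, 5, dimnames = list(nodes, nodes))
        for (p in pairs) { a[p[1], p[2]] <- TRUE; a[p[2], p[1]] <- TRUE }
        a
    }
    base <- adj(list(c(1, 2), c(2, 3)))
    # identical networks: everything stable
    same <- compareNetworks(base, base, base)
    expect_true(all(same$edges$class == "stable"))
    # disjoint before/after: no persistent edges involving baseline
    aft <- adj(list(c(3, 4), c(4, 5)))
    dis <- compareNetworks(base, aft, aft)
    expect_equal(sum(dis$edges$class == "stable"), 0)
    expect_equal(sum(dis$edges$class == "persistent"), 2)
    expect_equal(sum(dis$edges$class == "baselineOnly"), 2)
    # planted: 3 edges added at +2h and kept at +24h -> persistent
    a2 <- adj(list(c(1, 2), c(2, 3), c(1, 4), c(2, 5), c(3, 5)))
    cmp <- compareNetworks(base, a2, a2)
    expect_equal(sum(cmp$edges$class == "persistent"), 3)
    expect_equal(sum(cmp$edges$class == "stable"), 2)
    # acute and lagged and recurrent patterns
    only2 <- adj(list(c(1, 5)))
    only24 <- adj(list(c(2, 4)))
    cmp2 <- compareNetworks(adj(list(c(1, 3))), only2, only24)
    expect_setequal(as.character(cmp2$edges$class),
                    c("baselineOnly", "acute", "lagged"))
    # node-set mismatch
    bad <- matrix(FALSE, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
    expect_error(compareNetworks(base, base, bad), "alignment")
})

test_that("network export writes edge list and GraphML", {
    pr <- generatePrecisionMatrix(8, 0.3, seed = 23)
    x <- mvnDraws(120, pr$precision, seed = 24)
    net <- stabilityNetwork(x, K = 50, seed = 6)
    tsv <- tempfile(fileext = ".tsv")
    gml <- tempfile(fileext = ".graphml")
    exportNetwork(net, tsv = tsv, graphml = gml)
    el <- read.delim(tsv)
    expect_true(all(c("node1", "node2", "proportion", "stable") %in%
                    colnames(el)))
    doc <- readLines(gml)
    expect_true(any(grepl("graphml", doc)))
})
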