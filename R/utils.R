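# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a master seed and a stage label,
# so toggling one pipeline stage does not perturb another stage's stream.
stageSeed <- function(seed, label) {
    h <- as.numeric(seed) %% 2147483647
    for (k in utf8ToInt(label))
        h <- (h * 131 + k) %% 2147483647
    as.integer(h)
}

# Connected components of an undirected graph given a logical adjacency
# matrix; returns an integer membership vector (1-based, order of discovery).
graphComponents <- function(adj) {
    p <- nrow(adj)
    comp <- integer(p)
    cur <- 0L
    for (v in seq_len(p)) {
        if (comp[v] > 0L) next
        cur <- cur + 1L
        queue <- v
        comp[v] <- cur
        while (length(queue)) {
            u <- queue[[1L]]
            queue <- queue[-1L]
            nb <- which(adj[u, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

# Symmetric matrix from upper-triangle vector (pairs in column-major
# upper.tri order), zero diagonal.
symFromUpper <- function(v, p, dimnames = NULL) {
    m <- matrix(0, p, p, dimnames = dimnames)
    m[upper.tri(m)] <- v
    m + t(m)
}

upperVec <- function(m) m[upper.tri(m)]

# write a data.frame as TSV without quoting (shared output dialect)
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
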