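#' @importFrom stats fisher.test
NULL

#' Positive-mode adduct rules
#'
#' Monoisotopic mass shifts (Da) of the singly charged positive-mode ion
#' forms used for neutral-mass annotation: protonation \[M+H\]+, water
#' loss \[M-H2O+H\]+ and sodium adduct \[M+Na\]+.
#'
#' @return data.frame with `name`, `shift` (Da), `charge`.
#' @export
adductRules <- function() {
    data.frame(name = c("[M+H]+", "[M-H2O+H]+", "[M+Na]+"),
               shift = c(1.007276, -17.003289, 22.989218),
               charge = c(1L, 1L, 1L), stringsAsFactors = FALSE)
}

#' Match observed m/z values against a reference mass list
#'
#' For every adduct rule the implied neutral mass `M = mz - shift` is
#' compared with each reference monoisotopic mass; a match requires a
#' relative error of at most `tolPpm` parts per million (inclusive).
#' Multiple hits are all returned, ordered by absolute ppm error.
#'
#' @param mz observed mass-to-charge values (positive), optionally named.
#' @param referenceMasses neutral monoisotopic masses named by compound id.
#' @param rules adduct rule table, default [adductRules()].
#' @param tolPpm mass tolerance in ppm (default 8).
#' @return data.frame: `mz` (query name or value), `compound`, `adduct`,
#'   `ppmError`, sorted by `abs(ppmError)` within query.
#' @examples
#' matchMz(181.070665, c(glucose = 180.063388))  # [M+H]+ at ~0 ppm
#' @export
matchMz <- function(mz, referenceMasses, rules = adductRules(),
                    tolPpm = 8) {
    if (tolPpm <= 0) stop("tolPpm must be positive")
    if (any(mz <= 0)) stop("m/z values must be positive")
    ids <- names(referenceMasses)
    if (is.null(ids)) ids <- paste0("C", seq_along(referenceMasses))
    qn <- names(mz)
    if (is.null(qn)) qn <- as.character(mz)
    hits <- list()
    for (i in seq_along(mz)) {
        for (r in seq_len(nrow(rules))) {
            M <- mz[i] - rules$shift[r]
            ppm <- (M - referenceMasses) / referenceMasses * 1e6
            ok <- which(abs(ppm) <= tolPpm)
            if (length(ok))
                hits[[length(hits) + 1L]] <- data.frame(
                    mz = qn[i], compound = ids[ok],
                    adduct = rules$name[r], ppmError = ppm[ok],
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(hits))
        return(data.frame(mz = character(), compound = character(),
                          adduct = character(), ppmError = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, hits)
    out <- out[order(match(out$mz, qn), abs(out$ppmError)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fisher-exact over-representation analysis
#'
#' For each pathway, a one-sided Fisher exact test on the 2 x 2 table of
#' (in / out of pathway) x (selected / not selected) over the assayed
#' universe — the over-representation alternative. Equivalent to the
#' hypergeometric survival function at `overlap - 1`.
#'
#' @param selected character vector of selected compound ids (must lie in
#'   the universe).
#' @param pathways named list: pathway name -> compound id set.
#' @param universe all assayed compound ids; defaults to the union of the
#'   pathway sets and `selected`.
#' @return data.frame: `pathway`, `size` (pathway compounds in the
#'   universe), `overlap` (selected pathway compounds), `p`, ordered by
#'   `p`.
#' @export
oraFisher <- function(selected, pathways, universe = NULL) {
    if (is.null(universe))
        universe <- unique(c(unlist(pathways), selected))
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    if (!all(selected %in% universe))
        stop("selected compounds must be a subset of the universe")
    selected <- unique(selected)
    out <- do.call(rbind, lapply(names(pathways), function(nm) {
        pw <- intersect(unique(pathways[[nm]]), universe)
        ov <- length(intersect(pw, selected))
        tab <- matrix(c(ov, length(pw) - ov,
                        length(selected) - ov,
                        length(universe) - length(pw) -
                            length(selected) + ov), 2L)
        p <- fisher.test(tab, alternative = "greater")$p.value
        data.frame(pathway = nm, size = length(pw), overlap = ov, p = p,
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(out$p, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-pollutant significance thresholds for pathway set construction
#'
#' The p-value cutoffs applied per pollutant before building the selected
#' feature set for over-representation analysis: 0.05 for PM2.5 and PM10,
#' 0.01 for PCNT and BC, and 0.005 for NO2.
#'
#' @return named numeric vector of thresholds.
#' @export
oraThresholds <- function() {
    c(PM10 = 0.05, `PM2.5` = 0.05, NO2 = 0.005, BC = 0.01, PCNT = 0.01)
}

#' Read a reference mass list from TSV
#'
#' Expects columns `id` and `mass` (neutral monoisotopic mass, Da). A
#' small synthetic example ships under
#' `system.file("extdata", "reference_masses.tsv", package = "crossomix")`.
#'
#' @param path TSV file path.
#' @return named numeric vector of masses.
#' @export
readReferenceMasses <- function(path) {
    tab <- utils::read.delim(path)
    stopifnot(all(c("id", "mass") %in% colnames(tab)))
    setNames(tab$mass, tab$id)
}

#' Read pathway maps in GMT format
#'
#' One pathway per line: name, description, then member compound ids,
#' tab-separated. A small synthetic example ships under
#' `system.file("extdata", "pathways.gmt", package = "crossomix")`.
#'
#' @param path GMT file path.
#' @return named list of compound-id vectors.
#' @export
readPathwaysGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    setNames(lapply(parts, function(p) unique(p[-(1:2)])),
             vapply(parts, `[`, "", 1L))
}

#' Simulate a toy reference mass list and pathway map
#'
#' Synthetic desk-scale stand-in for a compound database: a fraction of
#' the features are given a "true" compound whose neutral mass places the
#' feature's m/z within tolerance of an adduct, and compounds are grouped
#' into pathways. Used to exercise annotation and over-representation
#' end-to-end; labelled synthetic throughout.
#'
#' @param mz feature m/z values (named by feature id).
#' @param nPathways number of pathways.
#' @param annotatedFraction fraction of features given a matching
#'   reference compound.
#' @param seed integer seed.
#' @return list: `referenceMasses` (named), `pathways` (named list),
#'   `featureCompound` (feature id -> compound id for annotated features).
#' @export
generateReferenceSet <- function(mz, nPathways = 5,
                                 annotatedFraction = 0.6, seed = 1) {
    set.seed(stageSeed(seed, "refset"))
    fid <- names(mz)
    if (is.null(fid)) fid <- paste0("F", seq_along(mz))
    nAnno <- max(1L, round(annotatedFraction * length(mz)))
    anno <- sort(sample(seq_along(mz), nAnno))
    rules <- adductRules()
    ad <- sample(nrow(rules), nAnno, replace = TRUE)
    # place the true neutral mass within ~2 ppm of the observed ion
    mass <- (mz[anno] - rules$shift[ad]) *
        (1 + runif(nAnno, -2e-6, 2e-6))
    cid <- sprintf("CPD%04d", seq_len(nAnno))
    names(mass) <- cid
    pw <- split(cid, sample(nPathways, nAnno, replace = TRUE))
    names(pw) <- sprintf("pathway_%02d", seq_along(pw))
    list(referenceMasses = mass, pathways = pw,
         featureCompound = setNames(cid, fid[anno]))
}
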