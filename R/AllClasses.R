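#' @include AllGenerics.R
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData rowData<- colData<-
NULL

# ---------------------------------------------------------------------------
# OmicsSet
# ---------------------------------------------------------------------------

#' Feature-by-sample omics container
#'
#' `OmicsSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' scale flag that tracks whether the single `"intensity"` assay holds raw
#' (non-negative) or log2-transformed values. Missing measurements are `NA`
#' in the assay; the mask is derived, never stored. Feature metadata
#' (`rowData`) may carry `mz` (Da), `rt` (min) and `symbol` columns for
#' metabolite and transcript features; sample metadata (`colData`) carries
#' the study design (participant, site, time point, visit, technical
#' factors, covariates).
#'
#' @slot scale `"raw"` or `"log2"`.
#' @export
setClass("OmicsSet",
         contains = "SummarizedExperiment",
         representation(scale = "character"),
         prototype(scale = "raw"))

setValidity("OmicsSet", function(object) {
    msg <- character()
    if (length(object@scale) != 1L || !object@scale %in% c("raw", "log2"))
        msg <- c(msg, "scale must be one of 'raw', 'log2'")
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "an assay named 'intensity' is required")
    else {
        a <- assay(object, "intensity")
        if (!is.numeric(a))
            msg <- c(msg, "'intensity' assay must be numeric")
        if (identical(object@scale, "raw") && any(a[!is.na(a)] < 0))
            msg <- c(msg, "raw intensities must be non-negative")
    }
    rd <- rowData(object)
    if ("mz" %in% colnames(rd)) {
        mz <- rd$mz
        if (any(!is.na(mz) & mz <= 0))
            msg <- c(msg, "feature m/z must be positive where present")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsSet
#'
#' @param intensity numeric feature x sample matrix; `NA` marks missing
#'   measurements.
#' @param rowData,colData feature and sample annotation, coercible to
#'   [S4Vectors::DataFrame].
#' @param scale `"raw"` or `"log2"`.
#' @return An [OmicsSet-class] object.
#' @examples
#' m <- matrix(2^rnorm(20, 10), 4, 5,
#'             dimnames = list(paste0("F", 1:4), paste0("S", 1:5)))
#' os <- OmicsSet(m)
#' omicsScale(os)
#' @export
OmicsSet <- function(intensity, rowData = NULL, colData = NULL,
                     scale = c("raw", "log2")) {
    scale <- match.arg(scale)
    intensity <- as.matrix(intensity)
    if (is.null(rownames(intensity)))
        rownames(intensity) <- sprintf("F%04d", seq_len(nrow(intensity)))
    if (is.null(colnames(intensity)))
        colnames(intensity) <- sprintf("S%03d", seq_len(ncol(intensity)))
    args <- list(assays = SimpleList(intensity = intensity))
    if (!is.null(rowData)) args$rowData <- DataFrame(rowData)
    if (!is.null(colData)) args$colData <- DataFrame(colData)
    se <- do.call(SummarizedExperiment, args)
    new("OmicsSet", se, scale = scale)
}

#' @describeIn OmicsSet the intensity matrix (features x samples).
#' @param x an `OmicsSet`.
#' @param ... unused.
#' @export
setMethod("intensities", "OmicsSet", function(x, ...) assay(x, "intensity"))

#' @describeIn OmicsSet the scale flag (`"raw"` or `"log2"`).
#' @export
setMethod("omicsScale", "OmicsSet", function(x) x@scale)

#' @describeIn OmicsSet logical matrix, `TRUE` where the measurement is
#'   missing.
#' @export
setMethod("missingMask", "OmicsSet", function(x) is.na(assay(x, "intensity")))

setMethod("show", "OmicsSet", function(object) {
    callNextMethod()
    cat("scale:", object@scale, "| missing:",
        sum(is.na(assay(object, "intensity"))), "values\n")
})

# internal: replace the intensity assay, keeping annotation
setIntensities <- function(x, value, scale = x@scale) {
    assay(x, "intensity") <- value
    x@scale <- scale
    validObject(x)
    x
}

# ---------------------------------------------------------------------------
# AssociationResults
# ---------------------------------------------------------------------------

#' Per-feature exposure association results
#'
#' One row per (feature, exposure) pair from the repeated-measures
#' multivariate-normal fit: effect estimate `beta` (log2 units per exposure
#' unit), standard error, Wald statistic, two-sided p-value, and two
#' Bonferroni significance flags — against the effective number of tests
#' (ENT) and against the full feature count.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `feature`, `exposure`,
#'   `beta`, `se`, `stat`, `p`, `significantENT`, `significantFull`, `model`.
#' @slot ent integer, effective number of tests used for the ENT flag.
#' @slot nFeatures integer, denominator of the full Bonferroni correction.
#' @slot fwer target family-wise error rate (default 0.05).
#' @export
setClass("AssociationResults",
         representation(table = "DataFrame", ent = "integer",
                        nFeatures = "integer", fwer = "numeric"))

setValidity("AssociationResults", function(object) {
    need <- c("feature", "exposure", "beta", "se", "stat", "p")
    if (!all(need %in% colnames(object@table)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    p <- object@table$p
    if (any(!is.na(p) & (p <= 0 | p > 1)))
        return("p-values must lie in (0, 1]")
    TRUE
})

#' @describeIn AssociationResults coerce to data.frame.
#' @param x an `AssociationResults`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "AssociationResults",
          function(x, ...) as.data.frame(x@table))

setMethod("show", "AssociationResults", function(object) {
    tab <- object@table
    cat(class(object), "with", nrow(tab), "tests (",
        length(unique(tab$feature)), "features x",
        length(unique(tab$exposure)), "exposures )\n")
    if (length(object@ent))
        cat("ENT =", object@ent, "| full correction n =", object@nFeatures,
            "| FWER =", object@fwer, "\n")
    if ("significantENT" %in% colnames(tab))
        cat("significant: ENT-Bonferroni", sum(tab$significantENT),
            "| full Bonferroni", sum(tab$significantFull), "\n")
})

# ---------------------------------------------------------------------------
# ClusterAssignment
# ---------------------------------------------------------------------------

#' Consensus clustering of features
#'
#' Holds the consensus comembership proportions across subsampled
#' clusterings, the calibrated number of clusters `G` and comembership
#' threshold, the final feature-to-cluster map and one medoid per cluster.
#'
#' @slot labels named integer vector, feature -> cluster.
#' @slot comembership features x features matrix of comembership proportions
#'   (symmetric, unit diagonal).
#' @slot G calibrated number of clusters.
#' @slot threshold calibrated comembership threshold (pi).
#' @slot medoids character vector, one feature id per cluster.
#' @slot score stability score at the calibrated (G, pi).
#' @export
setClass("ClusterAssignment",
         representation(labels = "integer", comembership = "matrix",
                        G = "integer", threshold = "numeric",
                        medoids = "character", score = "numeric"))

setValidity("ClusterAssignment", function(object) {
    cm <- object@comembership
    if (nrow(cm) != ncol(cm)) return("comembership must be square")
    if (max(abs(cm - t(cm))) > 1e-8) return("comembership must be symmetric")
    if (any(abs(diag(cm) - 1) > 1e-8)) return("comembership diagonal must be 1")
    if (length(object@labels) != nrow(cm))
        return("one label per feature required")
    for (g in seq_along(object@medoids)) {
        med <- object@medoids[g]
        if (!med %in% names(object@labels)[object@labels == g])
            return(sprintf("medoid '%s' not a member of cluster %d", med, g))
    }
    TRUE
})

#' @describeIn ClusterAssignment feature -> cluster map.
#' @param x a `ClusterAssignment`.
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @describeIn ClusterAssignment one representative feature id per cluster.
#' @export
setMethod("medoids", "ClusterAssignment", function(x) x@medoids)

#' @describeIn ClusterAssignment comembership proportion matrix.
#' @export
setMethod("comembership", "ClusterAssignment", function(x) x@comembership)

setMethod("show", "ClusterAssignment", function(object) {
    cat(class(object), ":", length(object@labels), "features in",
        object@G, "clusters (threshold", format(object@threshold), ")\n")
    cat("cluster sizes:", paste(tabulate(object@labels), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# StabilityNetwork
# ---------------------------------------------------------------------------

#' Stability-calibrated conditional-independence network
#'
#' Result of graphical-LASSO stability selection: per-edge selection
#' proportions over K subsamples, the jointly calibrated penalty (one value,
#' or one per block pair for multiomic fits) and selection-proportion
#' threshold, and the stable adjacency matrix.
#'
#' @slot proportions p x p selection-proportion matrix, zero diagonal.
#' @slot adjacency logical p x p stable adjacency (proportion >= pi).
#' @slot lambda named numeric, calibrated penalty per penalty group.
#' @slot pi calibrated selection-proportion threshold, in (0.5, 1).
#' @slot score stability score at the calibrated hyper-parameters.
#' @slot K number of subsamples.
#' @slot frac subsample fraction.
#' @slot blocks factor of block membership per node (empty for single-block).
#' @export
setClass("StabilityNetwork",
         representation(proportions = "matrix", adjacency = "matrix",
                        lambda = "numeric", pi = "numeric", score = "numeric",
                        K = "integer", frac = "numeric", blocks = "factor"))

setValidity("StabilityNetwork", function(object) {
    pr <- object@proportions
    ad <- object@adjacency
    if (!identical(dim(pr), dim(ad))) return("dimension mismatch")
    if (max(abs(pr - t(pr))) > 1e-8) return("proportions must be symmetric")
    if (any(pr < 0 | pr > 1)) return("proportions must lie in [0, 1]")
    if (any(diag(ad) != 0)) return("no self loops")
    if (length(object@pi) == 1L && (object@pi <= 0.5 || object@pi >= 1))
        return("threshold pi must lie in (0.5, 1)")
    if (any(ad & pr < object@pi - 1e-12))
        return("adjacency implies proportion >= pi")
    TRUE
})

#' @describeIn StabilityNetwork selection-proportion matrix.
#' @param x a `StabilityNetwork`.
#' @export
setMethod("selectionProportions", "StabilityNetwork",
          function(x) x@proportions)

#' @describeIn StabilityNetwork stable adjacency matrix (logical).
#' @param ... unused.
#' @export
setMethod("adjacency", "StabilityNetwork", function(x, ...) x@adjacency)

#' @describeIn StabilityNetwork edge table: `node1`, `node2`,
#'   `proportion`, `stable`, and `blockPair` for multiomic networks.
#' @export
setMethod("edgeList", "StabilityNetwork", function(x, ...) {
    pr <- x@proportions
    nodes <- rownames(pr)
    if (is.null(nodes)) nodes <- as.character(seq_len(nrow(pr)))
    idx <- which(upper.tri(pr) & (pr > 0 | x@adjacency), arr.ind = TRUE)
    out <- data.frame(node1 = nodes[idx[, 1L]], node2 = nodes[idx[, 2L]],
                      proportion = pr[idx], stable = x@adjacency[idx],
                      stringsAsFactors = FALSE)
    if (length(x@blocks) == nrow(pr)) {
        b <- as.character(x@blocks)
        out$blockPair <- paste(pmin(b[idx[, 1L]], b[idx[, 2L]]),
                               pmax(b[idx[, 1L]], b[idx[, 2L]]), sep = ":")
    }
    out[order(-out$proportion), , drop = FALSE]
})

setMethod("show", "StabilityNetwork", function(object) {
    p <- nrow(object@proportions)
    cat(class(object), ":", p, "nodes,",
        sum(object@adjacency[upper.tri(object@adjacency)]), "stable edges\n")
    lab <- if (is.null(names(object@lambda)))
        sprintf("%.4g", object@lambda)
    else sprintf("%s=%.4g", names(object@lambda), object@lambda)
    cat("lambda* =", paste(lab, collapse = ", "),
        "| pi* =", format(object@pi),
        "| K =", object@K, "x", format(object@frac), "subsamples\n")
})
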