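#' MethylWindowSet: windowed MeDIP/WGS counts with a CpG landscape
#'
#' An extension of \linkS4class{RangedSummarizedExperiment} holding, over one
#' shared grid of non-overlapping genome windows (rows) and one shared set of
#' samples (columns), the MeDIP-seq fragment counts (assay \code{"medip"}),
#' the matched WGS fragment counts (assay \code{"wgs"}), the per-window CpG
#' count (\code{rowData(x)$cpg}) and the per-sample group label
#' (\code{colData(x)$group}, \code{"low"} or \code{"high"}).
#'
#' @slot .. inherits all slots from RangedSummarizedExperiment.
#' @aliases MethylWindowSet-class
#' @exportClass MethylWindowSet
setClass("MethylWindowSet",
    contains = "RangedSummarizedExperiment")

setValidity("MethylWindowSet", function(object) {
    msg <- NULL
    an <- names(assays(object))
    if (!all(c("medip", "wgs") %in% an))
        msg <- c(msg, "assays 'medip' and 'wgs' are required")
    else {
        for (a in c("medip", "wgs")) {
            m <- assay(object, a)
            if (any(is.na(m)) || any(m < 0))
                msg <- c(msg, sprintf("assay '%s' has negative or NA entries", a))
        }
    }
    if (is.null(rowData(object)$cpg))
        msg <- c(msg, "rowData column 'cpg' (per-window CpG count) is required")
    else if (any(is.na(rowData(object)$cpg)) || any(rowData(object)$cpg < 0))
        msg <- c(msg, "rowData 'cpg' must be non-negative")
    grp <- colData(object)$group
    if (is.null(grp))
        msg <- c(msg, "colData column 'group' is required")
    else if (!all(as.character(grp) %in% GROUP_LEVELS))
        msg <- c(msg, "colData 'group' must be 'low' or 'high'")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MethylWindowSet
#'
#' @param medip,wgs integer matrices (windows x samples) of MeDIP-seq and WGS
#'   fragment counts, identically indexed.
#' @param cpg integer vector of CpG counts per window.
#' @param grid \code{GRanges} of the window grid (one range per row).
#' @param groups character/factor of \code{"low"}/\code{"high"} per sample.
#' @return A \linkS4class{MethylWindowSet}.
#' @examples
#' grid <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 100))
#' m <- matrix(rpois(8, 10), 2, dimnames = list(NULL, paste0("s", 1:4)))
#' w <- matrix(rpois(8, 10), 2, dimnames = list(NULL, paste0("s", 1:4)))
#' mws <- MethylWindowSet(m, w, cpg = c(2L, 0L), grid = grid,
#'                        groups = c("low", "low", "high", "high"))
#' @export
MethylWindowSet <- function(medip, wgs, cpg, grid, groups) {
    medip <- .assertCounts(medip)
    wgs <- .assertCounts(wgs)
    if (!identical(dim(medip), dim(wgs)))
        stop("'medip' and 'wgs' must have identical dimensions")
    if (length(cpg) != nrow(medip))
        stop("'cpg' must have one entry per window")
    if (length(grid) != nrow(medip))
        stop("'grid' must have one range per window")
    groups <- .assertGroups(groups)
    if (length(groups) != ncol(medip))
        stop("'groups' must have one label per sample")
    se <- SummarizedExperiment(
        assays = list(medip = medip, wgs = wgs),
        rowRanges = grid,
        colData = DataFrame(group = groups, row.names = colnames(medip)))
    rowData(se)$cpg <- as.integer(cpg)
    new("MethylWindowSet", se)
}

#' @rdname MethylWindowSet
#' @param x a \code{MethylWindowSet}.
#' @export
medipCounts <- function(x) assay(x, "medip")

#' @rdname MethylWindowSet
#' @export
wgsCounts <- function(x) assay(x, "wgs")

#' @rdname MethylWindowSet
#' @export
cpgCounts <- function(x) rowData(x)$cpg

#' @rdname MethylWindowSet
#' @export
sampleGroups <- function(x) {
    if (is(x, "SummarizedExperiment")) factor(colData(x)$group, GROUP_LEVELS)
    else if (is(x, "SnpGenotypes")) x@groups
    else .assertGroups(x)
}

setMethod("show", "MethylWindowSet", function(object) {
    cat("MethylWindowSet:", nrow(object), "windows x", ncol(object), "samples\n")
    tab <- table(sampleGroups(object))
    cat("  groups: low =", tab[["low"]], ", high =", tab[["high"]], "\n")
    cat("  CpG-free windows:",
        sprintf("%.1f%%", 100 * mean(rowData(object)$cpg == 0)), "\n")
    cat("  assays: medip, wgs\n")
})
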