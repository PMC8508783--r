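#' SnpGenotypes: biallelic genotype dosages for two groups
#'
#' Holds per-site alt-allele dosages (0/1/2, \code{NA} for missing) for all
#' samples, together with the site positions and the two-group design.
#' Sites are kept sorted by (chromosome, position).
#'
#' @slot positions \code{GRanges}, one 1-bp range per biallelic SNP.
#' @slot dosage integer matrix, sites x samples; entries 0, 1, 2 or NA.
#' @slot groups factor of \code{"low"}/\code{"high"} per sample.
#' @aliases SnpGenotypes-class
#' @exportClass SnpGenotypes
setClass("SnpGenotypes",
    slots = c(positions = "GRanges", dosage = "matrix", groups = "factor"))

setValidity("SnpGenotypes", function(object) {
    msg <- NULL
    if (length(object@positions) != nrow(object@dosage))
        msg <- c(msg, "one range per dosage row is required")
    if (ncol(object@dosage) != length(object@groups))
        msg <- c(msg, "one group label per dosage column is required")
    d <- object@dosage
    if (!all(d[!is.na(d)] %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (!all(levels(object@groups) == GROUP_LEVELS))
        msg <- c(msg, "groups must be a factor with levels low, high")
    if (length(object@positions) > 1L) {
        o <- order(as.integer(seqnames(object@positions)),
                   start(object@positions))
        if (!identical(o, seq_along(object@positions)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a SnpGenotypes object
#'
#' @param positions \code{GRanges} of SNP positions (width 1, 1-based).
#' @param dosage sites x samples matrix of alt-allele dosages (0/1/2/NA).
#' @param groups \code{"low"}/\code{"high"} label per sample.
#' @return A \linkS4class{SnpGenotypes}.
#' @export
SnpGenotypes <- function(positions, dosage, groups) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    groups <- .assertGroups(groups)
    o <- order(as.integer(seqnames(positions)), start(positions))
    new("SnpGenotypes", positions = positions[o],
        dosage = dosage[o, , drop = FALSE], groups = groups)
}

#' @rdname SnpGenotypes
#' @param x a \code{SnpGenotypes}.
#' @export
snpPositions <- function(x) x@positions

#' @rdname SnpGenotypes
#' @export
snpDosage <- function(x) x@dosage

setMethod("show", "SnpGenotypes", function(object) {
    tab <- table(object@groups)
    cat("SnpGenotypes:", nrow(object@dosage), "biallelic sites x",
        ncol(object@dosage), "samples",
        sprintf("(low = %d, high = %d)\n", tab[["low"]], tab[["high"]]))
    cat("  missing calls:",
        sprintf("%.2f%%", 100 * mean(is.na(object@dosage))), "\n")
})

setMethod("length", "SnpGenotypes", function(x) nrow(x@dosage))

setMethod("[", "SnpGenotypes", function(x, i, j, ..., drop = FALSE) {
    new("SnpGenotypes", positions = x@positions[i],
        dosage = x@dosage[i, , drop = FALSE], groups = x@groups)
})
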