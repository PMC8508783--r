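## Differentially methylated region calling: CPM filter, window-level NB
## exact test with q-values, merging into candidate regions, changepoint peak
## delineation, Wilcoxon peak testing, WGS confound filtering, annotation.

#' DmrResult: output of the DMR pipeline
#'
#' Bundles the tested windows, the merged candidate regions and the
#' delineated peaks, with the parameters used.
#'
#' @slot windows \code{GRanges} of tested windows with \code{p_value},
#'   \code{q_value}, \code{log2_fold_change}, \code{significant}.
#' @slot regions \code{GRanges} of candidate regions.
#' @slot peaks \code{GRanges} of delineated peaks with \code{wilcoxon_p},
#'   group medians, confound flags and \code{reported}.
#' @slot parameters list of pipeline parameters (incl. the fitted common
#'   dispersion and Storey \code{pi0}).
#' @aliases DmrResult-class
#' @exportClass DmrResult
setClass("DmrResult",
    slots = c(windows = "GRanges", regions = "GRanges", peaks = "GRanges",
              parameters = "list"))

setValidity("DmrResult", function(object) {
    msg <- NULL
    w <- mcols(object@windows)
    need <- c("p_value", "q_value", "log2_fold_change", "significant")
    if (!all(need %in% names(w)))
        msg <- c(msg, "windows must carry p_value, q_value, log2_fold_change, significant")
    else if (length(object@windows) &&
             !identical(w$significant,
                        w$q_value < object@parameters$q_max))
        msg <- c(msg, "significant flag must equal q_value < q_max (strict)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DmrResult-class
#' @param x a \code{DmrResult}.
#' @export
dmWindows <- function(x) x@windows

#' @rdname DmrResult-class
#' @export
dmRegions <- function(x) x@regions

#' @rdname DmrResult-class
#' @param onlyReported return only peaks that passed the Wilcoxon test and
#'   carry no confound flag.
#' @export
dmPeaks <- function(x, onlyReported = FALSE) {
    if (onlyReported && length(x@peaks) > 0)
        x@peaks[mcols(x@peaks)$reported]
    else x@peaks
}

setMethod("show", "DmrResult", function(object) {
    cat("DmrResult:", length(object@windows), "tested windows,",
        sum(mcols(object@windows)$significant), "significant (q <",
        object@parameters$q_max, ")\n")
    cat(" ", length(object@regions), "candidate regions;",
        length(object@peaks), "peaks,",
        sum(mcols(object@peaks)$reported), "reported\n")
    cat("  common dispersion:",
        signif(object@parameters$dispersion, 3),
        " pi0:", signif(object@parameters$pi0, 3), "\n")
})

#' Low-count window filter
#'
#' Keeps windows with at least \code{minCpm} counts-per-million in at least
#' \code{ceiling(minFraction * n_samples)} samples (both thresholds
#' inclusive).
#'
#' @param counts windows x samples MeDIP count matrix.
#' @param lib.sizes per-sample library sizes (default column sums).
#' @param minCpm CPM threshold (default 1).
#' @param minFraction fraction of samples (default 0.10).
#' @return Logical vector, \code{TRUE} for retained windows.
#' @export
lowCountFilter <- function(counts, lib.sizes = colSums(counts),
                           minCpm = 1, minFraction = 0.10) {
    cpm <- countsPerMillion(counts, lib.sizes)
    need <- ceiling(minFraction * ncol(counts))
    rowSums(cpm >= minCpm) >= need
}

#' Window-level differential-methylation test
#'
#' Composes TMM normalization, library equalization, robust common-dispersion
#' estimation, the conditional NB exact test and Storey q-values; windows with
#' \code{q < qMax} (strict) are flagged significant.
#'
#' @inheritParams lowCountFilter
#' @param groups \code{"low"}/\code{"high"} per sample.
#' @param qMax significance threshold on q-values (default 0.01, strict).
#' @return List with \code{table} (\code{data.frame}: p_value, q_value,
#'   log2_fold_change, significant), \code{dispersion}, \code{pi0},
#'   \code{norm_factors}.
#' @export
testWindows <- function(counts, groups, lib.sizes = colSums(counts),
                        qMax = 0.01) {
    counts <- .assertCounts(counts)
    groups <- .assertGroups(groups)
    nf <- tmmFactors(counts, lib.sizes)$factors
    disp <- estimateCommonDispersionRobust(counts, groups, lib.sizes, nf)
    et <- nbExactTest(counts, groups, disp$phi, lib.sizes, nf)
    qv <- storeyQvalues(et$p_value)
    tab <- data.frame(p_value = et$p_value,
                      q_value = qv$qvalues,
                      log2_fold_change = et$log2_fold_change)
    tab$significant <- tab$q_value < qMax
    list(table = tab, dispersion = disp$phi, pi0 = qv$pi0, norm_factors = nf)
}

#' Merge significant windows into candidate regions
#'
#' Chain-merges significant windows separated by strictly less than
#' \code{gap} bases; region bounds are the extremes of the member windows.
#'
#' @param sigWindows \code{GRanges} of the significant windows.
#' @param gap merge distance in bases (default 5000, strict).
#' @return \code{GRanges} of disjoint candidate regions with \code{n_windows}.
#' @export
mergeSignificantWindows <- function(sigWindows, gap = 5000) {
    if (length(sigWindows) == 0) return(GRanges())
    out <- reduce(sort(sigWindows), min.gapwidth = gap, with.revmap = TRUE)
    mcols(out)$n_windows <- lengths(mcols(out)$revmap)
    mcols(out)$revmap <- NULL
    out
}

## Window indices of `grid` overlapping `region`, extended by `flank`
## windows on each side within the chromosome.
.regionWindowIdx <- function(region, grid, flank) {
    idx <- which(countOverlaps(grid, region) > 0)
    chrom <- as.character(seqnames(grid)) == as.character(seqnames(region))
    lo <- max(min(idx) - flank, min(which(chrom)))
    hi <- min(max(idx) + flank, max(which(chrom)))
    lo:hi
}

#' Delineate methylation peaks inside a candidate region
#'
#' For each group, the per-window sum of normalized CPM over the region plus
#' a flank is segmented by \code{\link{segmentMeanVar}}; segments containing
#' at least one significant window are kept, and kept segments from the two
#' groups are merged when they overlap.
#'
#' @param region one candidate region (\code{GRanges} of length 1).
#' @param grid full window grid.
#' @param cpm normalized CPM matrix over the full grid.
#' @param groups \code{"low"}/\code{"high"} per sample.
#' @param sigIdx integer indices (into \code{grid}) of significant windows.
#' @param flank number of flanking windows added on each side (default 10).
#' @return \code{GRanges} of peak candidates (each contains a significant
#'   window).
#' @export
delineatePeaks <- function(region, grid, cpm, groups, sigIdx, flank = 10) {
    groups <- .assertGroups(groups)
    idx <- .regionWindowIdx(region, grid, flank)
    if (length(idx) < 4)                 # too short to segment: whole region
        return(granges(region))
    kept <- list()
    for (g in GROUP_LEVELS) {
        series <- rowSums(cpm[idx, groups == g, drop = FALSE])
        seg <- segmentMeanVar(series)
        ## a breakpoint-free group delineates nothing: its single all-span
        ## segment would only wash out the other group's boundaries
        if (length(seg$breakpoints) == 0) next
        bounds <- c(0, seg$breakpoints, length(idx))
        for (s in seq_len(length(bounds) - 1)) {
            segIdx <- idx[(bounds[s] + 1):bounds[s + 1]]
            if (any(segIdx %in% sigIdx)) {
                kept <- c(kept, GRanges(seqnames(region),
                                        IRanges(start(grid)[segIdx[1]],
                                                end(grid)[segIdx[length(segIdx)]])))
            }
        }
    }
    if (length(kept) == 0) return(granges(region))
    reduce(sort(do.call(c, kept)))     # merge overlapping segments across groups
}

#' Wilcoxon test of a peak's group difference
#'
#' Per-sample statistic is the sum of normalized CPM over the peak's windows;
#' the two groups are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param peakIdx integer indices (into the grid) of the peak's windows.
#' @param cpm normalized CPM matrix over the full grid.
#' @param groups \code{"low"}/\code{"high"} per sample.
#' @return List with \code{p_value}, \code{median_low}, \code{median_high}.
#' @export
peakGroupDifference <- function(peakIdx, cpm, groups) {
    groups <- .assertGroups(groups)
    sums <- colSums(cpm[peakIdx, , drop = FALSE])
    w <- wilcoxonRankSum(sums[groups == "low"], sums[groups == "high"])
    list(p_value = w$p_value,
         median_low = median(sums[groups == "low"]),
         median_high = median(sums[groups == "high"]))
}

#' WGS-coverage confound filter for a peak
#'
#' Flags a peak whose MeDIP signal tracks the DNA (WGS) coverage, the
#' signature of copy-number or repeat polymorphism rather than methylation:
#' (i) \code{wgs_group_diff} if the per-sample WGS CPM sums over the peak
#' differ between groups (Wilcoxon, p < \code{alpha}); (ii)
#' \code{medip_wgs_correlated} if the per-sample MeDIP and WGS sums are
#' positively Spearman-correlated (p < \code{alpha}, rho > 0). The peak is
#' discarded when either flag is set.
#'
#' @inheritParams peakGroupDifference
#' @param cpmWgs normalized WGS CPM matrix over the full grid.
#' @param alpha flag significance level (default 0.05).
#' @return List with \code{keep}, \code{wgs_group_diff},
#'   \code{medip_wgs_correlated}.
#' @export
wgsConfoundFilter <- function(peakIdx, cpm, cpmWgs, groups, alpha = 0.05) {
    groups <- .assertGroups(groups)
    medipSums <- colSums(cpm[peakIdx, , drop = FALSE])
    wgsSums <- colSums(cpmWgs[peakIdx, , drop = FALSE])
    wg <- wilcoxonRankSum(wgsSums[groups == "low"], wgsSums[groups == "high"])
    flagDiff <- wg$p_value < alpha
    ct <- suppressWarnings(
        cor.test(medipSums, wgsSums, method = "spearman"))
    flagCor <- !is.na(ct$p.value) && ct$p.value < alpha && ct$estimate > 0
    list(keep = !(flagDiff || flagCor),
         wgs_group_diff = flagDiff, medip_wgs_correlated = unname(flagCor))
}

#' Annotate peaks with overlapping genes
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes \code{GRanges} of gene models with \code{gene_id}.
#' @return \code{peaks} with a \code{CharacterList} column \code{genes};
#'   intergenic peaks get an empty list.
#' @export
annotatePeaks <- function(peaks, genes) genesOverlappingRegions(peaks, genes)

#' Call differentially methylated regions
#'
#' Runs the full DMR procedure on a \linkS4class{MethylWindowSet}: low-count
#' filtering, window-level NB exact testing with Storey q-values, merging of
#' significant windows into candidate regions, changepoint peak delineation,
#' Wilcoxon peak testing and WGS confound filtering, with optional gene
#' annotation. A peak is reported when its Wilcoxon p-value is below
#' \code{peakAlpha} and no confound flag is set.
#'
#' @param mws a \linkS4class{MethylWindowSet}.
#' @param genes optional \code{GRanges} of gene models.
#' @param qMax window significance threshold on q-values (default 0.01).
#' @param gap merge distance for significant windows (default 5000).
#' @param minCpm,minFraction low-count filter parameters (defaults 1, 0.10).
#' @param flank flank width, in windows, for peak delineation (default 10).
#' @param peakAlpha Wilcoxon significance level for peaks (default 0.05).
#' @param confoundAlpha significance level of the confound sub-tests
#'   (default 0.05).
#' @return A \linkS4class{DmrResult}.
#' @export
callDmrs <- function(mws, genes = NULL, qMax = 0.01, gap = 5000,
                     minCpm = 1, minFraction = 0.10, flank = 10,
                     peakAlpha = 0.05, confoundAlpha = 0.05) {
    stopifnot(is(mws, "MethylWindowSet"))
    medip <- medipCounts(mws)
    wgs <- wgsCounts(mws)
    grid <- rowRanges(mws)
    groups <- sampleGroups(mws)
    libAll <- colSums(medip)

    keep <- lowCountFilter(medip, libAll, minCpm, minFraction)
    tw <- testWindows(medip[keep, , drop = FALSE], groups, libAll, qMax)

    windows <- granges(grid[keep])
    mcols(windows) <- DataFrame(tw$table)

    ## normalized CPM over the full grid (factors from the filtered matrix)
    cpmM <- countsPerMillion(medip, libAll * tw$norm_factors)
    fW <- tmmFactors(wgs)$factors
    cpmW <- countsPerMillion(wgs, colSums(wgs) * fW)

    sigIdx <- which(keep)[tw$table$significant]
    regions <- mergeSignificantWindows(windows[tw$table$significant], gap)

    peakList <- lapply(seq_along(regions), function(i)
        delineatePeaks(regions[i], grid, cpmM, groups, sigIdx, flank))
    peaks <- if (length(peakList) > 0) do.call(c, peakList) else GRanges()
    if (length(peaks) > 0) {
        peaks <- reduce(sort(peaks))
        stats <- lapply(seq_along(peaks), function(i) {
            pidx <- which(countOverlaps(grid, peaks[i]) > 0)
            gd <- peakGroupDifference(pidx, cpmM, groups)
            cf <- wgsConfoundFilter(pidx, cpmM, cpmW, groups, confoundAlpha)
            c(gd, cf)
        })
        mcols(peaks)$wilcoxon_p <- vapply(stats, `[[`, numeric(1), "p_value")
        mcols(peaks)$median_low <- vapply(stats, `[[`, numeric(1), "median_low")
        mcols(peaks)$median_high <- vapply(stats, `[[`, numeric(1), "median_high")
        mcols(peaks)$wgs_group_diff <-
            vapply(stats, `[[`, logical(1), "wgs_group_diff")
        mcols(peaks)$medip_wgs_correlated <-
            vapply(stats, `[[`, logical(1), "medip_wgs_correlated")
        mcols(peaks)$reported <- mcols(peaks)$wilcoxon_p < peakAlpha &
            !mcols(peaks)$wgs_group_diff & !mcols(peaks)$medip_wgs_correlated
        if (!is.null(genes)) peaks <- annotatePeaks(peaks, genes)
    }
    new("DmrResult", windows = windows, regions = regions, peaks = peaks,
        parameters = list(q_max = qMax, gap = gap, min_cpm = minCpm,
                          min_fraction = minFraction, flank = flank,
                          peak_alpha = peakAlpha,
                          confound_alpha = confoundAlpha,
                          dispersion = tw$dispersion, pi0 = tw$pi0))
}
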