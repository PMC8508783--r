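## Genome tiling, fragment counting with multicov semantics, CpG counting
## from the reference, sample-correlation QC, ratio normalization and
## outlier-window removal.

#' Tile a genome into non-overlapping windows
#'
#' @param chromLengths named vector of chromosome lengths.
#' @param width window width in bases (default 100); the trailing window on
#'   each chromosome may be shorter.
#' @return \code{GRanges} of the window grid, in genome order.
#' @export
tileWindows <- function(chromLengths, width = 100) {
    if (any(chromLengths < 1)) stop("chromosome lengths must be >= 1")
    si <- Seqinfo(names(chromLengths), unname(chromLengths))
    tileGenome(si, tilewidth = width, cut.last.tile.in.chrom = TRUE)
}

#' Count fragments per window (multicov semantics)
#'
#' A fragment increments every window it overlaps by at least one base.
#' Fragments on chromosomes absent from the grid are skipped with a message.
#'
#' @param fragments a named list, one \code{GRanges} of fragment intervals per
#'   sample (or paths to BED files, read with \code{rtracklayer}).
#' @param grid window grid from \code{\link{tileWindows}}.
#' @return Integer matrix, windows x samples.
#' @export
countFragmentsInWindows <- function(fragments, grid) {
    counts <- vapply(seq_along(fragments), function(j) {
        fr <- fragments[[j]]
        if (is.character(fr)) fr <- import(fr, format = "bed")
        unknown <- !(as.character(seqnames(fr)) %in%
                     as.character(unique(seqnames(grid))))
        if (any(unknown)) {
            message(sum(unknown), " fragment(s) on unknown chromosome skipped")
            fr <- fr[!unknown]
        }
        ## suppress the benign seqinfo-merge notice for partial seqlevel sets
        suppressWarnings(
            countOverlaps(grid, fr, minoverlap = 1L, ignore.strand = TRUE))
    }, integer(length(grid)))
    colnames(counts) <- names(fragments)
    counts
}

#' Count CpG dinucleotides per window
#'
#' Counts \code{"CG"} occurrences (case-insensitive; \code{N} breaks a
#' dinucleotide) whose C lies inside the window, so a CpG straddling a window
#' boundary is assigned to the window containing the C.
#'
#' @param fasta a \code{DNAStringSet} or a path to a FASTA file.
#' @param grid window grid; all its chromosomes must be present in the FASTA.
#' @return Integer vector of CpG counts, one per window.
#' @export
countCpgPerWindow <- function(fasta, grid) {
    if (is.character(fasta)) fasta <- readDNAStringSet(fasta)
    names(fasta) <- sub("\\s.*$", "", names(fasta))
    chroms <- as.character(unique(seqnames(grid)))
    if (!all(chroms %in% names(fasta)))
        stop("chromosome(s) missing from FASTA: ",
             paste(setdiff(chroms, names(fasta)), collapse = ", "))
    hits <- vmatchPattern("CG", fasta[chroms], fixed = TRUE)
    cg <- GRanges(rep(chroms, lengths(hits)),
                  IRanges(start = unlist(lapply(hits, start)), width = 1L))
    countOverlaps(grid, cg, ignore.strand = TRUE)
}

#' Pairwise sample-correlation quality control
#'
#' Pearson correlations of per-window counts between all sample pairs; a
#' sample passes only if its correlation with every other sample is strictly
#' greater than \code{minR}. Zero-variance samples are flagged (their
#' correlations are undefined).
#'
#' @param counts windows x samples matrix.
#' @param minR pass threshold (default 0.6, strict).
#' @return List with \code{correlations} (full matrix), \code{flagged}
#'   (character vector of failing samples), \code{pass} (logical per sample).
#' @export
sampleCorrelationQc <- function(counts, minR = 0.6) {
    counts <- .assertCounts(counts)
    if (ncol(counts) < 2L) stop("at least two samples are required")
    zeroVar <- apply(counts, 2L, function(v) var(v) == 0)
    cc <- suppressWarnings(cor(counts, method = "pearson"))
    diag(cc) <- NA
    ## strict "> minR": a correlation at the threshold fails; the 1e-12 guard
    ## makes the boundary decision immune to floating-point noise
    pass <- apply(cc, 2L, function(v) all(v[!is.na(v)] > minR + 1e-12)) &
        !zeroVar & colSums(!is.na(cc)) > 0
    nm <- colnames(counts)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(counts)))
    list(correlations = cc, flagged = nm[!pass], pass = unname(pass))
}

#' CpG-methylation correlation across windows
#'
#' Pearson correlation, over windows, between the CpG count and the total
#' MeDIP-seq count (summed over samples), with a two-sided test.
#'
#' @param cpg integer vector of per-window CpG counts.
#' @param medip windows x samples MeDIP count matrix (or a pre-summed
#'   vector).
#' @return List with \code{r} and \code{p_value}.
#' @export
cpgMethylationCorrelation <- function(cpg, medip) {
    tot <- if (is.matrix(medip)) rowSums(medip) else medip
    if (length(cpg) != length(tot)) stop("window indices must match")
    if (length(cpg) < 3) stop("at least 3 windows are required")
    ct <- cor.test(cpg, tot, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Methylation-to-coverage ratio track
#'
#' TMM-normalized CPM is computed separately for the MeDIP and the WGS
#' matrices; the per-(window, sample) ratio \code{(medipCPM + 0.5) /
#' (wgsCPM + 0.5)} is returned rounded to two decimals. The pseudocount
#' guards zero coverage.
#'
#' @param medip,wgs count matrices on the same grid and samples.
#' @return Non-negative real matrix of rounded ratios.
#' @export
normalizeAndRatio <- function(medip, wgs) {
    if (!identical(dim(medip), dim(wgs)))
        stop("'medip' and 'wgs' must share grid and samples")
    fM <- tmmFactors(medip)$factors
    fW <- tmmFactors(wgs)$factors
    cpmM <- countsPerMillion(medip, colSums(medip) * fM)
    cpmW <- countsPerMillion(wgs, colSums(wgs) * fW)
    round((cpmM + 0.5) / (cpmW + 0.5), 2)
}

#' Remove outlier windows with runaway MeDIP totals
#'
#' Computes the per-window total TMM-normalized MeDIP count and, scanning the
#' totals in descending order, removes leading windows while each exceeds
#' \code{factor} times the next-ranked remaining total (PCR or alignment
#' artefacts).
#'
#' @param medip windows x samples MeDIP count matrix.
#' @param factor multiplier defining "times more than the others"
#'   (default 10).
#' @return List with \code{keep} (logical per window) and \code{removed}
#'   (integer indices of removed windows, in removal order).
#' @export
removeOutlierWindows <- function(medip, factor = 10) {
    medip <- .assertCounts(medip)
    if (factor <= 1) stop("factor must be > 1")
    f <- tmmFactors(medip)$factors
    tot <- rowSums(countsPerMillion(medip, colSums(medip) * f))
    o <- order(tot, decreasing = TRUE)
    removed <- integer(0)
    i <- 1
    while (i < length(o) && tot[o[i]] > factor * tot[o[i + 1]]) {
        removed <- c(removed, o[i])
        i <- i + 1
    }
    keep <- rep(TRUE, length(tot))
    keep[removed] <- FALSE
    list(keep = keep, removed = removed)
}

#' Assemble a MethylWindowSet from raw inputs
#'
#' Tiles the genome, counts MeDIP and WGS fragments per window with multicov
#' semantics, counts CpGs from the reference, and bundles everything with the
#' group design.
#'
#' @param medipFragments,wgsFragments named lists of per-sample fragment
#'   \code{GRanges} (or BED paths), same sample order.
#' @param fasta reference sequences (\code{DNAStringSet} or FASTA path).
#' @param chromLengths named vector of chromosome lengths.
#' @param groups \code{"low"}/\code{"high"} per sample.
#' @param width window width (default 100).
#' @return A \linkS4class{MethylWindowSet}.
#' @export
buildMethylWindowSet <- function(medipFragments, wgsFragments, fasta,
                                 chromLengths, groups, width = 100) {
    grid <- tileWindows(chromLengths, width)
    medip <- countFragmentsInWindows(medipFragments, grid)
    wgs <- countFragmentsInWindows(wgsFragments, grid)
    cpg <- countCpgPerWindow(fasta, grid)
    MethylWindowSet(medip, wgs, cpg, grid, groups)
}
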