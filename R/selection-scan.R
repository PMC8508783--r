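## Per-SNP Weir-Cockerham FST scan between the two environmental groups,
## variant filtering, top-quantile selection and candidate-region building.

#' Load biallelic SNP genotypes from a VCF
#'
#' Reads a VCF (plain or gzipped), keeps biallelic SNPs only, encodes
#' genotypes as alt-allele dosages (0/1/2, NA for missing) and attaches the
#' two-group design from a sample sheet.
#'
#' @param vcfPath path to a VCF file.
#' @param sampleSheet \code{data.frame} with columns \code{sample_id} and
#'   \code{group} (\code{"low"}/\code{"high"}), or a path to such a TSV.
#' @return A \linkS4class{SnpGenotypes}; the number of skipped multiallelic
#'   or non-SNP records is recorded in a message.
#' @export
loadBiallelicSites <- function(vcfPath, sampleSheet) {
    if (is.character(sampleSheet))
        sampleSheet <- read.table(sampleSheet, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% names(sampleSheet)))
        stop("sample sheet needs columns 'sample_id' and 'group'")
    vcf <- read.vcfR(vcfPath, verbose = FALSE)
    vcfSamples <- colnames(vcf@gt)[-1]
    missing <- setdiff(sampleSheet$sample_id, vcfSamples)
    if (length(missing) > 0)
        stop("samples in sheet absent from VCF: ",
             paste(missing, collapse = ", "))
    fix <- getFIX(vcf)
    isSnp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
        !grepl(",", fix[, "ALT"], fixed = TRUE)
    keep <- is.biallelic(vcf) & isSnp
    nSkipped <- sum(!keep)
    if (nSkipped > 0)
        message(nSkipped, " multiallelic or non-SNP record(s) skipped")
    vcf <- vcf[keep, ]
    fix <- getFIX(vcf)
    gt <- extract.gt(vcf, element = "GT")
    gt <- gt[, sampleSheet$sample_id, drop = FALSE]
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dos[clean %in% c("0/0")] <- 0L
    dos[clean %in% c("0/1", "1/0")] <- 1L
    dos[clean %in% c("1/1")] <- 2L
    pos <- GRanges(fix[, "CHROM"],
                   IRanges(as.integer(fix[, "POS"]), width = 1L))
    SnpGenotypes(pos, dos, sampleSheet$group)
}

#' Filter variants on missingness and minor allele frequency
#'
#' Keeps sites whose missing-call fraction is strictly below
#' \code{maxMissing} and whose minor allele frequency, computed over the
#' non-missing alleles of all samples pooled, is strictly above
#' \code{minMaf}.
#'
#' @param snp a \linkS4class{SnpGenotypes}.
#' @param maxMissing,minMaf thresholds in (0, 1); defaults 0.30 and 0.01.
#' @return The filtered \linkS4class{SnpGenotypes}.
#' @export
filterVariants <- function(snp, maxMissing = 0.30, minMaf = 0.01) {
    stopifnot(is(snp, "SnpGenotypes"))
    d <- snpDosage(snp)
    missFrac <- rowMeans(is.na(d))
    altFreq <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
    maf <- pmin(altFreq, 1 - altFreq)
    snp[which(missFrac < maxMissing & maf > minMaf)]
}

## Weir & Cockerham (1984) per-site variance components for r = 2
## populations, vectorized over sites. nI: matrix of per-group non-missing
## sample sizes; pI: per-group alt frequencies; hI: per-group observed
## heterozygote frequencies.
.wcComponents <- function(nI, pI, hI) {
    r <- 2
    nBar <- rowMeans(nI)
    nTot <- rowSums(nI)
    nC <- (nTot - rowSums(nI^2) / nTot) / (r - 1)
    pBar <- rowSums(nI * pI) / nTot
    s2 <- rowSums(nI * (pI - pBar)^2) / ((r - 1) * nBar)
    hBar <- rowSums(nI * hI) / nTot
    a <- nBar / nC *
        (s2 - (pBar * (1 - pBar) - (r - 1) / r * s2 - hBar / 4) / (nBar - 1))
    b <- nBar / (nBar - 1) *
        (pBar * (1 - pBar) - (r - 1) / r * s2 - (2 * nBar - 1) / (4 * nBar) * hBar)
    cc <- hBar / 2
    list(a = a, b = b, c = cc)
}

#' Per-SNP Weir-Cockerham FST
#'
#' The Weir & Cockerham (1984) two-level estimator with the heterozygosity
#' term, between the \code{"low"} and \code{"high"} groups: variance
#' components \code{a} (among populations), \code{b} (among individuals
#' within populations) and \code{c} (within individuals), with
#' \eqn{F_{ST} = a / (a + b + c)}. Negative estimates are retained; the
#' estimate is \code{NA} (undefined) when the denominator is zero or a group
#' has no non-missing call.
#'
#' @param snp a \linkS4class{SnpGenotypes}.
#' @return \code{GRanges} of the sites with metadata columns \code{a},
#'   \code{b}, \code{c}, \code{fst}.
#' @export
weirCockerhamFst <- function(snp) {
    stopifnot(is(snp, "SnpGenotypes"))
    d <- snpDosage(snp)
    g <- sampleGroups(snp)
    nI <- pI <- hI <- matrix(0, nrow(d), 2)
    for (k in 1:2) {
        dk <- d[, g == GROUP_LEVELS[k], drop = FALSE]
        nI[, k] <- rowSums(!is.na(dk))
        pI[, k] <- rowSums(dk, na.rm = TRUE) / (2 * nI[, k])
        hI[, k] <- rowSums(dk == 1L, na.rm = TRUE) / nI[, k]
    }
    comp <- .wcComponents(nI, pI, hI)
    denom <- comp$a + comp$b + comp$c
    fst <- ifelse(denom == 0, NA_real_, comp$a / denom)
    bad <- nI[, 1] == 0 | nI[, 2] == 0
    fst[bad] <- NA_real_
    gr <- granges(snpPositions(snp))
    mcols(gr) <- DataFrame(a = comp$a, b = comp$b, c = comp$c, fst = fst)
    gr
}

#' Top-quantile FST threshold
#'
#' The smallest value such that the number of sites with \code{fst >=
#' threshold} is \code{ceiling(m * topFraction)}, where \code{m} counts sites
#' with a defined estimate; ties at the threshold are all retained.
#'
#' @param fst numeric FST values (or the \code{GRanges} from
#'   \code{\link{weirCockerhamFst}}); \code{NA}s (undefined) are excluded.
#' @param topFraction fraction in (0, 1), e.g. \code{0.00025} for the top
#'   0.025\%.
#' @return The threshold value.
#' @export
fstQuantileThreshold <- function(fst, topFraction) {
    if (is(fst, "GRanges")) fst <- mcols(fst)$fst
    fst <- fst[!is.na(fst)]
    if (length(fst) == 0) stop("no defined FST values")
    if (topFraction <= 0 || topFraction >= 1)
        stop("topFraction must lie in (0, 1)")
    kTop <- ceiling(length(fst) * topFraction)
    sort(fst, decreasing = TRUE)[kTop]
}

#' Build candidate regions from top SNP positions
#'
#' Chain-merges SNPs whose inter-SNP distance is strictly less than
#' \code{mergeDist}, pads each resulting interval by \code{pad} bases on both
#' sides, clips to the chromosome, and re-merges overlaps created by the
#' padding. Output regions are sorted, disjoint, 0-based half-open.
#'
#' @param positions \code{GRanges} of SNP positions (1-based, width 1).
#' @param mergeDist merge SNPs closer than this many bases (default 5000).
#' @param pad bases added on each side of a merged interval (default 2500).
#' @param chromLengths named vector of chromosome lengths.
#' @return \code{GRanges} of disjoint candidate regions with metadata column
#'   \code{n_snps}.
#' @export
buildCandidateRegions <- function(positions, mergeDist = 5000, pad = 2500,
                                  chromLengths) {
    if (any(end(positions) > chromLengths[as.character(seqnames(positions))]))
        stop("a position lies beyond its chromosome length")
    positions <- sort(positions)
    ## chain-merge: gap between consecutive SNPs < mergeDist (strict);
    ## reduce() merges ranges with gapwidth <= min.gapwidth, so use -1.
    merged <- reduce(positions, min.gapwidth = mergeDist - 1,
                     with.revmap = TRUE)
    nSnps <- lengths(mcols(merged)$revmap)
    padded <- GRanges(seqnames(merged),
                      IRanges(pmax(start(merged) - pad, 1),
                              pmin(end(merged) + pad,
                                   chromLengths[as.character(seqnames(merged))])))
    mcols(padded)$n_snps <- nSnps
    ## re-merge only true overlaps created by the padding (not adjacency)
    out <- reduce(padded, min.gapwidth = 0L, with.revmap = TRUE)
    mcols(out)$n_snps <- vapply(mcols(out)$revmap,
                                function(i) sum(nSnps[i]), integer(1))
    mcols(out)$revmap <- NULL
    sort(out)
}

#' Read gene models from a GFF3 file
#'
#' @param gffPath path to a GFF3 file; features of type \code{"gene"} are
#'   retained.
#' @return \code{GRanges} with metadata column \code{gene_id}.
#' @export
readGenesGff <- function(gffPath) {
    gr <- import(gffPath, format = "gff3")
    gr <- gr[gr$type == "gene"]
    id <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
    out <- granges(gr)
    mcols(out)$gene_id <- as.character(id)
    out
}

#' Annotate regions with overlapping genes
#'
#' A gene is attached to a region iff their intervals share at least one
#' base; regions without genes are reported with an empty gene list
#' (intergenic).
#'
#' @param regions \code{GRanges} of regions.
#' @param genes \code{GRanges} of gene models with metadata column
#'   \code{gene_id}.
#' @return \code{regions} with an added \code{CharacterList} column
#'   \code{genes}.
#' @export
genesOverlappingRegions <- function(regions, genes) {
    hits <- findOverlaps(regions, genes, minoverlap = 1L)
    lst <- split(mcols(genes)$gene_id[subjectHits(hits)],
                 factor(queryHits(hits), levels = seq_along(regions)))
    mcols(regions)$genes <- CharacterList(lst)
    regions
}

#' Run the full selection scan
#'
#' Filters variants, computes per-SNP Weir-Cockerham FST, selects the top
#' \code{topFraction} of sites, builds merge-and-pad candidate regions and
#' annotates them with overlapping genes.
#'
#' @inheritParams filterVariants
#' @inheritParams buildCandidateRegions
#' @param genes \code{GRanges} of gene models (see \code{\link{readGenesGff}}).
#' @param topFraction top FST quantile retained (default 0.001, i.e. top
#'   0.1\%).
#' @return List with \code{fst} (per-site \code{GRanges}), \code{threshold},
#'   \code{regions} (annotated candidate regions).
#' @export
selectionScan <- function(snp, genes, chromLengths, topFraction = 0.001,
                          mergeDist = 5000, pad = 2500,
                          maxMissing = 0.30, minMaf = 0.01) {
    snp <- filterVariants(snp, maxMissing, minMaf)
    fst <- weirCockerhamFst(snp)
    thr <- fstQuantileThreshold(fst, topFraction)
    top <- fst[!is.na(fst$fst) & fst$fst >= thr]
    regions <- buildCandidateRegions(granges(top), mergeDist, pad, chromLengths)
    regions <- genesOverlappingRegions(regions, genes)
    list(fst = fst, threshold = thr, regions = regions)
}
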