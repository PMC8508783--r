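## Plain-text interchange: VCF genotype output for simulated data, window
## count TSVs, per-SNP FST TSV and BED region export (0-based half-open).

#' Write simulated genotypes as a VCF
#'
#' Minimal VCFv4.2 with GT-only genotype fields; dosage 0/1/2 becomes
#' 0/0, 0/1, 1/1 and missing becomes ./. .
#'
#' @param snp a \linkS4class{SnpGenotypes}.
#' @param path output path.
#' @param chromLengths named chromosome lengths for the contig header lines.
#' @export
writeSnpVcf <- function(snp, path, chromLengths) {
    d <- snpDosage(snp)
    pos <- snpPositions(snp)
    gtMap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtMap[as.character(d[ok])]
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", names(chromLengths),
                        as.integer(chromLengths)),
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- paste(as.character(seqnames(pos)), start(pos), ".", "A", "G",
                  ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
}

#' Write / read a window count matrix as TSV
#'
#' Columns: \code{chrom}, \code{start} (0-based), \code{end}, then one column
#' per sample.
#'
#' @param counts windows x samples matrix.
#' @param grid window \code{GRanges}.
#' @param path file path.
#' @export
writeWindowCounts <- function(counts, grid, path) {
    df <- data.frame(chrom = as.character(seqnames(grid)),
                     start = start(grid) - 1L, end = end(grid))
    df <- cbind(df, as.data.frame(counts))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeWindowCounts
#' @return \code{readWindowCounts}: list with \code{counts} and \code{grid}.
#' @export
readWindowCounts <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    grid <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    counts <- as.matrix(df[, -(1:3), drop = FALSE])
    list(counts = counts, grid = grid)
}

#' Export regions as BED (0-based half-open)
#'
#' @param regions \code{GRanges}.
#' @param path output path.
#' @export
exportRegionsBed <- function(regions, path) {
    df <- data.frame(as.character(seqnames(regions)),
                     start(regions) - 1L, end(regions))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
}

#' Write the per-SNP FST table as TSV
#'
#' @param fst \code{GRanges} from \code{\link{weirCockerhamFst}}.
#' @param path output path.
#' @export
writeFstTsv <- function(fst, path) {
    df <- data.frame(chrom = as.character(seqnames(fst)), pos = start(fst),
                     a = fst$a, b = fst$b, c = fst$c, fst = fst$fst)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
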