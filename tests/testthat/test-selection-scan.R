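## small VCF fixture written in code: 3 samples, 4 records, one multiallelic
makeVcfFixture <- function(path) {
    lines <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1,length=100000>",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
        "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
        "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1\t0/0",
        "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0\t0/1",
        "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0\t0/0")
    writeLines(lines, path)
    path
}

test_that("VCF loading encodes dosages and drops non-biallelic-SNP records", {
    vcf <- makeVcfFixture(withr::local_tempfile(fileext = ".vcf"))
    sheet <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        group = c("low", "low", "high", "high"))
    snp <- suppressMessages(loadBiallelicSites(vcf, sheet))
    d <- snpDosage(snp)
    expect_equal(nrow(d), 2)       # multiallelic and indel records skipped
    expect_equal(unname(d[1, ]), c(0L, 1L, 2L, NA))
    expect_equal(unname(d[2, ]), c(1L, 2L, 0L, 1L))   # phased bars handled
    expect_error(
        suppressMessages(loadBiallelicSites(
            vcf, data.frame(sample_id = "nope", group = "low"))),
        "absent")
})

test_that("variant filter applies strict missingness and MAF rules", {
    pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3 * 100, width = 1))
    groups <- rep(c("low", "high"), each = 5)
    d <- rbind(c(rep(NA, 4), rep(0L, 6)),          # 40% missing -> out
               c(1L, rep(0L, 9)),                  # MAF 0.05, kept
               rep(c(0L, 2L), 5))                  # MAF 0.5, kept
    snp <- SnpGenotypes(pos, d, groups)
    kept <- filterVariants(snp, maxMissing = 0.30, minMaf = 0.01)
    expect_equal(length(kept), 2)
    ## MAF exactly at the threshold is removed ("above" is strict)
    d2 <- rbind(rep(0:1, c(49, 1)), rep(c(0L, 2L), 25))
    snp2 <- SnpGenotypes(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1)),
        d2, rep(c("low", "high"), 25))
    expect_equal(length(filterVariants(snp2, minMaf = 0.01)), 1)
})

test_that("Weir-Cockerham FST hits closed cases and the formula oracle", {
    pos1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, width = 1))
    groups <- rep(c("low", "high"), each = 10)
    fixedDiff <- SnpGenotypes(pos1, matrix(rep(c(0L, 2L), each = 10), 1),
                              groups)
    expect_equal(weirCockerhamFst(fixedDiff)$fst, 1.0)

    same <- SnpGenotypes(pos1, matrix(rep(c(0L, 1L, 1L, 2L, 0L), 4), 1),
                         groups)
    expect_lte(weirCockerhamFst(same)$fst, 0)

    set.seed(40)
    n <- 100
    d <- matrix(sample(c(0:2, NA), n * 20, replace = TRUE,
                       prob = c(0.4, 0.3, 0.25, 0.05)), n, 20)
    snp <- SnpGenotypes(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(seq_len(n) * 50,
                                                        width = 1)),
        d, groups)
    fst <- weirCockerhamFst(snp)
    for (i in seq_len(n)) {
        o <- wcFstOracle(d[i, 1:10], d[i, 11:20])
        expect_equal(fst$a[i], o$a, tolerance = 1e-9)
        expect_equal(fst$b[i], o$b, tolerance = 1e-9)
        expect_equal(fst$c[i], o$c, tolerance = 1e-9)
        if (is.na(o$fst)) expect_true(is.na(fst$fst[i]))
        else expect_equal(fst$fst[i], o$fst, tolerance = 1e-9)
    }
})

test_that("top-quantile threshold follows the ceiling-and-ties rule", {
    set.seed(41)
    v <- sample(seq(0, 1, length.out = 10000))
    thr <- fstQuantileThreshold(v, 0.01)
    expect_equal(sum(v >= thr), 100)
    expect_equal(thr, sort(v, decreasing = TRUE)[100])
    expect_equal(fstQuantileThreshold(rep(0.3, 50), 0.1), 0.3)
    expect_equal(sum(rep(0.3, 50) >= fstQuantileThreshold(rep(0.3, 50), 0.1)),
                 50)  # ties all retained
    expect_error(fstQuantileThreshold(NA_real_, 0.1), "no defined")
})

test_that("candidate regions follow the merge-and-pad rules", {
    cl <- c(chr1 = 2e6)
    oneSnp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, width = 1))
    r1 <- buildCandidateRegions(oneSnp, chromLengths = cl)
    expect_equal(GenomicRanges::start(r1), 7500)
    expect_equal(GenomicRanges::end(r1), 12500)

    two <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(100000, 104500), width = 1))
    r2 <- buildCandidateRegions(two, chromLengths = cl)
    expect_equal(length(r2), 1)
    expect_equal(GenomicRanges::start(r2), 97500)
    expect_equal(GenomicRanges::end(r2), 107000)
    expect_equal(r2$n_snps, 2L)

    ## distance exactly mergeDist is not chain-merged (strict "closer than"),
    ## but the two padded intervals share one base and re-merge
    apart <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(50000, 55000), width = 1))
    rA <- buildCandidateRegions(apart, chromLengths = cl)
    expect_equal(length(rA), 1)
    expect_equal(GenomicRanges::start(rA), 47500)
    expect_equal(GenomicRanges::end(rA), 57500)
    ## one base further: padded intervals are merely adjacent and stay apart
    apart2 <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(50000, 55001), width = 1))
    expect_equal(length(buildCandidateRegions(apart2, chromLengths = cl)), 2)
    expect_error(buildCandidateRegions(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(3e6, width = 1)),
        chromLengths = cl), "beyond")
})

test_that("region building matches the naive interval-union oracle", {
    set.seed(42)
    cl <- c(chr1 = 1e6)
    for (rep in 1:50) {
        pos <- sort(sample(1e6, sample(5:80, 1)))
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
        got <- buildCandidateRegions(gr, chromLengths = cl)
        want <- mergePadOracle(pos, 5000, 2500, 1e6)
        expect_equal(GenomicRanges::start(got), want[, 1])
        expect_equal(GenomicRanges::end(got), want[, 2])
        ## disjoint and sorted
        expect_true(all(GenomicRanges::start(got)[-1] >
                        GenomicRanges::end(got)[-length(got)]))
    }
})

test_that("gene overlap annotation uses the 1-bp rule", {
    genes <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(100, 500, 2000),
                                                     width = c(100, 100, 100)))
    genes$gene_id <- c("inside", "edge", "far")
    regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 500))
    ann <- genesOverlappingRegions(regions, genes)
    expect_equal(sort(unname(unlist(ann$genes))), c("edge", "inside"))
    intergenic <- genesOverlappingRegions(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1000)), genes)
    expect_length(unlist(intergenic$genes), 0)
})
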