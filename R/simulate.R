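## Synthetic genotype and methylome data with planted ground truth. Every
## sub-generator draws from its own seeded RNG stream (seed, seed+1, seed+2)
## so adding one generator never perturbs the others.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: two groups of
#' 10 and 11 individuals, 100-bp windows, negative-binomial counts with
#' dispersion 0.1, a CpG landscape with 47\% CpG-free windows, planted
#' high-FST loci, DMRs and copy-number confounds.
#'
#' @param seed integer seed; every output is bit-reproducible given it.
#' @param n_low,n_high samples per group (defaults 10 and 11).
#' @param n_chrom,chrom_length genome shape (default 2 x 1 Mb).
#' @param n_snps simulated biallelic SNPs (default 5000).
#' @param background_fst Balding-Nichols differentiation parameter F
#'   (default 0.05).
#' @param n_selected_loci,selected_freq_delta planted high-FST loci and their
#'   between-group allele-frequency separation (defaults 10 and 0.9).
#' @param missing_rate genotype missingness (default 0.05, below the 30\%
#'   filter).
#' @param window_width methylome window width (default 100).
#' @param nb_dispersion common NB dispersion of window counts (default 0.1).
#' @param medip_depth,wgs_depth mean fragments per window per sample
#'   (defaults 20 and 20).
#' @param library_size_cv lognormal coefficient of variation of per-sample
#'   depth (default 0.2).
#' @param window_effect_sdlog lognormal standard deviation (log scale) of the
#'   per-window methylation-level effect shared by all samples (default 0.9,
#'   calibrated so the within-genome CpG-vs-MeDIP correlation sits in the
#'   high-0.4s, the regime seen in mammalian MeDIP data; 0 disables it).
#' @param n_dmr,dmr_log2fc,dmr_width_windows planted DMRs: count, high-group
#'   log2 fold change, width in windows (defaults 10, 2, 10).
#' @param n_confound,confound_copy_ratio planted copy-number confounds where
#'   MeDIP and WGS means co-vary in the high group (defaults 5 and 2).
#' @param cpg_zero_fraction target fraction of CpG-free windows
#'   (default 0.47).
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, n_low = 10L, n_high = 11L,
                      n_chrom = 2L, chrom_length = 1e6,
                      n_snps = 5000L, background_fst = 0.05,
                      n_selected_loci = 10L, selected_freq_delta = 0.9,
                      missing_rate = 0.05,
                      window_width = 100L, nb_dispersion = 0.1,
                      medip_depth = 20, wgs_depth = 20,
                      library_size_cv = 0.2, window_effect_sdlog = 0.9,
                      n_dmr = 10L, dmr_log2fc = 2, dmr_width_windows = 10L,
                      n_confound = 5L, confound_copy_ratio = 2,
                      cpg_zero_fraction = 0.47) {
    cfg <- as.list(environment())
    stopifnot(cfg$seed == round(cfg$seed),
              cfg$n_low >= 2, cfg$n_high >= 2,
              cfg$n_chrom >= 1, cfg$chrom_length >= 1000,
              cfg$background_fst >= 0, cfg$background_fst < 1,
              cfg$selected_freq_delta >= 0, cfg$selected_freq_delta <= 1,
              cfg$missing_rate >= 0, cfg$missing_rate < 1,
              cfg$nb_dispersion >= 0, cfg$library_size_cv >= 0,
              cfg$window_effect_sdlog >= 0,
              cfg$cpg_zero_fraction >= 0, cfg$cpg_zero_fraction < 1)
    structure(cfg, class = "SimConfig")
}

## Per-window CpG-count law: P(0) = cpg_zero_fraction, 1-4 CpGs ~ 50%,
## >4 ~ 3% (at the default 0.47), mirroring the landscape the pipeline
## expects in real mammalian data.
.cpgCountProbs <- function(zeroFrac) {
    rest <- 1 - zeroFrac
    body <- c(0.25, 0.13, 0.08, 0.04)            # 1..4 CpGs
    tail <- c(0.013, 0.008, 0.005, 0.002, 0.001, 0.001)  # 5..10 CpGs
    p <- c(body, tail) / sum(c(body, tail)) * rest
    c(zeroFrac, p)
}

#' Simulate a reference genome, window grid and toy gene annotation
#'
#' Generates CpG-depleted random sequence, then plants an exact number of CG
#' dinucleotides per 100-bp window drawn from a zero-inflated law calibrated
#' to \code{cpg_zero_fraction}; tiles toy genes (2 kb every 10 kb,
#' alternating strand) across each chromosome.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir optional output directory; writes \code{reference.fa},
#'   \code{chrom.sizes}, \code{genes.gff3}.
#' @return List with \code{fasta} (\code{DNAStringSet}),
#'   \code{chrom_lengths}, \code{grid} (window \code{GRanges}), \code{cpg}
#'   (planted per-window CpG counts), \code{genes} (\code{GRanges}).
#' @export
simulateReference <- function(config, dir = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    chromLengths <- setNames(rep(config$chrom_length, config$n_chrom),
                             paste0("chr", seq_len(config$n_chrom)))
    grid <- tileWindows(chromLengths, config$window_width)
    probs <- .cpgCountProbs(config$cpg_zero_fraction)
    cpgPlan <- sample(seq_along(probs) - 1L, length(grid), replace = TRUE,
                      prob = probs)
    seqs <- character(config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
        L <- chromLengths[ci]
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
        ## CpG depletion: break every CG (no new G is introduced, so one
        ## pass leaves the sequence CG-free)
        cgAt <- which(s[-L] == "C" & s[-1] == "G")
        if (length(cgAt) > 0)
            s[cgAt + 1] <- sample(c("A", "T"), length(cgAt), replace = TRUE)
        win <- which(as.character(seqnames(grid)) == names(chromLengths)[ci])
        for (w in win) {
            k <- cpgPlan[w]
            if (k == 0) next
            st <- start(grid)[w]
            wd <- width(grid)[w]
            slots <- seq(st, st + wd - 2, by = 2)   # non-adjacent C positions
            k <- min(k, length(slots))
            cpgPlan[w] <- k
            at <- sort(sample(slots, k))
            s[at] <- "C"
            s[at + 1] <- "G"
        }
        seqs[ci] <- paste(s, collapse = "")
    }
    fasta <- DNAStringSet(seqs)
    names(fasta) <- names(chromLengths)
    ## toy genes: 2 kb every 10 kb, alternating strand
    geneStarts <- lapply(seq_len(config$n_chrom), function(ci)
        seq(3001, chromLengths[ci] - 2000, by = 10000))
    genes <- GRanges(rep(names(chromLengths), lengths(geneStarts)),
                     IRanges(unlist(geneStarts), width = 2000),
                     strand = rep(c("+", "-"),
                                  length.out = sum(lengths(geneStarts))))
    mcols(genes)$gene_id <- sprintf("gene%05d", seq_along(genes))
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeXStringSet(fasta, file.path(dir, "reference.fa"))
        write.table(data.frame(names(chromLengths), unname(chromLengths)),
                    file.path(dir, "chrom.sizes"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        gff <- genes
        mcols(gff)$type <- "gene"
        mcols(gff)$ID <- mcols(gff)$gene_id
        export(gff, file.path(dir, "genes.gff3"), format = "gff3")
    }
    list(fasta = fasta, chrom_lengths = chromLengths, grid = grid,
         cpg = as.integer(cpgPlan), genes = genes)
}

#' Simulate two-group biallelic genotypes
#'
#' Background differentiation follows the Balding-Nichols model: per SNP an
#' ancestral frequency is drawn, then each group's frequency from
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with \code{F = background_fst};
#' diploid genotypes are binomial draws. Planted loci get group frequencies
#' separated by \code{selected_freq_delta}, centred at 0.5. Missing calls are
#' sprinkled at \code{missing_rate}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param chromLengths named chromosome lengths (e.g. from
#'   \code{\link{simulateReference}}).
#' @param dir optional output directory; writes \code{genotypes.vcf} and
#'   \code{samples.tsv}.
#' @return List with \code{snp} (\linkS4class{SnpGenotypes}) and
#'   \code{selected_loci} (\code{GRanges} with \code{p_low}, \code{p_high}).
#' @export
simulateGenotypes <- function(config, chromLengths, dir = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    n <- config$n_low + config$n_high
    groups <- rep(GROUP_LEVELS, c(config$n_low, config$n_high))
    perChrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1)))
    chrom <- rep(names(chromLengths), perChrom)
    pos <- unlist(lapply(seq_len(config$n_chrom), function(ci)
        sort(sample(chromLengths[ci], perChrom[ci]))))
    anc <- runif(config$n_snps, 0.1, 0.9)
    FF <- config$background_fst
    freq <- matrix(0, config$n_snps, 2)
    for (k in 1:2) {
        freq[, k] <- if (FF == 0) anc else
            rbeta(config$n_snps, anc * (1 - FF) / FF,
                  (1 - anc) * (1 - FF) / FF)
    }
    planted <- integer(0)
    if (config$n_selected_loci > 0) {
        planted <- sort(sample(config$n_snps, config$n_selected_loci))
        half <- config$selected_freq_delta / 2
        freq[planted, 1] <- 0.5 - half
        freq[planted, 2] <- 0.5 + half
    }
    dos <- matrix(NA_integer_, config$n_snps, n)
    for (j in seq_len(n)) {
        k <- if (groups[j] == "low") 1 else 2
        dos[, j] <- rbinom(config$n_snps, 2, freq[, k])
    }
    if (config$missing_rate > 0) {
        miss <- matrix(runif(length(dos)) < config$missing_rate,
                       nrow(dos), ncol(dos))
        dos[miss] <- NA_integer_
    }
    colnames(dos) <- sprintf("s%02d", seq_len(n))
    positions <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    snp <- SnpGenotypes(positions, dos, groups)
    sel <- positions[planted]
    mcols(sel)$p_low <- freq[planted, 1]
    mcols(sel)$p_high <- freq[planted, 2]
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeSnpVcf(snp, file.path(dir, "genotypes.vcf"), chromLengths)
        write.table(data.frame(sample_id = colnames(dos), group = groups),
                    file.path(dir, "samples.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    list(snp = snp, selected_loci = sel)
}

## Sample disjoint planted intervals (DMRs + confounds) on the window grid:
## one interval per 10 kb slot, centred, so planted features never merge.
.plantIntervals <- function(grid, nIntervals, widthWindows) {
    slotSize <- max(2L * widthWindows, 100L)
    chromIdx <- split(seq_along(grid), as.character(seqnames(grid)))
    slots <- list()
    for (idx in chromIdx) {
        nSlot <- length(idx) %/% slotSize
        if (nSlot < 1) next
        starts <- idx[1] + (seq_len(nSlot) - 1L) * slotSize +
            (slotSize - widthWindows) %/% 2L
        slots <- c(slots, as.list(starts))
    }
    if (length(slots) < nIntervals)
        stop("genome too small for the requested planted intervals")
    picked <- sort(sample(length(slots), nIntervals))
    lapply(slots[picked], function(s) s:(s + widthWindows - 1L))
}

#' Simulate MeDIP and WGS window counts with planted DMRs and confounds
#'
#' Baseline MeDIP means are proportional to \code{1 + CpG count} (tying
#' methylation signal to CpG density) times a lognormal per-window
#' methylation-level effect; WGS means are flat. Per-sample depths vary
#' lognormally; counts are negative-binomial with common dispersion.
#' Planted DMR windows multiply the high-group MeDIP mean by
#' \code{2^dmr_log2fc}; planted confound windows multiply BOTH the MeDIP and
#' the WGS mean in the high group by \code{confound_copy_ratio} (a copy
#' number shared by both assays).
#'
#' @param config a \code{\link{simConfig}}.
#' @param grid window grid.
#' @param cpg per-window CpG counts.
#' @param dir optional output directory; writes \code{medip_counts.tsv},
#'   \code{wgs_counts.tsv}.
#' @return List with \code{mws} (\linkS4class{MethylWindowSet}),
#'   \code{dmr_windows} and \code{confound_windows} (truth \code{GRanges}
#'   with \code{log2fc} / \code{copy_ratio}).
#' @export
simulateCounts <- function(config, grid, cpg, dir = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 2L)
    n <- config$n_low + config$n_high
    groups <- rep(GROUP_LEVELS, c(config$n_low, config$n_high))
    nw <- length(grid)
    cv <- config$library_size_cv
    sdlog <- sqrt(log(1 + cv^2))
    depthM <- rlnorm(n, -sdlog^2 / 2, sdlog)
    depthW <- rlnorm(n, -sdlog^2 / 2, sdlog)

    baseM <- config$medip_depth * (1 + cpg) / mean(1 + cpg)
    nPlant <- config$n_dmr + config$n_confound
    planted <- if (nPlant > 0)
        .plantIntervals(grid, nPlant, config$dmr_width_windows) else list()
    which_dmr <- seq_len(config$n_dmr)
    dmrIdx <- planted[which_dmr]
    cnfIdx <- planted[setdiff(seq_len(nPlant), which_dmr)]
    if (config$window_effect_sdlog > 0) {
        ## intrinsic per-window methylation level, shared by all samples:
        ## decouples methylation from raw CpG count as in real MeDIP data.
        ## Planted windows keep the neutral level 1: a DMR is by definition
        ## methylated in one group, so its effect applies to a typical
        ## baseline, not a silent window.
        sw <- config$window_effect_sdlog
        eff <- rlnorm(nw, -sw^2 / 2, sw)
        eff[unlist(planted)] <- 1
        baseM <- baseM * eff
    }
    baseW <- rep(config$wgs_depth, nw)

    muM <- matrix(baseM, nw, n) * matrix(depthM, nw, n, byrow = TRUE)
    muW <- matrix(baseW, nw, n) * matrix(depthW, nw, n, byrow = TRUE)
    hi <- groups == "high"
    for (idx in dmrIdx)
        muM[idx, hi] <- muM[idx, hi] * 2^config$dmr_log2fc
    for (idx in cnfIdx) {
        muM[idx, hi] <- muM[idx, hi] * config$confound_copy_ratio
        muW[idx, hi] <- muW[idx, hi] * config$confound_copy_ratio
    }
    draw <- function(mu) {
        m <- if (config$nb_dispersion > 0)
            rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu)
        else rpois(length(mu), mu)
        matrix(m, nw, n)
    }
    medip <- draw(muM)
    wgs <- draw(muW)
    colnames(medip) <- colnames(wgs) <- sprintf("s%02d", seq_len(n))
    mws <- MethylWindowSet(medip, wgs, cpg, grid, groups)

    asTruth <- function(lst, col, val) {
        if (length(lst) == 0) {
            gr <- GRanges()
        } else {
            gr <- GRanges(
                vapply(lst, function(i) as.character(seqnames(grid)[i[1]]), ""),
                IRanges(vapply(lst, function(i) start(grid)[i[1]], numeric(1)),
                        vapply(lst, function(i) end(grid)[i[length(i)]],
                               numeric(1))))
        }
        mcols(gr)[[col]] <- rep(val, length(gr))
        gr
    }
    truth <- list(
        mws = mws,
        dmr_windows = asTruth(dmrIdx, "log2fc", config$dmr_log2fc),
        confound_windows = asTruth(cnfIdx, "copy_ratio",
                                   config$confound_copy_ratio))
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeWindowCounts(medip, grid, file.path(dir, "medip_counts.tsv"))
        writeWindowCounts(wgs, grid, file.path(dir, "wgs_counts.tsv"))
    }
    truth
}

#' Write / read planted ground truth
#'
#' BED-style TSV tables (0-based half-open) for planted selected loci, DMR
#' windows and confound windows, suitable for sensitivity/FDR scoring.
#'
#' @param truth list with any of \code{selected_loci}, \code{dmr_windows},
#'   \code{confound_windows} (\code{GRanges} with their effect columns).
#' @param dir output directory.
#' @return \code{writeTruth}: the paths written, invisibly;
#'   \code{readTruth}: the truth list.
#' @export
writeTruth <- function(truth, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (nm in c("selected_loci", "dmr_windows", "confound_windows")) {
        gr <- truth[[nm]]
        if (is.null(gr)) next
        df <- data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L,   # 0-based half-open
                         end = end(gr))
        extra <- as.data.frame(mcols(gr))
        if (ncol(extra) > 0 && nrow(extra) == nrow(df)) df <- cbind(df, extra)
        p <- file.path(dir, paste0(nm, ".tsv"))
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
    out <- list()
    for (nm in c("selected_loci", "dmr_windows", "confound_windows")) {
        p <- file.path(dir, paste0(nm, ".tsv"))
        if (!file.exists(p)) next
        df <- read.table(p, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
        gr <- if (nrow(df) == 0) GRanges() else
            GRanges(df$chrom, IRanges(df$start + 1L, df$end))
        for (col in setdiff(names(df), c("chrom", "start", "end")))
            mcols(gr)[[col]] <- df[[col]]
        out[[nm]] <- gr
    }
    out
}
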