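## Independent oracles, deliberately written as direct transcriptions of the
## published formulas / naive algorithms, sharing no code with the package.

## Weir & Cockerham (1984) two-population per-site estimator, one site at a
## time, straight from the component definitions.
wcFstOracle <- function(dosLow, dosHigh) {
    pops <- list(dosLow[!is.na(dosLow)], dosHigh[!is.na(dosHigh)])
    r <- 2
    n <- vapply(pops, length, numeric(1))
    if (any(n == 0)) return(list(a = NA, b = NA, c = NA, fst = NA))
    p <- vapply(pops, function(d) sum(d) / (2 * length(d)), numeric(1))
    h <- vapply(pops, function(d) mean(d == 1), numeric(1))
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    list(a = a, b = b, c = cc,
         fst = if (denom == 0) NA_real_ else a / denom)
}

## Naive O(n^2) merge-and-pad: pad every SNP chain found by pairwise
## scanning, then union intervals by sweeping.
mergePadOracle <- function(pos, mergeDist, pad, chromLen) {
    pos <- sort(pos)
    ivs <- list()
    i <- 1
    while (i <= length(pos)) {
        j <- i
        while (j < length(pos) && pos[j + 1] - pos[j] < mergeDist) j <- j + 1
        ivs[[length(ivs) + 1]] <- c(max(pos[i] - pad, 1),
                                    min(pos[j] + pad, chromLen))
        i <- j + 1
    }
    ## union overlapping padded intervals
    out <- list()
    for (iv in ivs) {
        if (length(out) > 0 && iv[1] <= out[[length(out)]][2])
            out[[length(out)]][2] <- max(out[[length(out)]][2], iv[2])
        else out[[length(out) + 1]] <- iv
    }
    do.call(rbind, out)
}

## Exhaustive best single breakpoint under the same MBIC Normal
## mean/variance objective (twice-negative log likelihood + log segment
## length), searched by brute force rather than dynamic programming.
singleBreakOracle <- function(x, minLen = 2) {
    n <- length(x)
    floorVar <- max(1e-8, 1e-4 * (mean(x^2) - mean(x)^2))
    nll <- function(v) {
        m <- length(v)
        s2 <- max(mean(v^2) - mean(v)^2, floorVar)
        m * (log(2 * pi) + log(s2) + 1) + log(m)
    }
    costs <- vapply(minLen:(n - minLen), function(b)
        nll(x[1:b]) + nll(x[(b + 1):n]), numeric(1))
    (minLen:(n - minLen))[which.min(costs)]
}

## Exact two-sided Wilcoxon p by full enumeration of all C(n+m, n) group
## assignments of the pooled values.
wilcoxEnumOracle <- function(x, y) {
    n <- length(x)
    pooled <- c(x, y)
    r <- rank(pooled)
    W <- sum(r[seq_len(n)])
    combos <- combn(length(pooled), n)
    Ws <- apply(combos, 2, function(idx) sum(r[idx]))
    min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

## Brute-force window counting: every fragment vs every window.
countOverlapOracle <- function(fragStart, fragEnd, winStart, winEnd) {
    vapply(seq_along(winStart), function(w)
        sum(fragStart <= winEnd[w] & fragEnd >= winStart[w]),
        numeric(1))
}
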