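## Count statistics underlying the differential-methylation pipeline. All
## kernels are deterministic, pure-matrix operations; the two-group design is
## always a factor with levels c("low", "high").

#' Counts per million
#'
#' Scales each count by its sample's library size, times 1e6.
#'
#' @param counts non-negative matrix, windows x samples.
#' @param lib.sizes positive library size per sample; defaults to column sums.
#' @return Real matrix of CPM values, same dimensions as \code{counts}.
#' @export
countsPerMillion <- function(counts, lib.sizes = colSums(counts)) {
    counts <- .assertCounts(counts)
    if (any(lib.sizes <= 0)) stop("library sizes must be positive")
    sweep(counts, 2L, lib.sizes, "/") * 1e6
}

## 75th-percentile CPM per sample, used to pick the TMM reference.
.upperQuartileCpm <- function(counts, lib.sizes) {
    apply(sweep(counts, 2L, lib.sizes, "/"), 2L, quantile, probs = 0.75)
}

## One TMM factor: sample `obs` against sample `ref` (raw count vectors).
.tmmPairFactor <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
    pO <- obs / nO
    pR <- ref / nR
    logR <- log2(pO / pR)                      # M-values
    absE <- (log2(pO) + log2(pR)) / 2          # A-values
    v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)  # delta-method var
    keep <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[keep]; absE <- absE[keep]; v <- v[keep]
    if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
        rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) f <- 0
    2^f
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack 2010). The
#' reference sample is the one whose upper-quartile CPM is closest to the mean
#' upper-quartile; M-values are trimmed 30\% on each side and A-values 5\%,
#' and the retained M-values are combined by a precision-weighted mean.
#' Factors are rescaled so their geometric mean is exactly 1.
#'
#' @inheritParams countsPerMillion
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A values.
#' @return List with \code{factors} (one positive real per sample, geometric
#'   mean 1) and \code{reference_sample} (column name or index used as
#'   reference).
#' @export
tmmFactors <- function(counts, lib.sizes = colSums(counts),
                       logratioTrim = 0.30, sumTrim = 0.05) {
    counts <- .assertCounts(counts)
    if (ncol(counts) < 2L) stop("at least two samples are required")
    if (any(colSums(counts) == 0))
        stop("a sample with all-zero counts cannot be normalized")
    if (any(lib.sizes <= 0)) stop("library sizes must be positive")
    uq <- .upperQuartileCpm(counts, lib.sizes)
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        if (j == ref) return(1)
        .tmmPairFactor(counts[, j], counts[, ref], lib.sizes[j], lib.sizes[ref],
                       logratioTrim, sumTrim)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    refName <- if (!is.null(colnames(counts))) colnames(counts)[ref] else ref
    list(factors = f, reference_sample = refName)
}

## Moment-matched quantile map from NB(mu0, phi) to NB(mu1, phi): mean of a
## normal and a gamma map, as in the quantile-adjustment scheme of the
## conditional NB test. Zeros are preserved exactly.
.q2qNegBin <- function(y, mu0, mu1, phi) {
    out <- numeric(length(y))
    ok <- mu0 > 0 & mu1 > 0 & y > 0
    if (any(ok)) {
        y0 <- y[ok]; m0 <- mu0[ok]; m1 <- mu1[ok]
        v0 <- m0 + phi * m0^2
        v1 <- m1 + phi * m1^2
        qn <- m1 + sqrt(v1 / v0) * (y0 - m0)
        p <- pgamma(y0, shape = m0^2 / v0, rate = m0 / v0)
        qg <- qgamma(p, shape = m1^2 / v1, rate = m1 / v1)
        ## far in the upper tail pgamma saturates at 1; use the normal map
        qg[!is.finite(qg)] <- pmax(qn[!is.finite(qg)], 0)
        out[ok] <- pmax((pmax(qn, 0) + qg) / 2, 0)
    }
    out
}

#' Equalize library sizes by quantile-adjusted pseudo-counts
#'
#' Maps each count to the scale of a common library size (the geometric mean
#' of the effective sizes \code{lib.sizes * norm.factors}) by quantile
#' adjustment under a negative-binomial law with common dispersion. Row means
#' are estimated per group when \code{groups} is given, else pooled.
#'
#' @inheritParams countsPerMillion
#' @param groups optional \code{"low"}/\code{"high"} label per sample.
#' @param norm.factors per-sample normalization factors (default all 1).
#' @param dispersion common NB dispersion used for the quantile map.
#' @return List with \code{pseudo} (non-negative real matrix),
#'   \code{common.lib.size}.
#' @export
equalizeLibraries <- function(counts, groups = NULL,
                              lib.sizes = colSums(counts),
                              norm.factors = rep(1, ncol(counts)),
                              dispersion = 0) {
    counts <- .assertCounts(counts)
    eff <- lib.sizes * norm.factors
    if (any(eff <= 0)) stop("effective library sizes must be positive")
    common <- exp(mean(log(eff)))
    idx <- if (is.null(groups)) list(seq_len(ncol(counts)))
           else split(seq_len(ncol(counts)), .assertGroups(groups))
    pseudo <- counts
    for (cols in idx) {
        prop <- rowSums(counts[, cols, drop = FALSE]) / sum(eff[cols])
        for (j in cols) {
            pseudo[, j] <- .q2qNegBin(counts[, j], prop * eff[j],
                                      prop * common, dispersion)
        }
    }
    list(pseudo = pseudo, common.lib.size = common)
}

## Conditional (qCML) log-likelihood of a common dispersion phi given
## equalized pseudo-counts, summed over rows and groups. r = 1/phi.
.condLogLik <- function(pseudo, groupIdx, phi) {
    r <- 1 / phi
    ll <- 0
    for (cols in groupIdx) {
        y <- pseudo[, cols, drop = FALSE]
        n <- length(cols)
        z <- rowSums(y)
        ll <- ll + sum(lgamma(y + r)) + sum(lgamma(n * r) - lgamma(z + n * r)) -
            nrow(y) * n * lgamma(r)
    }
    ll
}

#' Robust common negative-binomial dispersion
#'
#' Estimates a single dispersion shared by all windows by maximizing the
#' conditional (qCML) log-likelihood on equalized pseudo-counts, with
#' iterative down-weighting of outlying observations: at each iteration,
#' Pearson residuals are clipped at the Huber threshold \code{k} (so an
#' outlier's influence is bounded), rescaled by the Huber consistency factor
#' \eqn{E[\min(Z^2, k^2)]^{-1/2}} so well-behaved data are not shrunk, and
#' the likelihood is re-maximized on the adjusted observations.
#'
#' @inheritParams equalizeLibraries
#' @param groups \code{"low"}/\code{"high"} label per sample (both groups need
#'   at least two samples).
#' @param k Huber threshold on Pearson residuals (default 1.345).
#' @param iterations robustness iterations (default 5).
#' @return List with \code{phi} (common dispersion, >= 0) and \code{weights}
#'   (per-observation robustness weights in [0, 1], same shape as
#'   \code{counts}).
#' @export
estimateCommonDispersionRobust <- function(counts, groups,
                                           lib.sizes = colSums(counts),
                                           norm.factors = rep(1, ncol(counts)),
                                           k = 1.345, iterations = 5) {
    counts <- .assertCounts(counts)
    groups <- .assertGroups(groups)
    if (any(table(groups) < 2L))
        stop("both groups need at least two samples")
    groupIdx <- split(seq_len(ncol(counts)), groups)

    phi <- 0.1
    pseudo <- equalizeLibraries(counts, groups, lib.sizes, norm.factors,
                                dispersion = phi)$pseudo
    fitPhi <- function(y) {
        opt <- optimize(function(lp) .condLogLik(y, groupIdx, exp(lp)),
                        interval = log(c(1e-6, 4)), maximum = TRUE)
        exp(opt$maximum)
    }
    phi <- fitPhi(pseudo)
    ## refresh the quantile adjustment once at the fitted dispersion
    pseudo <- equalizeLibraries(counts, groups, lib.sizes, norm.factors,
                                dispersion = phi)$pseudo
    phi <- fitPhi(pseudo)

    ## Huber consistency factor: E[min(Z^2, k^2)] for Z ~ N(0,1), so that
    ## clipping residuals at +/-k does not shrink well-behaved data
    consist <- sqrt(1 - 2 * ((1 - k^2) * (1 - pnorm(k)) + k * dnorm(k)))
    weights <- matrix(1, nrow(counts), ncol(counts))
    yAdj <- pseudo
    for (it in seq_len(iterations)) {
        ## group means from the adjusted values so one outlier cannot drag
        ## its own reference mean
        mu <- matrix(0, nrow(counts), ncol(counts))
        for (cols in groupIdx)
            mu[, cols] <- rowMeans(yAdj[, cols, drop = FALSE])
        sdev <- sqrt(pmax(mu + phi * mu^2, 1e-8))
        resid <- (pseudo - mu) / sdev
        weights <- pmin(1, k / pmax(abs(resid), 1e-12))
        ## observation-level Huber step: clipped, consistency-rescaled values
        yAdj <- pmax(mu + pmin(pmax(resid, -k), k) / consist * sdev, 0)
        phiNew <- fitPhi(yAdj)
        if (abs(phiNew - phi) < 1e-6 * (phi + 1e-6)) { phi <- phiNew; break }
        phi <- phiNew
    }
    if (phi <= 1.5e-6) phi <- 0
    list(phi = phi, weights = weights)
}

## Conditional distribution of the "low"-group sum given the row total under
## a common-dispersion NB with equal per-sample means; free of the mean
## parameter. Returns the doubled smaller tail including the observed point.
.doubleTailP <- function(zA, zTot, nA, nB, phi) {
    if (zTot == 0) return(1)
    ks <- 0:zTot
    if (phi <= 0) {
        logw <- dbinom(ks, zTot, nA / (nA + nB), log = TRUE)
    } else {
        r <- 1 / phi
        logw <- dnbinom(ks, size = nA * r, prob = 0.5, log = TRUE) +
            dnbinom(zTot - ks, size = nB * r, prob = 0.5, log = TRUE)
    }
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    lo <- sum(w[ks <= zA])
    hi <- sum(w[ks >= zA])
    min(1, 2 * min(lo, hi))
}

#' Exact negative-binomial test for a two-group count difference
#'
#' For each window, tests equality of the two group means under a common
#' dispersion: the p-value is the doubled smaller tail (including the
#' observed point) of the conditional distribution of the low-group
#' pseudo-count sum given the window total. Library sizes are equalized by
#' quantile adjustment first; group sums are rounded to integers for the
#' conditional enumeration. The log2 fold change (high vs low) is computed
#' from prior-damped group mean CPM.
#'
#' @inheritParams estimateCommonDispersionRobust
#' @param dispersion common NB dispersion (a number or the list returned by
#'   \code{\link{estimateCommonDispersionRobust}}).
#' @param priorCount prior count added per library-size-scaled sample in the
#'   fold-change computation (default 0.125).
#' @return \code{data.frame} with one row per window: \code{p_value},
#'   \code{log2_fold_change}.
#' @export
nbExactTest <- function(counts, groups, dispersion,
                        lib.sizes = colSums(counts),
                        norm.factors = rep(1, ncol(counts)),
                        priorCount = 0.125) {
    counts <- .assertCounts(counts)
    groups <- .assertGroups(groups)
    if (is.list(dispersion)) dispersion <- dispersion$phi
    eq <- equalizeLibraries(counts, groups, lib.sizes, norm.factors,
                            dispersion = dispersion)
    pseudo <- eq$pseudo
    isLow <- groups == "low"
    nA <- sum(isLow); nB <- sum(!isLow)
    zA <- round(rowSums(pseudo[, isLow, drop = FALSE]))
    zB <- round(rowSums(pseudo[, !isLow, drop = FALSE]))
    p <- vapply(seq_len(nrow(counts)), function(i) {
        .doubleTailP(zA[i], zA[i] + zB[i], nA, nB, dispersion)
    }, numeric(1))

    ## fold change from prior-damped CPM group means
    eff <- lib.sizes * norm.factors
    prior <- priorCount * eff / mean(eff)
    cpmP <- sweep(sweep(counts, 2L, prior, "+"), 2L, eff, "/") * 1e6
    muLow <- rowMeans(cpmP[, isLow, drop = FALSE])
    muHigh <- rowMeans(cpmP[, !isLow, drop = FALSE])
    lfc <- log2(muHigh / muLow)
    zero <- (zA + zB) == 0
    lfc[zero] <- 0
    p[zero] <- 1
    data.frame(p_value = p, log2_fold_change = lfc)
}

#' Storey q-values
#'
#' Converts p-values to q-values with the null proportion \eqn{\pi_0}
#' estimated on the lambda grid 0, 0.05, ..., 0.90 with spline smoothing.
#' Falls back to \eqn{\pi_0 = 1} (Benjamini-Hochberg) when fewer than 100
#' p-values are supplied or smoothing fails.
#'
#' @param p p-values in [0, 1].
#' @param pi0 optional fixed null proportion, overriding estimation.
#' @return List with \code{qvalues} (monotone in p, <= 1) and \code{pi0}.
#' @export
storeyQvalues <- function(p, pi0 = NULL) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (is.null(pi0)) {
        lambda <- seq(0, 0.90, by = 0.05)
        pi0Grid <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
        pi0 <- if (m < 100) 1 else tryCatch({
            fit <- smooth.spline(lambda, pi0Grid, df = 3)
            min(max(predict(fit, x = max(lambda))$y, 1e-8), 1)
        }, error = function(e) 1)
    }
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
    q <- pmin(cummin(q), 1)[ro]
    list(qvalues = q, pi0 = pi0)
}

#' Segment a series by changes in mean and variance
#'
#' Exact optimal partitioning (dynamic programming) under a per-segment
#' Normal likelihood with free mean and variance, with the MBIC
#' \code{log(segment length)} term in the segment cost; each extra
#' changepoint pays \code{penalty} on the twice-negative-log-likelihood
#' scale. The default penalty is the MBIC value for a two-parameter
#' (mean + variance) Normal segment model, \code{4 * log(n)}. The
#' per-segment variance estimate is floored at
#' \code{max(1e-8, 1e-4 * var(x))} so near-constant stretches cannot earn
#' unbounded likelihood.
#'
#' @param x numeric series.
#' @param penalty positive penalty per changepoint; default \code{4 * log(n)}.
#' @param minSegLen minimum segment length (>= 2, needed to estimate a
#'   variance).
#' @param maxBreakpoints optional cap on the number of breakpoints (e.g. 1
#'   for a single-split fit); default unlimited.
#' @return List with \code{breakpoints} (sorted exclusive segment ends,
#'   strictly inside \code{1..n}), \code{penalty}, \code{min_segment_length}.
#' @export
segmentMeanVar <- function(x, penalty = NULL, minSegLen = 2,
                           maxBreakpoints = Inf) {
    n <- length(x)
    if (minSegLen < 2) stop("minSegLen must be at least 2")
    if (is.null(penalty)) penalty <- 4 * log(max(n, 2))
    if (penalty <= 0) stop("penalty must be positive")
    if (n < 2 * minSegLen)
        return(list(breakpoints = integer(0), penalty = penalty,
                    min_segment_length = minSegLen))
    cx <- c(0, cumsum(x))
    cx2 <- c(0, cumsum(x^2))
    eps <- max(1e-8, 1e-4 * (cx2[n + 1] / n - (cx[n + 1] / n)^2))
    segCost <- function(i, j) {   # x[i..j]: 2*negloglik + MBIC length term
        m <- j - i + 1
        s <- cx[j + 1] - cx[i]
        s2 <- cx2[j + 1] - cx2[i]
        v <- max(s2 / m - (s / m)^2, eps)
        m * (log(2 * pi) + log(v) + 1) + log(m)
    }
    if (is.finite(maxBreakpoints)) {
        ## layered DP: Fcost[k, t+1] = best cost of x[1..t] in k segments
        maxSeg <- as.integer(maxBreakpoints) + 1L
        Fcost <- matrix(Inf, maxSeg, n + 1)
        lastCp <- matrix(0L, maxSeg, n + 1)
        for (t in minSegLen:n) Fcost[1, t + 1] <- segCost(1, t)
        if (maxSeg > 1) {
            for (k in 2:maxSeg) {
                for (t in seq_len(n)) {
                    if (t < k * minSegLen) next
                    best <- Inf; bestS <- 0L
                    for (s in ((k - 1) * minSegLen):(t - minSegLen)) {
                        if (is.finite(Fcost[k - 1, s + 1])) {
                            val <- Fcost[k - 1, s + 1] + segCost(s + 1, t)
                            if (val < best) { best <- val; bestS <- s }
                        }
                    }
                    Fcost[k, t + 1] <- best
                    lastCp[k, t + 1] <- bestS
                }
            }
        }
        total <- Fcost[, n + 1] + penalty * (seq_len(maxSeg) - 1)
        kBest <- which.min(total)
        bps <- integer(0)
        t <- n
        for (k in kBest:1) {
            s <- lastCp[k, t + 1]
            if (s > 0) bps <- c(s, bps)
            t <- s
        }
        return(list(breakpoints = bps, penalty = penalty,
                    min_segment_length = minSegLen))
    }
    Fcost <- rep(Inf, n + 1)
    Fcost[1] <- -penalty
    lastCp <- integer(n + 1)
    for (t in minSegLen:n) {
        best <- Inf; bestS <- 0L
        for (s in 0:(t - minSegLen)) {
            if (is.finite(Fcost[s + 1])) {
                val <- Fcost[s + 1] + segCost(s + 1, t) + penalty
                if (val < best) { best <- val; bestS <- s }
            }
        }
        Fcost[t + 1] <- best
        lastCp[t + 1] <- bestS
    }
    bps <- integer(0)
    t <- n
    while (t > 0) {
        s <- lastCp[t + 1]
        if (s > 0) bps <- c(s, bps)
        t <- s
    }
    list(breakpoints = bps, penalty = penalty, min_segment_length = minSegLen)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of a location difference between two samples.
#' Uses exact enumeration of the rank-sum null distribution when
#' \code{length(x) + length(y) <= 20} and there are no ties, else a normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (both non-empty).
#' @return List with \code{statistic} (rank-sum of \code{x}), \code{p_value},
#'   \code{method} (\code{"exact"} or \code{"normal-approximation"}).
#' @export
wilcoxonRankSum <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be non-empty")
    n <- length(x); m <- length(y); N <- n + m
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n)])
    ties <- any(duplicated(c(x, y)))
    if (N <= 20 && !ties) {
        ## DP over the exact null distribution of the rank-sum of n ranks
        maxW <- sum((N - n + 1):N)
        cnt <- matrix(0, n + 1, maxW + 1)   # cnt[k+1, w+1]
        cnt[1, 1] <- 1
        for (rk in seq_len(N)) {
            for (k in min(rk, n):1) {
                w <- seq(rk, maxW)
                cnt[k + 1, w + 1] <- cnt[k + 1, w + 1] + cnt[k, w - rk + 1]
            }
        }
        dist <- cnt[n + 1, ] / choose(N, n)
        ws <- 0:maxW
        p <- min(1, 2 * min(sum(dist[ws <= W]), sum(dist[ws >= W])))
        method <- "exact"
    } else {
        mu <- n * (N + 1) / 2
        tj <- table(r)
        tieAdj <- sum(tj^3 - tj) / (N * (N - 1))
        v <- n * m / 12 * ((N + 1) - tieAdj)
        if (v <= 0) {
            p <- 1
        } else {
            z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
            p <- min(1, 2 * pnorm(-abs(z)))
        }
        method <- "normal-approximation"
    }
    list(statistic = W, p_value = p, method = method)
}
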