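test_that("CPM follows its definition", {
    m <- matrix(c(1, 0, 5, 0), 2, 2)
    cpm <- countsPerMillion(m, lib.sizes = c(1e6, 2e6))
    expect_equal(cpm[1, 1], 1.0)
    expect_equal(cpm[1, 2], 2.5)
    expect_true(all(countsPerMillion(matrix(0, 3, 2), c(10, 10)) == 0))
    expect_error(countsPerMillion(m, c(0, 1e6)), "positive")
})

test_that("TMM factors are 1 for identical samples and geometric-mean 1", {
    set.seed(1)
    base <- rpois(2000, 30)
    yi <- cbind(base, base, base)
    expect_equal(unname(tmmFactors(yi)$factors), rep(1, 3))

    y <- matrix(rnbinom(2000 * 4, mu = 40, size = 8), 2000, 4)
    f <- tmmFactors(y)$factors
    expect_lt(abs(sum(log(f))), 1e-9)
    ## invariant to row order
    perm <- sample(nrow(y))
    expect_equal(tmmFactors(y[perm, ])$factors, f)
    expect_error(tmmFactors(cbind(y, 0)), "all-zero")
})

test_that("pure depth differences are absorbed by library size, not factor", {
    set.seed(2)
    a <- rnbinom(4000, mu = 50, size = 10)
    y <- cbind(a, 2L * a,
               rnbinom(4000, mu = 50, size = 10),
               rnbinom(4000, mu = 50, size = 10))
    f <- tmmFactors(y)$factors
    expect_lt(abs(f[[2]] - 1), 0.02)
})

test_that("composition bias is compensated through the effective library", {
    set.seed(3)
    a <- rnbinom(3000, mu = 50, size = 20)
    b <- a
    hot <- seq_len(300)                       # 10% of rows at 8x in sample B
    b[hot] <- 8L * a[hot]
    y <- cbind(A = a, B = b)
    f <- tmmFactors(y)$factors
    ## the hot rows inflate B's library; TMM shrinks B's factor so that the
    ## effective library (lib.size x factor) re-equalizes the unchanged bulk
    expect_lt(f[["B"]] / f[["A"]], 1)
    eff <- colSums(y) * f
    cpmBulk <- sweep(y[-hot, ], 2L, eff, "/")
    expect_equal(median(cpmBulk[, "B"] / cpmBulk[, "A"]), 1, tolerance = 0.05)
    skip_if_not_installed("edgeR")
    expect_equal(unname(f), unname(edgeR::calcNormFactors(y, method = "TMM")),
                 tolerance = 1e-6)
})

test_that("TMM agrees with the reference implementation on an NB fixture", {
    skip_if_not_installed("edgeR")
    set.seed(4)
    y <- matrix(rnbinom(4000 * 4, mu = 50, size = 10), 4000, 4)
    y[, 2] <- rnbinom(4000, mu = 100, size = 10)
    y[1:400, 3] <- rnbinom(400, mu = 400, size = 10)
    f <- tmmFactors(y)$factors
    fRef <- edgeR::calcNormFactors(y, method = "TMM")
    expect_lt(max(abs(unname(f) - fRef)), 1e-3)
})

test_that("library equalization is identity for equal libraries and keeps zeros", {
    set.seed(5)
    y <- matrix(rnbinom(500 * 4, mu = 20, size = 5), 500, 4)
    y[1, ] <- 0
    eq <- equalizeLibraries(y, lib.sizes = rep(1e6, 4), dispersion = 0.1)
    expect_equal(eq$pseudo, y)
    yu <- y
    eq2 <- equalizeLibraries(yu, lib.sizes = c(1e6, 2e6, 1e6, 1e6),
                             dispersion = 0.1)
    expect_true(all(eq2$pseudo[yu == 0] == 0))
    expect_true(all(eq2$pseudo >= 0))
})

test_that("a library at twice the common size maps to about half its counts", {
    set.seed(6)
    base <- rpois(4000, 1000)
    L <- sum(base)
    ## effective sizes (2L, L/2, L, L) have geometric mean exactly L, so
    ## sample 1 sits at twice the common size
    y <- cbind(2L * base, as.integer(round(base / 2)), base, base)
    libs <- c(2 * L, L / 2, L, L)
    eq <- equalizeLibraries(y, lib.sizes = libs, dispersion = 0)
    expect_equal(eq$common.lib.size, L, tolerance = 1e-12)
    ratio <- eq$pseudo[, 1] / (y[, 1] / 2)
    expect_lt(median(abs(ratio - 1)), 0.05)
})

test_that("common dispersion is recovered and robust to outliers", {
    set.seed(7)
    g <- rep(c("low", "high"), each = 10)
    yn <- matrix(rnbinom(5000 * 20, mu = 30, size = 10), 5000, 20)
    est <- estimateCommonDispersionRobust(yn, g)
    expect_gte(est$phi, 0.07)
    expect_lte(est$phi, 0.13)
    expect_true(all(est$weights >= 0 & est$weights <= 1))

    yp <- matrix(rpois(5000 * 20, 30), 5000, 20)
    expect_lt(estimateCommonDispersionRobust(yp, g)$phi, 0.02)

    ## 1% extreme outliers: the robust fit barely moves, the plain qCML fit
    ## (zero robustness iterations) explodes
    yo <- yn
    idx <- sample(length(yo), round(0.01 * length(yo)))
    yo[idx] <- yo[idx] * 20L
    phiRob <- estimateCommonDispersionRobust(yo, g)$phi
    phiPlain <- estimateCommonDispersionRobust(yo, g, iterations = 0)$phi
    expect_lt(abs(phiRob - est$phi) / est$phi, 0.25)
    expect_gt(abs(phiPlain - est$phi) / est$phi, 1.0)
    expect_error(estimateCommonDispersionRobust(yn[, 1:3],
                                                c("low", "low", "high")),
                 "two samples")
})

test_that("exact test is balanced on identical counts and hits the binomial limit", {
    g6 <- rep(c("low", "high"), each = 6)
    yEq <- matrix(7L, 50, 12)
    et <- nbExactTest(yEq, g6, 0.1)
    expect_true(all(et$p_value == 1))
    expect_true(all(et$log2_fold_change == 0))

    set.seed(8)
    y <- matrix(rpois(200 * 12, 10), 200, 12)
    et0 <- nbExactTest(y, g6, 0, lib.sizes = rep(1e6, 12))
    pBin <- vapply(seq_len(nrow(y)), function(i) {
        zA <- sum(y[i, 1:6]); z <- sum(y[i, ])
        if (z == 0) return(1)
        d <- dbinom(0:z, z, 0.5)
        min(1, 2 * min(sum(d[0:z <= zA]), sum(d[0:z >= zA])))
    }, numeric(1))
    expect_lt(max(abs(et0$p_value - pBin)), 1e-6)

    yZero <- matrix(0L, 2, 12); yZero[2, ] <- 5L
    etz <- nbExactTest(yZero, g6, 0.1)
    expect_equal(etz$p_value[1], 1)
    expect_equal(etz$log2_fold_change[1], 0)
})

test_that("null exact-test p-values are roughly uniform at small scale", {
    set.seed(9)
    g <- rep(c("low", "high"), c(10, 11))
    y <- matrix(rnbinom(3000 * 21, mu = 50, size = 10), 3000, 21)
    et <- nbExactTest(y, g, 0.1)
    expect_gt(mean(et$p_value <= 0.05), 0.03)
    expect_lt(mean(et$p_value <= 0.05), 0.07)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 on nulls", {
    p <- c(0.01, 0.02, 0.03)
    expect_equal(storeyQvalues(p, pi0 = 1)$qvalues, rep(0.03, 3))
    set.seed(10)
    p2 <- runif(500)
    expect_equal(storeyQvalues(p2, pi0 = 1)$qvalues,
                 p.adjust(p2, method = "BH"))
    expect_equal(storeyQvalues(rep(0.2, 5))$qvalues, rep(0.2, 5))

    p3 <- runif(10000)
    qv <- storeyQvalues(p3)
    expect_gte(qv$pi0, 0.9)
    expect_lte(qv$pi0, 1.0)
    ## monotone in p, bounded by 1
    o <- order(p3)
    expect_true(all(diff(qv$qvalues[o]) >= 0))
    expect_true(all(qv$qvalues <= 1))
    expect_error(storeyQvalues(c(0.5, 1.2)), "0, 1")
    ## fewer than 100 p-values: BH fallback
    expect_equal(storeyQvalues(runif(50))$pi0, 1)
})
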