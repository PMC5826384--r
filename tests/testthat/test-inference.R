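test_that("permutation p-values match exhaustive enumeration for small n", {
    # the engine enumerates all relabelings when feasible, so its p-value
    # must equal the brute-force oracle exactly
    cases <- list(
        list(a = c(5, 6, 7), b = c(1, 2, 3)),
        list(a = c(1.2, 3.4, 2.2, 5.0), b = c(0.5, 1.1, 2.0, 0.2)),
        list(a = c(10, 11), b = c(10, 11, 12, 9)),
        list(a = rnorm(4), b = rnorm(4)))
    set.seed(30)
    for (cs in cases) {
        for (dir in c("greater", "less")) {
            res <- permutationTestMetric(cs$a, cs$b, nPerm = 10000,
                                         direction = dir, seed = 1)
            expect_equal(res@pValue, exhaustivePermP(cs$a, cs$b, dir))
            expect_equal(res@nPerm, choose(length(cs$a) + length(cs$b),
                                           length(cs$a)))
        }
    }
})

test_that("permutation test handles degenerate and mirrored inputs", {
    res <- permutationTestMetric(c(2, 2, 2), c(2, 2, 2), nPerm = 500)
    expect_equal(res@observedDiff, 0)
    expect_equal(res@pValue, 1)

    # swapping groups negates the difference and mirrors the p-value
    a <- c(4.1, 5.2, 6.3, 3.9, 5.5); b <- c(2.0, 3.1, 2.8, 3.5, 2.2)
    r1 <- permutationTestMetric(a, b, direction = "greater", seed = 2)
    r2 <- permutationTestMetric(b, a, direction = "less", seed = 2)
    expect_equal(r1@observedDiff, -r2@observedDiff)
    expect_equal(r1@pValue, r2@pValue)

    # determinism in the sampled regime
    x <- rnorm(20); y <- rnorm(20)
    s1 <- permutationTestMetric(x, y, nPerm = 300, seed = 5)
    s2 <- permutationTestMetric(x, y, nPerm = 300, seed = 5)
    expect_identical(s1@nullDist, s2@nullDist)
    expect_warning(permutationTestMetric(x, y, nPerm = 50, seed = 1),
                   "coarse")
})

test_that("percentile rule and add-one p-value agree at their shared level", {
    set.seed(31)
    for (i in 1:20) {
        a <- rnorm(12); b <- rnorm(12)
        res <- permutationTestMetric(a, b, nPerm = 2000, seed = i)
        # the two decision rules may differ only within 1/nPerm of 0.05
        if (res@pValue < 0.05 - 1 / res@nPerm)
            expect_true(res@significantPercentile)
        if (res@pValue > 0.05 + 1 / res@nPerm)
            expect_false(res@significantPercentile)
    }
})

test_that("BH step-up rule matches hand computation and brute force", {
    expect_true(fdrBH(0.04, q = 0.05))
    expect_identical(fdrBH(numeric(0)), logical(0))
    expect_identical(fdrBH(rep(0.001, 10), q = 0.05), rep(TRUE, 10))

    # hand case: 0.03 <= (3/4) * 0.05 so the first three pass
    expect_identical(fdrBH(c(0.01, 0.02, 0.03, 0.20), q = 0.05),
                     c(TRUE, TRUE, TRUE, FALSE))

    # brute-force step-up enumeration over all cutoffs
    bruteBH <- function(p, q) {
        m <- length(p)
        ord <- order(p)
        k <- 0
        for (i in seq_len(m)) if (p[ord[i]] <= i / m * q) k <- i
        mask <- logical(m)
        if (k > 0) mask[ord[seq_len(k)]] <- TRUE
        mask
    }
    p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
    expect_identical(fdrBH(p, 0.05), bruteBH(p, 0.05))
    set.seed(32)
    for (i in 1:20) {
        p <- runif(sample(3:40, 1))
        expect_identical(fdrBH(p, 0.05), bruteBH(p, 0.05))
    }
})

test_that("nodal comparison shares permutations and controls FDR", {
    set.seed(33)
    nodalA <- matrix(rnorm(8 * 12), 8, 12)
    nodalB <- matrix(rnorm(8 * 12), 8, 12)
    nodalA[, 1] <- nodalA[, 1] + 3          # one real effect
    res <- nodalComparison(nodalA, nodalB, nPerm = 2000, seed = 3)
    expect_length(res$p, 12)
    expect_true(res$significant[1])
    expect_lt(res$p[1], 0.01)
    # identical inputs give identical outputs (shared index matrix)
    res2 <- nodalComparison(nodalA, nodalB, nPerm = 2000, seed = 3)
    expect_identical(res$p, res2$p)
})

test_that("summary t-test reproduces printed demographic comparisons", {
    age <- twoSampleTSummary(38.67, 9.53, 36, 37.79, 9.92, 38)
    expect_equal(round(age$p, 3), 0.699)
    expect_equal(age$df, 72)

    edu <- twoSampleTSummary(10.06, 3.81, 36, 11.66, 3.20, 38)
    expect_equal(round(edu$p, 3), 0.054)

    # identical groups: t = 0, p = 1
    same <- twoSampleTSummary(5, 1, 10, 5, 1, 10)
    expect_equal(same$t, 0); expect_equal(same$p, 1)
    degenerate <- twoSampleTSummary(5, 0, 10, 5, 0, 10)
    expect_equal(degenerate$p, 1)

    # raw-sample interface agrees with stats::t.test(var.equal = TRUE)
    set.seed(34)
    a <- rnorm(15, 1); b <- rnorm(12)
    mine <- twoSampleT(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("chi-square test matches the printed sex table and hand arithmetic", {
    sex <- chiSquare2x2(matrix(c(12, 24, 12, 26), 2, byrow = TRUE))
    expect_equal(round(sex$p, 3), 0.872)
    expect_equal(sex$df, 1)

    # perfectly proportional table: chi2 = 0
    prop <- chiSquare2x2(matrix(c(10, 20, 20, 40), 2, byrow = TRUE))
    expect_equal(prop$chi2, 0); expect_equal(prop$p, 1)

    # direct sum((O - E)^2 / E) oracle
    tab <- matrix(c(5, 15, 15, 5), 2, byrow = TRUE)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2Hand <- sum((tab - E)^2 / E)
    expect_equal(chiSquare2x2(tab)$chi2, chi2Hand, tolerance = 1e-12)

    expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("NBS components match a union-find-free oracle on fixed edges", {
    # construct connectivity stacks that force suprathreshold edges
    # exactly at (1,2), (2,3), (6,7): two components of sizes 2 and 1
    N <- 8; nSubj <- 12
    makeConn <- function(bump) {
        base <- matrix(0.4, N, N); diag(base) <- 0
        base[1, 2] <- base[2, 1] <- 0.4 + bump
        base[2, 3] <- base[3, 2] <- 0.4 + bump
        base[6, 7] <- base[7, 6] <- 0.4 + bump
        base
    }
    set.seed(35)
    jitter <- function(m) {
        e <- matrix(rnorm(N * N, 0, 0.01), N, N)
        e <- (e + t(e)) / 2; diag(e) <- 0
        out <- m + e
        dimnames(out) <- list(sprintf("R%02d", 1:N), sprintf("R%02d", 1:N))
        out
    }
    connA <- lapply(1:6, function(i) jitter(makeConn(0.3)))
    connB <- lapply(1:6, function(i) jitter(makeConn(0)))
    res <- nbs(connA, connB, primaryAlpha = 1e-6, nPerm = 200,
               positiveFrac = 0.85, seed = 4)
    expect_equal(sort(res@componentSizes, decreasing = TRUE), c(2L, 1L))
    top <- res@components[[1]]
    expect_setequal(paste(top$roi_a, top$roi_b),
                    c("R01 R02", "R02 R03"))
    # oracle: flood-fill over the suprathreshold adjacency
    supraW <- matrix(0, N, N)
    supraW[1, 2] <- supraW[2, 1] <- 1
    supraW[2, 3] <- supraW[3, 2] <- 1
    supraW[6, 7] <- supraW[7, 6] <- 1
    memb <- floodFillComponents(supraW)
    expect_equal(sum(memb[c(1, 2, 3)] == memb[1]), 3)
    expect_equal(memb[6], memb[7])
    expect_false(memb[1] == memb[6])
})

test_that("NBS respects the positivity rule and empty results warn", {
    N <- 6
    mk <- function(val) {
        m <- matrix(val, N, N); diag(m) <- 0
        m + (matrix(rnorm(N * N, 0, 1e-3), N, N) +
             t(matrix(rnorm(N * N, 0, 1e-3), N, N))) / 2
    }
    set.seed(36)
    negConn <- lapply(1:8, function(i) { m <- mk(-0.3); diag(m) <- 0; m })
    expect_warning(res <- nbs(negConn[1:4], negConn[5:8], nPerm = 50,
                              seed = 1),
                   "positivity")
    expect_length(res@componentSizes, 0)
})

test_that("NBS null distribution is stable across seeds", {
    conn <- nullConnectivitySet(seed = 11, nSubj = 16, nVolumes = 120)
    r1 <- nbs(conn[1:8], conn[9:16], nPerm = 2000, seed = 100)
    r2 <- nbs(conn[1:8], conn[9:16], nPerm = 2000, seed = 200)
    ks <- suppressWarnings(
        ks.test(r1@nullMaxSizes, r2@nullMaxSizes)$statistic)
    expect_lt(unname(ks), 0.05)
    # determinism under one seed
    r3 <- nbs(conn[1:8], conn[9:16], nPerm = 500, seed = 100)
    r4 <- nbs(conn[1:8], conn[9:16], nPerm = 500, seed = 100)
    expect_identical(r3@nullMaxSizes, r4@nullMaxSizes)
})
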