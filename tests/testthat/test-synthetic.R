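test_that("population covariance assembles block structure entry by entry", {
    sp <- syntheticSpec(nRois = 6, nVolumes = 30, nGroupA = 4, nGroupB = 4,
                        blockSizes = c(3, 3), withinBlockCov = 0.4,
                        betweenBlockCov = 0.1,
                        effectEdges = cbind(1L, 4L), effectDelta = 0.2,
                        noiseSd = 0)
    sigmaA <- buildPopulationCov(sp, "A")
    sigmaB <- buildPopulationCov(sp, "B")

    # element-by-element oracle: block id of each ROI decides the level
    blockOf <- rep(1:2, each = 3)
    for (i in 1:6) for (j in 1:6) {
        expected <- if (i == j) 1.0 else
            if (blockOf[i] == blockOf[j]) 0.4 else 0.1
        expect_equal(sigmaB[i, j], expected)
    }
    expect_equal(sigmaA[1, 4], 0.1 + 0.2)
    expect_equal(sigmaA[4, 1], 0.1 + 0.2)
    offEffect <- sigmaA; offEffect[1, 4] <- offEffect[4, 1] <- sigmaB[1, 4]
    expect_equal(offEffect, sigmaB)
})

test_that("zero effect delta makes the two group covariances identical", {
    sp <- syntheticSpec(nRois = 8, nVolumes = 30, nGroupA = 2, nGroupB = 2,
                        blockSizes = c(4, 4),
                        effectEdges = cbind(c(1L, 2L), c(2L, 3L)),
                        effectDelta = 0)
    expect_identical(buildPopulationCov(sp, "A"),
                     buildPopulationCov(sp, "B"))
})

test_that("single-block covariance with no noise is constant off-diagonal", {
    sp <- syntheticSpec(nRois = 4, nVolumes = 30, nGroupA = 2, nGroupB = 2,
                        blockSizes = 4L, withinBlockCov = 0.3,
                        betweenBlockCov = 0.05, noiseSd = 0)
    sigma <- buildPopulationCov(sp, "B")
    expect_equal(diag(sigma), rep(1, 4))
    expect_true(all(sigma[upper.tri(sigma)] == 0.3))
})

test_that("sampled series reproduce the generating covariance structure", {
    # identity innovations: off-diagonal sample correlations vanish
    ts <- sampleTimeSeries(diag(8), 50000, arCoeff = 0, seed = 42)
    r <- cor(seriesMatrix(ts))
    expect_lt(max(abs(r[upper.tri(r)])), 0.02)

    # planted r = 0.5 on one pair recovered within Fisher-z sampling error
    sigma <- diag(5); sigma[1, 2] <- sigma[2, 1] <- 0.5
    ts2 <- sampleTimeSeries(sigma, 10000, arCoeff = 0, seed = 7)
    r12 <- cor(seriesMatrix(ts2))[1, 2]
    expect_gt(r12, 0.45); expect_lt(r12, 0.55)

    # AR(1) filtering preserves cross-sectional correlation
    ts3 <- sampleTimeSeries(sigma, 10000, arCoeff = 0.5, seed = 7)
    expect_lt(abs(cor(seriesMatrix(ts3))[1, 2] - 0.5), 0.05)
})

test_that("time-series sampling is seed-deterministic and rejects short runs", {
    sigma <- diag(4)
    a <- sampleTimeSeries(sigma, 40, 0.3, seed = 11)
    b <- sampleTimeSeries(sigma, 40, 0.3, seed = 11)
    expect_identical(seriesMatrix(a), seriesMatrix(b))
    expect_error(sampleTimeSeries(sigma, 19, 0, seed = 1), "at least 20")
})

test_that("motion traces are random walks honouring amplitude and seed", {
    mp0 <- generateMotion(50, amplitude = 0, seed = 3)
    expect_true(all(motionMatrix(mp0) == 0))
    fd0 <- framewiseDisplacement(mp0)
    expect_true(all(fd0$fd == 0))
    expect_equal(fd0$max, 0)

    m1 <- generateMotion(50, amplitude = 0.05, seed = 9)
    m2 <- generateMotion(50, amplitude = 0.05, seed = 9)
    expect_identical(motionMatrix(m1), motionMatrix(m2))
    expect_true(all(motionMatrix(m1)[1, ] == 0))

    # a large-amplitude walk must cross the 2 mm exclusion limit:
    # 100 steps of SD 2 mm have cumulative SD 20 mm at the end
    big <- generateMotion(100, amplitude = 2, seed = 5)
    expect_true(motionExclusion(big)$exclude)
})

test_that("cohort generation is reproducible and carries the group design", {
    sp <- syntheticSpec(nRois = 10, nVolumes = 40, nGroupA = 5, nGroupB = 6,
                        blockSizes = c(5, 5), seed = 21)
    coh1 <- generateCohort(sp)
    coh2 <- generateCohort(sp)
    tab <- cohortTable(coh1)
    expect_equal(nrow(tab), 11)
    expect_equal(sum(tab$group == "A"), 5)
    expect_identical(tab, cohortTable(coh2))
    expect_identical(seriesMatrix(cohortTimeSeries(coh1)[["S003"]]),
                     seriesMatrix(cohortTimeSeries(coh2)[["S003"]]))
    # control-like group has no ESS / duration, patient-like group does
    expect_true(all(is.na(tab$ESS[tab$group == "B"])))
    expect_true(all(!is.na(tab$ESS[tab$group == "A"])))
})

test_that("default cohort size matches the study design (36 + 38)", {
    sp <- syntheticSpec()
    expect_equal(sp@nGroupA + sp@nGroupB, 74L)
    expect_equal(sp@nVolumes, 230L)
    expect_equal(sp@nRois, 246L)
    expect_equal(sum(sp@blockSizes), 246L)
})

test_that("planted effect shifts sample correlations only on effect edges", {
    # large-T single-subject check per group, strength jitter disabled
    eff <- cbind(c(1L, 2L), c(6L, 7L))
    sp <- syntheticSpec(nRois = 10, nVolumes = 20000, nGroupA = 2,
                        nGroupB = 2, blockSizes = c(5, 5),
                        withinBlockCov = 0.4, betweenBlockCov = 0.1,
                        effectEdges = eff, effectDelta = 0.3,
                        subjectStrengthSd = 0, arCoeff = 0, seed = 1)
    sigmaA <- buildPopulationCov(sp, "A")
    sigmaB <- buildPopulationCov(sp, "B")
    rA <- cor(seriesMatrix(sampleTimeSeries(sigmaA, 20000, seed = 2)))
    rB <- cor(seriesMatrix(sampleTimeSeries(sigmaB, 20000, seed = 3)))
    diffs <- abs(rA - rB)
    onEffect <- matrix(FALSE, 10, 10)
    onEffect[eff] <- TRUE; onEffect <- onEffect | t(onEffect)
    # effect edges move by ~ delta / diag; everything else stays put
    expect_true(all(diffs[onEffect] > 0.15))
    expect_lt(max(diffs[!onEffect & upper.tri(diffs)]), 0.06)
})

test_that("behavioral coupling links the coupled score to connectivity strength", {
    sp <- syntheticSpec(nRois = 10, nVolumes = 40, nGroupA = 30, nGroupB = 5,
                        blockSizes = c(5, 5), behaviorCoupling = 20,
                        behaviorNoiseSd = 0.1, subjectStrengthSd = 0.8,
                        effectEdges = plantedClique()[1:3, , drop = FALSE],
                        effectDelta = 0.2, seed = 4)
    coh <- generateCohort(sp)
    tab <- cohortTable(coh)
    # stronger global connectivity => larger coupled score by construction
    expect_gt(stats::sd(tab$coupled), 0)
    # zero coupling gives scores that are pure noise
    sp0 <- syntheticSpec(nRois = 10, nVolumes = 40, nGroupA = 30,
                         nGroupB = 5, blockSizes = c(5, 5),
                         behaviorCoupling = 0, seed = 4)
    tab0 <- cohortTable(generateCohort(sp0))
    expect_lt(abs(mean(tab0$coupled)), 1)
})

test_that("invalid specs are rejected with informative errors", {
    expect_error(syntheticSpec(nRois = 10, blockSizes = c(4, 4)),
                 "sum to nRois")
    expect_error(syntheticSpec(nRois = 10, blockSizes = c(5, 5),
                               withinBlockCov = 0.2, betweenBlockCov = 0.3),
                 "betweenBlockCov")
    expect_error(syntheticSpec(nRois = 10, blockSizes = c(5, 5),
                               arCoeff = 1), "arCoeff")
    expect_error(syntheticSpec(nRois = 10, blockSizes = c(5, 5),
                               effectEdges = cbind(1L, 11L)),
                 "out of range")
})
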