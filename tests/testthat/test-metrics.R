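test_that("shortest paths use reciprocal-weight lengths", {
    # chain of unit lengths
    d <- shortestPathLengths(makePathGraph(4))
    expect_equal(d[1, 4], 3)

    # indirect strong path beats a weak direct edge
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 0.9
    w[2, 3] <- w[3, 2] <- 0.9
    w[1, 3] <- w[3, 1] <- 0.2
    d2 <- shortestPathLengths(brainGraph(w))
    expect_equal(d2[1, 3], 1 / 0.9 + 1 / 0.9)

    # disconnected dyads are infinitely far apart
    w3 <- matrix(0, 4, 4)
    w3[1, 2] <- w3[2, 1] <- 1
    w3[3, 4] <- w3[4, 3] <- 1
    d3 <- shortestPathLengths(brainGraph(w3))
    expect_equal(d3[1, 3], Inf)
    expect_equal(d3[2, 4], Inf)
})

test_that("distances equal a Floyd-Warshall oracle on random graphs", {
    for (seed in 1:20) {
        N <- sample(4:12, 1)
        g <- makeRandomWeightedGraph(N, density = runif(1, 0.2, 0.7),
                                     seed = seed * 13)
        expect_equal(unname(shortestPathLengths(g)),
                     floydWarshallOracle(adjacency(g)),
                     tolerance = 1e-12)
    }
})

test_that("efficiency closed forms hold on canonical graphs", {
    # complete unit-weight graph
    k4 <- brainGraph(matrix(1, 4, 4) - diag(4))
    expect_equal(globalEfficiency(k4), 1)
    expect_equal(unname(nodalEfficiency(k4)), rep(1, 4))
    expect_equal(localEfficiency(k4), 1)

    # unit-weight path on 4 nodes: pair distances {1,1,1,2,2,3}
    gPath <- makePathGraph(4)
    expect_equal(globalEfficiency(gPath), 13 / 18)
    expect_equal(unname(nodalEfficiency(gPath)[1]), 11 / 18)
    expect_equal(localEfficiency(gPath), 0)     # triangle-free

    # empty graph: all pairs unreachable
    expect_equal(globalEfficiency(brainGraph(matrix(0, 5, 5))), 0)

    # isolated node has zero nodal efficiency
    w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
    expect_equal(unname(nodalEfficiency(brainGraph(w))[3]), 0)

    # triangle {1,2,3} with pendants 3-4, 3-5: E_loc = 13/30
    w5 <- matrix(0, 5, 5)
    for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5)))
        w5[e[1], e[2]] <- w5[e[2], e[1]] <- 1
    expect_equal(localEfficiency(brainGraph(w5)), 13 / 30)
})

test_that("global efficiency equals mean nodal efficiency on random graphs", {
    for (seed in 1:200) {
        N <- sample(4:12, 1)
        g <- makeRandomWeightedGraph(N, density = runif(1, 0.1, 0.9),
                                     seed = seed)
        expect_equal(globalEfficiency(g), mean(nodalEfficiency(g)),
                     tolerance = 1e-12)
    }
})

test_that("efficiency is bounded and monotone under edge addition", {
    for (seed in 1:25) {
        g <- makeRandomWeightedGraph(10, density = 0.3, seed = seed + 500)
        e <- globalEfficiency(g)
        expect_gte(e, 0); expect_lte(e, 1)
        expect_true(all(nodalEfficiency(g) >= 0 & nodalEfficiency(g) <= 1))
        # add one absent edge with maximal weight
        w <- adjacency(g)
        absent <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
        if (nrow(absent) == 0) next
        ij <- absent[1, ]
        w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- 1
        g2 <- brainGraph(w)
        expect_gte(globalEfficiency(g2), e)
        expect_true(all(nodalEfficiency(g2) >= nodalEfficiency(g) - 1e-12))
    }
})

test_that("rewiring preserves degrees and the weight multiset", {
    g <- makeRandomWeightedGraph(16, density = 0.35, seed = 77)
    degrees <- rowSums(adjacency(g) != 0)
    weights <- sort(adjacency(g)[upper.tri(adjacency(g))])
    weights <- weights[weights != 0]
    changed <- 0
    for (seed in 1:100) {
        rg <- rewirePreservingDegree(g, seed = seed)
        expect_identical(rowSums(adjacency(rg) != 0), degrees)
        expect_equal(nodeCount(rg), nodeCount(g))
        expect_equal(edgeCount(rg), edgeCount(g))
        wts <- adjacency(rg)[upper.tri(adjacency(rg))]
        expect_equal(sort(wts[wts != 0]), unname(weights))
        if (!identical(adjacency(rg) != 0, adjacency(g) != 0))
            changed <- changed + 1
    }
    expect_gt(changed, 95)   # rewiring actually moves the topology

    # complete graph cannot be rewired
    k5 <- brainGraph(matrix(1, 5, 5) - diag(5))
    expect_warning(same <- rewirePreservingDegree(k5, seed = 1),
                   "complete")
    expect_identical(adjacency(same), adjacency(k5))

    # determinism
    r1 <- rewirePreservingDegree(g, seed = 42)
    r2 <- rewirePreservingDegree(g, seed = 42)
    expect_identical(adjacency(r1), adjacency(r2))
})

test_that("normalization behaves correctly for random and lattice graphs", {
    # a random graph is statistically identical to its own rewires
    gr <- makeRandomGraph(60, p = 0.12, seed = 3)
    nr <- normalizedEfficiencies(gr, nRandom = 100, seed = 3)
    expect_gt(nr$normEGlob, 0.95); expect_lt(nr$normEGlob, 1.05)

    # lattice clustering exceeds rewired clustering
    gl <- makeRingLattice(60, 4)
    nl <- normalizedEfficiencies(gl, nRandom = 30, seed = 4)
    expect_gt(nl$normELoc, 1)
    # rewires of a lattice are more globally efficient than the lattice
    expect_gt(mean(nl$randEGlob), globalEfficiency(gl))

    # determinism at nRandom = 1
    a <- normalizedEfficiencies(gr, nRandom = 1, seed = 9)
    b <- normalizedEfficiencies(gr, nRandom = 1, seed = 9)
    expect_identical(a, b)
})

test_that("the small-world rule applies both criteria with margins", {
    expect_true(isSmallWorld(globalMetrics(0.5, 0.6, 0.940, 1.270, 100L)))
    expect_true(isSmallWorld(globalMetrics(0.5, 0.6, 0.954, 1.221, 100L)))
    expect_false(isSmallWorld(globalMetrics(0.5, 0.6, 1.0, 0.9, 100L)))
    expect_false(isSmallWorld(globalMetrics(0.5, 0.6, 0.85, 1.5, 100L)))
    # strict textbook reading available via locTol = 0
    expect_true(isSmallWorld(globalMetrics(0.5, 0.6, 1.0, 1.01, 100L),
                             locTol = 0))
    expect_false(isSmallWorld(globalMetrics(0.5, 0.6, 1.0, 1.01, 100L)))
    expect_error(isSmallWorld(globalMetrics(0.5, 0.6)), "missing")
})
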