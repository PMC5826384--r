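# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (loops, enumeration) and share no code
# with the package internals they check.

# unit-weight path graph on n nodes
makePathGraph <- function(n = 4) {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
    brainGraph(w)
}

# ring lattice: every node linked to its k nearest ring neighbours
makeRingLattice <- function(N = 60, k = 4) {
    w <- matrix(0, N, N)
    for (i in seq_len(N)) {
        for (d in seq_len(k / 2)) {
            j <- ((i + d - 1) %% N) + 1
            w[i, j] <- w[j, i] <- 1
        }
    }
    brainGraph(w)
}

# ring lattice plus random unit-weight shortcuts (small-world regime)
makeShortcutLattice <- function(N = 60, k = 4, shortcuts = 60, seed = 1) {
    g <- makeRingLattice(N, k)
    w <- adjacency(g)
    set.seed(seed)
    added <- 0
    while (added < shortcuts) {
        ij <- sample(N, 2)
        if (w[ij[1], ij[2]] == 0) {
            w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- 1
            added <- added + 1
        }
    }
    brainGraph(w)
}

# Erdos-Renyi-like random graph with unit weights
makeRandomGraph <- function(N = 60, p = 0.12, seed = 1, weights = FALSE) {
    set.seed(seed)
    w <- matrix(0, N, N)
    ut <- upper.tri(w)
    edge <- stats::runif(sum(ut)) < p
    vals <- if (weights) stats::runif(sum(ut), 0.2, 1) else 1
    w[ut] <- edge * vals
    w <- w + t(w)
    brainGraph(w)
}

# random weighted graph for property sweeps (weights in (0, 1])
makeRandomWeightedGraph <- function(N, density = 0.4, seed = 1) {
    set.seed(seed)
    w <- matrix(0, N, N)
    ut <- upper.tri(w)
    m <- sum(ut)
    vals <- stats::runif(m, 0.1, 1)
    vals[stats::runif(m) > density] <- 0
    w[ut] <- vals
    brainGraph(w + t(w))
}

# --- oracles ----------------------------------------------------------

# Floyd-Warshall all-pairs shortest paths on lengths 1/w (triple loop)
floydWarshallOracle <- function(w) {
    n <- nrow(w)
    d <- matrix(Inf, n, n)
    d[w != 0] <- 1 / w[w != 0]
    diag(d) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    d
}

# component membership by breadth-first flood fill (independent of the
# package's union-find)
floodFillComponents <- function(w) {
    n <- nrow(w)
    memb <- rep(NA_integer_, n)
    comp <- 0L
    for (s in seq_len(n)) {
        if (!is.na(memb[s])) next
        comp <- comp + 1L
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (!is.na(memb[v])) next
            memb[v] <- comp
            queue <- c(queue, which(w[v, ] != 0 & is.na(memb)))
        }
    }
    memb
}

# exhaustive permutation p-value for a difference in group means
exhaustivePermP <- function(a, b, direction = "greater") {
    pooled <- c(a, b)
    nA <- length(a)
    obs <- mean(a) - mean(b)
    combos <- utils::combn(length(pooled), nA)
    null <- apply(combos, 2, function(idx)
        mean(pooled[idx]) - mean(pooled[-idx]))
    if (direction == "greater") mean(null >= obs) else mean(null <= obs)
}

# Jaccard similarity between two edge sets given as 2-column index matrices
edgeJaccard <- function(e1, e2) {
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    length(intersect(key(e1), key(e2))) / length(union(key(e1), key(e2)))
}

# map component ROI labels back to indices
componentEdgeIndices <- function(component, labels) {
    cbind(match(component$roi_a, labels), match(component$roi_b, labels))
}

# 4-node clique (6 edges) planted in the first block; the standard
# effect fixture for NBS recovery tests
plantedClique <- function() {
    cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L))
}

# low-noise planted-effect cohort: four independent 5-ROI systems,
# moderate within-system covariance, effect on the 6-edge clique
effectCohortSpec <- function(seed, delta = 0.4, nA = 8, nB = 8) {
    syntheticSpec(nRois = 20, nVolumes = 230, nGroupA = nA, nGroupB = nB,
                  blockSizes = c(5, 5, 5, 5), withinBlockCov = 0.3,
                  betweenBlockCov = 0, effectEdges = plantedClique(),
                  effectDelta = delta, subjectStrengthSd = 0.1,
                  seed = seed)
}

# null-calibration cohort family: two independent 10-ROI systems, no
# group effect; richer edge universe so component sizes vary finely
nullConnectivitySet <- function(seed, nSubj = 16, nVolumes = 230) {
    sp <- syntheticSpec(nRois = 20, nVolumes = nVolumes, nGroupA = nSubj / 2,
                        nGroupB = nSubj / 2, blockSizes = c(10, 10),
                        withinBlockCov = 0.3, betweenBlockCov = 0,
                        subjectStrengthSd = 0.1, seed = seed)
    sigma <- buildPopulationCov(sp, "A")
    set.seed(seed + 5000)
    g <- stats::plogis(stats::rnorm(nSubj, stats::qlogis(0.75), 0.1))
    lapply(seq_len(nSubj), function(i) {
        sigmaS <- g[i] * sigma + (1 - g[i]) * diag(diag(sigma))
        correlationMatrix(sampleTimeSeries(sigmaS, nVolumes, 0.3,
                                           seed = seed * 100 + i))
    })
}
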