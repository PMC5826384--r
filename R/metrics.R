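#' All-pairs shortest functional distances
#'
#' Shortest-path distances on edge lengths `l_ij = 1 / w_ij` (a strong
#' correlation is a short functional distance), computed by Dijkstra's
#' algorithm. Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param g a [BrainGraph-class].
#' @return symmetric N x N distance matrix.
#' @export
shortestPathLengths <- function(g) {
    N <- nodeCount(g)
    if (edgeCount(g) == 0L) {
        d <- matrix(Inf, N, N); diag(d) <- 0
        dimnames(d) <- dimnames(g@w)
        return(d)
    }
    ig <- asIgraph(g)
    d <- igraph::distances(ig, weights = igraph::E(ig)$length,
                           algorithm = "dijkstra")
    dimnames(d) <- dimnames(g@w)
    d
}

# efficiency of a raw weight matrix (internal; the 1/Inf := 0 convention
# makes isolated nodes contribute zero rather than dropping them)
efficiencyFromW <- function(w) {
    N <- nrow(w)
    if (N < 2L) return(0)
    d <- if (all(w == 0)) {
        m <- matrix(Inf, N, N); diag(m) <- 0; m
    } else {
        ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                                  weighted = TRUE,
                                                  diag = FALSE)
        igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                          algorithm = "dijkstra")
    }
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (N * (N - 1))
}

#' Global efficiency
#'
#' `E_glob(G) = (1 / (N(N-1))) * sum_(i != j) 1 / d_ij`, the mean inverse
#' shortest functional distance over ordered node pairs; unreachable
#' pairs contribute 0 (1/Inf convention), so disconnected graphs and
#' isolated nodes are handled without dropping anything.
#'
#' @param g a [BrainGraph-class] with at least 2 nodes.
#' @return efficiency in [0, 1] for correlation-valued weights.
#' @examples
#' w <- matrix(0, 4, 4)
#' for (i in 1:3) w[i, i + 1] <- w[i + 1, i] <- 1   # unit-weight path
#' globalEfficiency(brainGraph(w))                  # 13/18
#' @export
globalEfficiency <- function(g) {
    if (nodeCount(g) < 2L) stop("need at least 2 nodes")
    efficiencyFromW(g@w)
}

#' Nodal efficiency
#'
#' `e_i = (1 / (N-1)) * sum_(j != i) 1 / d_ij`: the mean inverse distance
#' from node i to every other node. Its mean over nodes is exactly the
#' global efficiency. Isolated nodes score 0.
#'
#' @param g a [BrainGraph-class].
#' @return named numeric vector of length N.
#' @export
nodalEfficiency <- function(g) {
    N <- nodeCount(g)
    if (N < 2L) stop("need at least 2 nodes")
    d <- shortestPathLengths(g)
    inv <- 1 / d
    diag(inv) <- 0
    e <- rowSums(inv) / (N - 1)
    names(e) <- roiLabels(g)
    e
}

#' Local efficiency
#'
#' `E_loc(G) = (1/N) * sum_i E_glob(G_i)`, where `G_i` is the subgraph
#' induced on the neighbors of node i (node i itself excluded), keeping
#' the original weights between neighbors. Subgraphs with fewer than two
#' nodes contribute 0. Local efficiency indexes fault tolerance: how
#' well information flows among a node's neighbors when the node is
#' removed.
#'
#' @param g a [BrainGraph-class].
#' @return local efficiency (nonnegative; in [0, 1] for
#'   correlation-valued weights).
#' @export
localEfficiency <- function(g) {
    w <- g@w
    N <- nrow(w)
    if (N < 1L) stop("need at least 1 node")
    vals <- vapply(seq_len(N), function(i) {
        nb <- which(w[i, ] != 0)
        if (length(nb) < 2L) return(0)
        efficiencyFromW(w[nb, nb, drop = FALSE])
    }, 0.0)
    mean(vals)
}

#' Degree-preserving random rewiring
#'
#' Randomizes the binary topology by repeated double-edge swaps (a swap
#' is rejected if it would create a self-loop or duplicate edge),
#' attempting `swapFactor * K` swaps, then reassigns the original weight
#' multiset to the rewired edges in a seeded random permutation. Node
#' count, edge count, the exact degree sequence, and the weight multiset
#' are all preserved; only the wiring (and the weight-to-edge pairing)
#' changes. This is the null model the efficiency normalization divides
#' by.
#'
#' @param g a [BrainGraph-class] with at least 2 edges.
#' @param seed RNG seed.
#' @param swapFactor attempted swaps per edge (default 20, enough for the
#'   topology to decorrelate from the input on graphs of this size).
#' @return a rewired [BrainGraph-class].
#' @export
rewirePreservingDegree <- function(g, seed = 1L, swapFactor = 20) {
    K <- edgeCount(g)
    if (K < 2L) stop("rewiring needs at least 2 edges")
    N <- nodeCount(g)
    if (K == N * (N - 1) / 2) {
        warning("complete graph: no degree-preserving swap exists; returned unchanged")
        return(g)
    }
    set.seed(as.integer(seed))
    ig <- igraph::graph_from_adjacency_matrix(g@w != 0, mode = "undirected",
                                              diag = FALSE)
    ig <- igraph::rewire(ig, igraph::keeping_degseq(niter = swapFactor * K))
    el <- igraph::as_edgelist(ig, names = FALSE)
    weights <- g@w[upper.tri(g@w)]
    weights <- sample(weights[weights != 0])
    w <- matrix(0, N, N)
    w[el] <- weights
    w[el[, c(2L, 1L)]] <- weights
    brainGraph(w, roiLabels = roiLabels(g))
}

#' Random-network normalized efficiencies
#'
#' Divides a network's global and local efficiency by the corresponding
#' means over `nRandom` degree-preserving random rewires (independently
#' seeded from `seed`, hence reproducible). Values near 1 mean the
#' network behaves like its degree-matched random counterpart.
#'
#' @param g a [BrainGraph-class].
#' @param nRandom number of random networks (default 100).
#' @param seed RNG seed.
#' @param swapFactor passed to [rewirePreservingDegree()].
#' @return list with `normEGlob`, `normELoc`, `randEGlob`, `randELoc`
#'   (the per-rewire values). A zero random mean yields NA with a
#'   warning.
#' @export
normalizedEfficiencies <- function(g, nRandom = 100L, seed = 1L,
                                   swapFactor = 20) {
    seeds <- vapply(seq_len(nRandom),
                    function(i) deriveSeed(seed, i), 0L)
    randG <- numeric(nRandom); randL <- numeric(nRandom)
    for (i in seq_len(nRandom)) {
        rg <- suppressWarnings(
            rewirePreservingDegree(g, seed = seeds[i],
                                   swapFactor = swapFactor))
        randG[i] <- globalEfficiency(rg)
        randL[i] <- localEfficiency(rg)
    }
    mG <- mean(randG); mL <- mean(randL)
    normG <- if (mG > 0) globalEfficiency(g) / mG else {
        warning("mean random global efficiency is zero; normalization undefined")
        NA_real_
    }
    normL <- if (mL > 0) localEfficiency(g) / mL else {
        warning("mean random local efficiency is zero; normalization undefined")
        NA_real_
    }
    list(normEGlob = normG, normELoc = normL,
         randEGlob = randG, randELoc = randL)
}

#' Per-subject small-world metric summary
#'
#' Convenience wrapper computing density, global/local efficiency and
#' their random-network normalizations for one network.
#'
#' @param g a [BrainGraph-class].
#' @param nRandom random networks for normalization (default 100; 0
#'   skips normalization).
#' @param seed RNG seed.
#' @param swapFactor passed to [rewirePreservingDegree()].
#' @return a [GlobalMetrics-class].
#' @export
computeGlobalMetrics <- function(g, nRandom = 100L, seed = 1L,
                                 swapFactor = 20) {
    eG <- globalEfficiency(g)
    eL <- localEfficiency(g)
    if (nRandom > 0L && edgeCount(g) >= 2L) {
        nrm <- normalizedEfficiencies(g, nRandom = nRandom, seed = seed,
                                      swapFactor = swapFactor)
        globalMetrics(eG, eL, nrm$normEGlob, nrm$normELoc, nRandom,
                      networkDensity(g))
    } else {
        globalMetrics(eG, eL, density = networkDensity(g))
    }
}

#' Small-world criterion
#'
#' A network is called small-world when its normalized global efficiency
#' is approximately 1 (within `globTol`) and its normalized local
#' efficiency exceeds 1 by more than `locTol`. The margin `locTol`
#' (default 0.05) guards against the sampling fluctuation of the
#' rewiring null: for a graph that *is* its own null (a random graph)
#' the local ratio straddles 1, and a strict `> 1` rule would classify
#' half of such graphs as small-world. `locTol = 0` recovers the strict
#' textbook rule.
#'
#' @param m a [GlobalMetrics-class] with normalized values present.
#' @param globTol tolerance on |normEGlob - 1| (default 0.1).
#' @param locTol required margin of normELoc above 1 (default 0.05).
#' @return logical.
#' @examples
#' isSmallWorld(globalMetrics(0.5, 0.6, 0.94, 1.27, 100L))  # TRUE
#' @export
isSmallWorld <- function(m, globTol = 0.1, locTol = 0.05) {
    if (is.na(m@normEGlob) || is.na(m@normELoc))
        stop("normalized efficiencies are missing; run normalizedEfficiencies first")
    abs(m@normEGlob - 1) <= globTol && m@normELoc > 1 + locTol
}
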