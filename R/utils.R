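# Internal helpers shared across modules.

# Connected-component labelling on an edge list via weighted union-find.
# edges: integer matrix with two columns of 1-based node indices.
# Returns an integer membership vector of length n (component ids 1..k).
unionFindLabel <- function(edges, n) {
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    if (nrow(edges)) {
        for (e in seq_len(nrow(edges))) {
            ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
            if (ra != rb) parent[rb] <- ra
        }
    }
    roots <- vapply(seq_len(n), find, 0L)
    match(roots, unique(roots))
}

# Indices of the upper triangle as a two-column matrix (column-major order,
# i < j), shared by the NBS and thresholding code so edge vectorization is
# consistent everywhere.
upperTriPairs <- function(n) {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector.
symmetricFromUpper <- function(values, n, labels = NULL) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- values
    m <- m + t(m)
    if (!is.null(labels)) dimnames(m) <- list(labels, labels)
    m
}

# Stage seeds are derived from one master seed by fixed small offsets so a
# whole run is reproducible from the configuration alone; kept < 2^31.
deriveSeed <- function(masterSeed, offset) {
    as.integer((as.numeric(masterSeed) * 1000 + offset) %% 2147483647)
}

# Deterministic per-subject seed stream.
subjectSeeds <- function(masterSeed, nSubjects, stage) {
    vapply(seq_len(nSubjects),
           function(i) deriveSeed(masterSeed, stage * 100000 + i), 0L)
}
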