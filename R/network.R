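#' Pairwise ROI correlation matrix with p-values
#'
#' Computes the N x N Pearson correlation matrix between ROI time series
#' and its two-tailed p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#' The diagonal of `r` is set to 0 by convention (self-correlations are
#' never analysed). Constant columns yield r = 0, p = 1 with a warning.
#'
#' @param ts a [RoiTimeSeries-class] with at least 5 time points.
#' @return a [ConnectivityMatrix-class].
#' @export
correlationMatrix <- function(ts) {
    x <- ts@data
    n <- nrow(x)
    if (n < 5L) stop("need at least 5 time points for correlation")
    sds <- apply(x, 2L, stats::sd)
    constant <- sds == 0
    if (any(constant)) {
        warning(sprintf("%d constant ROI column(s); their correlations are set to 0 (p = 1)",
                        sum(constant)))
        x[, constant] <- seq_len(n)  # placeholder; entries overwritten below
    }
    r <- stats::cor(x)
    r[constant, ] <- 0; r[, constant] <- 0
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[constant, ] <- 1; p[, constant] <- 1
    diag(r) <- 0
    diag(p) <- 1
    dimnames(r) <- dimnames(p) <- list(colnames(ts@data), colnames(ts@data))
    new("ConnectivityMatrix", subjectID = ts@subjectID, r = r, p = p,
        nSamples = as.integer(n))
}

#' Bonferroni significance thresholding
#'
#' Retains edge (i, j) iff its two-tailed p-value is below
#' `alpha / m`, with m = N(N-1)/2 unique connections, AND its
#' correlation is positive (negative correlations are excluded).
#' Retained weights are the raw correlation coefficients, unrescaled.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param alpha family-wise significance level (default 0.05).
#' @return a [BrainGraph-class].
#' @examples
#' ts <- sampleTimeSeries(diag(6) * 0.5 + 0.5, 100, seed = 1)
#' g <- thresholdBonferroni(correlationMatrix(ts))
#' networkDensity(g)
#' @export
thresholdBonferroni <- function(cm, alpha = 0.05) {
    N <- nrow(cm@r)
    m <- N * (N - 1) / 2
    keep <- (cm@p < alpha / m) & (cm@r > 0)
    w <- ifelse(keep, cm@r, 0)
    diag(w) <- 0
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    brainGraph(w, roiLabels = rownames(cm@r))
}

#' Network density
#'
#' Fraction of the N(N-1)/2 possible connections that are present:
#' `2K / (N(N-1))`.
#'
#' @param g a [BrainGraph-class].
#' @return density in [0, 1].
#' @export
networkDensity <- function(g) {
    N <- nodeCount(g)
    if (N < 2L) stop("density needs at least 2 nodes")
    2 * edgeCount(g) / (N * (N - 1))
}

#' Connected-component census
#'
#' Finds connected components of the binarized topology and reports the
#' isolated (degree-zero) nodes; the analysis keeps such nodes in the
#' graph, where they contribute zero to efficiency sums.
#'
#' @param g a [BrainGraph-class].
#' @return list with `nComponents`, `largestSize`, `isolated` (character
#'   labels) and `membership` (integer vector).
#' @export
componentCensus <- function(g) {
    ig <- asIgraph(g)
    comp <- igraph::components(ig)
    deg <- igraph::degree(ig)
    list(nComponents = comp$no,
         largestSize = max(comp$csize),
         isolated = roiLabels(g)[deg == 0],
         membership = as.integer(comp$membership))
}

# BrainGraph -> igraph with edge lengths 1/w available as 'length'
asIgraph <- function(g) {
    ig <- igraph::graph_from_adjacency_matrix(g@w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    if (igraph::ecount(ig) > 0)
        igraph::E(ig)$length <- 1 / igraph::E(ig)$weight
    ig
}
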