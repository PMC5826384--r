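# Permutation relabeling matrix: rows = relabelings, TRUE marks membership
# of group A. When the total number of distinct relabelings is within
# nPerm, all of them are enumerated (the test becomes exact); otherwise
# nPerm seeded random relabelings are drawn.
relabelMatrix <- function(n, nA, nPerm, seed) {
    nTotal <- choose(n, nA)
    if (is.finite(nTotal) && nTotal <= nPerm) {
        combos <- utils::combn(n, nA)
        P <- matrix(FALSE, ncol(combos), n)
        for (i in seq_len(ncol(combos))) P[i, combos[, i]] <- TRUE
        attr(P, "exhaustive") <- TRUE
        return(P)
    }
    set.seed(as.integer(seed))
    P <- matrix(FALSE, nPerm, n)
    for (i in seq_len(nPerm)) P[i, sample.int(n, nA)] <- TRUE
    attr(P, "exhaustive") <- FALSE
    P
}

#' Permutation test for a group difference in a scalar metric
#'
#' Tests `mean(valuesA) - mean(valuesB)` against the empirical null
#' obtained by randomly reallocating all values into two groups of the
#' original sizes. Two significance readings are reported: the add-one
#' (never-zero) permutation p-value, and the 95th-percentile critical
#' value rule (one-tailed: the observed difference is significant when
#' it exceeds the null's 95th percentile). When all distinct relabelings
#' number at most `nPerm` they are enumerated exhaustively and the
#' p-value is exact.
#'
#' @param valuesA,valuesB per-subject metric values (each length >= 2).
#' @param nPerm number of permutations (default 10000).
#' @param direction "greater" tests A > B, "less" tests A < B.
#' @param seed RNG seed.
#' @param metricName label stored in the result.
#' @return a [PermutationResult-class].
#' @examples
#' r <- permutationTestMetric(c(5, 6, 7), c(1, 2, 3), direction = "greater")
#' r
#' @export
permutationTestMetric <- function(valuesA, valuesB, nPerm = 10000L,
                                  direction = c("greater", "less"),
                                  seed = 1L, metricName = "metric") {
    direction <- match.arg(direction)
    if (length(valuesA) < 2L || length(valuesB) < 2L)
        stop("each group needs at least 2 subjects")
    if (nPerm < 100L) warning("fewer than 100 permutations: p-values are coarse")
    nA <- length(valuesA); nB <- length(valuesB)
    pooled <- c(valuesA, valuesB)
    observed <- mean(valuesA) - mean(valuesB)
    P <- relabelMatrix(nA + nB, nA, nPerm, seed)
    sumA <- as.vector(P %*% pooled)
    null <- sumA / nA - (sum(pooled) - sumA) / nB
    exhaustive <- attr(P, "exhaustive")
    # tie tolerance: relabelings reproducing the observed difference must
    # count as ties despite floating-point summation order
    tol <- 1e-10 * max(1, abs(observed))
    if (direction == "greater") {
        p <- if (exhaustive) mean(null >= observed - tol)
             else (1 + sum(null >= observed - tol)) / (1 + nrow(P))
        crit <- stats::quantile(null, 0.95, names = FALSE)
        sig <- observed > crit
    } else {
        p <- if (exhaustive) mean(null <= observed + tol)
             else (1 + sum(null <= observed + tol)) / (1 + nrow(P))
        crit <- stats::quantile(null, 0.05, names = FALSE)
        sig <- observed < crit
    }
    new("PermutationResult", metricName = metricName,
        observedDiff = observed, nullDist = null, pValue = p,
        critValue = crit, significantPercentile = sig,
        nPerm = nrow(P), direction = direction, seed = as.integer(seed))
}

#' Node-wise permutation comparison with FDR correction
#'
#' Runs the group permutation test at every node, sharing one
#' permutation-relabeling matrix across nodes (which preserves the
#' cross-node dependence structure in the null), then applies the
#' Benjamini-Hochberg step-up procedure across nodes at level `q`.
#'
#' @param nodalA,nodalB subjects x N matrices of per-node values (e.g.
#'   nodal efficiency), same N.
#' @param nPerm number of permutations (default 10000).
#' @param q FDR level (default 0.05).
#' @param direction "greater" tests A > B per node, "less" the reverse.
#' @param seed RNG seed.
#' @return list with `observedDiff`, `p` (per-node permutation
#'   p-values), `significant` (BH mask at level q), `nPerm`.
#' @export
nodalComparison <- function(nodalA, nodalB, nPerm = 10000L, q = 0.05,
                            direction = c("greater", "less"), seed = 1L) {
    direction <- match.arg(direction)
    nodalA <- as.matrix(nodalA); nodalB <- as.matrix(nodalB)
    if (ncol(nodalA) != ncol(nodalB))
        stop("both groups must have the same number of nodes")
    nA <- nrow(nodalA); nB <- nrow(nodalB)
    X <- rbind(nodalA, nodalB)
    observed <- colMeans(nodalA) - colMeans(nodalB)
    P <- relabelMatrix(nA + nB, nA, nPerm, seed)
    sumA <- P %*% X                      # relabelings x N
    null <- sumA / nA - sweep(-sumA, 2L, colSums(X), `+`) / nB
    exhaustive <- attr(P, "exhaustive")
    tol <- 1e-10 * pmax(1, abs(observed))
    cmp <- if (direction == "greater") {
        sweep(null, 2L, observed - tol, `>=`)
    } else {
        sweep(null, 2L, observed + tol, `<=`)
    }
    counts <- colSums(cmp)
    p <- if (exhaustive) counts / nrow(P) else (1 + counts) / (1 + nrow(P))
    list(observedDiff = observed, p = p, significant = fdrBH(p, q),
         nPerm = nrow(P))
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control: significant tests are those
#' whose BH-adjusted p-value is at most `q`.
#'
#' @param pValues vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical mask, same length as `pValues`.
#' @export
fdrBH <- function(pValues, q = 0.05) {
    if (!length(pValues)) return(logical(0))
    if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(pValues, method = "BH") <= q
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's two-sample t with pooled variance,
#' `df = nA + nB - 2`, two-tailed. This is the summary-statistic form
#' used to check printed demographic tables; [twoSampleT()] accepts raw
#' samples.
#'
#' @param meanA,sdA,nA group A mean, SD, size.
#' @param meanB,sdB,nB group B mean, SD, size.
#' @return list with `t`, `df`, `p`.
#' @examples
#' twoSampleTSummary(38.67, 9.53, 36, 37.79, 9.92, 38)$p   # 0.699
#' @export
twoSampleTSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
    if (nA < 2L || nB < 2L) stop("each group needs n >= 2")
    if (sdA < 0 || sdB < 0) stop("standard deviations must be nonnegative")
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    if (se == 0) {
        if (meanA == meanB) return(list(t = 0, df = df, p = 1))
        return(list(t = sign(meanA - meanB) * Inf, df = df, p = 0))
    }
    tval <- (meanA - meanB) / se
    list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pooled-variance two-sample t-test on raw samples
#'
#' @param a,b numeric sample vectors (each length >= 2).
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
twoSampleT <- function(a, b) {
    twoSampleTSummary(mean(a), stats::sd(a), length(a),
                      mean(b), stats::sd(b), length(b))
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Pearson's chi-square without continuity correction (the form under
#' which printed sex-distribution p-values reproduce).
#'
#' @param table 2 x 2 matrix of counts.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @examples
#' chiSquare2x2(matrix(c(12, 24, 12, 26), 2, byrow = TRUE))$p   # 0.872
#' @export
chiSquare2x2 <- function(table) {
    table <- as.matrix(table)
    if (!identical(dim(table), c(2L, 2L))) stop("need a 2 x 2 table")
    if (any(table < 0)) stop("counts must be nonnegative")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("all margins must be positive")
    res <- stats::chisq.test(table, correct = FALSE)
    list(chi2 = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value))
}

# Pooled-variance t statistics for every column of X, for a batch of
# relabelings. P: relabelings x n logical (TRUE = group A). Returns a
# relabelings x ncol(X) matrix.
batchTStats <- function(P, X, nA, nB) {
    sumA <- P %*% X
    sumsqA <- P %*% (X^2)
    totals <- colSums(X); totalsSq <- colSums(X^2)
    meanA <- sumA / nA
    meanB <- sweep(-sumA, 2L, totals, `+`) / nB
    varA <- (sumsqA - nA * meanA^2) / (nA - 1)
    varB <- (sweep(-sumsqA, 2L, totalsSq, `+`) - nB * meanB^2) / (nB - 1)
    sp2 <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
    sp2[sp2 < .Machine$double.eps] <- .Machine$double.eps
    (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

# Largest connected-component size (in edges) among suprathreshold edges.
maxComponentEdges <- function(pairs, supra, n) {
    edges <- pairs[supra, , drop = FALSE]
    if (!nrow(edges)) return(0L)
    memb <- unionFindLabel(edges, n)
    edgeComp <- memb[edges[, 1L]]
    max(tabulate(edgeComp))
}

#' Network-based statistic (NBS)
#'
#' Permutation inference on connected components of suprathreshold
#' edges. Edge inclusion first requires the raw correlation to be
#' positive in strictly more than `positiveFrac` of all subjects (both
#' groups pooled). On the included edges, a pooled-variance two-sample
#' t-test is computed per edge and edges with one-sided p below
#' `primaryAlpha` in the requested direction are kept; their connected
#' components are recorded with size = link count. The null distribution
#' of the maximal component size is built from `nPerm` random group
#' relabelings, and each observed component of size M receives
#' `corrected p = (1 + #\{null max >= M\}) / (1 + nPerm)` (the
#' conservative at-least-as-large count; `strictNull = TRUE` counts
#' strict exceedances instead).
#'
#' @param connA,connB lists of [ConnectivityMatrix-class] objects (or
#'   plain symmetric correlation matrices), one per subject.
#' @param primaryAlpha edge-level one-sided threshold (default 0.05).
#' @param nPerm number of permutations (default 10000).
#' @param positiveFrac positivity-rule fraction (default 0.85).
#' @param direction "A>B" finds components stronger in group A; "B>A"
#'   the reverse.
#' @param seed RNG seed.
#' @param strictNull count only strictly larger null maxima.
#' @param chunkSize permutations processed per vectorized block.
#' @return an [NbsResult-class]; empty (with a warning) when no edge
#'   passes the positivity rule.
#' @export
nbs <- function(connA, connB, primaryAlpha = 0.05, nPerm = 10000L,
                positiveFrac = 0.85, direction = c("A>B", "B>A"),
                seed = 1L, strictNull = FALSE, chunkSize = 1000L) {
    direction <- match.arg(direction)
    getR <- function(x) if (is(x, "ConnectivityMatrix")) x@r else as.matrix(x)
    matsA <- lapply(connA, getR); matsB <- lapply(connB, getR)
    nA <- length(matsA); nB <- length(matsB); n <- nA + nB
    if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
    N <- nrow(matsA[[1L]])
    labels <- rownames(matsA[[1L]])
    if (is.null(labels)) labels <- defaultRoiLabels(N)
    pairs <- upperTriPairs(N)
    # subjects x edges matrix of raw correlations
    X <- t(vapply(c(matsA, matsB), function(m) m[upper.tri(m)],
                  numeric(nrow(pairs))))
    included <- colMeans(X > 0) > positiveFrac
    emptyResult <- function() new("NbsResult",
        components = list(), componentSizes = integer(0),
        correctedP = numeric(0),
        includedEdges = symmetricFromUpper(included, N, labels) > 0,
        nullMaxSizes = integer(0), primaryAlpha = primaryAlpha,
        positiveFrac = positiveFrac, nPerm = as.integer(nPerm),
        direction = direction, seed = as.integer(seed))
    if (!any(included)) {
        warning("no edge passes the positivity rule; NBS result is empty")
        return(emptyResult())
    }
    Xin <- X[, included, drop = FALSE]
    pairsIn <- pairs[included, , drop = FALSE]
    df <- n - 2L
    tCrit <- stats::qt(1 - primaryAlpha, df)
    sgn <- if (direction == "A>B") 1 else -1

    obsP <- matrix(c(rep(TRUE, nA), rep(FALSE, nB)), 1L)
    tObs <- as.vector(batchTStats(obsP, Xin, nA, nB)) * sgn
    supra <- tObs > tCrit

    # observed components
    components <- list(); sizes <- integer(0)
    if (any(supra)) {
        edges <- pairsIn[supra, , drop = FALSE]
        memb <- unionFindLabel(edges, N)
        edgeComp <- memb[edges[, 1L]]
        ord <- order(tabulate(edgeComp)[edgeComp], decreasing = TRUE)
        for (comp in unique(edgeComp[ord])) {
            sel <- which(edgeComp == comp)
            tv <- (tObs * sgn)[supra][sel]
            components[[length(components) + 1L]] <- data.frame(
                roi_a = labels[edges[sel, 1L]],
                roi_b = labels[edges[sel, 2L]],
                t = tv, p_edge = stats::pt(tObs[supra][sel], df,
                                           lower.tail = FALSE),
                stringsAsFactors = FALSE)
            sizes <- c(sizes, length(sel))
        }
    }

    # permutation null of the maximal component size
    set.seed(as.integer(seed))
    nullMax <- integer(nPerm)
    done <- 0L
    while (done < nPerm) {
        k <- min(chunkSize, nPerm - done)
        P <- matrix(FALSE, k, n)
        for (i in seq_len(k)) P[i, sample.int(n, nA)] <- TRUE
        tNull <- batchTStats(P, Xin, nA, nB) * sgn
        supraNull <- tNull > tCrit
        for (i in seq_len(k)) {
            nullMax[done + i] <- maxComponentEdges(pairsIn, supraNull[i, ], N)
        }
        done <- done + k
    }
    corrected <- vapply(sizes, function(M) {
        exceed <- if (strictNull) sum(nullMax > M) else sum(nullMax >= M)
        (1 + exceed) / (1 + nPerm)
    }, 0.0)
    new("NbsResult", components = components,
        componentSizes = as.integer(sizes), correctedP = corrected,
        includedEdges = symmetricFromUpper(included, N, labels) > 0,
        nullMaxSizes = nullMax, primaryAlpha = primaryAlpha,
        positiveFrac = positiveFrac, nPerm = as.integer(nPerm),
        direction = direction, seed = as.integer(seed))
}
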