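#' @import methods
NULL

#' RoiTimeSeries: one subject's ROI-averaged BOLD-like signals
#'
#' A T x N matrix of regional mean time series (rows = time frames,
#' columns = regions of interest) together with the sampling interval.
#' This is the unit of data every cleaning and network-construction step
#' operates on.
#'
#' @slot subjectID character scalar identifying the subject.
#' @slot data numeric T x N matrix; column names are the ROI labels.
#' @slot trSeconds sampling interval (repetition time) in seconds.
#'
#' @seealso [roiTimeSeries()] for the user-facing constructor,
#'   [detrendLinear()], [bandpassFilter()], [regressNuisance()],
#'   [correlationMatrix()].
#' @export
setClass("RoiTimeSeries",
    representation(subjectID = "character", data = "matrix",
                   trSeconds = "numeric"))

setValidity("RoiTimeSeries", function(object) {
    d <- object@data
    if (!is.numeric(d)) return("data must be a numeric matrix")
    if (anyNA(d)) return("data contains missing values")
    if (nrow(d) < 3L) return("need at least 3 time points")
    if (is.null(colnames(d))) return("data must carry ROI labels as colnames")
    if (anyDuplicated(colnames(d))) return("ROI labels must be unique")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
        return("trSeconds must be a positive scalar")
    if (length(object@subjectID) != 1L) return("subjectID must be a scalar")
    TRUE
})

#' MotionParams: rigid-body head-motion parameters
#'
#' A T x 6 matrix of realignment parameters: three translations (mm) and
#' three rotations (radians), one row per acquired frame.
#'
#' @slot subjectID character scalar.
#' @slot data numeric T x 6 matrix (x, y, z, pitch, roll, yaw).
#'
#' @seealso [motionParams()], [friston24()], [framewiseDisplacement()],
#'   [motionExclusion()].
#' @export
setClass("MotionParams",
    representation(subjectID = "character", data = "matrix"))

setValidity("MotionParams", function(object) {
    d <- object@data
    if (!is.numeric(d) || ncol(d) != 6L)
        return("motion data must be a numeric T x 6 matrix")
    if (anyNA(d)) return("motion data contains missing values")
    if (length(object@subjectID) != 1L) return("subjectID must be a scalar")
    TRUE
})

#' ConnectivityMatrix: pairwise ROI correlations with p-values
#'
#' Symmetric N x N Pearson correlation matrix between ROI time series,
#' with the matching two-tailed p-value matrix. The diagonal of `r` is
#' set to zero by convention and is excluded from all downstream
#' statistics.
#'
#' @slot subjectID character scalar.
#' @slot r numeric N x N correlation matrix, zero diagonal.
#' @slot p numeric N x N two-tailed p-value matrix, unit diagonal.
#' @slot nSamples number of time points the correlations were computed from.
#'
#' @seealso [correlationMatrix()], [thresholdBonferroni()].
#' @export
setClass("ConnectivityMatrix",
    representation(subjectID = "character", r = "matrix", p = "matrix",
                   nSamples = "integer"))

setValidity("ConnectivityMatrix", function(object) {
    r <- object@r; p <- object@p
    if (nrow(r) != ncol(r)) return("r must be square")
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-10))) return("r not symmetric")
    if (any(abs(r) > 1 + 1e-12)) return("|r| must be <= 1")
    if (any(diag(r) != 0)) return("diagonal of r must be 0 by convention")
    if (!identical(dim(r), dim(p))) return("r and p dimensions differ")
    if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
    if (!isTRUE(all.equal(p, t(p), tolerance = 1e-10))) return("p not symmetric")
    TRUE
})

#' BrainGraph: thresholded positive-weight functional network
#'
#' The analysis substrate: an undirected weighted graph on N ROIs whose
#' nonzero weights are the retained (significant, positive) correlation
#' coefficients, so every weight lies in (0, 1]. Edge lengths used for
#' shortest paths are the reciprocals 1/w.
#'
#' @slot w numeric N x N symmetric weight matrix with zero diagonal;
#'   dimnames carry the ROI labels.
#'
#' @seealso [brainGraph()], [thresholdBonferroni()], [globalEfficiency()],
#'   [localEfficiency()], [nodalEfficiency()], [rewirePreservingDegree()].
#' @export
setClass("BrainGraph", representation(w = "matrix"))

setValidity("BrainGraph", function(object) {
    w <- object@w
    if (nrow(w) != ncol(w)) return("weight matrix must be square")
    if (anyNA(w)) return("weight matrix contains missing values")
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
        return("weight matrix not symmetric")
    if (any(diag(w) != 0)) return("diagonal must be zero")
    nz <- w[w != 0]
    if (length(nz) && (any(nz <= 0) || any(nz > 1 + 1e-12)))
        return("nonzero weights must lie in (0, 1]")
    if (is.null(rownames(w))) return("weight matrix must carry ROI labels")
    TRUE
})

#' GlobalMetrics: per-subject small-world efficiency summary
#'
#' Holds global and local efficiency of a subject's network plus their
#' normalized versions (ratio to the mean of degree-preserving random
#' rewires) and the network density.
#'
#' @slot eGlob global efficiency in [0, 1].
#' @slot eLoc local efficiency in [0, 1].
#' @slot normEGlob normalized global efficiency (NA before normalization).
#' @slot normELoc normalized local efficiency (NA before normalization).
#' @slot nRandom number of random networks used for normalization.
#' @slot density network density 2K / (N(N-1)).
#'
#' @seealso [globalMetrics()], [normalizedEfficiencies()], [isSmallWorld()].
#' @export
setClass("GlobalMetrics",
    representation(eGlob = "numeric", eLoc = "numeric",
                   normEGlob = "numeric", normELoc = "numeric",
                   nRandom = "integer", density = "numeric"))

setValidity("GlobalMetrics", function(object) {
    if (object@eGlob < 0 || object@eLoc < 0)
        return("efficiencies must be nonnegative")
    TRUE
})

#' PermutationResult: a group-difference permutation test
#'
#' Output of [permutationTestMetric()]: the observed group-mean
#' difference, its permutation null distribution, and significance under
#' both the add-one p-value estimator and the 95th-percentile critical
#' value rule.
#'
#' @slot metricName label of the metric tested.
#' @slot observedDiff mean(group A) - mean(group B).
#' @slot nullDist permutation null distribution of the difference.
#' @slot pValue add-one permutation p-value, never exactly zero.
#' @slot critValue 95th percentile of the null (one-tailed critical value).
#' @slot significantPercentile logical; observed exceeds the critical value.
#' @slot nPerm number of permutations.
#' @slot direction "greater" (A > B) or "less".
#' @slot seed RNG seed used for the relabelings.
#' @export
setClass("PermutationResult",
    representation(metricName = "character", observedDiff = "numeric",
                   nullDist = "numeric", pValue = "numeric",
                   critValue = "numeric", significantPercentile = "logical",
                   nPerm = "integer", direction = "character",
                   seed = "integer"))

setValidity("PermutationResult", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    if (!object@direction %in% c("greater", "less"))
        return("direction must be 'greater' or 'less'")
    TRUE
})

#' NbsResult: network-based statistic inference output
#'
#' Connected components of suprathreshold edges from an edge-wise
#' group comparison, with family-wise-corrected p-values derived from the
#' permutation null distribution of the maximal component size.
#'
#' @slot components list of data.frames (one per component, largest first)
#'   with columns roi_a, roi_b, t, p_edge.
#' @slot componentSizes integer link counts per component.
#' @slot correctedP corrected p-value per component.
#' @slot includedEdges logical N x N mask of edges passing the positivity
#'   rule (raw correlation positive in more than `positiveFrac` of all
#'   subjects).
#' @slot nullMaxSizes permutation null distribution of maximal component size.
#' @slot primaryAlpha edge-level primary threshold.
#' @slot positiveFrac positivity-rule fraction.
#' @slot nPerm number of permutations.
#' @slot direction "A>B" or "B>A".
#' @slot seed RNG seed.
#' @export
setClass("NbsResult",
    representation(components = "list", componentSizes = "integer",
                   correctedP = "numeric", includedEdges = "matrix",
                   nullMaxSizes = "integer", primaryAlpha = "numeric",
                   positiveFrac = "numeric", nPerm = "integer",
                   direction = "character", seed = "integer"))

setValidity("NbsResult", function(object) {
    if (length(object@components) != length(object@componentSizes))
        return("components and componentSizes lengths differ")
    if (length(object@correctedP) != length(object@components))
        return("correctedP length mismatch")
    sz <- vapply(object@components, nrow, 0L)
    if (length(sz) && !identical(as.integer(sz), object@componentSizes))
        return("componentSizes must equal component edge-list lengths")
    if (any(object@correctedP <= 0 | object@correctedP > 1))
        return("correctedP must lie in (0, 1]")
    TRUE
})

#' SyntheticSpec: parameters of the synthetic two-group cohort
#'
#' Describes the population the generator draws from: ROI community
#' blocks with positive within/between-block covariance, an optional
#' planted group effect on a designated edge set, lag-1 autocorrelated
#' Gaussian noise, subject-level connectivity strength variation, and a
#' behavioral score linearly coupled to each subject's mean generating
#' covariance on the effect edges.
#'
#' @slot nRois number of ROIs.
#' @slot nVolumes retained time points per subject.
#' @slot trSeconds sampling interval (s).
#' @slot nGroupA,nGroupB group sizes (A = patient-like, B = control-like).
#' @slot blockSizes integer partition of the ROIs into community blocks.
#' @slot withinBlockCov covariance level inside a block, in (0, 1).
#' @slot betweenBlockCov covariance level between blocks, in
#'   [0, withinBlockCov).
#' @slot effectEdges two-column integer matrix of ROI index pairs carrying
#'   the planted group effect (may have zero rows).
#' @slot effectDelta additive covariance increment for group A on the
#'   effect edges.
#' @slot arCoeff lag-1 autoregressive coefficient in [0, 1).
#' @slot noiseSd standard deviation of ROI-specific white noise.
#' @slot subjectStrengthSd spread (on the logit scale) of the per-subject
#'   connectivity strength factor in (0, 1).
#' @slot behaviorCoupling slope linking a subject's mean generating
#'   covariance on the effect edges to the synthetic behavioral score.
#' @slot behaviorNoiseSd residual SD of the behavioral score.
#' @slot seed master RNG seed of the cohort.
#'
#' @seealso [syntheticSpec()], [generateCohort()].
#' @export
setClass("SyntheticSpec",
    representation(nRois = "integer", nVolumes = "integer",
                   trSeconds = "numeric", nGroupA = "integer",
                   nGroupB = "integer", blockSizes = "integer",
                   withinBlockCov = "numeric", betweenBlockCov = "numeric",
                   effectEdges = "matrix", effectDelta = "numeric",
                   arCoeff = "numeric", noiseSd = "numeric",
                   subjectStrengthSd = "numeric",
                   behaviorCoupling = "numeric", behaviorNoiseSd = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@nRois < 4L) return("need at least 4 ROIs")
    if (object@nVolumes < 20L) return("need at least 20 volumes")
    if (sum(object@blockSizes) != object@nRois)
        return("blockSizes must sum to nRois")
    if (any(object@blockSizes < 1L)) return("blockSizes must be positive")
    if (object@withinBlockCov <= 0 || object@withinBlockCov >= 1)
        return("withinBlockCov must lie in (0, 1)")
    if (object@betweenBlockCov < 0 ||
        object@betweenBlockCov >= object@withinBlockCov)
        return("betweenBlockCov must lie in [0, withinBlockCov)")
    if (ncol(object@effectEdges) != 2L)
        return("effectEdges must be a two-column matrix")
    if (nrow(object@effectEdges) &&
        (any(object@effectEdges < 1L) || any(object@effectEdges > object@nRois)))
        return("effectEdges indices out of range")
    if (nrow(object@effectEdges) &&
        any(object@effectEdges[, 1L] == object@effectEdges[, 2L]))
        return("effectEdges must not touch the diagonal")
    if (object@arCoeff < 0 || object@arCoeff >= 1)
        return("arCoeff must lie in [0, 1)")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    if (object@nGroupA < 1L || object@nGroupB < 1L)
        return("both groups need at least one subject")
    if (object@subjectStrengthSd < 0)
        return("subjectStrengthSd must be nonnegative")
    TRUE
})

#' Cohort: a generated synthetic cohort bundle
#'
#' @slot table data.frame with one row per subject: subject_id, group
#'   ("A"/"B"), age, sex ("M"/"F"), education, and the behavioral scores
#'   PSQI, ISI, SAS, SDS, ESS, duration (ESS and duration are NA for
#'   group B, mirroring typical clinical reporting).
#' @slot timeSeries named list of [RoiTimeSeries-class] objects.
#' @slot motion named list of [MotionParams-class] objects.
#' @slot spec the [SyntheticSpec-class] the cohort was drawn from.
#' @export
setClass("Cohort",
    representation(table = "data.frame", timeSeries = "list",
                   motion = "list", spec = "SyntheticSpec"))

setValidity("Cohort", function(object) {
    tab <- object@table
    if (anyDuplicated(tab$subject_id)) return("subject ids must be unique")
    if (!all(tab$group %in% c("A", "B"))) return("group must be 'A' or 'B'")
    if (!identical(sort(names(object@timeSeries)), sort(tab$subject_id)))
        return("timeSeries names must match subject ids")
    if (!identical(sort(names(object@motion)), sort(tab$subject_id)))
        return("motion names must match subject ids")
    TRUE
})
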