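#' Accessors for fcnet classes
#'
#' Small accessor generics shared across the package's S4 classes:
#' `subjectID()` returns the subject identifier, `roiLabels()` the ROI
#' label vector, `nodeCount()`/`edgeCount()` the graph order and size.
#'
#' @param object an fcnet S4 object.
#' @return `subjectID()` and `roiLabels()` return character vectors;
#'   `nodeCount()` and `edgeCount()` return integers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("nodeCount", function(object) standardGeneric("nodeCount"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setMethod("subjectID", "RoiTimeSeries", function(object) object@subjectID)

#' @rdname accessors
#' @export
setMethod("subjectID", "MotionParams", function(object) object@subjectID)

#' @rdname accessors
#' @export
setMethod("subjectID", "ConnectivityMatrix", function(object) object@subjectID)

#' @rdname accessors
#' @export
setMethod("roiLabels", "RoiTimeSeries", function(object) colnames(object@data))

#' @rdname accessors
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(object) colnames(object@r))

#' @rdname accessors
#' @export
setMethod("roiLabels", "BrainGraph", function(object) rownames(object@w))

#' @rdname accessors
#' @export
setMethod("nodeCount", "BrainGraph", function(object) nrow(object@w))

#' @rdname accessors
#' @export
setMethod("edgeCount", "BrainGraph",
    function(object) as.integer(sum(object@w[upper.tri(object@w)] != 0)))

#' Extract the signal matrix of a RoiTimeSeries
#'
#' @param object a [RoiTimeSeries-class].
#' @return the numeric T x N matrix of regional signals.
#' @export
setGeneric("seriesMatrix", function(object) standardGeneric("seriesMatrix"))

#' @rdname seriesMatrix
#' @export
setMethod("seriesMatrix", "RoiTimeSeries", function(object) object@data)

#' Sampling interval accessor
#'
#' @param object a [RoiTimeSeries-class].
#' @return repetition time in seconds.
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))

#' @rdname trSeconds
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(object) object@trSeconds)

#' Motion parameter matrix accessor
#'
#' @param object a [MotionParams-class].
#' @return the T x 6 rigid-body parameter matrix.
#' @export
setGeneric("motionMatrix", function(object) standardGeneric("motionMatrix"))

#' @rdname motionMatrix
#' @export
setMethod("motionMatrix", "MotionParams", function(object) object@data)

#' Correlation and p-value matrix accessors
#'
#' @param object a [ConnectivityMatrix-class].
#' @return `corMatrix()` the N x N correlation matrix (zero diagonal);
#'   `pMatrix()` the matching two-tailed p-value matrix.
#' @name connectivity-accessors
NULL

#' @rdname connectivity-accessors
#' @export
setGeneric("corMatrix", function(object) standardGeneric("corMatrix"))

#' @rdname connectivity-accessors
#' @export
setMethod("corMatrix", "ConnectivityMatrix", function(object) object@r)

#' @rdname connectivity-accessors
#' @export
setGeneric("pMatrix", function(object) standardGeneric("pMatrix"))

#' @rdname connectivity-accessors
#' @export
setMethod("pMatrix", "ConnectivityMatrix", function(object) object@p)

#' Weight matrix accessor
#'
#' @param object a [BrainGraph-class].
#' @return the symmetric N x N weight matrix.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "BrainGraph", function(object) object@w)

setMethod("show", "RoiTimeSeries", function(object) {
    cat("RoiTimeSeries '", object@subjectID, "': ",
        nrow(object@data), " frames x ", ncol(object@data),
        " ROIs, TR = ", object@trSeconds, " s\n", sep = "")
})

setMethod("show", "MotionParams", function(object) {
    cat("MotionParams '", object@subjectID, "': ",
        nrow(object@data), " frames\n", sep = "")
})

setMethod("show", "ConnectivityMatrix", function(object) {
    r <- object@r[upper.tri(object@r)]
    cat("ConnectivityMatrix '", object@subjectID, "': ",
        nrow(object@r), " ROIs, n = ", object@nSamples,
        ", mean r = ", signif(mean(r), 3), "\n", sep = "")
})

setMethod("show", "BrainGraph", function(object) {
    N <- nodeCount(object); K <- edgeCount(object)
    cat("BrainGraph: ", N, " nodes, ", K, " edges, density = ",
        signif(networkDensity(object), 3), "\n", sep = "")
})

setMethod("show", "GlobalMetrics", function(object) {
    cat("GlobalMetrics: e_glob = ", signif(object@eGlob, 4),
        ", e_loc = ", signif(object@eLoc, 4), sep = "")
    if (!is.na(object@normEGlob))
        cat(", norm e_glob = ", signif(object@normEGlob, 4),
            ", norm e_loc = ", signif(object@normELoc, 4),
            " (", object@nRandom, " random nets)", sep = "")
    cat("\n")
})

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult '", object@metricName, "': diff = ",
        signif(object@observedDiff, 4), ", p = ",
        signif(object@pValue, 4), " (", object@direction, ", ",
        object@nPerm, " permutations)\n", sep = "")
})

setMethod("show", "NbsResult", function(object) {
    cat("NbsResult (", object@direction, "): ",
        length(object@components), " component(s)", sep = "")
    if (length(object@components))
        cat("; sizes ", paste(object@componentSizes, collapse = ", "),
            "; corrected p ", paste(signif(object@correctedP, 3),
                                    collapse = ", "), sep = "")
    cat("\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec: ", object@nRois, " ROIs, ", object@nVolumes,
        " volumes @ TR ", object@trSeconds, " s, groups ",
        object@nGroupA, "+", object@nGroupB, ", ",
        nrow(object@effectEdges), " effect edge(s), seed ",
        object@seed, "\n", sep = "")
})

setMethod("show", "Cohort", function(object) {
    cat("Cohort: ", nrow(object@table), " subjects (",
        sum(object@table$group == "A"), " A / ",
        sum(object@table$group == "B"), " B)\n", sep = "")
})
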