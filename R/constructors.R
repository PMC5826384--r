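#' Construct a RoiTimeSeries
#'
#' @param data numeric T x N matrix (rows = frames, columns = ROIs).
#' @param trSeconds sampling interval in seconds.
#' @param subjectID subject identifier.
#' @param roiLabels optional ROI labels; defaults to existing column names
#'   or `ROI_001`-style placeholders.
#' @return a [RoiTimeSeries-class] object.
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(200), 50, 4), trSeconds = 2)
#' ts
#' @export
roiTimeSeries <- function(data, trSeconds = 2, subjectID = "subj",
                          roiLabels = NULL) {
    data <- as.matrix(data)
    if (is.null(roiLabels)) roiLabels <- colnames(data)
    if (is.null(roiLabels)) roiLabels <- defaultRoiLabels(ncol(data))
    colnames(data) <- roiLabels
    rownames(data) <- NULL
    new("RoiTimeSeries", subjectID = as.character(subjectID),
        data = data, trSeconds = as.numeric(trSeconds))
}

#' Construct a MotionParams object
#'
#' @param data numeric T x 6 matrix: translations x, y, z (mm) then
#'   rotations pitch, roll, yaw (radians).
#' @param subjectID subject identifier.
#' @return a [MotionParams-class] object.
#' @export
motionParams <- function(data, subjectID = "subj") {
    data <- as.matrix(data)
    colnames(data) <- c("trans_x", "trans_y", "trans_z",
                        "rot_pitch", "rot_roll", "rot_yaw")
    rownames(data) <- NULL
    new("MotionParams", subjectID = as.character(subjectID), data = data)
}

#' Construct a BrainGraph from a weight matrix
#'
#' @param w symmetric nonnegative N x N weight matrix with zero diagonal;
#'   nonzero weights must lie in (0, 1] (correlation-valued).
#' @param roiLabels optional node labels.
#' @return a [BrainGraph-class] object.
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 0.8
#' g <- brainGraph(w)
#' edgeCount(g)
#' @export
brainGraph <- function(w, roiLabels = NULL) {
    w <- as.matrix(w)
    if (is.null(roiLabels)) roiLabels <- rownames(w)
    if (is.null(roiLabels)) roiLabels <- defaultRoiLabels(nrow(w))
    dimnames(w) <- list(roiLabels, roiLabels)
    new("BrainGraph", w = w)
}

#' Construct a GlobalMetrics summary
#'
#' @param eGlob,eLoc global and local efficiency.
#' @param normEGlob,normELoc normalized efficiencies (NA if not computed).
#' @param nRandom number of random networks used in normalization.
#' @param density network density.
#' @return a [GlobalMetrics-class] object.
#' @export
globalMetrics <- function(eGlob, eLoc, normEGlob = NA_real_,
                          normELoc = NA_real_, nRandom = 0L,
                          density = NA_real_) {
    new("GlobalMetrics", eGlob = eGlob, eLoc = eLoc,
        normEGlob = as.numeric(normEGlob), normELoc = as.numeric(normELoc),
        nRandom = as.integer(nRandom), density = as.numeric(density))
}

defaultRoiLabels <- function(n) sprintf("ROI_%03d", seq_len(n))
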