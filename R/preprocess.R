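#' Remove per-column linear trends
#'
#' Fits and subtracts an ordinary-least-squares line (intercept plus
#' slope on the frame index) from every ROI column. Residual columns
#' have exactly zero mean and zero linear trend, removing slow scanner
#' drift before filtering.
#'
#' @param ts a [RoiTimeSeries-class].
#' @return a detrended [RoiTimeSeries-class].
#' @export
detrendLinear <- function(ts) {
    x <- ts@data
    T_ <- nrow(x)
    X <- cbind(1, seq_len(T_))
    coef <- solve(crossprod(X), crossprod(X, x))
    out <- x - X %*% coef
    roiTimeSeries(out, trSeconds = ts@trSeconds, subjectID = ts@subjectID,
                  roiLabels = colnames(x))
}

#' Zero-phase band-pass filter
#'
#' Applies a fourth-order Butterworth band-pass (default 0.01-0.08 Hz,
#' the conventional resting-state fluctuation band) forward and backward
#' (`signal::filtfilt`), so the filter is zero-phase and does not shift
#' correlations in time. Columns are demeaned first, making the DC
#' response exactly zero.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < 1/(2 * trSeconds)`.
#' @param order Butterworth prototype order (default 4).
#' @return a filtered [RoiTimeSeries-class].
#' @examples
#' t <- seq_len(230)
#' ts <- roiTimeSeries(cbind(sin(2 * pi * 0.04 * t * 2)), trSeconds = 2)
#' out <- bandpassFilter(ts)
#' sd(seriesMatrix(out)) / sd(seriesMatrix(ts))   # pass-band: close to 1
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.08, order = 4L) {
    nyquist <- 1 / (2 * ts@trSeconds)
    if (lowHz <= 0 || lowHz >= highHz)
        stop("need 0 < lowHz < highHz")
    if (highHz >= nyquist)
        stop(sprintf("highHz (%g Hz) must be below the Nyquist frequency (%g Hz)",
                     highHz, nyquist))
    bf <- signal::butter(order, c(lowHz, highHz) / nyquist, type = "pass")
    x <- scale(ts@data, center = TRUE, scale = FALSE)
    out <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
    roiTimeSeries(out, trSeconds = ts@trSeconds, subjectID = ts@subjectID,
                  roiLabels = colnames(ts@data))
}

#' Friston 24-parameter motion regressor expansion
#'
#' Expands the six rigid-body parameters R into the 24-column nuisance
#' set `[R, R^2, R_(t-1), R_(t-1)^2]`, where the lagged blocks are the
#' one-frame backward shift with a zero-padded first row.
#'
#' @param mp a [MotionParams-class].
#' @return numeric T x 24 nuisance matrix.
#' @export
friston24 <- function(mp) {
    R <- mp@data
    T_ <- nrow(R)
    lag <- rbind(0, R[-T_, , drop = FALSE])
    out <- cbind(R, R^2, lag, lag^2)
    colnames(out) <- c(paste0(colnames(R)),
                       paste0(colnames(R), "_sq"),
                       paste0(colnames(R), "_lag"),
                       paste0(colnames(R), "_lag_sq"))
    out
}

#' Regress nuisance signals out of ROI time series
#'
#' Projects every ROI column onto the orthogonal complement of the
#' nuisance column space (an intercept column is always appended, so the
#' output is also demeaned). Rank-deficient nuisance matrices are
#' handled by the pseudoinverse, so duplicated or constant regressors
#' are harmless.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param nuisance numeric matrix with T rows (e.g. [friston24()] output
#'   plus white-matter / CSF surrogate columns).
#' @return the residual [RoiTimeSeries-class].
#' @export
regressNuisance <- function(ts, nuisance) {
    x <- ts@data
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(x))
        stop("nuisance matrix must have the same number of rows as the series")
    X <- cbind(1, nuisance)
    # pseudoinverse projection: residual = (I - X X^+) y
    sv <- svd(X)
    keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
    U <- sv$u[, keep, drop = FALSE]
    out <- x - U %*% crossprod(U, x)
    roiTimeSeries(out, trSeconds = ts@trSeconds, subjectID = ts@subjectID,
                  roiLabels = colnames(x))
}

#' Framewise displacement (Power convention)
#'
#' FD(t) is the sum of absolute backward differences of the six motion
#' parameters, with rotations converted to arc length at a
#' `headRadiusMm` sphere: `FD(t) = sum|d trans| + headRadius * sum|d rot|`;
#' FD(1) = 0 by definition.
#'
#' @param mp a [MotionParams-class].
#' @param headRadiusMm head radius for the rotation arc length
#'   (default 50 mm).
#' @return list with `fd` (T values, mm) and summaries `max`, `mean`,
#'   `rms`.
#' @export
framewiseDisplacement <- function(mp, headRadiusMm = 50) {
    R <- mp@data
    d <- abs(diff(R))
    fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
                headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
    list(fd = fd, max = max(fd), mean = mean(fd), rms = sqrt(mean(fd^2)))
}

#' Motion-based subject exclusion
#'
#' Flags a subject for exclusion when any translation exceeds
#' `transLimitMm` (absolute, mm) or any rotation exceeds `rotLimitDeg`
#' (absolute, degrees; parameters are stored in radians and converted) at
#' any frame.
#'
#' @param mp a [MotionParams-class].
#' @param transLimitMm translation limit in mm (default 2).
#' @param rotLimitDeg rotation limit in degrees (default 2).
#' @return list with `exclude` (logical) and `reason` (character; names
#'   the offending axis and frame, or "within limits").
#' @export
motionExclusion <- function(mp, transLimitMm = 2, rotLimitDeg = 2) {
    R <- mp@data
    trans <- abs(R[, 1:3, drop = FALSE])
    rotDeg <- abs(R[, 4:6, drop = FALSE]) * 180 / pi
    if (any(trans > transLimitMm)) {
        idx <- which(trans > transLimitMm, arr.ind = TRUE)[1L, ]
        return(list(exclude = TRUE,
                    reason = sprintf("translation %s = %.2f mm at frame %d exceeds %g mm",
                                     colnames(R)[idx[2L]],
                                     R[idx[1L], idx[2L]], idx[1L],
                                     transLimitMm)))
    }
    if (any(rotDeg > rotLimitDeg)) {
        idx <- which(rotDeg > rotLimitDeg, arr.ind = TRUE)[1L, ]
        return(list(exclude = TRUE,
                    reason = sprintf("rotation %s = %.2f deg at frame %d exceeds %g deg",
                                     colnames(R)[idx[2L] + 3L],
                                     rotDeg[idx[1L], idx[2L]], idx[1L],
                                     rotLimitDeg)))
    }
    list(exclude = FALSE, reason = "within limits")
}

#' Full cleaning pipeline for one subject
#'
#' Applies the fixed cleaning order: linear detrend, 0.01-0.08 Hz
#' zero-phase band-pass, then nuisance regression of the Friston-24
#' motion expansion (plus any extra nuisance columns such as
#' white-matter / CSF surrogates).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param mp the subject's [MotionParams-class].
#' @param extraNuisance optional T x k matrix of additional nuisance
#'   columns.
#' @param lowHz,highHz band-pass edges.
#' @return the cleaned [RoiTimeSeries-class].
#' @export
cleanTimeSeries <- function(ts, mp, extraNuisance = NULL,
                            lowHz = 0.01, highHz = 0.08) {
    out <- detrendLinear(ts)
    out <- bandpassFilter(out, lowHz = lowHz, highHz = highHz)
    nuis <- friston24(mp)
    if (!is.null(extraNuisance)) nuis <- cbind(nuis, extraNuisance)
    regressNuisance(out, nuis)
}
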