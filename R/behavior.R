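#' Covariate-adjusted partial correlation
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on
#' `[intercept | covariates]`, with the p-value from the t transform at
#' `df = n - 2 - C` (C = number of retained covariate columns).
#' Incomplete rows are dropped listwise; collinear covariate columns are
#' dropped with a warning. With no covariates this reduces exactly to
#' the plain Pearson correlation.
#'
#' @param x,y per-subject numeric vectors.
#' @param covariates matrix or data.frame of covariates (subjects x C),
#'   or NULL for a plain correlation. Factor-like columns (e.g. sex
#'   coded "M"/"F") are converted to 0/1; any affine coding gives the
#'   same result.
#' @return list with `r`, `p`, `n` (complete subjects used), `df`.
#' @examples
#' set.seed(1)
#' z <- rnorm(40); x <- z + rnorm(40); y <- z + rnorm(40)
#' partialCorrelation(x, y, cbind(z))   # association explained by z
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        for (j in seq_along(covariates)) {
            if (!is.numeric(covariates[[j]]))
                covariates[[j]] <-
                    as.numeric(factor(covariates[[j]])) - 1
        }
        covariates <- as.matrix(covariates)
    }
    complete <- !is.na(x) & !is.na(y)
    if (!is.null(covariates))
        complete <- complete & stats::complete.cases(covariates)
    x <- x[complete]; y <- y[complete]
    C <- 0L
    if (!is.null(covariates)) {
        Z <- covariates[complete, , drop = FALSE]
        X <- cbind(1, Z)
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
            warning("covariate matrix is rank-deficient; collinear columns dropped")
            X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
        }
        C <- ncol(X) - 1L
        xVar0 <- stats::var(x); yVar0 <- stats::var(y)
        x <- stats::lm.fit(X, x)$residuals
        y <- stats::lm.fit(X, y)$residuals
        # a variable fully explained by the covariates leaves numerical
        # dust as residual; treat it as exactly zero association
        if (xVar0 > 0 && stats::var(x) / xVar0 < 1e-12) x[] <- 0
        if (yVar0 > 0 && stats::var(y) / yVar0 < 1e-12) y[] <- 0
    } else {
        x <- x - mean(x); y <- y - mean(y)
    }
    n <- length(x)
    if (n < C + 3L) stop("need at least C + 3 complete subjects")
    denom <- sqrt(sum(x^2) * sum(y^2))
    r <- if (denom == 0) 0 else sum(x * y) / denom
    r <- min(1, max(-1, r))
    df <- n - 2L - C
    tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Metric-by-score partial-correlation table
#'
#' Computes the covariate-adjusted correlation of every network metric
#' with every behavioral score over the subjects present in both tables.
#' No multiple-testing correction is applied (the p-values are reported
#' raw, flagged as uncorrected).
#'
#' @param metrics data.frame with a `subject_id` column and one column
#'   per network metric.
#' @param scores data.frame with a `subject_id` column and one column
#'   per behavioral score.
#' @param covariates data.frame with `subject_id` plus covariate columns
#'   (e.g. age, sex, education), or NULL.
#' @return data.frame with columns metric, score, r, p, n, covariates,
#'   corrected (always FALSE).
#' @export
behaviorTable <- function(metrics, scores, covariates = NULL) {
    ids <- intersect(metrics$subject_id, scores$subject_id)
    if (!length(ids)) stop("no overlapping subjects between metrics and scores")
    m <- metrics[match(ids, metrics$subject_id), , drop = FALSE]
    s <- scores[match(ids, scores$subject_id), , drop = FALSE]
    covNames <- "none"
    Z <- NULL
    if (!is.null(covariates)) {
        Z <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
        Z <- Z[, setdiff(names(Z), "subject_id"), drop = FALSE]
        covNames <- paste(names(Z), collapse = ",")
    }
    metricNames <- setdiff(names(m), "subject_id")
    scoreNames <- setdiff(names(s), "subject_id")
    rows <- list()
    for (mn in metricNames) {
        for (sn in scoreNames) {
            pc <- partialCorrelation(m[[mn]], s[[sn]], Z)
            rows[[length(rows) + 1L]] <- data.frame(
                metric = mn, score = sn, r = pc$r, p = pc$p, n = pc$n,
                covariates = covNames, corrected = FALSE,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
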