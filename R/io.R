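# TSV / JSON readers and writers. All numeric TSVs are written at full
# double precision (%.17g) so read(write(x)) round-trips to 1e-12 and
# better; missing values are encoded as "NA".

fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

#' Write / read a square labelled matrix as TSV
#'
#' The file carries the ROI labels both as a header row and as a first
#' column, so the matrix is self-describing.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @return `writeMatrixTsv` returns `path` invisibly; `readMatrixTsv`
#'   the matrix.
#' @name matrix-tsv
NULL

#' @rdname matrix-tsv
#' @export
writeMatrixTsv <- function(m, path) {
    if (nrow(m) != ncol(m)) stop("matrix must be square")
    labels <- rownames(m)
    if (is.null(labels)) labels <- defaultRoiLabels(nrow(m))
    lines <- c(paste(c("label", labels), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(c(labels[i], fmtNum(m[i, ])), collapse = "\t"),
                   ""))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname matrix-tsv
#' @export
readMatrixTsv <- function(path) {
    lines <- readLines(path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    labels <- header[-1L]
    if (anyDuplicated(labels))
        stop("duplicate labels in header of ", path)
    n <- length(labels)
    m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    if (length(lines) - 1L != n)
        stop(sprintf("%s: expected %d data rows, found %d", path, n,
                     length(lines) - 1L))
    for (i in seq_len(n)) {
        fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != n + 1L)
            stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                         path, i + 1L, length(fields), n + 1L))
        vals <- suppressWarnings(as.numeric(fields[-1L]))
        bad <- is.na(vals) & fields[-1L] != "NA"
        if (any(bad))
            stop(sprintf("%s: non-numeric cell at line %d, column %d",
                         path, i + 1L, which(bad)[1L] + 1L))
        m[i, ] <- vals
    }
    m
}

#' Write / read an ROI time-series TSV
#'
#' Rows are time frames, columns are ROIs; a header row carries the ROI
#' labels.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param path file path.
#' @param trSeconds,subjectID metadata applied on read.
#' @return `writeTimeSeriesTsv` returns `path` invisibly;
#'   `readTimeSeriesTsv` a [RoiTimeSeries-class].
#' @name timeseries-tsv
NULL

#' @rdname timeseries-tsv
#' @export
writeTimeSeriesTsv <- function(ts, path) {
    x <- ts@data
    lines <- c(paste(colnames(x), collapse = "\t"),
               vapply(seq_len(nrow(x)), function(i)
                   paste(fmtNum(x[i, ]), collapse = "\t"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname timeseries-tsv
#' @export
readTimeSeriesTsv <- function(path, trSeconds = 2, subjectID = "subj") {
    lines <- readLines(path)
    labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    n <- length(labels)
    rows <- lapply(seq_along(lines)[-1L], function(i) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != n)
            stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                         path, i, length(fields), n))
        vals <- suppressWarnings(as.numeric(fields))
        bad <- is.na(vals) & fields != "NA"
        if (any(bad))
            stop(sprintf("%s: non-numeric cell at line %d, column %d",
                         path, i, which(bad)[1L]))
        vals
    })
    roiTimeSeries(do.call(rbind, rows), trSeconds = trSeconds,
                  subjectID = subjectID, roiLabels = labels)
}

#' Write / read a motion-parameter TSV (six columns)
#'
#' @param mp a [MotionParams-class].
#' @param path file path.
#' @param subjectID subject id applied on read.
#' @return `writeMotionTsv` returns `path` invisibly; `readMotionTsv` a
#'   [MotionParams-class].
#' @name motion-tsv
NULL

#' @rdname motion-tsv
#' @export
writeMotionTsv <- function(mp, path) {
    x <- mp@data
    lines <- c(paste(colnames(x), collapse = "\t"),
               vapply(seq_len(nrow(x)), function(i)
                   paste(fmtNum(x[i, ]), collapse = "\t"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname motion-tsv
#' @export
readMotionTsv <- function(path, subjectID = "subj") {
    lines <- readLines(path)
    rows <- lapply(seq_along(lines)[-1L], function(i) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != 6L)
            stop(sprintf("%s: ragged row at line %d (%d fields, expected 6)",
                         path, i, length(fields)))
        as.numeric(fields)
    })
    motionParams(do.call(rbind, rows), subjectID = subjectID)
}

#' Write / read the cohort table TSV
#'
#' @param table cohort data.frame (see [Cohort-class]).
#' @param path file path.
#' @return `writeCohortTsv` returns `path` invisibly; `readCohortTsv`
#'   the data.frame.
#' @name cohort-tsv
NULL

#' @rdname cohort-tsv
#' @export
writeCohortTsv <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname cohort-tsv
#' @export
readCohortTsv <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (anyDuplicated(tab$subject_id))
        stop("duplicate subject ids in ", path)
    tab
}

#' Write a results list as JSON
#'
#' @param x named list of results (scalars unboxed, full precision).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeResultsJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
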