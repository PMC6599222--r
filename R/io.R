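#' Read manual segmentations from long-form CSV
#'
#' Expected columns: \code{rater_id}, \code{scan_id}, \code{timepoint},
#' \code{repeat_index} (1-3), \code{column_index} (0-based) and
#' \code{depth_um}.  Every (rater, scan, timepoint, repeat) record must
#' cover each column exactly once and all depths must fall inside the
#' raster.
#'
#' @param path CSV file path.
#' @param geometry a \code{\link{ScanGeometry}} the records are validated
#'   against.
#' @return Named list of \code{\link{SegmentationSet}}, one per rater.
#' @export
readSegmentations <- function(path, geometry) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("rater_id", "scan_id", "timepoint", "repeat_index",
              "column_index", "depth_um")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("segmentation CSV is missing column(s): ",
             paste(miss, collapse = ", "))
    hi <- maxDepthUm(geometry)
    bad <- which(!is.finite(df$depth_um) | df$depth_um < 0 | df$depth_um > hi)
    if (length(bad))
        stop(sprintf(
            "depth outside [0, %g] um at row %d (rater '%s', scan '%s')",
            hi, bad[1L], df$rater_id[bad[1L]], df$scan_id[bad[1L]]))
    n <- nColumns(geometry)
    out <- lapply(split(df, df$rater_id), function(d) {
        key <- paste(d$scan_id, d$timepoint, d$repeat_index, sep = "\r")
        cnt <- table(key)
        if (any(cnt != n) || anyDuplicated(paste(key, d$column_index))) {
            off <- strsplit(names(cnt)[which(cnt != n)[1L]], "\r")[[1L]]
            stop(sprintf(
                "incomplete contour for rater '%s', scan '%s' (timepoint %s, repeat %s): expected %d columns",
                d$rater_id[1L], off[1L], off[2L], off[3L], n))
        }
        o <- order(key, d$column_index)
        d <- d[o, ]
        first <- seq(1L, nrow(d), by = n)
        if (!all(d$column_index == rep(0:(n - 1L), length(first))))
            stop(sprintf("column indices for rater '%s' are not 0..%d",
                         d$rater_id[1L], n - 1L))
        segmentationSet(matrix(d$depth_um, nrow = n),
                        scanId = d$scan_id[first],
                        timepoint = d$timepoint[first],
                        repeatIndex = d$repeat_index[first],
                        rater = d$rater_id[1L], geometry = geometry)
    })
    out[order(names(out))]
}

#' Write segmentation sets to long-form CSV
#'
#' Inverse of \code{\link{readSegmentations}}; a write-then-read round trip
#' reproduces depths exactly (depths are serialised at full precision).
#'
#' @param sets a \code{SegmentationSet} or list thereof.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentations <- function(sets, path) {
    if (is(sets, "SegmentationSet")) sets <- list(sets)
    rows <- lapply(sets, function(x) {
        cd <- colData(x)
        n <- nColumns(geometry(x))
        data.frame(
            rater_id = rater(x),
            scan_id = rep(cd$scan_id, each = n),
            timepoint = rep(cd$timepoint, each = n),
            repeat_index = rep(cd$repeat_index, each = n),
            column_index = rep(0:(n - 1L), ncol(x)),
            depth_um = as.vector(depths(x)))
    })
    df <- do.call(rbind, rows)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read displacement fields from long-form CSV
#'
#' Expected columns \code{rater_id}, \code{scan_id}, \code{column_index}
#' (0-based), \code{dz_um}; optional per-scan labels
#' \code{interval_months}, \code{eye}, \code{pair_id} are carried into
#' colData.
#'
#' @inheritParams readSegmentations
#' @return Named list of \code{\link{DisplacementFieldSet}}, one per rater.
#' @export
readDisplacements <- function(path, geometry) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("rater_id", "scan_id", "column_index", "dz_um")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("displacement CSV is missing column(s): ",
             paste(miss, collapse = ", "))
    n <- nColumns(geometry)
    extra <- intersect(c("interval_months", "eye", "pair_id"), colnames(df))
    out <- lapply(split(df, df$rater_id), function(d) {
        cnt <- table(d$scan_id)
        if (any(cnt != n))
            stop(sprintf("incomplete field for rater '%s', scan '%s'",
                         d$rater_id[1L], names(cnt)[which(cnt != n)[1L]]))
        o <- order(d$scan_id, d$column_index)
        d <- d[o, ]
        first <- seq(1L, nrow(d), by = n)
        info <- NULL
        if (length(extra))
            info <- cbind(data.frame(scan_id = d$scan_id[first]),
                          d[first, extra, drop = FALSE])
        displacementFieldSet(matrix(d$dz_um, nrow = n),
                             scanId = d$scan_id[first],
                             rater = d$rater_id[1L], geometry = geometry,
                             scanInfo = info)
    })
    out[order(names(out))]
}

#' Write displacement field sets to long-form CSV
#'
#' @param sets a \code{DisplacementFieldSet} or list thereof.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDisplacements <- function(sets, path) {
    if (is(sets, "DisplacementFieldSet")) sets <- list(sets)
    rows <- lapply(sets, function(x) {
        cd <- colData(x)
        n <- nColumns(geometry(x))
        df <- data.frame(
            rater_id = rater(x),
            scan_id = rep(cd$scan_id, each = n),
            column_index = rep(0:(n - 1L), ncol(x)),
            dz_um = as.vector(dzValues(x)))
        for (nm in intersect(c("interval_months", "eye", "pair_id"),
                             colnames(cd)))
            df[[nm]] <- rep(cd[[nm]], each = n)
        df
    })
    df <- do.call(rbind, rows)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
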