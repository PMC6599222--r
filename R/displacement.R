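#' Construct a displacement field set
#'
#' @param dzUm numeric matrix of per-column displacements in micrometres,
#'   \code{nColumns(geometry)} rows, one column per B-scan.
#' @param scanId character vector of scan identifiers, one per column.
#' @param rater rater (or \code{"method"}) identifier.
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param scanInfo optional data.frame with per-scan labels
#'   (\code{interval_months}, \code{eye}, \code{pair_id}), recycled into
#'   colData by \code{scan_id}.
#' @return A \code{\link{DisplacementFieldSet}}.
#' @export
displacementFieldSet <- function(dzUm, scanId, rater, geometry,
                                 scanInfo = NULL) {
    dzUm <- as.matrix(dzUm)
    cd <- DataFrame(scan_id = as.character(scanId))
    if (!is.null(scanInfo)) {
        j <- match(cd$scan_id, scanInfo$scan_id)
        for (nm in setdiff(colnames(scanInfo), "scan_id"))
            cd[[nm]] <- scanInfo[[nm]][j]
    }
    se <- SummarizedExperiment(assays = list(dz_um = unname(dzUm)),
                               colData = cd)
    metadata(se) <- list(rater = as.character(rater), geometry = geometry)
    new("DisplacementFieldSet", se)
}

#' @rdname DisplacementFieldSet-class
#' @export
setMethod("dzValues", "DisplacementFieldSet", function(x) assay(x, "dz_um"))

#' @rdname DisplacementFieldSet-class
#' @export
setMethod("geometry", "DisplacementFieldSet", function(x) metadata(x)$geometry)

#' @rdname DisplacementFieldSet-class
#' @export
setMethod("rater", "DisplacementFieldSet", function(x) metadata(x)$rater)

#' @rdname DisplacementFieldSet-class
#' @export
setMethod("scanIds", "DisplacementFieldSet", function(x) colData(x)$scan_id)

setMethod("show", "DisplacementFieldSet", function(object) {
    dz <- dzValues(object)
    cat(sprintf("DisplacementFieldSet rater '%s': %d scans x %d columns\n",
                rater(object), ncol(dz), nrow(dz)))
    if (ncol(dz))
        cat(sprintf("  dz mean %.2f um, sd %.2f um\n", mean(dz), stats::sd(dz)))
})

#' Displacement between the two measurement sessions
#'
#' Per-column anterior-posterior CSI displacement, computed as the repeat-
#' aggregated depth at the second session minus the first
#' (positive = thickening).  Repeats are aggregated by their mean by
#' default.
#'
#' @param x a \code{\link{SegmentationSet}} containing both timepoints.
#' @param scanId scans to compute; defaults to every scan with both
#'   timepoints present.
#' @param timepoints length-2 character, the session labels in (first,
#'   second) order.
#' @param aggregate repeat-aggregation rule, \code{"mean"} or
#'   \code{"median"}.
#' @return A \code{\link{DisplacementFieldSet}} for the same rater.
#' @examples
#' g <- scanGeometry(nColumns = 4, mDepth = 100, dzUm = 4)
#' m <- cbind(rep(100, 4), rep(110, 4))
#' ss <- segmentationSet(m, c("s1", "s1"), c("t1", "t2"), c(1, 1), "E1", g)
#' dzValues(displacementFromTimepoints(ss))
#' @export
displacementFromTimepoints <- function(x, scanId = NULL,
                                       timepoints = c("t1", "t2"),
                                       aggregate = c("mean", "median")) {
    aggregate <- match.arg(aggregate)
    cd <- colData(x)
    if (is.null(scanId)) {
        s1 <- unique(cd$scan_id[cd$timepoint == timepoints[1L]])
        s2 <- unique(cd$scan_id[cd$timepoint == timepoints[2L]])
        scanId <- intersect(s1, s2)
        if (!length(scanId))
            stop("no scan has both timepoints present")
    }
    agg <- function(scn, tp) {
        i <- which(cd$scan_id == scn & cd$timepoint == tp)
        if (!length(i))
            stop(sprintf("scan '%s' is missing timepoint '%s' for rater '%s'",
                         scn, tp, rater(x)))
        d <- depths(x)[, i, drop = FALSE]
        if (aggregate == "mean") rowMeans(d) else apply(d, 1L, stats::median)
    }
    dz <- vapply(scanId,
                 function(scn) agg(scn, timepoints[2L]) - agg(scn, timepoints[1L]),
                 numeric(nColumns(geometry(x))))
    displacementFieldSet(dz, scanId, rater(x), geometry(x))
}

#' Build the C-B-A-B-C region partition
#'
#' Splits the raster width into five contiguous, equidistant column blocks
#' symmetric about the foveal centre (raster midpoint by default): A the
#' foveal, B the parafoveal and C the perifoveal region.  Stored labels are
#' in image order; the eye side determines how \code{\link{regionMeans}}
#' reads them temporal to nasal.
#'
#' @param geometry a \code{\link{ScanGeometry}} (or an integer column count).
#' @param eye \code{"right"} or \code{"left"}.
#' @return A \code{\link{RegionPartition}}.
#' @export
regionPartition <- function(geometry, eye = c("right", "left")) {
    eye <- match.arg(eye)
    n <- if (is(geometry, "ScanGeometry")) nColumns(geometry)
         else as.integer(geometry)
    if (n < 5L) stop("need at least five columns for a five-region partition")
    b <- round(seq(0L, n, length.out = 6L))
    new("RegionPartition",
        starts = as.integer(b[-6L] + 1L), ends = as.integer(b[-1L]),
        labels = c("C", "B", "A", "B", "C"), eye = eye)
}

setMethod("show", "RegionPartition", function(object) {
    cat(sprintf("RegionPartition (%s eye): %s\n", object@eye,
        paste(sprintf("%s[%d-%d]", object@labels, object@starts - 1L,
                      object@ends - 1L), collapse = " ")))
})

#' Mean displacement per choroidal region
#'
#' Averages a per-column field over the five C-B-A-B-C blocks.  Values are
#' returned temporal to nasal: for a right eye that is the image column
#' order, for a left eye the block order is mirrored before labelling
#' (stored data always remain in image order).
#'
#' @param field numeric per-column vector, or a
#'   \code{\link{DisplacementFieldSet}} (then a scans x 5 matrix is
#'   returned, using each scan's own \code{eye} label when present).
#' @param partition a \code{\link{RegionPartition}}.
#' @return Named numeric(5) (or a matrix), labels C,B,A,B,C temporal to
#'   nasal.
#' @examples
#' p <- regionPartition(500)
#' regionMeans(rep(10, 500), p)
#' @export
regionMeans <- function(field, partition) {
    if (is(field, "DisplacementFieldSet")) {
        if (nColumns(geometry(field)) != partition@ends[5L])
            stop("partition does not cover the field's columns")
        cd <- colData(field)
        eyes <- if ("eye" %in% colnames(cd)) cd$eye else partition@eye
        out <- t(vapply(seq_len(ncol(field)), function(j) {
            pj <- partition
            pj@eye <- eyes[[min(j, length(eyes))]]
            regionMeans(dzValues(field)[, j], pj)
        }, numeric(5L)))
        rownames(out) <- scanIds(field)
        return(out)
    }
    if (length(field) != partition@ends[5L])
        stop(sprintf("field has %d columns but partition covers %d",
                     length(field), partition@ends[5L]))
    m <- vapply(seq_len(5L), function(k)
        mean(field[partition@starts[k]:partition@ends[k]]), numeric(1))
    if (partition@eye == "left") m <- rev(m)
    names(m) <- partition@labels
    m
}
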