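#' Construct a contour
#'
#' @param scanId scan identifier.
#' @param depthsUm per-column CSI depth in micrometres from the image top.
#' @param timepoint session label, conventionally \code{"t1"} or \code{"t2"}.
#' @param repeatIndex repeat number.
#' @return A \code{\link{Contour}}.
#' @export
contour <- function(scanId, depthsUm, timepoint = "t1", repeatIndex = 1L) {
    new("Contour", scanId = as.character(scanId),
        timepoint = as.character(timepoint),
        repeatIndex = as.integer(repeatIndex),
        depthsUm = as.numeric(depthsUm))
}

#' @rdname Contour-class
#' @param x a \code{Contour}.
#' @export
setMethod("depths", "Contour", function(x) x@depthsUm)

#' @rdname Contour-class
#' @export
setMethod("scanIds", "Contour", function(x) x@scanId)

setMethod("show", "Contour", function(object) {
    cat(sprintf("Contour %s [%s, repeat %d]: %d columns, depth %.1f-%.1f um\n",
                object@scanId, object@timepoint, object@repeatIndex,
                length(object@depthsUm), min(object@depthsUm),
                max(object@depthsUm)))
})

#' Construct a segmentation set
#'
#' Bundles all tracings of one rater into a
#' \code{\link{SegmentationSet}} (a SummarizedExperiment with assay
#' \code{depth_um}).  Records are indexed by (scan, timepoint, repeat);
#' each (scan, timepoint) must carry either a single tracing or the full
#' triple repeat.
#'
#' @param depthsUm numeric matrix, \code{nColumns(geometry)} rows, one
#'   column per traced line; or a list of \code{\link{Contour}} objects.
#' @param scanId,timepoint,repeatIndex record index vectors, one entry per
#'   assay column (ignored when \code{depthsUm} is a list of contours).
#' @param rater rater identifier.
#' @param geometry a \code{\link{ScanGeometry}}.
#' @return A \code{SegmentationSet}.
#' @examples
#' g <- scanGeometry(nColumns = 10, mDepth = 100, dzUm = 4)
#' m <- matrix(200, nrow = 10, ncol = 2)
#' ss <- segmentationSet(m, scanId = c("s1", "s1"), timepoint = c("t1", "t2"),
#'                       repeatIndex = c(1, 1), rater = "E1", geometry = g)
#' scanIds(ss)
#' @export
segmentationSet <- function(depthsUm, scanId, timepoint, repeatIndex,
                            rater, geometry) {
    if (is.list(depthsUm)) {
        cts <- depthsUm
        stopifnot(all(vapply(cts, is, logical(1), "Contour")))
        scanId <- vapply(cts, function(ct) ct@scanId, character(1))
        timepoint <- vapply(cts, function(ct) ct@timepoint, character(1))
        repeatIndex <- vapply(cts, function(ct) ct@repeatIndex, integer(1))
        depthsUm <- vapply(cts, function(ct) ct@depthsUm,
                           numeric(nColumns(geometry)))
    }
    depthsUm <- as.matrix(depthsUm)
    cd <- DataFrame(scan_id = as.character(scanId),
                    timepoint = as.character(timepoint),
                    repeat_index = as.integer(repeatIndex))
    se <- SummarizedExperiment(assays = list(depth_um = unname(depthsUm)),
                               colData = cd)
    metadata(se) <- list(rater = as.character(rater), geometry = geometry)
    new("SegmentationSet", se)
}

#' @rdname SegmentationSet-class
#' @export
setMethod("geometry", "SegmentationSet", function(x) metadata(x)$geometry)

#' @rdname SegmentationSet-class
#' @export
setMethod("rater", "SegmentationSet", function(x) metadata(x)$rater)

#' @rdname SegmentationSet-class
#' @export
setMethod("depths", "SegmentationSet", function(x) assay(x, "depth_um"))

#' @rdname SegmentationSet-class
#' @export
setMethod("scanIds", "SegmentationSet", function(x) colData(x)$scan_id)

#' @rdname SegmentationSet-class
#' @export
setMethod("timepoints", "SegmentationSet", function(x) colData(x)$timepoint)

#' @rdname SegmentationSet-class
#' @export
setMethod("repeatIndex", "SegmentationSet", function(x) colData(x)$repeat_index)

setMethod("show", "SegmentationSet", function(object) {
    cd <- colData(object)
    cat(sprintf("SegmentationSet rater '%s': %d tracings on %d scans (%s)\n",
                rater(object), ncol(object),
                length(unique(cd$scan_id)),
                paste(sort(unique(cd$timepoint)), collapse = ", ")))
    cat(sprintf("  geometry %d x %d px, dz %.2f um/px\n",
                nColumns(geometry(object)), mDepth(geometry(object)),
                pixelSpacings(geometry(object))[["dz_um"]]))
})

#' Extract a single contour from a set
#'
#' @param x a \code{SegmentationSet}.
#' @param scanId,timepoint,repeatIndex record index of the tracing.
#' @return A \code{\link{Contour}}.
#' @export
getContour <- function(x, scanId, timepoint = "t1", repeatIndex = 1L) {
    cd <- colData(x)
    i <- which(cd$scan_id == scanId & cd$timepoint == timepoint &
               cd$repeat_index == repeatIndex)
    if (length(i) != 1L)
        stop(sprintf("no unique tracing for scan '%s', timepoint '%s', repeat %d",
                     scanId, timepoint, repeatIndex))
    contour(scanId, depths(x)[, i], timepoint, repeatIndex)
}

#' Repeat-averaged contour
#'
#' Mean of the available repeat tracings of one (scan, timepoint), the
#' default repeat-aggregation rule of the displacement computation.
#'
#' @inheritParams getContour
#' @return numeric vector of per-column depths in micrometres.
#' @export
meanContour <- function(x, scanId, timepoint = "t1") {
    cd <- colData(x)
    i <- which(cd$scan_id == scanId & cd$timepoint == timepoint)
    if (!length(i))
        stop(sprintf("scan '%s' has no tracings at timepoint '%s' for rater '%s'",
                     scanId, timepoint, rater(x)))
    rowMeans(depths(x)[, i, drop = FALSE])
}
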