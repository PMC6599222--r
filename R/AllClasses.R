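#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' B-scan raster geometry
#'
#' Physical description of the OCT B-scan raster on which contours live:
#' number of A-scan columns, number of depth pixels per A-scan, and the
#' pixel spacings in micrometres.  Depth coordinates throughout the package
#' are continuous micrometres measured from the image top (anterior),
#' increasing towards posterior; columns are 0-based image order
#' (temporal to nasal for a right eye).
#'
#' @slot nColumns integer, A-scans per B-scan.
#' @slot mDepth integer, depth pixels per A-scan.
#' @slot dxUm,dyUm,dzUm numeric, pixel spacing in micrometres per pixel in
#'   the nasal-temporal (x), superior-inferior (y) and anterior-posterior
#'   (z) directions.
#' @name ScanGeometry-class
#' @aliases ScanGeometry
#' @exportClass ScanGeometry
setClass("ScanGeometry",
    representation(
        nColumns = "integer",
        mDepth   = "integer",
        dxUm     = "numeric",
        dyUm     = "numeric",
        dzUm     = "numeric"
    )
)

setValidity("ScanGeometry", function(object) {
    msg <- character()
    if (length(object@nColumns) != 1L || is.na(object@nColumns) ||
        object@nColumns < 1L)
        msg <- c(msg, "nColumns must be a single integer >= 1")
    if (length(object@mDepth) != 1L || is.na(object@mDepth) ||
        object@mDepth < 1L)
        msg <- c(msg, "mDepth must be a single integer >= 1")
    for (sl in c("dxUm", "dyUm", "dzUm")) {
        v <- slot(object, sl)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("%s must be a single positive number", sl))
    }
    if (length(msg)) msg else TRUE
})

#' A single CSI contour
#'
#' One manual (or simulated) tracing of the choroid-sclera interface on one
#' B-scan: a depth value in micrometres for every A-scan column.
#'
#' @slot scanId character scan identifier.
#' @slot timepoint character, measurement session label (\code{"t1"}/\code{"t2"}).
#' @slot repeatIndex integer repeat number (1--3).
#' @slot depthsUm numeric vector of per-column depths in micrometres.
#' @name Contour-class
#' @aliases Contour
#' @exportClass Contour
setClass("Contour",
    representation(
        scanId      = "character",
        timepoint   = "character",
        repeatIndex = "integer",
        depthsUm    = "numeric"
    )
)

setValidity("Contour", function(object) {
    msg <- character()
    if (length(object@scanId) != 1L)    msg <- c(msg, "scanId must be length 1")
    if (length(object@timepoint) != 1L) msg <- c(msg, "timepoint must be length 1")
    if (length(object@repeatIndex) != 1L)
        msg <- c(msg, "repeatIndex must be length 1")
    if (anyNA(object@depthsUm) || !all(is.finite(object@depthsUm)))
        msg <- c(msg, "depths must be finite and non-missing")
    if (length(msg)) msg else TRUE
})

#' A rater's segmentation collection
#'
#' All contours drawn by one rater, stored as a SummarizedExperiment whose
#' assay \code{"depth_um"} is an nColumns x records matrix (one column per
#' traced line) and whose colData carries \code{scan_id}, \code{timepoint}
#' and \code{repeat_index}.  The raster geometry and the rater id live in
#' the metadata.  Depths are validated against the geometry: within
#' \code{[0, mDepth * dzUm]}, complete, finite.
#'
#' @name SegmentationSet-class
#' @aliases SegmentationSet
#' @exportClass SegmentationSet
setClass("SegmentationSet", contains = "SummarizedExperiment")

setValidity("SegmentationSet", function(object) {
    msg <- character()
    md <- metadata(object)
    if (is.null(md$geometry) || !is(md$geometry, "ScanGeometry"))
        return("metadata must contain a ScanGeometry under 'geometry'")
    if (is.null(md$rater) || length(md$rater) != 1L)
        msg <- c(msg, "metadata must contain a single rater id under 'rater'")
    if (!"depth_um" %in% SummarizedExperiment::assayNames(object))
        return("assay 'depth_um' is required")
    g <- md$geometry
    m <- assay(object, "depth_um")
    if (nrow(m) != g@nColumns)
        msg <- c(msg, sprintf("assay has %d rows; geometry expects %d columns per contour",
                              nrow(m), g@nColumns))
    cd <- colData(object)
    need <- c("scan_id", "timepoint", "repeat_index")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain", paste(need, collapse = ", ")))
    if (ncol(m)) {
        if (anyNA(m) || !all(is.finite(m)))
            msg <- c(msg, "depths contain missing or non-finite values")
        else {
            hi <- g@mDepth * g@dzUm
            if (min(m) < 0 || max(m) > hi)
                msg <- c(msg, sprintf("depths outside [0, %g] um", hi))
        }
        key <- paste(cd$scan_id, cd$timepoint)
        reps <- table(key)
        if (any(duplicated(paste(key, cd$repeat_index))))
            msg <- c(msg, "duplicated (scan, timepoint, repeat) records")
        if (!all(reps %in% c(1L, 3L)))
            msg <- c(msg, sprintf("repeats per (scan, timepoint) must be 1 or 3; offending: %s",
                                  paste(names(reps)[!reps %in% c(1L, 3L)], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Per-column displacement fields for a rater
#'
#' Anterior-posterior CSI displacement between two measurement sessions,
#' one column of the assay \code{"dz_um"} per B-scan (positive values =
#' thickening, CSI displaced posteriorly).  colData holds \code{scan_id}
#' and optionally \code{interval_months}, \code{eye} and \code{pair_id}
#' labels used by the reporting layer.
#'
#' @name DisplacementFieldSet-class
#' @aliases DisplacementFieldSet
#' @exportClass DisplacementFieldSet
setClass("DisplacementFieldSet", contains = "SummarizedExperiment")

setValidity("DisplacementFieldSet", function(object) {
    msg <- character()
    md <- metadata(object)
    if (is.null(md$geometry) || !is(md$geometry, "ScanGeometry"))
        return("metadata must contain a ScanGeometry under 'geometry'")
    if (is.null(md$rater) || length(md$rater) != 1L)
        msg <- c(msg, "metadata must contain a single rater id under 'rater'")
    if (!"dz_um" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dz_um' is required")
    m <- assay(object, "dz_um")
    if (nrow(m) != md$geometry@nColumns)
        msg <- c(msg, "assay row count does not match geometry nColumns")
    if (!"scan_id" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain scan_id")
    if (ncol(m) && (anyNA(m) || !all(is.finite(m))))
        msg <- c(msg, "displacements contain missing or non-finite values")
    if (any(duplicated(colData(object)$scan_id)))
        msg <- c(msg, "duplicated scan_id in displacement set")
    if (length(msg)) msg else TRUE
})

#' Five-region nasal-temporal partition
#'
#' Contiguous, disjoint column blocks labelled C-B-A-B-C covering the
#' raster width: A foveal, B parafoveal, C perifoveal, symmetric about the
#' foveal centre (taken at the raster midpoint by default).  Labels read
#' temporal to nasal; for a left eye the image column order is mirrored
#' relative to that reading, which \code{\link{regionMeans}} handles at
#' reporting time.
#'
#' @slot starts,ends integer(5), 1-based inclusive column ranges in image order.
#' @slot labels character(5), region labels in image order.
#' @slot eye \code{"right"} or \code{"left"}.
#' @name RegionPartition-class
#' @aliases RegionPartition
#' @exportClass RegionPartition
setClass("RegionPartition",
    representation(
        starts = "integer",
        ends   = "integer",
        labels = "character",
        eye    = "character"
    )
)

setValidity("RegionPartition", function(object) {
    msg <- character()
    k <- length(object@starts)
    if (k != 5L || length(object@ends) != 5L || length(object@labels) != 5L)
        return("partition must have exactly five regions")
    if (object@starts[1L] != 1L)
        msg <- c(msg, "first region must start at column 1")
    if (any(object@starts[-1L] != object@ends[-k] + 1L))
        msg <- c(msg, "regions must be contiguous and disjoint")
    sizes <- object@ends - object@starts + 1L
    if (any(sizes < 1L)) msg <- c(msg, "empty region")
    if (diff(range(sizes)) > 1L)
        msg <- c(msg, "region sizes must differ by at most one column")
    if (!object@eye %in% c("right", "left"))
        msg <- c(msg, "eye must be 'right' or 'left'")
    if (length(msg)) msg else TRUE
})

#' Pairwise similarity matrix between raters
#'
#' Symmetric unit-diagonal matrix of similarities in [0, 1] between the
#' predictions of each pair of raters (possibly including the automated
#' method), together with the metric name and the number of shared scans
#' each pairwise value was computed over.
#'
#' @slot values numeric r x r matrix, symmetric, diagonal 1.
#' @slot metric character, one of \code{"DC"}, \code{"JC"}, \code{"BLD"},
#'   \code{"diffZ"}.
#' @slot nShared integer r x r matrix of shared-scan counts.
#' @name SimilarityMatrix-class
#' @aliases SimilarityMatrix
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(
        values  = "matrix",
        metric  = "character",
        nShared = "matrix"
    )
)

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) return("values must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "values must carry identical row/col rater names")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
        msg <- c(msg, "values must be symmetric")
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
        msg <- c(msg, "similarities must lie in [0, 1]")
    if (!isTRUE(all.equal(unname(diag(v)), rep(1, nrow(v)))))
        msg <- c(msg, "diagonal must be 1")
    if (!identical(dim(object@nShared), dim(v)))
        msg <- c(msg, "nShared must match values in shape")
    if (length(msg)) msg else TRUE
})
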