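#' @rdname ScanGeometry-class
#' @param x,object a package object.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname ScanGeometry-class
#' @export
setGeneric("mDepth", function(x) standardGeneric("mDepth"))

#' @rdname ScanGeometry-class
#' @export
setGeneric("pixelSpacings", function(x) standardGeneric("pixelSpacings"))

#' @rdname ScanGeometry-class
#' @export
setGeneric("maxDepthUm", function(x) standardGeneric("maxDepthUm"))

#' @rdname SegmentationSet-class
#' @param x a package object.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("rater", function(x) standardGeneric("rater"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("scanIds", function(x) standardGeneric("scanIds"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname SegmentationSet-class
#' @export
setGeneric("repeatIndex", function(x) standardGeneric("repeatIndex"))

#' @rdname DisplacementFieldSet-class
#' @param x a package object.
#' @export
setGeneric("dzValues", function(x) standardGeneric("dzValues"))

#' @rdname SimilarityMatrix-class
#' @param x a \code{SimilarityMatrix}.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("raterIds", function(x) standardGeneric("raterIds"))
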