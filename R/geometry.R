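#' Construct a B-scan raster geometry
#'
#' Defaults reproduce the study raster: 25-scan volume stacks of 500 x 768
#' pixel B-scans with pixel spacings 11.46 / 245 / 3.87 um in x/y/z, i.e. a
#' usable A-scan depth of about 2.97 mm of which roughly 1.9 mm is imaged
#' tissue.
#'
#' @param nColumns A-scans per B-scan.
#' @param mDepth depth pixels per A-scan.
#' @param dxUm,dyUm,dzUm pixel spacings in micrometres per pixel.
#' @return A \code{\link{ScanGeometry}} object.
#' @examples
#' g <- scanGeometry()
#' maxDepthUm(g)
#' @export
scanGeometry <- function(nColumns = 500L, mDepth = 768L,
                         dxUm = 11.46, dyUm = 245, dzUm = 3.87) {
    new("ScanGeometry",
        nColumns = as.integer(nColumns), mDepth = as.integer(mDepth),
        dxUm = as.numeric(dxUm), dyUm = as.numeric(dyUm),
        dzUm = as.numeric(dzUm))
}

#' @rdname ScanGeometry-class
#' @export
setMethod("nColumns", "ScanGeometry", function(x) x@nColumns)

#' @rdname ScanGeometry-class
#' @export
setMethod("mDepth", "ScanGeometry", function(x) x@mDepth)

#' @rdname ScanGeometry-class
#' @export
setMethod("pixelSpacings", "ScanGeometry",
    function(x) c(dx_um = x@dxUm, dy_um = x@dyUm, dz_um = x@dzUm))

#' @rdname ScanGeometry-class
#' @export
setMethod("maxDepthUm", "ScanGeometry", function(x) x@mDepth * x@dzUm)

setMethod("show", "ScanGeometry", function(object) {
    cat("ScanGeometry:", object@nColumns, "columns x", object@mDepth,
        "depth pixels\n")
    cat(sprintf("  spacing (um/px): dx=%.2f dy=%.2f dz=%.2f; max depth %.1f um\n",
                object@dxUm, object@dyUm, object@dzUm, maxDepthUm(object)))
})
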