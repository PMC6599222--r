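#' diffZ dissimilarity between two displacement field sets
#'
#' Normalised mean absolute difference between the per-column displacements
#' of two raters over the same scans,
#' \eqn{diffZ = \sum_s \sum_i |\Delta E_a^s(i) - \Delta E_b^s(i)| / (m n S)},
#' computed in depth-pixel units (micrometre inputs are divided by the
#' axial spacing \code{dzUm}; the image height m is in pixels).  0 means
#' maximal agreement, 1 complete disagreement.  diffZ is a metric on
#' displacement field sets.
#'
#' @param a,b \code{\link{DisplacementFieldSet}} objects over the same
#'   scans (order may differ), or numeric matrices in micrometres with
#'   matching scan columns.
#' @param geometry a \code{\link{ScanGeometry}}; defaults to the sets' own.
#' @return Dissimilarity in [0, 1].
#' @export
diffZ <- function(a, b, geometry = NULL) {
    if (is(a, "DisplacementFieldSet")) {
        if (is.null(geometry)) geometry <- geometry(a)
        ia <- scanIds(a); ib <- scanIds(b)
        if (!setequal(ia, ib))
            stop("displacement sets cover different scans: ",
                 paste(c(setdiff(ia, ib), setdiff(ib, ia)), collapse = ", "))
        ma <- dzValues(a)
        mb <- dzValues(b)[, match(ia, ib), drop = FALSE]
    } else {
        if (is.null(geometry))
            stop("geometry is required for matrix input")
        ma <- as.matrix(a); mb <- as.matrix(b)
        if (!identical(dim(ma), dim(mb)))
            stop("displacement matrices differ in shape")
    }
    sp <- pixelSpacings(geometry)
    m <- mDepth(geometry)
    sum(abs(ma - mb) / sp[["dz_um"]]) / (m * nrow(ma) * ncol(ma))
}
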