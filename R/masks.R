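#' Rasterise a contour to a binary region mask
#'
#' Builds the "anterior of CSI" region: a logical \code{mDepth x nColumns}
#' matrix that is TRUE from the image top down to the contour, per column
#' (block length \code{round(depth / dzUm)}).  Dice and Jaccard between two
#' tracings are computed on these masks.
#'
#' @param depthsUm per-column contour depths in micrometres (or a
#'   \code{\link{Contour}}).
#' @param geometry a \code{\link{ScanGeometry}}.
#' @return Logical matrix, rows = depth pixels, columns = A-scans.
#' @export
contourMask <- function(depthsUm, geometry) {
    if (is(depthsUm, "Contour")) depthsUm <- depths(depthsUm)
    if (length(depthsUm) != nColumns(geometry))
        stop("contour length does not match geometry")
    k <- pmin(pmax(round(depthsUm / pixelSpacings(geometry)[["dz_um"]]), 0),
              mDepth(geometry))
    outer(seq_len(mDepth(geometry)), k, "<=")
}

#' Dice coefficient between two binary masks
#'
#' \eqn{DC = 2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return Similarity in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
    if (!identical(dim(a), dim(b)))
        stop("mask shapes differ")
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) return(1)
    2 * sum(a & b) / (na + nb)
}

#' Jaccard coefficient between two binary masks
#'
#' \eqn{JC = |A \cap B| / |A \cup B|}; defined as 1 when both masks are
#' empty.  Algebraically \eqn{JC = DC / (2 - DC)}.
#'
#' @inheritParams diceCoefficient
#' @return Similarity in [0, 1].
#' @export
jaccardCoefficient <- function(a, b) {
    if (!identical(dim(a), dim(b)))
        stop("mask shapes differ")
    un <- sum(a | b)
    if (un == 0) return(1)
    sum(a & b) / un
}
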