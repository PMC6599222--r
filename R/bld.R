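#' Bidirectional local distance between two contours
#'
#' For every point p on the reference contour, BLD(p, E') is the maximum of
#' (i) the minimum Euclidean distance from p to the test contour E' and
#' (ii) the largest minimum distance among test points q whose nearest
#' reference point is p (0 if no test point maps to p).  Distances are
#' measured in the (x, z) plane in physical micrometres, using the
#' anisotropic pixel spacings of the geometry, and contours are treated as
#' the discrete point sets of their column samples.  Nearest-point ties are
#' broken towards the lower column index.
#'
#' @param referenceUm,testUm per-column depths in micrometres (numeric
#'   vectors of equal length, or \code{\link{Contour}} objects).
#' @param geometry a \code{\link{ScanGeometry}} supplying \code{dxUm} (and
#'   implicitly the micrometre z scale).
#' @return Numeric vector of per-reference-point BLD distances in
#'   micrometres.
#' @examples
#' g <- scanGeometry(nColumns = 5, mDepth = 100, dxUm = 1, dzUm = 1)
#' ref <- rep(0, 5); tst <- c(0, 0, 5, 0, 0)
#' bldPointDistances(ref, tst, g)[3]   # forward 1, inverse 5 -> 5
#' @export
bldPointDistances <- function(referenceUm, testUm, geometry) {
    if (is(referenceUm, "Contour")) referenceUm <- depths(referenceUm)
    if (is(testUm, "Contour")) testUm <- depths(testUm)
    if (length(referenceUm) != length(testUm))
        stop("contours must have the same number of columns")
    x <- (seq_along(referenceUm) - 1L) * pixelSpacings(geometry)[["dx_um"]]
    # full point-pair distance matrix, reference rows x test columns
    d2 <- outer(x, x, "-")^2 + outer(referenceUm, testUm, "-")^2
    d <- sqrt(d2)
    forward <- apply(d, 1L, min)
    nearestRef <- apply(d, 2L, which.min)   # for each test point q
    qmin <- apply(d, 2L, min)               # d_min(q, reference)
    inverse <- numeric(length(referenceUm))
    agg <- tapply(qmin, nearestRef, max)
    inverse[as.integer(names(agg))] <- agg
    pmax(forward, inverse)
}

#' Aggregate BLD over a set of scans
#'
#' Per scan the per-point distances are summed and normalised by
#' \eqn{n \cdot \max_p BLD(p)} so each scan contributes a value in [0, 1]
#' (identical contours give 0/0, defined as 0, i.e. perfect agreement);
#' the overall aggregate is the mean over scans.  The unnormalised mean
#' point distance in micrometres is reported alongside.
#'
#' @param reference,test named lists of per-column depth vectors (names =
#'   scan identifiers; both lists must cover the same scans).
#' @param geometry a \code{\link{ScanGeometry}}.
#' @return A \code{bldResult} list: \code{perScan} (named numeric),
#'   \code{aggregate} in [0, 1], \code{meanDistanceUm}.
#' @export
bldAggregate <- function(reference, test, geometry) {
    if (!setequal(names(reference), names(test)))
        stop("reference and test cover different scans")
    ids <- names(reference)
    n <- nColumns(geometry)
    per <- numeric(length(ids)); names(per) <- ids
    tot <- 0; cnt <- 0L
    for (s in ids) {
        bp <- bldPointDistances(reference[[s]], test[[s]], geometry)
        mx <- max(bp)
        per[s] <- if (mx == 0) 0 else sum(bp) / (n * mx)
        tot <- tot + sum(bp); cnt <- cnt + length(bp)
    }
    structure(list(perScan = per, aggregate = mean(per),
                   meanDistanceUm = tot / cnt),
              class = "bldResult")
}

#' @export
print.bldResult <- function(x, ...) {
    cat(sprintf("BLD over %d scans: aggregate %.4f (mean distance %.2f um)\n",
                length(x$perScan), x$aggregate, x$meanDistanceUm))
    invisible(x)
}
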