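#' Intra-Rater Coefficient
#'
#' Repeatability of a rater who traced each of S images three times.  Per
#' image and column the deviation of each repeat from the mean of the three
#' repeats is taken; the IRC is the fraction of all 3nS deviations whose
#' absolute value is within the tolerance l.  Three identical repeats give
#' IRC = 1; a rater redrawing contours at random over the full A-scan depth
#' stays below about 0.2; reliable manual raters reach at least 0.70, which
#' for Gaussian repeat noise corresponds to a per-point standard deviation
#' of roughly 25 um at l = 20 um.
#'
#' Every (scan, timepoint) image in the set counts towards S and must carry
#' exactly three repeats.
#'
#' @param x a \code{\link{SegmentationSet}} with triple repeats.
#' @param toleranceUm tolerance l in micrometres (default 20, i.e. 5 axial
#'   pixels on the study raster).
#' @return An \code{ircResult} list: \code{rater}, \code{toleranceUm},
#'   \code{counts}, \code{total} (= 3nS), \code{irc}.
#' @export
intraRaterCoefficient <- function(x, toleranceUm = 20) {
    stopifnot(toleranceUm > 0)
    cd <- colData(x)
    key <- paste(cd$scan_id, cd$timepoint, sep = "\r")
    reps <- table(key)
    if (any(reps != 3L)) {
        off <- strsplit(names(reps)[which(reps != 3L)[1L]], "\r")[[1L]]
        stop(sprintf("scan '%s' (timepoint %s) has %d repeats; the IRC needs exactly 3",
                     off[1L], off[2L], reps[which(reps != 3L)[1L]]))
    }
    d <- depths(x)
    counts <- 0
    for (k in unique(key)) {
        i <- which(key == k)
        dev <- d[, i, drop = FALSE] - rowMeans(d[, i, drop = FALSE])
        counts <- counts + sum(abs(dev) <= toleranceUm)
    }
    total <- 3L * nrow(d) * length(reps)
    structure(list(rater = rater(x), toleranceUm = toleranceUm,
                   counts = counts, total = total, irc = counts / total),
              class = "ircResult")
}

#' @export
print.ircResult <- function(x, ...) {
    cat(sprintf("IRC(rater '%s', l = %g um) = %.4f  [%d / %d deviations in tolerance]\n",
                x$rater, x$toleranceUm, x$irc, x$counts, x$total))
    invisible(x)
}

#' Construct a similarity matrix
#'
#' @param values symmetric numeric matrix in [0, 1] with unit diagonal and
#'   rater ids as dimnames.
#' @param metric metric name.
#' @param nShared integer matrix of shared-scan counts (optional).
#' @return A \code{\link{SimilarityMatrix}}.
#' @export
similarityMatrix <- function(values, metric, nShared = NULL) {
    if (is.null(nShared)) {
        nShared <- matrix(NA_integer_, nrow(values), ncol(values),
                          dimnames = dimnames(values))
    }
    new("SimilarityMatrix", values = values, metric = metric,
        nShared = nShared)
}

#' @rdname SimilarityMatrix-class
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("metricName", "SimilarityMatrix", function(x) x@metric)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("raterIds", "SimilarityMatrix", function(x) rownames(x@values))

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix (%s) over %d raters\n", object@metric,
                nrow(object@values)))
    print(round(object@values, 4))
})

.sharedImages <- function(a, b) {
    ka <- unique(paste(scanIds(a), timepoints(a), sep = "\r"))
    kb <- unique(paste(scanIds(b), timepoints(b), sep = "\r"))
    intersect(ka, kb)
}

.meanContours <- function(x, keys) {
    out <- lapply(keys, function(k) {
        p <- strsplit(k, "\r")[[1L]]
        meanContour(x, p[1L], p[2L])
    })
    names(out) <- keys
    out
}

#' Pairwise similarities between raters
#'
#' Builds the symmetric rater-by-rater similarity matrix that feeds the
#' Williams' index, over the scans each pair shares.  For the contour
#' metrics (\code{"DC"}, \code{"JC"}, \code{"BLD"}) the input is a list of
#' \code{\link{SegmentationSet}}s; repeats are aggregated to their mean
#' contour and every shared (scan, timepoint) image contributes.  For
#' \code{"diffZ"} the input is a list of
#' \code{\link{DisplacementFieldSet}}s (the automated method can
#' participate here).  Dissimilarities (BLD aggregate, diffZ) are converted
#' to similarities as \eqn{s = 1 - d}; BLD, being asymmetric in
#' reference/test, is symmetrised by averaging the two directions.
#'
#' @param raters named list of per-rater sets (all sharing one geometry).
#' @param metric one of \code{"DC"}, \code{"JC"}, \code{"BLD"},
#'   \code{"diffZ"}.
#' @return A \code{\link{SimilarityMatrix}}.
#' @export
pairwiseSimilarities <- function(raters,
                                 metric = c("diffZ", "BLD", "DC", "JC")) {
    metric <- match.arg(metric)
    r <- length(raters)
    if (r < 2L) stop("need at least two raters")
    ids <- names(raters)
    if (is.null(ids) || any(ids == ""))
        stop("raters must be a named list")
    g <- geometry(raters[[1L]])
    v <- diag(1, r); dimnames(v) <- list(ids, ids)
    ns <- matrix(0L, r, r, dimnames = dimnames(v))
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
        a <- raters[[i]]; b <- raters[[j]]
        if (metric == "diffZ") {
            shared <- intersect(scanIds(a), scanIds(b))
            if (!length(shared))
                stop(sprintf("raters '%s' and '%s' share no scans",
                             ids[i], ids[j]))
            sub <- function(x) {
                k <- match(shared, scanIds(x))
                displacementFieldSet(dzValues(x)[, k, drop = FALSE],
                                     shared, rater(x), geometry(x))
            }
            s <- 1 - diffZ(sub(a), sub(b))
        } else {
            shared <- .sharedImages(a, b)
            if (!length(shared))
                stop(sprintf("raters '%s' and '%s' share no scans",
                             ids[i], ids[j]))
            ca <- .meanContours(a, shared)
            cb <- .meanContours(b, shared)
            s <- switch(metric,
                BLD = 1 - (bldAggregate(ca, cb, g)$aggregate +
                           bldAggregate(cb, ca, g)$aggregate) / 2,
                DC = mean(vapply(shared, function(k)
                        diceCoefficient(contourMask(ca[[k]], g),
                                        contourMask(cb[[k]], g)),
                        numeric(1))),
                JC = mean(vapply(shared, function(k)
                        jaccardCoefficient(contourMask(ca[[k]], g),
                                           contourMask(cb[[k]], g)),
                        numeric(1))))
        }
        v[i, j] <- v[j, i] <- min(max(s, 0), 1)
        ns[i, j] <- ns[j, i] <- length(shared)
    }
    similarityMatrix(v, metric, ns)
}

.wiFromMatrix <- function(v, j) {
    r <- nrow(v)
    others <- setdiff(seq_len(r), j)
    num <- (r - 2) * sum(v[j, others])
    pairs <- utils::combn(others, 2L)
    den <- 2 * sum(v[cbind(pairs[1L, ], pairs[2L, ])])
    if (den <= .Machine$double.eps)
        stop("Williams' index undefined: inter-group similarities sum to zero")
    num / den
}

#' Williams' agreement index
#'
#' Ratio of rater j's mean similarity with the rest of the group to the
#' mean pairwise similarity within the rest of the group:
#' \deqn{WI_j = \frac{(r-2)\sum_{j' \ne j} s(j, j')}
#'                   {2 \sum_{j' \ne j} \sum_{j'' < j', j'' \ne j} s(j', j'')}.}
#' A value of at least 1 means rater j agrees with the group at least as
#' often as its members agree with each other.
#'
#' @param sim a \code{\link{SimilarityMatrix}} over \eqn{r \ge 3} raters.
#' @param raterId the rater (or \code{"method"}) to score.
#' @return A \code{wiResult} list: \code{rater}, \code{wi}, \code{metric},
#'   \code{atLeastGroup} (\code{wi >= 1}).
#' @examples
#' v <- matrix(c(1, .9, .8, .9, 1, .7, .8, .7, 1), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' williamsIndex(similarityMatrix(v, "diffZ"), "a")$wi  # (0.9+0.8)/(2*0.7)
#' @export
williamsIndex <- function(sim, raterId) {
    v <- similarityValues(sim)
    if (nrow(v) < 3L)
        stop("Williams' index needs at least 3 raters")
    j <- match(raterId, rownames(v))
    if (is.na(j)) stop(sprintf("rater '%s' is not in the matrix", raterId))
    wi <- .wiFromMatrix(v, j)
    structure(list(rater = raterId, wi = wi, metric = metricName(sim),
                   atLeastGroup = wi >= 1),
              class = "wiResult")
}

#' @export
print.wiResult <- function(x, ...) {
    cat(sprintf("WI(rater '%s', metric %s) = %.4f (%s group agreement)\n",
                x$rater, x$metric, x$wi,
                if (x$atLeastGroup) "at least" else "below"))
    if (!is.null(x$leaveOneOut)) {
        cat("  leave-one-out:\n")
        print(x$leaveOneOut, row.names = FALSE)
    }
    invisible(x)
}

#' Leave-one-out Williams' index
#'
#' Recomputes the Williams' index of a target rater after omitting each of
#' the other raters in turn, to check that no single rater dominates the
#' agreement.  Needs at least 4 raters so every reduced group keeps 3.
#'
#' @inheritParams williamsIndex
#' @param raterId the rater whose WI is recomputed.
#' @return A \code{wiResult} with a \code{leaveOneOut} data.frame
#'   (omitted rater, recomputed WI) plus \code{looMin}/\code{looMax}.
#' @export
williamsIndexLOO <- function(sim, raterId) {
    v <- similarityValues(sim)
    if (nrow(v) < 4L)
        stop("leave-one-out WI needs at least 4 raters")
    j <- match(raterId, rownames(v))
    if (is.na(j)) stop(sprintf("rater '%s' is not in the matrix", raterId))
    others <- setdiff(rownames(v), raterId)
    wis <- vapply(others, function(o) {
        keep <- setdiff(rownames(v), o)
        .wiFromMatrix(v[keep, keep], match(raterId, keep))
    }, numeric(1))
    out <- williamsIndex(sim, raterId)
    out$leaveOneOut <- data.frame(omitted = others, wi = unname(wis))
    out$looMin <- min(wis)
    out$looMax <- max(wis)
    out
}
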