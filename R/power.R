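#' Leave-one-out artificial ground truth
#'
#' Averages, per scan and column, the displacement fields of all raters
#' except the omitted one: \eqn{\bar G_j = \frac{1}{r-1}\sum_{j' \ne j}
#' \Delta E_{j'}} (cells covered by only a subset of raters average over
#' the raters that have them).  The result is the n x S matrix used as
#' reference in the power analysis.
#'
#' @param fields named list of per-rater
#'   \code{\link{DisplacementFieldSet}}s.
#' @param omit rater id to leave out (must be in \code{fields}).
#' @param scanId scans to cover; defaults to every scan present in any
#'   remaining rater.  A scan with no contributing rater is an error.
#' @return A \code{looGroundTruth} list: \code{omitted}, \code{gbar}
#'   (n x S matrix, scan ids as colnames), \code{nContributors}.
#' @export
looGroundTruth <- function(fields, omit, scanId = NULL) {
    if (!omit %in% names(fields))
        stop(sprintf("rater '%s' is not among the fields", omit))
    rest <- fields[setdiff(names(fields), omit)]
    if (!length(rest))
        stop("need at least 2 raters to leave one out")
    if (is.null(scanId))
        scanId <- sort(unique(unlist(lapply(rest, scanIds))))
    n <- nColumns(geometry(rest[[1L]]))
    gbar <- matrix(0, n, length(scanId), dimnames = list(NULL, scanId))
    nc <- integer(length(scanId)); names(nc) <- scanId
    for (f in rest) {
        k <- match(scanIds(f), scanId)
        keep <- !is.na(k)
        gbar[, k[keep]] <- gbar[, k[keep]] + dzValues(f)[, keep, drop = FALSE]
        nc[k[keep]] <- nc[k[keep]] + 1L
    }
    if (any(nc == 0L))
        stop("no contributing rater for scan(s): ",
             paste(scanId[nc == 0L], collapse = ", "))
    gbar <- sweep(gbar, 2L, nc, "/")
    structure(list(omitted = omit, gbar = gbar, nContributors = nc),
              class = "looGroundTruth")
}

#' @export
print.looGroundTruth <- function(x, ...) {
    cat(sprintf("Leave-one-out ground truth without '%s': %d x %d matrix (%d-%d contributors/scan)\n",
                x$omitted, nrow(x$gbar), ncol(x$gbar),
                min(x$nContributors), max(x$nContributors)))
    invisible(x)
}

#' Matched method/expert error samples against a LOO ground truth
#'
#' Builds \eqn{X_j = X - \bar G_j} (method error) and \eqn{Y_j = \Delta E_j
#' - \bar G_j} (omitted expert's error), matched element by element over
#' the (scan, column) cells the omitted expert covered.  Note that in the
#' signed difference the ground truth cancels: \eqn{X_j - Y_j = X -
#' \Delta E_j} identically.
#'
#' @param method the method's \code{\link{DisplacementFieldSet}}.
#' @param expert the omitted expert's \code{\link{DisplacementFieldSet}}.
#' @param gbar a \code{looGroundTruth} (or n x S matrix with scan-id
#'   colnames).
#' @return An \code{errorPair} list: \code{x}, \code{y} (flattened matched
#'   vectors), \code{scanIds}, \code{omitted}.
#' @export
errorPairs <- function(method, expert, gbar) {
    omit <- NULL
    if (inherits(gbar, "looGroundTruth")) {
        omit <- gbar$omitted
        gbar <- gbar$gbar
    }
    scans <- scanIds(expert)
    if (!all(scans %in% colnames(gbar)))
        stop("ground truth does not cover scan(s): ",
             paste(setdiff(scans, colnames(gbar)), collapse = ", "))
    if (!all(scans %in% scanIds(method)))
        stop("method does not cover scan(s): ",
             paste(setdiff(scans, scanIds(method)), collapse = ", "))
    g <- gbar[, scans, drop = FALSE]
    mx <- dzValues(method)[, match(scans, scanIds(method)), drop = FALSE]
    ex <- dzValues(expert)
    structure(list(x = as.vector(mx - g), y = as.vector(ex - g),
                   scanIds = scans,
                   omitted = if (is.null(omit)) rater(expert) else omit),
              class = "errorPair")
}

#' Paired t-test on error differences
#'
#' Tests whether the per-cell differences between two matched error
#' samples have zero mean: \eqn{t = \bar D / (s_D / \sqrt{n})} with
#' \eqn{D = |X_j| - |Y_j|} (mode \code{"absolute"}, the default, comparing
#' error magnitudes) or \eqn{D = X_j - Y_j} (mode \code{"signed"});
#' two-sided p from the Student t distribution with n - 1 degrees of
#' freedom, rejected when p < alpha.
#'
#' @param pair an \code{errorPair} (or \code{x}, \code{y} given directly).
#' @param x,y matched numeric samples (alternative to \code{pair}).
#' @param alpha significance level (default 0.01).
#' @param mode \code{"absolute"} or \code{"signed"}.
#' @return A \code{tTestEffect} list: \code{t}, \code{df}, \code{p},
#'   \code{alpha}, \code{reject}, \code{meanDiff}, \code{n}, \code{mode}.
#' @export
pairedTTest <- function(pair = NULL, x = NULL, y = NULL, alpha = 0.01,
                        mode = c("absolute", "signed")) {
    mode <- match.arg(mode)
    stopifnot(alpha > 0, alpha < 1)
    if (!is.null(pair)) {
        x <- pair$x; y <- pair$y
    }
    if (length(x) != length(y))
        stop("samples must be matched element by element")
    if (length(x) < 2L) stop("need at least 2 matched pairs")
    D <- if (mode == "absolute") abs(x) - abs(y) else x - y
    sdD <- stats::sd(D)
    n <- length(D)
    if (sdD == 0) {
        if (mean(D) != 0)
            stop("degenerate case: differences have zero variance but nonzero mean")
        tstat <- 0; p <- 1
    } else {
        tstat <- mean(D) / (sdD / sqrt(n))
        p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
    }
    structure(list(t = tstat, df = n - 1L, p = p, alpha = alpha,
                   reject = p < alpha, meanDiff = mean(D), n = n,
                   mode = mode),
              class = "tTestEffect")
}

#' @export
print.tTestEffect <- function(x, ...) {
    cat(sprintf("paired t-test (%s errors): t = %.4f, df = %d, p = %.3g -> %s H0 at alpha = %g\n",
                x$mode, x$t, x$df, x$p,
                if (x$reject) "reject" else "retain", x$alpha))
    invisible(x)
}

#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = \frac{\mu(X) - \mu(Y)}{S}, \qquad
#'   S = \sqrt{\frac{(|X|-1)\sigma^2(X) + (|Y|-1)\sigma^2(Y)}{|X|+|Y|-2}}.}
#' Magnitudes around 0.2 are conventionally "small", around 0.5 "medium".
#'
#' @param x,y numeric samples (sizes may differ, each of length >= 2).
#' @return List with \code{d}, \code{pooledSd}, \code{magnitude} label.
#' @export
cohensD <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("both samples need at least 2 values")
    s2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
          (length(x) + length(y) - 2)
    if (s2 <= 0)
        stop("pooled standard deviation is zero")
    d <- (mean(x) - mean(y)) / sqrt(s2)
    mag <- if (abs(d) < 0.35) "small" else if (abs(d) < 0.65) "medium"
           else "large"
    list(d = d, pooledSd = sqrt(s2), magnitude = mag)
}

#' Cohort-level power and displacement summary
#'
#' Reproduces the reporting layer of the validation framework on any
#' cohort: displacement means and SDs per time interval and per C-B-A-B-C
#' region (experts pooled vs method), the per-expert leave-one-out paired
#' t-test with effect size, and cross-interval effect sizes.  The reported
#' \code{effectSize} of each leave-one-out test is Cohen's d of the
#' expert's absolute errors versus the method's (positive = the method's
#' error is smaller).
#'
#' @param expertFields named list of expert
#'   \code{\link{DisplacementFieldSet}}s.
#' @param methodFields the method's \code{\link{DisplacementFieldSet}}
#'   covering all scans.
#' @param scanInfo data.frame with \code{scan_id}, \code{interval_months},
#'   \code{eye}; optional, enables the interval/region tables.
#' @param alpha significance level for the t-tests.
#' @param mode t-test mode, see \code{\link{pairedTTest}}.
#' @return A \code{powerSummary} list of data.frames:
#'   \code{intervalTable}, \code{regionTable}, \code{looTests},
#'   \code{crossIntervalEffects} (the last three NULL when the needed
#'   labels are absent).
#' @export
powerSummary <- function(expertFields, methodFields, scanInfo = NULL,
                         alpha = 0.01, mode = c("absolute", "signed")) {
    mode <- match.arg(mode)
    g <- geometry(methodFields)

    loo <- lapply(names(expertFields), function(j) {
        gb <- looGroundTruth(expertFields, omit = j)
        pr <- errorPairs(methodFields, expertFields[[j]], gb)
        tt <- pairedTTest(pr, alpha = alpha, mode = mode)
        es <- cohensD(abs(pr$y), abs(pr$x))
        data.frame(omitted_expert = j, n = tt$n, t = tt$t, df = tt$df,
                   p = tt$p, reject = tt$reject, effect_size = es$d,
                   pooled_sd = es$pooledSd)
    })
    looTests <- do.call(rbind, loo)

    intervalTable <- regionTable <- crossIntervalEffects <- NULL
    if (!is.null(scanInfo) && "interval_months" %in% colnames(scanInfo)) {
        cells <- function(f, scans) {
            k <- match(intersect(scans, scanIds(f)), scanIds(f))
            as.vector(dzValues(f)[, k, drop = FALSE])
        }
        pooled <- function(scans)
            unlist(lapply(expertFields, cells, scans = scans))
        ivs <- sort(unique(scanInfo$interval_months))
        intervalTable <- do.call(rbind, lapply(ivs, function(iv) {
            scans <- scanInfo$scan_id[scanInfo$interval_months == iv]
            pe <- pooled(scans); me <- cells(methodFields, scans)
            data.frame(interval_months = iv,
                       experts_mean = mean(pe), experts_sd = stats::sd(pe),
                       method_mean = mean(me), method_sd = stats::sd(me),
                       n_scans = length(scans))
        }))
        if (length(ivs) >= 2L) {
            lo <- scanInfo$scan_id[scanInfo$interval_months == min(ivs)]
            hi <- scanInfo$scan_id[scanInfo$interval_months == max(ivs)]
            crossIntervalEffects <- data.frame(
                group = c("experts", "method"),
                interval_a = min(ivs), interval_b = max(ivs),
                cohens_d = c(cohensD(pooled(hi), pooled(lo))$d,
                             cohensD(cells(methodFields, hi),
                                     cells(methodFields, lo))$d))
        }
        if ("eye" %in% colnames(scanInfo)) {
            part <- regionPartition(g)
            regCells <- function(f) {
                ids <- scanIds(f)
                info <- scanInfo[match(ids, scanInfo$scan_id), ]
                res <- vector("list", 5L)
                for (j in seq_along(ids)) {
                    pj <- part; pj@eye <- info$eye[j]
                    v <- dzValues(f)[, j]
                    ord <- if (pj@eye == "left") 5L:1L else 1L:5L
                    for (k in seq_len(5L)) {
                        blk <- ord[k]
                        res[[k]] <- c(res[[k]],
                                      v[part@starts[blk]:part@ends[blk]])
                    }
                }
                res
            }
            pooledReg <- regCells(expertFields[[1L]])
            for (f in expertFields[-1L]) {
                r2 <- regCells(f)
                pooledReg <- lapply(seq_len(5L),
                                    function(k) c(pooledReg[[k]], r2[[k]]))
            }
            methReg <- regCells(methodFields)
            regionTable <- do.call(rbind, lapply(seq_len(5L), function(k)
                data.frame(region = part@labels[k], position = k,
                           experts_mean = mean(pooledReg[[k]]),
                           experts_sd = stats::sd(pooledReg[[k]]),
                           method_mean = mean(methReg[[k]]),
                           method_sd = stats::sd(methReg[[k]]))))
        }
    }
    structure(list(looTests = looTests, intervalTable = intervalTable,
                   regionTable = regionTable,
                   crossIntervalEffects = crossIntervalEffects,
                   alpha = alpha, mode = mode),
              class = "powerSummary")
}

#' @export
print.powerSummary <- function(x, ...) {
    cat("Leave-one-out power analysis (mode:", x$mode, ", alpha:",
        x$alpha, ")\n")
    print(x$looTests, row.names = FALSE)
    if (!is.null(x$intervalTable)) {
        cat("\nDisplacement by time interval (um):\n")
        print(x$intervalTable, row.names = FALSE)
    }
    if (!is.null(x$regionTable)) {
        cat("\nDisplacement by C-B-A-B-C region (um):\n")
        print(x$regionTable, row.names = FALSE)
    }
    if (!is.null(x$crossIntervalEffects)) {
        cat("\nCross-interval effect sizes:\n")
        print(x$crossIntervalEffects, row.names = FALSE)
    }
    invisible(x)
}
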