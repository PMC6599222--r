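#' Simulate true CSI contours for one volume-stack pair
#'
#' Baseline session (t1) truth: per B-scan a smooth low-order B-spline
#' relief around a subject-specific baseline depth, clipped to the raster.
#' Reproducible: the stream is derived from the config master seed and the
#' pair id.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param pairId pair identifier (e.g. \code{"P001"}).
#' @return Numeric matrix, \code{nColumns} x number of scan positions,
#'   colnames = scan ids.
#' @export
generateTruthContours <- function(config, pairId) {
    g <- config$geometry
    n <- nColumns(g)
    withSeed(subSeed(config$seed, "truth", pairId), {
        base <- stats::runif(1L, config$truthBaselineRangeUm[1L],
                             config$truthBaselineRangeUm[2L])
        m <- vapply(config$scanPositions, function(pos)
            pmin(pmax(base + smoothNoise(n, config$nKnots,
                                         config$truthAmplitudeSdUm),
                      0), maxDepthUm(g)),
            numeric(n))
    })
    colnames(m) <- .scanId(pairId, config$scanPositions)
    m
}

# Regional growth-multiplier profile as a per-column step function, image
# order; mirrored for left eyes so that regions keep their temporal/nasal
# meaning.  Normalised so the column mean is exactly 1 when block sizes are
# equal.
.regionalProfile <- function(config, eye) {
    n <- nColumns(config$geometry)
    part <- regionPartition(n)
    w <- config$regionalMultipliers
    if (eye == "left") w <- rev(w)
    out <- numeric(n)
    for (k in seq_len(5L))
        out[part@starts[k]:part@ends[k]] <- w[k]
    out
}

#' Simulate a true growth displacement field for one pair
#'
#' Per column: interval growth mean scaled by the C-B-A-B-C regional
#' profile, plus a between-subject effect shared across the pair's scans,
#' plus smooth within-scan spatial variation.  The two random parts split
#' the configured interval SD (variance fraction \code{subjectSdFrac} to
#' the subject effect).  The t2 truth contours are the t1 truth plus this
#' field.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param pairId pair identifier.
#' @param intervalMonths follow-up interval, one of
#'   \code{config$intervalsMonths}.
#' @param eye \code{"right"} or \code{"left"}.
#' @return Numeric matrix, \code{nColumns} x scans, colnames = scan ids.
#' @export
simulateGrowthField <- function(config, pairId, intervalMonths,
                                eye = "right") {
    iv <- match(intervalMonths, config$intervalsMonths)
    if (is.na(iv))
        stop(sprintf("unknown interval %s months (configured: %s)",
                     intervalMonths,
                     paste(config$intervalsMonths, collapse = ", ")))
    g <- config$geometry
    n <- nColumns(g)
    mu <- config$intervalMeansUm[iv] * .regionalProfile(config, eye)
    sdTot <- config$intervalSdsUm[iv]
    sdSubj <- sqrt(config$subjectSdFrac) * sdTot
    sdSpat <- sqrt(1 - config$subjectSdFrac) * sdTot
    withSeed(subSeed(config$seed, "growth", pairId), {
        subj <- stats::rnorm(1L, 0, sdSubj)
        m <- vapply(config$scanPositions, function(pos)
            mu + subj + smoothNoise(n, config$nKnots, sdSpat),
            numeric(n))
    })
    colnames(m) <- .scanId(pairId, config$scanPositions)
    m
}

#' Simulate one expert's noisy repeat segmentations
#'
#' Each repeat tracing is the true contour plus a constant expert bias, a
#' smooth spatially correlated deviation (fresh per repeat) and iid
#' per-column jitter.  The pointwise marginal repeat SD is exactly
#' \code{sqrt(expertSmoothSdUm^2 + expertJitterSdUm^2)}, so closed-form
#' repeatability predictions apply.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param expertId expert identifier (e.g. \code{"E1"}; indexes the bias
#'   vector).
#' @param truthT1,truthT2 truth depth matrices (columns = scan ids) for
#'   the two sessions; \code{truthT2} may be NULL for single-session sets.
#' @return A \code{\link{SegmentationSet}} with \code{config$repeats}
#'   repeats per (scan, session).
#' @export
simulateExpert <- function(config, expertId, truthT1, truthT2 = NULL) {
    g <- config$geometry
    n <- nColumns(g)
    bias <- config$expertBiasUm[match(expertId, .expertIds(config))]
    if (is.na(bias)) bias <- 0
    sessions <- list(t1 = truthT1)
    if (!is.null(truthT2)) sessions$t2 <- truthT2
    nLines <- sum(vapply(sessions, ncol, integer(1))) * config$repeats
    depthsUm <- matrix(0, n, nLines)
    scanId <- character(nLines); tp <- character(nLines)
    rep_ <- integer(nLines)
    k <- 0L
    withSeed(subSeed(config$seed, "expert", expertId), {
        for (tpName in names(sessions)) {
            tr <- sessions[[tpName]]
            for (s in colnames(tr)) for (r in seq_len(config$repeats)) {
                k <- k + 1L
                depthsUm[, k] <- pmin(pmax(
                    tr[, s] + bias +
                        smoothNoise(n, config$nKnots, config$expertSmoothSdUm) +
                        stats::rnorm(n, 0, config$expertJitterSdUm),
                    0), maxDepthUm(g))
                scanId[k] <- s; tp[k] <- tpName; rep_[k] <- r
            }
        }
    })
    segmentationSet(depthsUm, scanId, tp, rep_, expertId, g)
}

#' Simulate a rater who redraws contours at random
#'
#' Each repeat is an independent smooth B-spline curve whose control
#' depths are uniform over the full usable A-scan range (1.9 mm by
#' default), emulating random synthetic deformations.  Such a rater has no
#' memory across repeats and realises the "random rater" repeatability
#' floor (IRC well below 0.2 at l = 20 um).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param nScans number of B-scans to trace (each traced thrice at one
#'   session).
#' @param raterId rater label.
#' @return A \code{\link{SegmentationSet}} with triple repeats.
#' @export
simulateRandomRater <- function(config, nScans = 200L,
                                raterId = "random") {
    g <- config$geometry
    n <- nColumns(g)
    B <- splineBasis(n, max(config$nKnots, 15L))
    lo <- config$randomRaterRangeUm[1L]
    hi <- config$randomRaterRangeUm[2L]
    nLines <- nScans * 3L
    withSeed(subSeed(config$seed, "random-rater", raterId), {
        depthsUm <- vapply(seq_len(nLines), function(k)
            as.vector(B %*% stats::runif(ncol(B), lo, hi)), numeric(n))
    })
    segmentationSet(depthsUm,
                    scanId = rep(sprintf("R%03d", seq_len(nScans)), each = 3L),
                    timepoint = "t1",
                    repeatIndex = rep(1:3, nScans),
                    rater = raterId, geometry = g)
}

#' Simulate the automated method's displacement output
#'
#' Method output = true growth field plus centred iid Gaussian error with
#' SD \code{methodSdUm}.  The output is a deterministic function of the
#' config seed: repeated invocation is bit-identical, i.e. the method has
#' perfect repeatability (IRC = 1 on duplicated outputs), unlike the human
#' raters.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param truthFields numeric matrix of true displacement fields
#'   (\code{nColumns} x scans, colnames = scan ids).
#' @param scanInfo optional per-scan label data.frame passed to
#'   \code{\link{displacementFieldSet}}.
#' @return A \code{\link{DisplacementFieldSet}} labelled \code{"method"}.
#' @export
simulateMethod <- function(config, truthFields, scanInfo = NULL) {
    g <- config$geometry
    withSeed(subSeed(config$seed, "method"), {
        err <- matrix(stats::rnorm(length(truthFields), 0, config$methodSdUm),
                      nrow(truthFields))
    })
    displacementFieldSet(truthFields + err, colnames(truthFields),
                         "method", g, scanInfo = scanInfo)
}

#' Simulate a complete synthetic cohort in memory
#'
#' Runs the whole generator: allocation design, truth contours and growth
#' fields for every pair, noisy triple-repeat expert segmentations
#' restricted to each expert's assigned pairs, the experts' derived
#' displacement fields, and the simulated method.  Everything is a pure
#' function of the config (master seed included).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A \code{syntheticCohort} list: \code{config}, \code{design},
#'   \code{truthT1}, \code{truthFields} (matrices over all scans),
#'   \code{experts} (named list of \code{\link{SegmentationSet}}),
#'   \code{expertFields} (named list of
#'   \code{\link{DisplacementFieldSet}}), \code{method}, \code{scanInfo}.
#' @export
simulateCohort <- function(config) {
    design <- buildDesign(config)
    pairs <- .pairIds(config)
    truthT1 <- do.call(cbind, lapply(pairs, function(p)
        generateTruthContours(config, p)))
    truthFields <- do.call(cbind, lapply(pairs, function(p)
        simulateGrowthField(config, p, design$pairInterval[[p]],
                            design$pairEye[[p]])))
    truthT2 <- truthT1 + truthFields
    scanInfo <- design$scanInfo
    pairOf <- function(scans) scanInfo$pair_id[match(scans, scanInfo$scan_id)]
    experts <- lapply(.expertIds(config), function(ex) {
        mine <- names(design$assignment)[vapply(design$assignment,
                                                function(a) ex %in% a,
                                                logical(1))]
        keep <- colnames(truthT1)[pairOf(colnames(truthT1)) %in% mine]
        simulateExpert(config, ex,
                       truthT1[, keep, drop = FALSE],
                       truthT2[, keep, drop = FALSE])
    })
    names(experts) <- .expertIds(config)
    expertFields <- lapply(experts, function(ss) {
        f <- displacementFromTimepoints(ss)
        displacementFieldSet(dzValues(f), scanIds(f), rater(ss),
                             geometry(ss), scanInfo = scanInfo)
    })
    method <- simulateMethod(config, truthFields, scanInfo = scanInfo)
    structure(list(config = config, design = design, truthT1 = truthT1,
                   truthFields = truthFields, experts = experts,
                   expertFields = expertFields, method = method,
                   scanInfo = scanInfo),
              class = "syntheticCohort")
}

#' @export
print.syntheticCohort <- function(x, ...) {
    cat(sprintf("syntheticCohort: %d pairs x %d scan positions, %d experts + method (seed %d)\n",
                x$config$nPairs, length(x$config$scanPositions),
                length(x$experts), x$config$seed))
    invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Serialises a cohort to the package's plain-text interchange formats:
#' \code{segmentations.csv} (all experts, long form),
#' \code{method_displacements.csv}, \code{truth_fields.csv} (for
#' oracle-based checks), \code{scan_info.csv}, \code{design.json} and a
#' \code{manifest.json} recording the seed and generator parameters.
#' Regeneration with the same config is byte-identical.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param dir output directory (created if missing).
#' @return The cohort (from \code{\link{simulateCohort}}), invisibly.
#' @export
generateCohort <- function(config, dir) {
    cohort <- simulateCohort(config)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeSegmentations(cohort$experts, file.path(dir, "segmentations.csv"))
    writeDisplacements(cohort$method,
                       file.path(dir, "method_displacements.csv"))
    truth <- displacementFieldSet(cohort$truthFields,
                                  colnames(cohort$truthFields), "truth",
                                  config$geometry,
                                  scanInfo = cohort$scanInfo)
    writeDisplacements(truth, file.path(dir, "truth_fields.csv"))
    utils::write.csv(cohort$scanInfo, file.path(dir, "scan_info.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(cohort$design$assignment,
                         file.path(dir, "design.json"))
    manifest <- config
    manifest$geometry <- list(nColumns = nColumns(config$geometry),
                              mDepth = mDepth(config$geometry),
                              spacings = as.list(pixelSpacings(config$geometry)))
    class(manifest) <- NULL
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(cohort)
}

#' Sweep repeat-noise SD against the intra-rater coefficient
#'
#' For each per-point Gaussian repeat SD, simulates triple repeats (truth
#' plus iid noise) over \code{nScans} B-scans and computes the IRC at the
#' given tolerance.  Used to locate the repeat noise at which a rater
#' crosses a target repeatability; for Gaussian noise the closed form is
#' \eqn{IRC = 2\Phi(l / (\sigma\sqrt{2/3})) - 1}.
#'
#' @param config a \code{\link{cohortConfig}} (geometry and seed).
#' @param sdsUm numeric vector of repeat SDs to sweep, micrometres.
#' @param toleranceUm IRC tolerance l.
#' @param nScans B-scans per sweep point.
#' @return data.frame with columns \code{sd_um}, \code{irc}.
#' @export
ircNoiseSweep <- function(config, sdsUm = 15:35, toleranceUm = 20,
                          nScans = 120L) {
    g <- config$geometry
    n <- nColumns(g)
    irc <- vapply(sdsUm, function(sd) {
        withSeed(subSeed(config$seed, "irc-sweep", sd), {
            truth <- matrix(stats::runif(n * nScans, 800, 1600), n)
            counts <- 0
            for (s in seq_len(nScans)) {
                reps <- truth[, s] + matrix(stats::rnorm(3L * n, 0, sd), n)
                dev <- reps - rowMeans(reps)
                counts <- counts + sum(abs(dev) <= toleranceUm)
            }
            counts / (3 * n * nScans)
        })
    }, numeric(1))
    data.frame(sd_um = sdsUm, irc = irc)
}

#' Locate where an IRC sweep crosses a target value
#'
#' Linear interpolation between the neighbouring grid points of a
#' monotonically decreasing sweep.
#'
#' @param sweep data.frame from \code{\link{ircNoiseSweep}}.
#' @param target IRC level to cross (default 0.70, the reliability
#'   threshold for manual raters).
#' @return The interpolated SD in micrometres.
#' @export
ircCrossing <- function(sweep, target = 0.70) {
    o <- order(sweep$sd_um)
    sd <- sweep$sd_um[o]; irc <- sweep$irc[o]
    above <- which(irc >= target)
    below <- which(irc < target)
    if (!length(above) || !length(below))
        stop(sprintf("IRC sweep does not cross %g within the grid", target))
    i <- max(above[above < min(below)])
    j <- i + 1L
    sd[i] + (irc[i] - target) / (irc[i] - irc[j]) * (sd[j] - sd[i])
}
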