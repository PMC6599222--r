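#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic study: the raster geometry, the
#' expert-to-scan allocation design, the longitudinal growth model and the
#' rater/method noise model.  Defaults reproduce the study conditions: 90
#' volume-stack pairs split evenly over follow-up intervals of 3, 8 and 14
#' months, 8 B-scan positions per stack, 6 experts with 50 pairs each and
#' at least 3 experts per pair, triple repeats, interval growth means/SDs
#' of 1.76/26.72, 5.67/32.48 and 7.62/39.15 um, and a C-B-A-B-C regional
#' profile (perifoveal > parafoveal > foveal, normalised to overall mean 1)
#' derived from the regional displacement pattern 9.95/5.13/1.81/4.17/6.27
#' um.  Expert repeat noise is split into a smooth spatially correlated
#' part and iid jitter whose pointwise marginal SDs combine to 25 um; the
#' method error SD defaults to 10 um, below the experts' effective
#' displacement noise of 25 sqrt(2/3) = 20.4 um.
#'
#' @param geometry a \code{\link{ScanGeometry}}.
#' @param nPairs number of volume-stack pairs (subjects' eyes).
#' @param nExperts number of simulated experts.
#' @param pairsPerExpert pairs assigned to each expert.
#' @param minExpertsPerPair minimum experts per pair.
#' @param scanPositions B-scan positions segmented per stack.
#' @param repeats repeats per traced line.
#' @param intervalsMonths follow-up intervals.
#' @param intervalMeansUm,intervalSdsUm true growth mean / marginal SD per
#'   interval, micrometres.
#' @param regionalMeansUm regional displacement pattern (temporal to
#'   nasal, C-B-A-B-C) the multiplier profile is derived from.
#' @param subjectSdFrac fraction of growth variance attributed to the
#'   between-subject effect (the rest is smooth within-scan variation).
#' @param expertSmoothSdUm,expertJitterSdUm pointwise marginal SD of the
#'   smooth and iid components of expert repeat noise, micrometres.
#' @param expertBiasUm per-expert constant depth bias, recycled.
#' @param methodSdUm SD of the method's centred Gaussian displacement
#'   error, micrometres.
#' @param truthBaselineRangeUm uniform range of the CSI baseline depth.
#' @param truthAmplitudeSdUm pointwise SD of the smooth truth-contour
#'   relief.
#' @param nKnots B-spline basis size for smooth curves.
#' @param randomRaterRangeUm depth range of the random rater's uniform
#'   control coefficients (the usable 1.9 mm A-scan depth).
#' @param seed master seed; all substreams derive from it.
#' @return A validated \code{cohortConfig} list.
#' @export
cohortConfig <- function(geometry = scanGeometry(),
                         nPairs = 90L, nExperts = 6L,
                         pairsPerExpert = 50L, minExpertsPerPair = 3L,
                         scanPositions = c(1L, 3L, 6L, 11L, 13L, 16L, 21L, 23L),
                         repeats = 3L,
                         intervalsMonths = c(3L, 8L, 14L),
                         intervalMeansUm = c(1.76, 5.67, 7.62),
                         intervalSdsUm = c(26.72, 32.48, 39.15),
                         regionalMeansUm = c(9.95, 5.13, 1.81, 4.17, 6.27),
                         subjectSdFrac = 0.5,
                         expertSmoothSdUm = 15, expertJitterSdUm = 20,
                         expertBiasUm = 0,
                         methodSdUm = 10,
                         truthBaselineRangeUm = c(950, 1450),
                         truthAmplitudeSdUm = 80,
                         nKnots = 8L,
                         randomRaterRangeUm = c(0, 1900),
                         seed = 1L) {
    cfg <- list(geometry = geometry, nPairs = as.integer(nPairs),
                nExperts = as.integer(nExperts),
                pairsPerExpert = as.integer(pairsPerExpert),
                minExpertsPerPair = as.integer(minExpertsPerPair),
                scanPositions = as.integer(scanPositions),
                repeats = as.integer(repeats),
                intervalsMonths = as.integer(intervalsMonths),
                intervalMeansUm = intervalMeansUm,
                intervalSdsUm = intervalSdsUm,
                regionalMultipliers = regionalMeansUm / mean(regionalMeansUm),
                subjectSdFrac = subjectSdFrac,
                expertSmoothSdUm = expertSmoothSdUm,
                expertJitterSdUm = expertJitterSdUm,
                expertBiasUm = rep_len(expertBiasUm, nExperts),
                methodSdUm = methodSdUm,
                truthBaselineRangeUm = truthBaselineRangeUm,
                truthAmplitudeSdUm = truthAmplitudeSdUm,
                nKnots = as.integer(nKnots),
                randomRaterRangeUm = randomRaterRangeUm,
                seed = as.integer(seed))
    stopifnot(is(geometry, "ScanGeometry"),
              length(cfg$intervalMeansUm) == length(cfg$intervalsMonths),
              length(cfg$intervalSdsUm) == length(cfg$intervalsMonths),
              length(cfg$regionalMultipliers) == 5L,
              cfg$subjectSdFrac >= 0, cfg$subjectSdFrac <= 1,
              cfg$expertSmoothSdUm >= 0, cfg$expertJitterSdUm >= 0,
              cfg$methodSdUm >= 0, cfg$truthAmplitudeSdUm >= 0,
              all(cfg$intervalSdsUm >= 0))
    if (cfg$minExpertsPerPair > cfg$nExperts)
        stop(sprintf(
            "infeasible design: minExpertsPerPair = %d exceeds nExperts = %d",
            cfg$minExpertsPerPair, cfg$nExperts))
    if (cfg$nExperts * cfg$pairsPerExpert < cfg$nPairs * cfg$minExpertsPerPair)
        stop(sprintf(
            "infeasible design: nExperts * pairsPerExpert = %d < nPairs * minExpertsPerPair = %d",
            cfg$nExperts * cfg$pairsPerExpert,
            cfg$nPairs * cfg$minExpertsPerPair))
    class(cfg) <- "cohortConfig"
    cfg
}

#' @export
print.cohortConfig <- function(x, ...) {
    cat(sprintf("cohortConfig: %d pairs, %d experts (%d pairs each, >= %d experts/pair)\n",
                x$nPairs, x$nExperts, x$pairsPerExpert, x$minExpertsPerPair))
    cat(sprintf("  %d scan positions x 2 sessions x %d repeats; intervals %s months\n",
                length(x$scanPositions), x$repeats,
                paste(x$intervalsMonths, collapse = "/")))
    cat(sprintf("  growth means %s um; expert noise sd %.1f um (smooth %.0f + jitter %.0f); method sd %.1f um; seed %d\n",
                paste(x$intervalMeansUm, collapse = "/"),
                sqrt(x$expertSmoothSdUm^2 + x$expertJitterSdUm^2),
                x$expertSmoothSdUm, x$expertJitterSdUm, x$methodSdUm,
                x$seed))
    invisible(x)
}

.pairIds <- function(cfg) sprintf("P%03d", seq_len(cfg$nPairs))
.expertIds <- function(cfg) sprintf("E%d", seq_len(cfg$nExperts))
.scanId <- function(pair, pos) sprintf("%s_S%02d", pair, pos)

#' Build the expert-to-pair allocation design
#'
#' Distributes the volume-stack pairs among the experts so that every
#' expert receives exactly \code{pairsPerExpert} pairs and every pair is
#' seen by at least \code{minExpertsPerPair} (distinct) experts.  The
#' total of \code{nExperts * pairsPerExpert} assignments is spread as
#' evenly as possible (with the defaults: 60 pairs get 3 experts, 30 get
#' 4); experts are drawn least-loaded-first with seeded random
#' tie-breaking, which guarantees the exact per-expert count.  Interval
#' groups are split evenly over the pairs and eye sides alternate
#' (half left, half right).  Deterministic given the config seed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A \code{studyDesign} list: \code{assignment} (pair -> expert
#'   ids), \code{pairInterval}, \code{pairEye}, \code{linesPerExpert},
#'   \code{scanPositions}, \code{scanInfo} data.frame.
#' @export
buildDesign <- function(config) {
    stopifnot(inherits(config, "cohortConfig"))
    P <- config$nPairs; e <- config$nExperts
    A <- e * config$pairsPerExpert
    base <- A %/% P; extra <- A %% P
    if (base + (extra > 0L) > e)
        stop(sprintf(
            "infeasible design: %d assignments over %d pairs need up to %d experts on one pair but only %d exist",
            A, P, base + 1L, e))
    pairs <- .pairIds(config)
    experts <- .expertIds(config)
    withSeed(subSeed(config$seed, "design"), {
        sizes <- rep(base, P)
        if (extra) sizes[sample.int(P, extra)] <- base + 1L
        load <- integer(e); names(load) <- experts
        assignment <- vector("list", P); names(assignment) <- pairs
        for (i in sample.int(P)) {
            ord <- order(load + stats::runif(e))  # least-loaded, random ties
            chosen <- experts[ord[seq_len(sizes[i])]]
            assignment[[i]] <- sort(chosen)
            load[chosen] <- load[chosen] + 1L
        }
    })
    nIv <- length(config$intervalsMonths)
    pairInterval <- config$intervalsMonths[rep(seq_len(nIv), each = ceiling(P / nIv))[seq_len(P)]]
    names(pairInterval) <- pairs
    pairEye <- rep(c("right", "left"), length.out = P)
    names(pairEye) <- pairs
    scanInfo <- do.call(rbind, lapply(pairs, function(p)
        data.frame(scan_id = .scanId(p, config$scanPositions),
                   pair_id = p,
                   interval_months = pairInterval[[p]],
                   eye = pairEye[[p]])))
    design <- structure(list(
        assignment = assignment,
        pairInterval = pairInterval,
        pairEye = pairEye,
        linesPerExpert = length(config$scanPositions) * 2L *
            config$pairsPerExpert * config$repeats,
        scanPositions = config$scanPositions,
        scanInfo = scanInfo), class = "studyDesign")
    validateDesign(design, config)
    design
}

#' Check a design against its configuration
#'
#' Asserts the allocation invariants: every expert has exactly
#' \code{pairsPerExpert} pairs, every pair at least
#' \code{minExpertsPerPair} distinct experts.  An invalid design is an
#' error, never silently returned.
#'
#' @param design a \code{studyDesign}.
#' @param config the \code{\link{cohortConfig}} it was built from.
#' @return \code{design}, invisibly.
#' @export
validateDesign <- function(design, config) {
    perPair <- lengths(design$assignment)
    if (any(perPair < config$minExpertsPerPair))
        stop("design invalid: pair(s) with too few experts: ",
             paste(names(perPair)[perPair < config$minExpertsPerPair],
                   collapse = ", "))
    if (any(vapply(design$assignment, anyDuplicated, integer(1)) > 0L))
        stop("design invalid: duplicated expert within a pair")
    cnt <- table(unlist(design$assignment))
    ex <- .expertIds(config)
    if (!setequal(names(cnt), ex) ||
        any(cnt[ex] != config$pairsPerExpert))
        stop("design invalid: per-expert pair counts are not exactly ",
             config$pairsPerExpert)
    invisible(design)
}

#' @export
print.studyDesign <- function(x, ...) {
    perPair <- table(lengths(x$assignment))
    cat(sprintf("studyDesign: %d pairs, %d experts, %d lines per expert\n",
                length(x$assignment), length(unique(unlist(x$assignment))),
                x$linesPerExpert))
    cat("  experts per pair:",
        paste(sprintf("%s pairs x %s experts", perPair, names(perPair)),
              collapse = ", "), "\n")
    invisible(x)
}
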