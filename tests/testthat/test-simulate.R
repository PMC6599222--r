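test_that("truth contours are smooth, bounded and seed-reproducible", {
    cfg <- cohortConfig(seed = 2L)
    a <- generateTruthContours(cfg, "P001")
    b <- generateTruthContours(cfg, "P001")
    expect_identical(a, b)
    expect_false(identical(a, generateTruthContours(cfg, "P002")))
    expect_equal(dim(a), c(500L, 8L))
    # property sweep: depth bounds and bounded column-to-column steps
    many <- do.call(cbind, lapply(sprintf("P%03d", 1:40), function(p)
        generateTruthContours(cfg, p)))
    expect_true(all(many >= 0 & many <= maxDepthUm(cfg$geometry)))
    expect_lt(max(abs(diff(many))), 50)
})

test_that("growth fields realise interval means and the regional ordering", {
    czero <- cohortConfig(intervalSdsUm = c(0, 0, 0), seed = 6L)
    f3 <- simulateGrowthField(czero, "P001", 3, "right")
    # zero noise: column mean is exactly the 3-month growth mean
    expect_equal(mean(f3[, 1]), 1.76)
    expect_equal(unique(round(colMeans(f3), 10)), 1.76)
    # regional profile: foveal < parafoveal < perifoveal at zero noise
    rm3 <- regionMeans(f3[, 1], regionPartition(500))
    expect_lt(rm3[3], min(rm3[c(2, 4)]))
    expect_lt(max(rm3[c(2, 4)]), min(rm3[c(1, 5)]))
    # left eye mirrors the profile in image coordinates
    fl <- simulateGrowthField(czero, "P001", 3, "left")
    expect_equal(regionMeans(fl[, 1], regionPartition(500, "left")),
                 rm3)
    expect_error(simulateGrowthField(czero, "P001", 5, "right"),
                 "unknown interval")
    # Monte-Carlo recovery of the 14-month mean over many pairs
    cfg <- cohortConfig(seed = 6L)
    mus <- vapply(sprintf("P%03d", 1:60), function(p)
        mean(simulateGrowthField(cfg, p, 14, "right")), numeric(1))
    se <- cfg$intervalSdsUm[3] / sqrt(60)
    expect_lt(abs(mean(mus) - 7.62), 3 * se)
})

test_that("expert simulation has the configured repeat-noise behaviour", {
    g <- scanGeometry()
    truth <- matrix(1200, 500, 4,
                    dimnames = list(NULL, sprintf("P001_S%02d", c(1, 3, 6, 11))))
    # zero noise: repeats equal truth and IRC = 1
    c0 <- cohortConfig(expertSmoothSdUm = 0, expertJitterSdUm = 0, seed = 3L)
    e0 <- simulateExpert(c0, "E1", truth)
    expect_true(all(depths(e0) == 1200))
    expect_equal(intraRaterCoefficient(e0, 20)$irc, 1)
    # 25 um marginal jitter: IRC ~ 2 Phi(l / (sigma sqrt(2/3))) - 1 = 0.673
    c25 <- cohortConfig(expertSmoothSdUm = 0, expertJitterSdUm = 25,
                        seed = 3L)
    bigTruth <- matrix(1200, 500, 40,
                       dimnames = list(NULL, sprintf("S%02d", 1:40)))
    e25 <- simulateExpert(c25, "E1", bigTruth)
    p <- 2 * pnorm(20 / (25 * sqrt(2 / 3))) - 1
    se <- sqrt(p * (1 - p) / (500 * 40))
    expect_lt(abs(intraRaterCoefficient(e25, 20)$irc - p), 3 * se)
    # smooth + jitter split keeps the marginal SD at the combined value, so
    # the same closed form applies with sigma = sqrt(15^2 + 20^2) = 25; the
    # smooth part correlates columns within a scan, so the tolerance is set
    # by the between-scan variability (150 scans) rather than per-column SE
    cMix <- cohortConfig(expertSmoothSdUm = 15, expertJitterSdUm = 20,
                         seed = 3L)
    mixTruth <- matrix(1200, 500, 150,
                       dimnames = list(NULL, sprintf("S%03d", 1:150)))
    eMix <- simulateExpert(cMix, "E1", mixTruth)
    expect_lt(abs(intraRaterCoefficient(eMix, 20)$irc - p), 0.05)
    # determinism per expert id, distinct streams across experts
    expect_identical(depths(simulateExpert(c25, "E1", truth)),
                     depths(simulateExpert(c25, "E1", truth)))
    expect_false(identical(depths(simulateExpert(c25, "E1", truth)),
                           depths(simulateExpert(c25, "E2", truth))))
})

test_that("the random rater stays below the repeatability floor", {
    cfg <- cohortConfig(seed = 12L)
    rr <- simulateRandomRater(cfg, nScans = 120L)
    irc <- intraRaterCoefficient(rr, 20)$irc
    expect_lte(irc, 0.2)
    expect_true(all(depths(rr) >= 0 & depths(rr) <= 1900))
    expect_identical(depths(simulateRandomRater(cfg, nScans = 10L)),
                     depths(simulateRandomRater(cfg, nScans = 10L)))
})

test_that("the simulated method is exact at zero noise and repeatable", {
    cfg <- cohortConfig(methodSdUm = 0, seed = 13L)
    truth <- matrix(rnorm(500 * 3), 500,
                    dimnames = list(NULL, c("a", "b", "c")))
    m0 <- simulateMethod(cfg, truth)
    expect_equal(unname(dzValues(m0)), unname(truth))
    cfg2 <- cohortConfig(methodSdUm = 10, seed = 13L)
    expect_identical(dzValues(simulateMethod(cfg2, truth)),
                     dzValues(simulateMethod(cfg2, truth)))
})

test_that("method displacements vary less than expert displacements", {
    cfg <- fullOverlapConfig(nPairs = 8L, nExperts = 4L, seed = 21L)
    co <- simulateCohort(cfg)
    vMethod <- var(as.vector(dzValues(co$method)))
    vExperts <- vapply(co$expertFields, function(f)
        var(as.vector(dzValues(f))), numeric(1))
    expect_true(all(vMethod < vExperts))
})

test_that("cohort generation matches the design and is byte-stable", {
    cfg <- fullOverlapConfig(nPairs = 3L, nExperts = 3L,
                             scanPositions = c(1L, 3L), seed = 30L)
    co <- simulateCohort(cfg)
    # record counts: positions x 2 sessions x assigned pairs x repeats
    for (ss in co$experts)
        expect_equal(ncol(ss), 2L * 2L * 3L * 3L)
    expect_equal(ncol(co$method), 3L * 2L)
    # expert displacement fields inherit interval labels for reporting
    expect_true("interval_months" %in%
                colnames(SummarizedExperiment::colData(co$expertFields$E1)))
    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    generateCohort(cfg, dir1)
    generateCohort(cfg, dir2)
    for (f in c("segmentations.csv", "method_displacements.csv",
                "truth_fields.csv", "scan_info.csv", "design.json"))
        expect_identical(readLines(file.path(dir1, f)),
                         readLines(file.path(dir2, f)))
    # disk round trip reproduces the in-memory cohort
    back <- readSegmentations(file.path(dir1, "segmentations.csv"),
                              cfg$geometry)
    o <- function(x) order(scanIds(x), timepoints(x), repeatIndex(x))
    expect_equal(depths(back$E2)[, o(back$E2)],
                 depths(co$experts$E2)[, o(co$experts$E2)])
})

test_that("inflating one expert's noise lowers that expert's WI", {
    wiOf <- function(seed, noisy) {
        cfg <- fullOverlapConfig(nPairs = 4L, nExperts = 4L,
                                 scanPositions = c(1L, 3L), seed = seed)
        co <- simulateCohort(cfg)
        if (noisy) {
            # re-simulate E4 with tripled repeat noise
            loud <- cohortConfig(nPairs = 4L, nExperts = 4L,
                                 pairsPerExpert = 4L, minExpertsPerPair = 4L,
                                 scanPositions = c(1L, 3L), seed = seed,
                                 expertSmoothSdUm = 45, expertJitterSdUm = 60)
            co$experts$E4 <- simulateExpert(loud, "E4", co$truthT1,
                                            co$truthT1 + co$truthFields)
            f <- displacementFromTimepoints(co$experts$E4)
            co$expertFields$E4 <- f
        }
        sim <- pairwiseSimilarities(co$expertFields, "diffZ")
        williamsIndex(sim, "E4")$wi
    }
    base <- vapply(1:3, wiOf, numeric(1), noisy = FALSE)
    loud <- vapply(1:3, wiOf, numeric(1), noisy = TRUE)
    # well-behaved equal-noise experts sit near WI = 1
    expect_true(all(abs(base - 1) < 0.05))
    expect_lt(mean(loud), mean(base))
})
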