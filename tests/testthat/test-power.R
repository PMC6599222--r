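test_that("leave-one-out ground truth averages the remaining raters", {
    g <- tinyGeometry()
    scans <- c("s1", "s2")
    f1 <- makeFieldSet(function(s) rep(5, 10), scans, "E1", g)
    f2 <- makeFieldSet(function(s) rep(10, 10), scans, "E2", g)
    f3 <- makeFieldSet(function(s) rep(20, 10), scans, "E3", g)
    # r = 2: the ground truth is the other rater, exactly
    gb2 <- looGroundTruth(list(E1 = f1, E2 = f2), "E1")
    expect_equal(unname(gb2$gbar), unname(dzValues(f2)))
    # arithmetic mean of the remaining raters
    gb <- looGroundTruth(list(E1 = f1, E2 = f2, E3 = f3), "E1")
    expect_equal(unname(gb$gbar), matrix(15, 10, 2))
    expect_equal(unname(gb$nContributors), c(2L, 2L))
    expect_error(looGroundTruth(list(E1 = f1), "E2"), "not among")
})

test_that("staggered scan coverage averages cell-wise over contributors", {
    g <- tinyGeometry()
    set.seed(17)
    fields <- list(
        E1 = makeFieldSet(function(s) rnorm(10), c("s1", "s2"), "E1", g),
        E2 = makeFieldSet(function(s) rnorm(10), c("s2", "s3"), "E2", g),
        E3 = makeFieldSet(function(s) rnorm(10), c("s1", "s3"), "E3", g))
    gb <- looGroundTruth(fields, "E1")
    # cell-wise brute-force oracle
    for (s in c("s1", "s2", "s3")) {
        contrib <- Filter(function(f) s %in% scanIds(f), fields[-1L])
        manual <- rowMeans(vapply(contrib, function(f)
            dzValues(f)[, match(s, scanIds(f))], numeric(10)))
        expect_equal(gb$gbar[, s], manual)
    }
    # a scan covered by nobody else is an error naming the scan
    only1 <- list(E1 = fields$E1,   # covers s1, s2
                  E2 = makeFieldSet(function(s) rnorm(10), "s2", "E2", g))
    expect_error(
        looGroundTruth(only1, "E1", scanId = c("s1", "s2")), "s1")
})

test_that("the ground truth cancels in signed differences but not in SDs", {
    g <- tinyGeometry()
    set.seed(3)
    scans <- c("s1", "s2", "s3")
    fields <- lapply(1:4, function(i)
        makeFieldSet(function(s) rnorm(10, 0, 5), scans, paste0("E", i), g))
    names(fields) <- paste0("E", 1:4)
    method <- makeFieldSet(function(s) rnorm(10, 0, 2), scans, "method", g)
    gb <- looGroundTruth(fields, "E2")
    pr <- errorPairs(method, fields$E2, gb)
    # X_j - Y_j == X - dE_j identically
    expect_equal(pr$x - pr$y,
                 as.vector(dzValues(method)) - as.vector(dzValues(fields$E2)))
    # ...yet the effect size on (X_j, Y_j) differs from the one on (X, dE_j)
    dLoo <- cohensD(pr$x, pr$y)$d
    dRaw <- cohensD(as.vector(dzValues(method)),
                    as.vector(dzValues(fields$E2)))$d
    expect_false(isTRUE(all.equal(dLoo, dRaw)))
})

test_that("the paired t-test follows the Student-t reference", {
    # null case: all differences zero
    r0 <- pairedTTest(x = rep(1, 5), y = rep(1, 5), mode = "signed")
    expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_false(r0$reject)
    # D = 1..5: t = 3 / (sqrt(2.5)/sqrt(5)), df = 4
    r1 <- pairedTTest(x = as.numeric(1:5), y = rep(0, 5), mode = "signed",
                      alpha = 0.05)
    expect_equal(r1$t, 3 / (sqrt(2.5) / sqrt(5)))
    expect_equal(r1$df, 4L)
    expect_equal(r1$p, 2 * pt(-3 / (sqrt(2.5) / sqrt(5)), 4))
    expect_true(r1$reject)
    # degenerate: constant nonzero difference
    expect_error(pairedTTest(x = 1:10 + 0.5, y = as.numeric(1:10),
                             mode = "signed"), "zero variance")
    expect_error(pairedTTest(x = 1, y = 2), "at least 2")
    expect_error(pairedTTest(x = 1:4, y = 1:5), "matched")
    # reference implementation to 1e-10 on random inputs, both modes
    set.seed(12)
    for (i in 1:10) {
        x <- rnorm(50, 0.2); y <- rnorm(50)
        rs <- pairedTTest(x = x, y = y, mode = "signed")
        ref <- t.test(x, y, paired = TRUE)
        expect_lt(abs(rs$t - unname(ref$statistic)), 1e-10)
        expect_lt(abs(rs$p - ref$p.value), 1e-10)
        ra <- pairedTTest(x = x, y = y, mode = "absolute")
        refa <- t.test(abs(x), abs(y), paired = TRUE)
        expect_lt(abs(ra$t - unname(refa$statistic)), 1e-10)
        expect_lt(abs(ra$p - refa$p.value), 1e-10)
    }
})

test_that("Cohen's d uses the pooled standard deviation", {
    set.seed(9)
    x <- exactSample(30, 1, 1); y <- exactSample(30, 0.5, 1)
    expect_equal(cohensD(x, y)$d, 0.5)
    expect_equal(cohensD(x, x)$d, 0)
    # unequal sizes: |X|=10 (mean 3, sd 2), |Y|=20 (mean 2, sd 1)
    x2 <- exactSample(10, 3, 2); y2 <- exactSample(20, 2, 1)
    r <- cohensD(x2, y2)
    expect_equal(r$pooledSd, sqrt(55 / 28))
    expect_equal(r$d, 1 / sqrt(55 / 28))
    expect_equal(r$magnitude, "large")
    # invariances: common shift and common positive rescaling
    expect_equal(cohensD(x2 + 7, y2 + 7)$d, r$d)
    expect_equal(cohensD(3 * x2, 3 * y2)$d, r$d)
    expect_error(cohensD(rep(1, 5), rep(2, 5)), "zero")
    expect_error(cohensD(1, 1:5), "at least 2")
})

test_that("powerSummary recovers generator conditions at zero noise", {
    cfg <- fullOverlapConfig(nPairs = 6L, nExperts = 3L,
                             scanPositions = c(1L, 3L), seed = 5L,
                             intervalSdsUm = c(0, 0, 0),
                             expertSmoothSdUm = 0, expertJitterSdUm = 0,
                             methodSdUm = 0, truthAmplitudeSdUm = 0)
    co <- simulateCohort(cfg)
    ps <- powerSummary(co$expertFields, co$method, scanInfo = co$scanInfo)
    # interval means are exactly the configured growth means, SD 0 within
    # rounding (regional profile averages to 1 across columns)
    expect_equal(ps$intervalTable$experts_mean, c(1.76, 5.67, 7.62))
    expect_equal(ps$intervalTable$method_mean, c(1.76, 5.67, 7.62))
    # pooled expert cells triplicate the method cells, so the sample SDs
    # differ only through the n-1 denominator
    expect_true(all(abs(ps$intervalTable$method_sd -
                        ps$intervalTable$experts_sd) < 1e-2))
    # regional table: foveal (A) mean below parafoveal below perifoveal
    reg <- ps$regionTable
    expect_lt(reg$experts_mean[reg$position == 3],
              min(reg$experts_mean[reg$position %in% c(2, 4)]))
    expect_lt(max(reg$experts_mean[reg$position %in% c(2, 4)]),
              min(reg$experts_mean[reg$position %in% c(1, 5)]))
})

test_that("powerSummary group means track the generator within 3 SE", {
    cfg <- fullOverlapConfig(nPairs = 12L, nExperts = 3L,
                             scanPositions = c(1L, 3L), seed = 8L)
    co <- simulateCohort(cfg)
    ps <- powerSummary(co$expertFields, co$method, scanInfo = co$scanInfo)
    tab <- ps$intervalTable
    for (k in seq_len(nrow(tab))) {
        mu <- cfg$intervalMeansUm[match(tab$interval_months[k],
                                        cfg$intervalsMonths)]
        # dominant variance: 4 subject draws per interval group
        se <- cfg$intervalSdsUm[k] * sqrt(cfg$subjectSdFrac) / sqrt(4)
        expect_lt(abs(tab$experts_mean[k] - mu), 3 * se + 1)
    }
    expect_s3_class(ps$looTests, "data.frame")
    expect_true(all(ps$looTests$n > 0))
})
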