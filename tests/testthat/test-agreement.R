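test_that("IRC is 1 for identical repeats and errors on missing repeats", {
    g <- tinyGeometry()
    ss <- makeSegSet(function(...) rep(50, 10), c("s1", "s2"),
                     c("t1", "t2"), 3L, geometry = g)
    r <- intraRaterCoefficient(ss, 20)
    expect_equal(r$irc, 1)
    expect_equal(r$total, 3 * 10 * 4)   # 4 (scan, timepoint) images
    bad <- makeSegSet(function(...) rep(50, 10), "s9", geometry = g)
    expect_error(intraRaterCoefficient(bad), "scan 's9'.*exactly 3")
})

test_that("IRC of uniform random repeats matches the analytic probability", {
    # deviations (2X1 - X2 - X3)/3 for X ~ U(0, R); P(|dev| <= l) by
    # numeric integration of the 2U1 vs (U2 + U3) convolution
    R <- 1900; l <- 20; tau <- 3 * l / R
    Ftri <- function(v) ifelse(v <= 0, 0,
                        ifelse(v <= 1, v^2 / 2,
                        ifelse(v <= 2, 1 - (2 - v)^2 / 2, 1)))
    pAnalytic <- integrate(function(u) 0.5 * (Ftri(u + tau) - Ftri(u - tau)),
                           0, 2, rel.tol = 1e-10)$value
    expect_lt(pAnalytic, 0.04)   # the random-rater floor is far below 0.2

    g <- scanGeometry(mDepth = 768L, dzUm = 3.87)
    n <- 500L; S <- 200L
    set.seed(31)
    ss <- segmentationSet(matrix(runif(n * 3L * S, 0, R), n),
                          scanId = rep(sprintf("s%03d", 1:S), each = 3L),
                          timepoint = "t1",
                          repeatIndex = rep(1:3, S),
                          rater = "rand", geometry = g)
    irc <- intraRaterCoefficient(ss, l)$irc
    se <- sqrt(pAnalytic * (1 - pAnalytic) / (n * S))
    expect_lt(abs(irc - pAnalytic), 3 * se)
})

test_that("Monte-Carlo IRC under Gaussian noise matches the closed form", {
    g <- scanGeometry()
    n <- 500L; S <- 40L; l <- 20
    for (sigma in c(10, 25, 50)) {
        set.seed(1000 + sigma)
        truth <- runif(n, 800, 1600)
        d <- matrix(rep(truth, 3L * S), n) + rnorm(n * 3L * S, 0, sigma)
        ss <- segmentationSet(d,
                              scanId = rep(sprintf("s%03d", 1:S), each = 3L),
                              timepoint = "t1", repeatIndex = rep(1:3, S),
                              rater = "mc", geometry = g)
        irc <- intraRaterCoefficient(ss, l)$irc
        p <- 2 * pnorm(l / (sigma * sqrt(2 / 3))) - 1
        se <- sqrt(p * (1 - p) / (n * S))
        expect_lt(abs(irc - p), 3 * se)
    }
})

test_that("IRC is shift-invariant and decreases with repeat noise", {
    g <- tinyGeometry(n = 50L, m = 2000L, dz = 1)
    set.seed(8)
    base <- matrix(runif(50 * 3, 100, 200), 50)
    mk <- function(d) segmentationSet(d, rep("s1", 3), "t1", 1:3, "r", g)
    expect_equal(intraRaterCoefficient(mk(base), 5)$irc,
                 intraRaterCoefficient(mk(base + 123.4), 5)$irc)
    sweep <- ircNoiseSweep(cohortConfig(seed = 3), sdsUm = c(10, 20, 40, 80),
                           nScans = 25L)
    expect_true(all(diff(sweep$irc) < 0))
    expect_true(all(sweep$irc >= 0 & sweep$irc <= 1))
})

test_that("pairwise similarities match per-pair metric evaluation", {
    g <- tinyGeometry(n = 20L, m = 200L, dz = 2)
    scans <- c("s1", "s2")
    set.seed(21)
    mk <- function(id, shift) makeSegSet(
        function(scan, tp, rep) runif(20, 80, 120) + shift,
        scans, c("t1", "t2"), 1L, id, g)
    segs <- list(A = mk("A", 0), B = mk("B", 5), C = mk("C", -5))
    for (metric in c("DC", "JC")) {
        sim <- pairwiseSimilarities(segs, metric)
        v <- similarityValues(sim)
        expect_true(isSymmetric(v))
        expect_equal(unname(diag(v)), rep(1, 3))
        fn <- if (metric == "DC") diceCoefficient else jaccardCoefficient
        # element-wise oracle over the shared images
        direct <- mean(vapply(
            c(outer(scans, c("t1", "t2"), paste)), function(k) {
                p <- strsplit(k, " ")[[1L]]
                fn(contourMask(meanContour(segs$A, p[1], p[2]), g),
                   contourMask(meanContour(segs$B, p[1], p[2]), g))
            }, numeric(1)))
        expect_equal(v["A", "B"], direct)
    }
    # identical raters give off-diagonal 1 for every metric
    same <- list(A = segs$A, B = segs$A, C = segs$A)
    for (metric in c("DC", "JC", "BLD"))
        expect_equal(unname(similarityValues(
            pairwiseSimilarities(same, metric))), matrix(1, 3, 3))
})

test_that("diffZ similarities are 1 - d over shared scans only", {
    g <- scanGeometry()
    n <- nColumns(g)
    # constant 0.25 dissimilarity: offset of 0.25 * m depth pixels
    off <- 0.25 * mDepth(g) * pixelSpacings(g)[["dz_um"]]
    fl <- list(a = makeFieldSet(function(s) rep(0, n), c("s1", "s2"), "a", g),
               b = makeFieldSet(function(s) rep(off, n), c("s2", "s1"), "b", g))
    sim <- pairwiseSimilarities(fl, "diffZ")
    expect_equal(similarityValues(sim)["a", "b"], 0.75)
    # partial overlap: only shared scans contribute, counts recorded
    fl$c <- makeFieldSet(function(s) rep(0, n), c("s2", "s3"), "c", g)
    sim2 <- pairwiseSimilarities(fl, "diffZ")
    expect_equal(sim2@nShared["a", "c"], 1L)
    expect_equal(similarityValues(sim2)["a", "c"], 1)
    fl$d <- makeFieldSet(function(s) rep(0, n), "s9", "d", g)
    expect_error(pairwiseSimilarities(fl, "diffZ"), "share no scans")
})

test_that("Williams' index reproduces direct Eq evaluation", {
    mk <- function(v, ids) similarityMatrix(
        `dimnames<-`(v, list(ids, ids)), "diffZ")
    # 0.9 / 0.8 / 0.7 hand case
    v <- diag(3); v[1, 2] <- v[2, 1] <- 0.9
    v[1, 3] <- v[3, 1] <- 0.8; v[2, 3] <- v[3, 2] <- 0.7
    sim <- mk(v, c("j", "a", "b"))
    expect_equal(williamsIndex(sim, "j")$wi, (0.9 + 0.8) / (2 * 0.7))
    expect_true(williamsIndex(sim, "j")$atLeastGroup)
    # equal similarities force WI = 1 for every rater and group size
    for (r in 3:6) {
        v <- matrix(0.5, r, r); diag(v) <- 1
        sim <- mk(v, paste0("r", 1:r))
        for (id in paste0("r", 1:r))
            expect_equal(williamsIndex(sim, id)$wi, 1)
    }
    expect_error(williamsIndex(mk(diag(2), c("a", "b")), "a"), "at least 3")
    expect_error(williamsIndex(sim, "nobody"), "not in the matrix")
    # zero inter-group similarity is an error, not an infinity
    v0 <- diag(3)
    expect_error(williamsIndex(mk(v0, c("a", "b", "c")), "a"), "undefined")
})

test_that("WI is invariant under rescaling all similarities", {
    set.seed(14)
    r <- 5L
    v <- matrix(0, r, r)
    v[upper.tri(v)] <- runif(r * (r - 1) / 2, 0.3, 0.9)
    v <- v + t(v); diag(v) <- 1
    ids <- paste0("r", 1:r)
    dimnames(v) <- list(ids, ids)
    base <- vapply(ids, function(id)
        williamsIndex(similarityMatrix(v, "diffZ"), id)$wi, numeric(1))
    for (c in c(0.5, 0.9)) {
        vs <- v * c; diag(vs) <- 1
        scaled <- vapply(ids, function(id)
            williamsIndex(similarityMatrix(vs, "diffZ"), id)$wi, numeric(1))
        expect_equal(scaled, base)
    }
})

test_that("leave-one-out WI matches the submatrix oracle", {
    set.seed(77)
    r <- 6L
    ids <- c("method", paste0("E", 1:5))
    v <- matrix(0, r, r)
    v[upper.tri(v)] <- runif(r * (r - 1) / 2, 0.6, 0.95)
    v <- v + t(v); diag(v) <- 1
    dimnames(v) <- list(ids, ids)
    sim <- similarityMatrix(v, "diffZ")
    loo <- williamsIndexLOO(sim, "method")
    expect_equal(nrow(loo$leaveOneOut), 5L)
    for (k in seq_len(5L)) {
        o <- loo$leaveOneOut$omitted[k]
        keep <- setdiff(ids, o)
        sub <- similarityMatrix(v[keep, keep], "diffZ")
        expect_equal(loo$leaveOneOut$wi[k],
                     williamsIndex(sub, "method")$wi)
    }
    expect_equal(loo$looMin, min(loo$leaveOneOut$wi))
    # equal similarities -> every LOO value is 1
    ve <- matrix(0.8, r, r); diag(ve) <- 1; dimnames(ve) <- list(ids, ids)
    looE <- williamsIndexLOO(similarityMatrix(ve, "diffZ"), "method")
    expect_equal(looE$leaveOneOut$wi, rep(1, 5))
    # domain checks
    expect_error(williamsIndexLOO(sim, "E99"), "not in the matrix")
    v3 <- v[1:3, 1:3]
    expect_error(williamsIndexLOO(similarityMatrix(v3, "diffZ"), "method"),
                 "at least 4")
})
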