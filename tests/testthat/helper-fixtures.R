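# Shared fixtures: small geometries, configs and hand-built sets.

tinyGeometry <- function(n = 10L, m = 100L, dx = 1, dz = 1)
    scanGeometry(nColumns = n, mDepth = m, dxUm = dx, dyUm = 245, dzUm = dz)

studyGeometry <- scanGeometry()   # 500 x 768, 11.46/245/3.87 um

# Config with every expert segmenting every pair (guaranteed overlap for
# similarity matrices), small enough for fast end-to-end runs.
fullOverlapConfig <- function(nPairs = 6L, nExperts = 5L,
                              scanPositions = c(1L, 3L), seed = 1L, ...)
    cohortConfig(nPairs = nPairs, nExperts = nExperts,
                 pairsPerExpert = nPairs, minExpertsPerPair = nExperts,
                 scanPositions = scanPositions, seed = seed, ...)

# SegmentationSet from a depth-generating function f(scan, timepoint, rep)
# returning one per-column vector.
makeSegSet <- function(f, scans, timepoints = "t1", repeats = 1L,
                       rater = "E1", geometry = tinyGeometry()) {
    grid <- expand.grid(rep = seq_len(repeats), tp = timepoints,
                        scan = scans, stringsAsFactors = FALSE)
    d <- mapply(f, grid$scan, grid$tp, grid$rep)
    segmentationSet(d, grid$scan, grid$tp, grid$rep, rater, geometry)
}

# Displacement set from a dz-generating function f(scan).
makeFieldSet <- function(f, scans, rater = "E1",
                         geometry = tinyGeometry()) {
    displacementFieldSet(vapply(scans, f, numeric(nColumns(geometry))),
                         scans, rater, geometry)
}

# Exhaustive O(n^2) point-pair BLD oracle, independent of the package
# implementation: plain double loops over all reference/test point pairs.
bldOracle <- function(refUm, testUm, geometry) {
    dx <- pixelSpacings(geometry)[["dx_um"]]
    n <- length(refUm)
    x <- (seq_len(n) - 1) * dx
    dist2 <- function(i, j)
        sqrt((x[i] - x[j])^2 + (refUm[i] - testUm[j])^2)
    out <- numeric(n)
    # nearest reference point of every test point, by exhaustive search
    nearRef <- integer(n); minD <- numeric(n)
    for (q in seq_len(n)) {
        best <- Inf; bi <- 1L
        for (p in seq_len(n)) {
            dd <- sqrt((x[p] - x[q])^2 + (refUm[p] - testUm[q])^2)
            if (dd < best) { best <- dd; bi <- p }
        }
        nearRef[q] <- bi; minD[q] <- best
    }
    for (p in seq_len(n)) {
        fwd <- Inf
        for (q in seq_len(n))
            fwd <- min(fwd, sqrt((x[p] - x[q])^2 + (refUm[p] - testUm[q])^2))
        inv <- 0
        for (q in seq_len(n))
            if (nearRef[q] == p) inv <- max(inv, minD[q])
        out[p] <- max(fwd, inv)
    }
    out
}

# Samples with exact mean and sd, for effect-size oracles.
exactSample <- function(n, mean, sd) {
    z <- scale(stats::rnorm(n))[, 1L]
    mean + sd * z
}
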