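# Internal helpers: seeded substreams and smooth B-spline bases.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

# Deterministic substream seed from a master seed and string keys; stays
# below 2^31 so it is a valid R integer seed.
subSeed <- function(master, ...) {
    s <- paste(c(...), collapse = "/")
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483563
    as.integer((h + as.numeric(master) %% 2147483563 * 48271) %% 2147483563)
}

# Cubic B-spline basis over n columns with K basis functions; rows sum to 1
# (partition of unity), so coefficients in [a, b] give values in [a, b].
splineBasis <- function(n, K) {
    splines::bs(seq_len(n), df = K, intercept = TRUE)
}

# Basis with rows rescaled to unit sum of squares: iid N(0, sd) coefficients
# then give exactly sd as the pointwise marginal standard deviation at every
# column, while keeping the smooth spatial correlation.
unitVarBasis <- function(n, K) {
    B <- splineBasis(n, K)
    B / sqrt(rowSums(B^2))
}

# One smooth zero-mean noise curve with exact pointwise marginal sd.
smoothNoise <- function(n, K, sd) {
    if (sd == 0) return(numeric(n))
    as.vector(unitVarBasis(n, K) %*% stats::rnorm(K, 0, sd))
}
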