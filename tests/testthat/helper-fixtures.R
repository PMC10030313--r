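# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# A quick CV configuration for toys where penalty search is irrelevant.
fastCfg <- function(seed = 0L, nFolds = 5L, alphaGrid = c(0, 0.1, 10)) {
    cvConfig(nFolds = nFolds, alphaGrid = alphaGrid, seed = seed)
}

# Independent standard-normal pattern pair.
nullPair <- function(nTrials, nX = 5L, nY = 5L, seed = 1L) {
    withr::with_seed(seed, list(
        X = matrix(rnorm(nTrials * nX), nTrials),
        Y = matrix(rnorm(nTrials * nY), nTrials)))
}

# Noisy linear-map pair with known transformation.
linearPair <- function(nTrials = 80L, nX = 4L, nY = 3L, noise = 0,
                       seed = 1L) {
    withr::with_seed(seed, {
        X <- matrix(rnorm(nTrials * nX), nTrials)
        T0 <- matrix(rnorm(nX * nY), nX)
        Y <- X %*% T0 + noise * matrix(rnorm(nTrials * nY), nTrials)
        list(X = X, Y = Y, T0 = T0)
    })
}

# Vertices built as noisy copies of m prototype trial courses.
redundantPattern <- function(nTrials = 60L, nProto = 6L, nVertices = 30L,
                             noise = 0.15, seed = 1L) {
    withr::with_seed(seed, {
        proto <- matrix(rnorm(nTrials * nProto), nTrials) * 2
        assign_ <- rep_len(seq_len(nProto), nVertices)
        list(values = proto[, assign_] +
                 noise * matrix(rnorm(nTrials * nVertices), nTrials),
             proto = assign_)
    })
}

# Per-subject lists of null 24x24 "TTM" maps for the permutation test.
nullSubjectMaps <- function(nSubjects = 18L, nLat = 24L) {
    replicate(nSubjects, matrix(rnorm(nLat * nLat), nLat), simplify = FALSE)
}

# Small toy resolution setup: 10 vertices, 2 ROIs, asymmetric smearing.
toyResolution <- function() {
    R <- diag(10)
    R[1:5, 6:10] <- 0.08   # b leaks into a
    R[6:10, 1:5] <- 0.25   # a leaks into b, more strongly
    resolutionInputs(R, list(a = 1:5, b = 6:10))
}
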