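## Simulation scenarios comparing the multidimensional and unidimensional
## metrics across SNR, trial count, vertex count and transformation
## sparsity.

#' Scenario 1: two independent random patterns
#'
#' Draws two independent standard-normal pattern matrices (no relationship
#' of any kind); used to check that neither metric produces spurious
#' connectivity.
#'
#' @param spec a [scenarioSpec()] with `scenario = "null"`.
#' @return List with elements `X` and `Y`.
#' @export
genNull <- function(spec) {
    withr::with_seed(spec@seed, {
        list(X = matrix(stats::rnorm(spec@nTrials * spec@nX), spec@nTrials),
             Y = matrix(stats::rnorm(spec@nTrials * spec@nY), spec@nTrials))
    })
}

#' Scenario 2: a unidimensional (shared-amplitude) dependency
#'
#' One standard-normal per-trial amplitude `x` is replicated across all
#' vertices of region X; region Y carries `constant * x` across its
#' vertices. Independent Gaussian noise of standard deviation
#' `10^noiseStdPow` is added to every vertex of both regions.
#'
#' @param spec a [scenarioSpec()] with `scenario = "unidimensional"`.
#' @return List with elements `X` and `Y`.
#' @export
genUnidimensional <- function(spec) {
    withr::with_seed(spec@seed, {
        x <- stats::rnorm(spec@nTrials)
        sd <- 10^spec@noiseStdPow
        X <- matrix(x, spec@nTrials, spec@nX) +
            sd * matrix(stats::rnorm(spec@nTrials * spec@nX), spec@nTrials)
        Y <- matrix(spec@constant * x, spec@nTrials, spec@nY) +
            sd * matrix(stats::rnorm(spec@nTrials * spec@nY), spec@nTrials)
        list(X = X, Y = Y)
    })
}

#' Scenario 3: a multidimensional (linear-map) dependency
#'
#' Region X is standard normal; Y is `X %*% T` plus Gaussian noise of
#' standard deviation `10^noiseStdPow`. The transformation `T` has
#' `round(sparsityFrac * nX * nY)` non-zero entries at uniformly random
#' positions, with standard-normal values.
#'
#' @param spec a [scenarioSpec()] with `scenario = "multidimensional"`.
#' @return List with elements `X`, `Y` and `T` (the true transformation).
#' @export
genMultidimensional <- function(spec) {
    if (spec@sparsityFrac <= 0 || spec@sparsityFrac > 1)
        stop("'sparsityFrac' must lie in (0, 1]")
    withr::with_seed(spec@seed, {
        X <- matrix(stats::rnorm(spec@nTrials * spec@nX), spec@nTrials)
        nzo <- max(1L, round(spec@sparsityFrac * spec@nX * spec@nY))
        Tm <- matrix(0, spec@nX, spec@nY)
        pos <- sample.int(spec@nX * spec@nY, nzo)
        Tm[pos] <- stats::rnorm(nzo)
        E <- 10^spec@noiseStdPow *
            matrix(stats::rnorm(spec@nTrials * spec@nY), spec@nTrials)
        list(X = X, Y = X %*% Tm + E, T = Tm)
    })
}

#' SNR in dB implied by a noise-std exponent
#'
#' The simulated signal standard deviation is fixed at 1 and the noise
#' standard deviation is `10^noiseStdPow`, so
#' `SNR_dB = 20 log10(1 / 10^noiseStdPow) = -20 * noiseStdPow`.
#'
#' @param noiseStdPow base-10 exponent(s) of the noise standard deviation.
#' @return SNR value(s) in dB.
#' @examples
#' snrDb(c(-2, 0, 1.5))  # 40, 0, -30
#' @export
snrDb <- function(noiseStdPow) -20 * noiseStdPow

## Default parameter grids of the three scenarios.
.scenarioDefaults <- function(scenario) {
    switch(scenario,
        null = list(nTrials = c(30L, 50L, 100L, 150L, 300L),
                    stdPow = NA_real_),
        unidimensional = list(nTrials = c(30L, 50L, 100L),
                              stdPow = c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5)),
        multidimensional = list(nTrials = c(30L, 50L, 100L),
                                stdPow = c(-2, -1.5, -1, -0.5, 0, 0.5, 1,
                                           1.5, 2)))
}

#' Run a simulation scenario over its parameter grid
#'
#' For every grid cell (noise level x trial count x vertex-count pair),
#' `nReps` independent datasets are generated and scored with the
#' multidimensional ([bidirectionalEV()]) and/or unidimensional ([udcEV()])
#' metric on the same data. When `constants` (unidimensional scenario) or
#' `sparsity` (multidimensional scenario) holds several values, the
#' repetitions cycle round-robin through them, so each cell mean is the
#' grid-averaged quantity. The multidimensional default is a dense
#' transformation (`sparsity = 1`): the headline SNR curves assume every
#' target vertex carries signal (a sparse map leaves some target vertices
#' as pure noise, which caps the attainable mean EV well below 1); pass
#' `sparsity = seq(0.1, 1, 0.1)` to explore the sparsity dimension. The
#' vertex sub-sampling step is bypassed: simulated vertices are generated
#' directly at the target dimensionality and carry no redundancy.
#'
#' @param scenario `"null"`, `"unidimensional"` or `"multidimensional"`.
#' @param nTrialsGrid trial counts (scenario-specific defaults: 30/50/100,
#'   plus 150/300 for the null scenario).
#' @param verticesGrid list of `c(nX, nY)` pairs (default `(5,5)` and
#'   `(15,15)`).
#' @param stdPowGrid noise-std exponents (scenario defaults; ignored for the
#'   null scenario).
#' @param constants scaling constants averaged over in scenario 2.
#' @param sparsity sparsity fraction(s) of the scenario-3 transformation
#'   (dense by default; a vector is averaged over round-robin).
#' @param nReps repetitions per cell (100 in the full design).
#' @param cfg a [cvConfig()].
#' @param methods which metrics to score.
#' @param seed master seed; every repetition derives its own sub-seed.
#' @return A data.frame with one row per (cell, method): columns scenario,
#'   method, nTrials, nX, nY, stdPow, snrDb, meanEV, sdEV, nReps.
#' @examples
#' runScenarioGrid("null", nTrialsGrid = 30, verticesGrid = list(c(5, 5)),
#'                 nReps = 3, cfg = cvConfig(nFolds = 5, seed = 1))
#' @export
runScenarioGrid <- function(scenario = c("null", "unidimensional",
                                         "multidimensional"),
                            nTrialsGrid = NULL,
                            verticesGrid = list(c(5L, 5L), c(15L, 15L)),
                            stdPowGrid = NULL,
                            constants = c(-2, -1.5, -1, -0.5, 0.01, 0.5, 1,
                                          1.5, 2),
                            sparsity = 1,
                            nReps = 100L, cfg = cvConfig(),
                            methods = c("MDPC", "UDC"), seed = 0L) {
    scenario <- match.arg(scenario)
    methods <- match.arg(methods, several.ok = TRUE)
    defaults <- .scenarioDefaults(scenario)
    nTrialsGrid <- as.integer(nTrialsGrid %||% defaults$nTrials)
    stdPowGrid <- stdPowGrid %||% defaults$stdPow
    gen <- switch(scenario, null = genNull,
                  unidimensional = genUnidimensional,
                  multidimensional = genMultidimensional)
    rows <- list()
    counter <- 0L
    for (sp in stdPowGrid) {
        for (nt in nTrialsGrid) {
            for (vx in verticesGrid) {
                ev <- matrix(NA_real_, nReps, length(methods),
                             dimnames = list(NULL, methods))
                for (r in seq_len(nReps)) {
                    counter <- counter + 1L
                    spec <- scenarioSpec(
                        scenario, nTrials = nt, nX = vx[1L], nY = vx[2L],
                        noiseStdPow = if (is.na(sp)) 0 else sp,
                        constant = constants[(r - 1L) %% length(constants) + 1L],
                        sparsityFrac = sparsity[(r - 1L) %% length(sparsity) + 1L],
                        seed = .childSeed(seed, counter))
                    d <- gen(spec)
                    if ("MDPC" %in% methods)
                        ev[r, "MDPC"] <- bidirectionalEV(d$X, d$Y, cfg)
                    if ("UDC" %in% methods)
                        ev[r, "UDC"] <- udcEV(d$X, d$Y, cfg)
                }
                for (m in methods) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        scenario = scenario, method = m, nTrials = nt,
                        nX = vx[1L], nY = vx[2L], stdPow = sp,
                        snrDb = if (is.na(sp)) NA_real_ else snrDb(sp),
                        meanEV = mean(ev[, m]), sdEV = stats::sd(ev[, m]),
                        nReps = nReps)
                }
            }
        }
    }
    do.call(rbind, rows)
}
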