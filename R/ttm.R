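## Temporal transformation matrices: scanning all latency pairs of an ROI
## pair with the pattern-transformation metric, block averaging, and
## assembly of the all-pairs inter-regional connectivity matrix.

#' Latency grid for TTM construction
#'
#' Half-open grid `[tMin, tMax)` in steps of `stepMs`. The default analysis
#' axis, `latencyGrid(-100, 500, 25)`, has 24 points from -100 to 475 ms.
#'
#' @param tMinMs,tMaxMs grid limits in ms (`tMin < tMax`; `tMax` excluded).
#' @param stepMs positive step in ms.
#' @return Integer vector of latencies.
#' @examples
#' length(latencyGrid(-100, 500, 25))  # 24
#' @export
latencyGrid <- function(tMinMs, tMaxMs, stepMs) {
    if (stepMs <= 0) stop("'stepMs' must be positive")
    if (tMinMs >= tMaxMs) stop("'tMinMs' must be below 'tMaxMs'")
    n <- ceiling((tMaxMs - tMinMs) / stepMs)
    as.integer(seq.int(tMinMs, by = stepMs, length.out = n))
}

## Extract the trials x vertices slice of an epochs object at one latency,
## optionally averaging a bin of width binMs centred forward from the
## latency (single sample by default).
.epochSlice <- function(ep, latency, binMs = 0L) {
    lats <- ep@latenciesMs
    if (binMs > 0L) {
        sel <- which(lats >= latency & lats < latency + binMs)
        if (!length(sel)) stop("no samples in bin at ", latency, " ms")
        if (length(sel) == 1L) return(ep@values[, , sel])
        return(apply(ep@values[, , sel, drop = FALSE], c(1, 2), mean))
    }
    i <- match(latency, lats)
    ep@values[, , i]
}

#' Compute the temporal transformation matrix of an ROI pair
#'
#' Scores every pair of grid latencies: cell `(i, j)` is the clamped,
#' direction-averaged EV ([bidirectionalEV()], or [udcEV()] for
#' `method = "UDC"`) between ROI Y's pattern at row latency `i` and ROI X's
#' pattern at column latency `j`. When a sub-sampling configuration is
#' given, each ROI is reduced independently at each latency with
#' [subsampleVertices()] before scoring; otherwise patterns are standardised
#' inside the metric only.
#'
#' @param xEpochs,yEpochs [ROIEpochs-class] objects with equal trial counts.
#' @param grid latency vector; every value must be present in both epochs'
#'   latency axes.
#' @param cfg a [cvConfig()]; its seed is shared by all cells, making the
#'   TTM of `(Y, X)` exactly the transpose of the TTM of `(X, Y)`.
#' @param method `"MDPC"` or `"UDC"`.
#' @param subsampleCfg optional list with elements `kMin`, `kMax`,
#'   `fallback`, `seed` (missing elements take [subsampleVertices()]
#'   defaults); `NULL` disables sub-sampling.
#' @param binMs average the samples in a `[t, t + binMs)` window at each
#'   grid latency instead of taking the single sample at `t` (0 = single
#'   sample, the default).
#' @return A [TTM-class].
#' @export
computeTTM <- function(xEpochs, yEpochs, grid = latencyGrid(-100, 500, 25),
                       cfg = cvConfig(), method = c("MDPC", "UDC"),
                       subsampleCfg = NULL, binMs = 0L) {
    method <- match.arg(method)
    if (dim(xEpochs@values)[1L] != dim(yEpochs@values)[1L])
        stop("epoch trial counts differ between the two ROIs")
    for (ep in list(xEpochs, yEpochs)) {
        missing <- setdiff(grid, ep@latenciesMs)
        if (length(missing) && binMs == 0L)
            stop("grid latencies absent from ROI '", ep@roiLabel, "': ",
                 paste(missing, collapse = ", "))
    }
    reduce <- function(slice) {
        if (is.null(subsampleCfg)) return(slice)
        sc <- subsampleCfg
        subsampleVertices(slice,
                          kMin = sc$kMin %||% 5L, kMax = sc$kMax %||% 13L,
                          fallback = sc$fallback %||% 10L,
                          seed = sc$seed %||% 0L)@reduced@values
    }
    xSlices <- lapply(grid, function(t) reduce(.epochSlice(xEpochs, t, binMs)))
    ySlices <- lapply(grid, function(t) reduce(.epochSlice(yEpochs, t, binMs)))
    score <- if (method == "MDPC") bidirectionalEV else udcEV
    nL <- length(grid)
    vals <- matrix(NA_real_, nL, nL)
    for (i in seq_len(nL))
        for (j in seq_len(nL))
            vals[i, j] <- score(xSlices[[j]], ySlices[[i]], cfg)
    new("TTM", values = vals, latenciesMs = as.integer(grid),
        roiPair = c(xEpochs@roiLabel, yEpochs@roiLabel), method = method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average TTMs across blocks
#'
#' Cell-wise arithmetic mean of TTMs computed per experimental block (the
#' standard way to handle a condition recorded in several blocks before a
#' between-condition comparison). Inputs are already clamped, so the mean
#' stays in `[0, 1]` and clamping is not re-applied.
#'
#' @param ttms list of [TTM-class] objects with identical grids, ROI pair
#'   and method.
#' @return A [TTM-class].
#' @export
averageBlocks <- function(ttms) {
    if (!length(ttms)) stop("empty TTM list")
    ref <- ttms[[1L]]
    for (t in ttms[-1L]) {
        if (!identical(t@latenciesMs, ref@latenciesMs))
            stop("TTMs have mismatched latency grids")
        if (!identical(t@roiPair, ref@roiPair) ||
            !identical(t@method, ref@method))
            stop("TTMs must share ROI pair and method")
    }
    vals <- Reduce(`+`, lapply(ttms, function(t) t@values)) / length(ttms)
    initialize(ref, values = vals)
}

#' Equalise trial counts by seeded random sub-sampling
#'
#' Convenience for balancing trial numbers across conditions before TTM
#' computation, so connectivity estimates are not biased by unequal trial
#' counts.
#'
#' @param epochs an [ROIEpochs-class].
#' @param nTrials target trial count (at most the available trials).
#' @param seed seed for the draw.
#' @return The epochs restricted to the sampled trials.
#' @export
equaliseTrials <- function(epochs, nTrials, seed = 0L) {
    n <- dim(epochs@values)[1L]
    if (nTrials > n)
        stop("cannot sample ", nTrials, " trials from ", n)
    keep <- sort(withr::with_seed(seed, sample.int(n, nTrials)))
    initialize(epochs, values = epochs@values[keep, , , drop = FALSE])
}

## ---------------------------------------------------------------------------
## Inter-regional connectivity matrix
## ---------------------------------------------------------------------------

#' Assemble TTMs of all ROI pairs into an inter-regional connectivity matrix
#'
#' Builds the standard all-pairs summary layout: a block matrix over the
#' ROIs in which the block below the diagonal at (row ROI `b`, column ROI
#' `a`) holds the MDPC TTM of the pair `(a, b)` (computed with X = `a`,
#' Y = `b` where `a` precedes `b` in `roiOrder`), and the block above the
#' diagonal at (row `a`, column `b`) holds the transposed UDC TTM of the
#' same pair. Diagonal blocks are `NA`.
#'
#' @param ttms list of [TTM-class] objects covering every unordered ROI pair
#'   for both methods; each TTM's stored `roiPair` identifies its block.
#' @param roiOrder optional explicit ROI ordering along the block axes.
#' @return An [ICM-class].
#' @export
assembleICM <- function(ttms, roiOrder = NULL) {
    pairs <- t(vapply(ttms, function(t) t@roiPair, character(2)))
    labs <- roiOrder %||% unique(as.vector(t(pairs)))
    nR <- length(labs)
    lats <- ttms[[1L]]@latenciesMs
    nL <- length(lats)
    key <- function(a, b, m) paste(a, b, m, sep = "\r")
    lut <- new.env(parent = emptyenv())
    for (t in ttms) {
        if (!identical(t@latenciesMs, lats))
            stop("all TTMs must share one latency grid")
        assign(key(t@roiPair[1L], t@roiPair[2L], t@method), t, envir = lut)
    }
    fetch <- function(a, b, m) {
        k1 <- key(a, b, m)
        if (exists(k1, envir = lut)) return(get(k1, envir = lut)@values)
        k2 <- key(b, a, m)  # bidirectional metric: swapped pair = transpose
        if (exists(k2, envir = lut)) return(t(get(k2, envir = lut)@values))
        stop("missing ", m, " TTM for ROI pair (", a, ", ", b, ")")
    }
    big <- matrix(NA_real_, nR * nL, nR * nL)
    block <- function(i) seq.int((i - 1L) * nL + 1L, i * nL)
    for (i in seq_len(nR - 1L)) {
        for (j in seq.int(i + 1L, nR)) {
            a <- labs[i]; b <- labs[j]
            big[block(j), block(i)] <- fetch(a, b, "MDPC")
            big[block(i), block(j)] <- t(fetch(a, b, "UDC"))
        }
    }
    new("ICM", values = big, roiLabels = labs, latenciesMs = lats)
}

#' Extract one TTM from an assembled ICM
#'
#' Inverse of [assembleICM()]: returns the stored TTM of an ROI pair
#' bit-exactly (undoing the transposition of upper-triangle UDC blocks).
#'
#' @param icm an [ICM-class].
#' @param roiX,roiY the pair, in the order it was computed (X, then Y).
#' @param method `"MDPC"` or `"UDC"`.
#' @return A [TTM-class].
#' @export
extractTTM <- function(icm, roiX, roiY, method = c("MDPC", "UDC")) {
    method <- match.arg(method)
    labs <- icm@roiLabels
    i <- match(roiX, labs); j <- match(roiY, labs)
    if (is.na(i) || is.na(j)) stop("unknown ROI label")
    if (i == j) stop("no TTM is stored for a region with itself")
    nL <- length(icm@latenciesMs)
    block <- function(k) seq.int((k - 1L) * nL + 1L, k * nL)
    a <- min(i, j); b <- max(i, j)  # canonical order used at assembly
    vals <- if (method == "MDPC") icm@values[block(b), block(a)]
            else t(icm@values[block(a), block(b)])
    ## stored orientation is X = labs[a], Y = labs[b]; transpose if asked
    ## for the swapped orientation
    if (i != a) vals <- t(vals)
    new("TTM", values = vals, latenciesMs = icm@latenciesMs,
        roiPair = c(roiX, roiY), method = method)
}
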