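## ROI-to-ROI leakage indices from a source-resolution matrix: random
## non-homogeneous activations propagated through point-spread functions.

## One batch of random non-homogeneous activation vectors over the source
## vertices: per-vertex amplitudes uniform in (0.5, 1.5), all positive so
## spatial non-homogeneity cannot cancel by sign. Returns nSrc x nReps.
.drawActivations <- function(nSrc, nReps, seed) {
    withr::with_seed(seed,
        matrix(stats::runif(nSrc * nReps, 0.5, 1.5), nSrc, nReps))
}

#' Monte-Carlo leakage from one ROI into another
#'
#' Per repetition, a random non-homogeneous activation over the source
#' ROI's vertices is propagated through the source vertices' point-spread
#' functions (the corresponding columns of the resolution matrix), and the
#' absolute values of the resulting estimate at the destination ROI's
#' vertices are summed. The returned index is the average over `nReps`
#' repetitions.
#'
#' @param inputs a [resolutionInputs()].
#' @param srcRoi,dstRoi ROI labels (must be present in the inputs).
#' @param nReps Monte-Carlo repetitions (default 100).
#' @param seed seed for the activation draws.
#' @return Single non-negative leakage value (unnormalised).
#' @export
psfLeakage <- function(inputs, srcRoi, dstRoi, nReps = 100L, seed = 0L) {
    idx <- inputs@roiVertexIndices
    for (lab in c(srcRoi, dstRoi))
        if (!lab %in% names(idx)) stop("unknown ROI label: ", lab)
    A <- .drawActivations(length(idx[[srcRoi]]), nReps, seed)
    est <- inputs@resolutionMatrix[idx[[dstRoi]], idx[[srcRoi]],
                                   drop = FALSE] %*% A
    mean(colSums(abs(est)))
}

#' Normalised ROI-by-ROI leakage matrix
#'
#' Computes the Monte-Carlo leakage index for every ordered ROI pair and
#' normalises each column by that ROI's self-leakage, so that column `i`
#' shows how much every ROI leaks into ROI `i` relative to ROI `i`'s
#' leakage into itself (diagonal = 1). Each value is additionally labelled
#' low / low-medium / medium / medium-high / high in 0.2-wide bins.
#'
#' @param inputs a [resolutionInputs()] with at least two ROIs.
#' @param nReps Monte-Carlo repetitions per source ROI.
#' @param seed master seed; each source ROI draws its own activations from
#'   a derived sub-seed, so the matrix does not depend on ROI iteration
#'   order.
#' @return A [LeakageMatrix-class].
#' @examples
#' R <- diag(6) + 0.05
#' li <- resolutionInputs(R, list(a = 1:3, b = 4:6))
#' leakageMatrix(li, nReps = 20)
#' @export
leakageMatrix <- function(inputs, nReps = 100L, seed = 0L) {
    labs <- names(inputs@roiVertexIndices)
    if (length(labs) < 2L) stop("need at least 2 ROIs")
    nR <- length(labs)
    raw <- matrix(NA_real_, nR, nR, dimnames = list(labs, labs))
    for (s in seq_len(nR)) {
        src <- labs[s]
        I <- inputs@roiVertexIndices[[src]]
        A <- .drawActivations(length(I), nReps, .childSeed(seed, s))
        est <- inputs@resolutionMatrix[, I, drop = FALSE] %*% A
        for (d in seq_len(nR)) {
            J <- inputs@roiVertexIndices[[labs[d]]]
            raw[s, d] <- mean(colSums(abs(est[J, , drop = FALSE])))
        }
    }
    self <- diag(raw)
    if (any(self == 0)) stop("zero self-leakage for ROI(s): ",
                             paste(labs[self == 0], collapse = ", "))
    norm <- sweep(raw, 2L, self, "/")
    new("LeakageMatrix", values = norm, roiLabels = labs,
        category = matrix(leakageCategory(pmin(norm, 1)), nR, nR,
                          dimnames = dimnames(norm)))
}

#' Categorise a leakage value
#'
#' Bins a normalised leakage value in `[0, 1]` into low `[0, 0.2)`,
#' low-medium `[0.2, 0.4)`, medium `[0.4, 0.6)`, medium-high `[0.6, 0.8)`
#' or high `[0.8, 1]`.
#'
#' @param value numeric value(s) in `[0, 1]`.
#' @return Character label(s).
#' @examples
#' leakageCategory(c(0.1, 0.45, 1))
#' @export
leakageCategory <- function(value) {
    if (any(value < 0 | value > 1))
        stop("leakage values must lie in [0, 1]")
    labs <- c("low", "low-medium", "medium", "medium-high", "high")
    labs[pmin(5L, findInterval(value, c(0, 0.2, 0.4, 0.6, 0.8)))]
}
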