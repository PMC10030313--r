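## Group-level statistics: paired t-maps over subjects' TTMs and
## cluster-based permutation tests with sign-flip randomisation, plus the
## small-cluster size filter.

## Sentinel for degenerate zero-variance cells (t would be infinite).
.T_CAP <- 1e6

## Coerce a per-subject list of TTMs (or matrices) to an n_subj x n_cells
## matrix of vectorised values, checking grids agree.
.stackTTMs <- function(ttms) {
    mats <- lapply(ttms, function(t) if (is(t, "TTM")) t@values else as.matrix(t))
    d <- dim(mats[[1L]])
    for (m in mats[-1L])
        if (!identical(dim(m), d)) stop("subjects' TTM grids differ")
    list(values = do.call(rbind, lapply(mats, as.vector)), dim = d)
}

#' Cell-wise paired t statistics between two sets of subject TTMs
#'
#' @param ttmsA,ttmsB lists with one TTM (or plain matrix) per subject, in
#'   the same subject order; the statistic tests A minus B.
#' @return Matrix of paired t values, same shape as the TTMs. Cells with
#'   zero difference variance get a capped sentinel (+/- 1e6, 0 when the
#'   mean difference is also zero) with a warning.
#' @export
pairedTMap <- function(ttmsA, ttmsB) {
    if (length(ttmsA) != length(ttmsB))
        stop("condition A and B must have the same subjects")
    n <- length(ttmsA)
    if (n < 2L) stop("need at least 2 subjects for a paired t statistic")
    a <- .stackTTMs(ttmsA); b <- .stackTTMs(ttmsB)
    if (!identical(a$dim, b$dim)) stop("condition grids differ")
    D <- a$values - b$values
    m <- colMeans(D)
    v <- pmax(.colVars(D), 0)
    t <- m / sqrt(v / n)
    bad <- !is.finite(t) | abs(t) > .T_CAP
    if (any(bad)) {
        warning(sum(bad), " cell(s) have (near-)zero difference variance; ",
                "t capped at +/-", format(.T_CAP))
        t[bad] <- sign(m[bad]) * .T_CAP
    }
    matrix(t, a$dim[1L], a$dim[2L])
}

## Connected components (4-neighbour adjacency) of the TRUE cells of a
## logical matrix given as linear indices. Union-find over the supra-
## threshold cells only.
.components <- function(maskIdx, nRow) {
    m <- length(maskIdx)
    if (!m) return(list())
    parent <- seq_len(m)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    link <- function(nb) {
        for (i in which(!is.na(nb))) {
            a <- find(i); b <- find(nb[i])
            if (a != b) parent[a] <<- b
        }
    }
    r <- (maskIdx - 1L) %% nRow + 1L
    down <- maskIdx + 1L
    down[r == nRow] <- NA_integer_
    link(match(down, maskIdx))          # vertical neighbours
    link(match(maskIdx + nRow, maskIdx))  # horizontal neighbours
    roots <- vapply(seq_len(m), find, integer(1))
    unname(split(maskIdx, roots))
}

## Maximum cluster statistic (count or summed |t|) of one thresholded map,
## for the permutation null.
.maxClusterStat <- function(tvec, thr, nRow, stat) {
    idx <- which(tvec > thr)
    if (!length(idx)) return(0)
    comps <- .components(idx, nRow)
    if (stat == "count") max(lengths(comps))
    else max(vapply(comps, function(ix) sum(tvec[ix]), numeric(1)))
}

#' Cluster-based permutation test on a TTM contrast
#'
#' Compares two within-subject conditions across participants. Cell-wise
#' paired t statistics are thresholded at the two-tailed `cellAlpha`
#' quantile of the t distribution; supra-threshold cells of each sign are
#' grouped into 4-connected clusters; and the null distribution of the
#' maximal cluster statistic in each tail is built from `nPerm` random
#' sign flips of the per-subject difference maps (exact for a paired
#' design). Each observed cluster's p-value is the proportion of
#' permutation maxima in its tail at least as large as its statistic, and
#' it is called significant when that proportion falls in the upper
#' `cellAlpha / 2` tail (2.5% per direction at the default 0.05).
#'
#' @param ttmsA,ttmsB per-subject TTM lists (same subject order).
#' @param nPerm number of sign-flip permutations (default 5000).
#' @param cellAlpha two-tailed cell-level alpha for the t threshold, also
#'   reused as the overall two-tailed cluster alpha.
#' @param clusterStat `"mass"` (summed `|t|` over the cluster, the
#'   default; continuous, so the permutation p-values are finely graded and
#'   the test is calibrated) or `"count"` (cluster size in cells; its
#'   discreteness makes the test noticeably conservative).
#' @param seed seed for the sign flips.
#' @return A [ClusterStatResult-class].
#' @export
clusterPermutationTest <- function(ttmsA, ttmsB, nPerm = 5000L,
                                   cellAlpha = 0.05,
                                   clusterStat = c("mass", "count"),
                                   seed = 0L) {
    clusterStat <- match.arg(clusterStat)
    if (nPerm < 100L) stop("'nPerm' must be at least 100")
    if (cellAlpha <= 0 || cellAlpha >= 1)
        stop("'cellAlpha' must lie in (0, 1)")
    a <- .stackTTMs(ttmsA); b <- .stackTTMs(ttmsB)
    if (!identical(a$dim, b$dim)) stop("condition grids differ")
    if (length(ttmsA) != length(ttmsB))
        stop("condition A and B must have the same subjects")
    n <- length(ttmsA)
    if (n < 3L)
        stop("need at least 3 subjects for the thresholded paired design")
    D <- a$values - b$values
    nRow <- a$dim[1L]
    thr <- stats::qt(1 - cellAlpha / 2, df = n - 1L)

    tObs <- as.vector(pairedTMap(ttmsA, ttmsB))

    ## Observed clusters, per tail.
    statOf <- function(ix, tv) {
        if (clusterStat == "count") length(ix) else sum(abs(tv[ix]))
    }
    posC <- .components(which(tObs > thr), nRow)
    negC <- .components(which(tObs < -thr), nRow)
    clusters <- c(posC, negC)
    signs <- c(rep("A_gt_B", length(posC)), rep("B_gt_A", length(negC)))
    obsStat <- vapply(clusters, statOf, numeric(1), tv = tObs)

    ## Vectorised sign-flip null: sign flips do not change the squared
    ## differences, so the permutation t-maps come from one matrix product.
    S <- withr::with_seed(seed,
        matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
    M <- (S %*% D) / n
    ss <- colSums(D * D)
    varP <- (rep(ss, each = nPerm) - n * M * M) / (n - 1L)
    varP[varP <= 0] <- NA_real_
    tP <- M / sqrt(varP / n)
    tP[is.na(tP)] <- 0
    nullPos <- numeric(nPerm)
    nullNeg <- numeric(nPerm)
    for (p in seq_len(nPerm)) {
        tv <- tP[p, ]
        nullPos[p] <- .maxClusterStat(tv, thr, nRow, clusterStat)
        nullNeg[p] <- .maxClusterStat(-tv, thr, nRow, clusterStat)
    }
    pvals <- numeric(length(clusters))
    for (i in seq_along(clusters)) {
        null <- if (signs[i] == "A_gt_B") nullPos else nullNeg
        pvals[i] <- mean(null >= obsStat[i])
    }
    new("ClusterStatResult",
        tMap = matrix(tObs, a$dim[1L], a$dim[2L]),
        clusters = clusters, clusterP = pvals, sign = signs,
        significant = pvals <= cellAlpha / 2,
        keptAfterSizeFilter = rep(TRUE, length(clusters)),
        tThreshold = thr, nPerm = as.integer(nPerm),
        clusterStat = clusterStat)
}

#' Filter out small clusters
#'
#' Marks clusters whose cell count exceeds `round(frac * gridSize^2)` as
#' kept; smaller ones are flagged out as possibly spurious. At the standard
#' settings (`frac = 0.02` on a 24-point axis) the minimum kept size is
#' 12 cells.
#'
#' @param result a [ClusterStatResult-class].
#' @param frac fraction of the total TTM size, in `[0, 1]`.
#' @param gridSize number of latencies along one TTM axis.
#' @return The result with `keptAfterSizeFilter` updated.
#' @export
sizeFilter <- function(result, frac = 0.02,
                       gridSize = nrow(result@tMap)) {
    if (frac < 0 || frac > 1) stop("'frac' must lie in [0, 1]")
    minSize <- round(frac * gridSize^2)
    kept <- lengths(result@clusters) > minSize
    initialize(result, keptAfterSizeFilter = kept)
}
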