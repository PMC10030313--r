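## Spatial sub-sampling of redundant source vertices: k-means clustering of
## vertices over trials, elbow-based choice of the cluster count, and
## selection of the highest-variance vertex of each cluster. This is feature
## selection: the reduced matrix contains original (standardised) vertex
## columns, never linear mixtures.

.standardiseCols <- function(m, context = "vertex") {
    mu <- colMeans(m)
    sdv <- sqrt(.colVars(m))
    if (any(sdv == 0))
        stop("zero-variance ", context, " column(s): ",
             paste(which(sdv == 0), collapse = ", "),
             "; cannot standardise")
    .centerCols(m, mu) / rep(sdv, each = nrow(m))
}

#' Standardise a pattern matrix per vertex
#'
#' Demeans and variance-normalises each vertex column across trials, so that
#' every column has mean 0 and variance 1.
#'
#' @param P a [PatternMatrix-class] or numeric matrix.
#' @return An object of the same kind with standardised columns.
#' @export
standardisePattern <- function(P) {
    if (is(P, "PatternMatrix")) {
        initialize(P, values = .standardiseCols(P@values))
    } else {
        .standardiseCols(as.matrix(P))
    }
}

## k-means++ seeding: the first centre is a uniform draw, each further
## centre is drawn with probability proportional to its squared distance to
## the nearest centre already chosen. Spreads the seeds across separated
## groups, where plain random restarts routinely miss one.
.kmeansppCenters <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    chosen <- sample.int(n, 1L)
    centers[1L, ] <- x[chosen, ]
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in seq_len(k)[-1L]) {
        tot <- sum(d2)
        chosen <- if (tot > 0) sample.int(n, 1L, prob = d2 / tot)
                  else sample(which(!seq_len(n) %in% chosen), 1L)
        centers[j, ] <- x[chosen, ]
        d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
    centers
}

## Best of 10 k-means++ initialised runs over vertices (vertices are
## observations, trials are features); iter.max fixed at a robust default.
.kmeansFit <- function(vertexMat, k, seed) {
    withr::with_seed(seed, {
        best <- NULL
        for (r in 1:10) {
            fit <- tryCatch(
                stats::kmeans(vertexMat, centers = .kmeansppCenters(vertexMat, k),
                              iter.max = 300L),
                error = function(e) NULL)
            if (!is.null(fit) &&
                (is.null(best) || fit$tot.withinss < best$tot.withinss))
                best <- fit
        }
        if (is.null(best)) stop("k-means failed for k = ", k)
        best
    })
}

#' Choose the cluster count by the elbow of the distortion curve
#'
#' Runs k-means for every `k` in `[kMin, kMax]` over the vertices (vertices
#' as observations, trials as features) and locates the knee of the
#' within-cluster-distortion-versus-k curve by a maximum-curvature
#' (kneedle-style) criterion: both axes are normalised to `[0, 1]` and the
#' knee is the `k` maximising the gap between the normalised distortion drop
#' and the diagonal. When no knee stands out (the gap never exceeds
#' `sensitivity`, as for an essentially straight curve on unstructured
#' data), `fallback` is returned.
#'
#' @param P pattern matrix (trials x vertices); `n_vertices > kMax`.
#' @param kMin,kMax search range (defaults 5 and 13).
#' @param fallback value returned when no knee is detected (default 10).
#' @param seed seed for the k-means restarts.
#' @param sensitivity minimum normalised gap for a knee to count.
#' @return Integer cluster count.
#' @export
chooseKElbow <- function(P, kMin = 5L, kMax = 13L, fallback = 10L, seed = 0L,
                         sensitivity = 0.1) {
    m <- .pm(P)
    if (kMin < 1L || kMin > kMax)
        stop("need 1 <= kMin <= kMax")
    if (ncol(m) <= kMax)
        stop("n_vertices (", ncol(m), ") must exceed kMax (", kMax, ")")
    vm <- t(m)
    ks <- seq.int(kMin, kMax)
    inertia <- vapply(seq_along(ks), function(i)
        .kmeansFit(vm, ks[i], .childSeed(seed, i))$tot.withinss, numeric(1))
    rng <- max(inertia) - min(inertia)
    if (rng <= 0) return(as.integer(fallback))
    x <- (ks - kMin) / (kMax - kMin)
    y <- (inertia - min(inertia)) / rng        # decreasing, 1 -> 0
    gap <- (1 - y) - x                         # kneedle difference curve
    if (max(gap) < sensitivity) return(as.integer(fallback))
    as.integer(ks[which.max(gap)])
}

#' Cluster vertices by their activation profiles across trials
#'
#' Seeded k-means with vertices as observations and trials as features;
#' re-initialises (bounded retries) in the degenerate case of an empty
#' cluster.
#'
#' @param P pattern matrix (trials x vertices).
#' @param k number of clusters, `k <= n_vertices`.
#' @param seed seed controlling initialisation.
#' @return Integer cluster label per vertex; all `k` labels occupied.
#' @export
clusterVertices <- function(P, k, seed = 0L) {
    m <- .pm(P)
    if (k > ncol(m))
        stop("k (", k, ") exceeds the number of vertices (", ncol(m), ")")
    if (k == ncol(m)) return(seq_len(k))  # exact solution: all singletons
    vm <- t(m)
    for (try in 0:4) {
        fit <- .kmeansFit(vm, k, .childSeed(seed, try * 101L))
        labels <- as.integer(fit$cluster)
        if (length(unique(labels)) == k) return(labels)
    }
    stop("k-means produced an empty cluster in all retries (k = ", k, ")")
}

#' Pick the highest-variance representative of each cluster
#'
#' @param P pattern matrix the clustering was computed on.
#' @param labels integer cluster label per vertex (a valid partition).
#' @return Integer vector, one original-vertex index per cluster (ordered by
#'   cluster label); ties broken by the lowest index.
#' @export
pickRepresentatives <- function(P, labels) {
    m <- .pm(P)
    if (length(labels) != ncol(m))
        stop("'labels' must have one entry per vertex")
    vars <- .colVars(m)
    vapply(sort(unique(labels)), function(cl) {
        members <- which(labels == cl)
        members[which.max(vars[members])]
    }, integer(1))
}

#' Sub-sample an ROI's vertices to its informative representatives
#'
#' The full reduction pipeline for one ROI at one latency: standardise each
#' vertex column, choose the cluster count by the elbow criterion, cluster
#' the vertices, and keep the highest-variance vertex of each cluster. The
#' reduced matrix consists of original standardised columns at the
#' representative indices, so the genuine pattern space is preserved.
#'
#' @param P pattern matrix (trials x vertices), `n_vertices > kMax`.
#' @param kMin,kMax,fallback,seed,sensitivity passed to [chooseKElbow()].
#' @return A [SubsampleResult-class].
#' @examples
#' proto <- matrix(rnorm(50 * 3), 50, 3)
#' P <- proto[, rep(1:3, each = 10)] + 0.1 * matrix(rnorm(50 * 30), 50, 30)
#' subsampleVertices(P, kMin = 2, kMax = 8, seed = 1)
#' @export
subsampleVertices <- function(P, kMin = 5L, kMax = 13L, fallback = 10L,
                              seed = 0L, sensitivity = 0.1) {
    roi <- if (is(P, "PatternMatrix")) P@roiLabel else NA_character_
    lat <- if (is(P, "PatternMatrix")) P@latencyMs else NA_integer_
    s <- .standardiseCols(.pm(P))
    k <- chooseKElbow(s, kMin, kMax, fallback, seed, sensitivity)
    labels <- clusterVertices(s, k, seed)
    reps <- pickRepresentatives(s, labels)
    new("SubsampleResult", k = k, labels = labels,
        representativeIndices = reps,
        reduced = patternMatrix(s[, reps, drop = FALSE], roi, lat))
}
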