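#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core containers
## ---------------------------------------------------------------------------

#' PatternMatrix: trial-by-vertex activity of one ROI at one latency
#'
#' The elementary data unit of the pattern-transformation metric: a numeric
#' matrix whose rows are trials and whose columns are source vertices of a
#' single region of interest, optionally tagged with the ROI label and the
#' latency (in ms relative to stimulus onset) the patterns were taken at.
#'
#' @slot values numeric matrix, `n_trials x n_vertices`; no missing values,
#'   at least two trials and one vertex.
#' @slot roiLabel character scalar (may be `NA`).
#' @slot latencyMs integer scalar latency in milliseconds (may be `NA`).
#' @export
setClass("PatternMatrix",
         representation(values = "matrix",
                        roiLabel = "character",
                        latencyMs = "integer"),
         prototype(roiLabel = NA_character_, latencyMs = NA_integer_))

setValidity("PatternMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 2L) return("a PatternMatrix needs at least 2 trials (rows)")
    if (ncol(v) < 1L) return("a PatternMatrix needs at least 1 vertex (column)")
    if (anyNA(v) || any(!is.finite(v)))
        return("'values' must not contain missing or non-finite entries")
    if (length(object@roiLabel) != 1L) return("'roiLabel' must be length 1")
    if (length(object@latencyMs) != 1L) return("'latencyMs' must be length 1")
    TRUE
})

#' Construct a PatternMatrix
#'
#' @param values numeric matrix of activity, trials in rows, vertices in
#'   columns.
#' @param roiLabel optional ROI label.
#' @param latencyMs optional latency in ms.
#' @return A [PatternMatrix-class] object.
#' @examples
#' p <- patternMatrix(matrix(rnorm(40), 10, 4), roiLabel = "lATL")
#' dim(p)
#' @export
patternMatrix <- function(values, roiLabel = NA_character_,
                          latencyMs = NA_integer_) {
    new("PatternMatrix", values = as.matrix(values),
        roiLabel = as.character(roiLabel),
        latencyMs = as.integer(latencyMs))
}

#' Estimated linear pattern transformation between two ROIs
#'
#' Holds the ridge-regression coefficient matrix mapping the source ROI's
#' vertices onto the target ROI's vertices, together with the penalty it was
#' fitted with.
#'
#' @slot coefficients numeric matrix `n_source_vertices x n_target_vertices`.
#' @slot alpha non-negative ridge penalty.
#' @slot direction `"X_to_Y"` or `"Y_to_X"`.
#' @export
setClass("TransformEstimate",
         representation(coefficients = "matrix",
                        alpha = "numeric",
                        direction = "character"),
         prototype(direction = "X_to_Y"))

setValidity("TransformEstimate", function(object) {
    if (length(object@alpha) != 1L || object@alpha < 0)
        return("'alpha' must be a single non-negative number")
    if (!object@direction %in% c("X_to_Y", "Y_to_X"))
        return("'direction' must be 'X_to_Y' or 'Y_to_X'")
    TRUE
})

#' Per-vertex explained variance of a predicted pattern
#'
#' @slot perVertex explained variance per target vertex (may be negative).
#' @slot meanEV arithmetic mean of `perVertex` before any clamping.
#' @slot clamped whether zero-clamping has been applied to `meanEV`.
#' @export
setClass("EVScore",
         representation(perVertex = "numeric",
                        meanEV = "numeric",
                        clamped = "logical"),
         prototype(clamped = FALSE))

#' Cross-validation configuration for the transformation metric
#'
#' @slot nFolds outer folds (default 10).
#' @slot alphaGrid candidate ridge penalties, selected per outer fold by
#'   inner cross-validation.
#' @slot innerFolds inner folds used for penalty selection (default 5).
#' @slot seed integer seed controlling all fold shuffles.
#' @slot pooling `"fold"` (average of per-fold mean EVs, the default) or
#'   `"pooled"` (EV computed from residuals pooled across folds).
#' @export
setClass("CVConfig",
         representation(nFolds = "integer",
                        alphaGrid = "numeric",
                        innerFolds = "integer",
                        seed = "integer",
                        pooling = "character"))

setValidity("CVConfig", function(object) {
    if (object@nFolds < 2L) return("'nFolds' must be >= 2")
    if (length(object@alphaGrid) < 1L || any(object@alphaGrid < 0))
        return("'alphaGrid' must be non-empty and non-negative")
    if (object@innerFolds < 2L) return("'innerFolds' must be >= 2")
    if (!object@pooling %in% c("fold", "pooled"))
        return("'pooling' must be 'fold' or 'pooled'")
    TRUE
})

#' Construct a cross-validation configuration
#'
#' Defaults follow the metric's standard operating point: 10 outer folds, a
#' logarithmic penalty grid `10^-4 ... 10^4` applied to standardised data,
#' 5 inner folds for penalty selection, and an explicit seed so fold splits
#' are reproducible.
#'
#' @param nFolds,alphaGrid,innerFolds,seed,pooling see [CVConfig-class].
#' @return A [CVConfig-class] object.
#' @examples
#' cvConfig(nFolds = 5, seed = 42)
#' @export
cvConfig <- function(nFolds = 10L, alphaGrid = 10^seq(-4, 4, by = 1),
                     innerFolds = 5L, seed = 0L, pooling = c("fold", "pooled")) {
    new("CVConfig", nFolds = as.integer(nFolds), alphaGrid = alphaGrid,
        innerFolds = as.integer(innerFolds), seed = as.integer(seed),
        pooling = match.arg(pooling))
}

## ---------------------------------------------------------------------------
## Vertex sub-sampling
## ---------------------------------------------------------------------------

#' Result of k-means spatial sub-sampling of an ROI
#'
#' @slot k number of clusters (informative vertices retained).
#' @slot labels cluster membership per original vertex.
#' @slot representativeIndices index (into the original vertices) of the
#'   highest-variance member of each cluster.
#' @slot reduced the standardised pattern matrix restricted to the
#'   representative columns (feature selection: columns are original,
#'   standardised vertex time courses, never linear mixtures).
#' @export
setClass("SubsampleResult",
         representation(k = "integer",
                        labels = "integer",
                        representativeIndices = "integer",
                        reduced = "PatternMatrix"))

setValidity("SubsampleResult", function(object) {
    if (length(object@representativeIndices) != object@k)
        return("exactly one representative per cluster is required")
    if (anyDuplicated(object@representativeIndices))
        return("representative indices must be distinct")
    if (ncol(object@reduced@values) != object@k)
        return("reduced matrix must have k columns")
    TRUE
})

## ---------------------------------------------------------------------------
## Epochs and temporal transformation matrices
## ---------------------------------------------------------------------------

#' Multi-trial source-space epochs of one ROI
#'
#' A 3-D array of event-related source activity for one region of interest:
#' trials x vertices x time samples, with the sample latencies in ms.
#'
#' @slot values numeric 3-D array `n_trials x n_vertices x n_times`.
#' @slot latenciesMs strictly increasing integer latencies, one per time
#'   sample.
#' @slot roiLabel,subjectId,conditionLabel,blockId metadata (blockId may be
#'   `NA` when the condition is not split into blocks).
#' @export
setClass("ROIEpochs",
         representation(values = "array",
                        latenciesMs = "integer",
                        roiLabel = "character",
                        subjectId = "character",
                        conditionLabel = "character",
                        blockId = "character"),
         prototype(blockId = NA_character_))

setValidity("ROIEpochs", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("'values' must be a 3-D array")
    if (d[3L] != length(object@latenciesMs))
        return("third array dimension must match length(latenciesMs)")
    if (is.unsorted(object@latenciesMs, strictly = TRUE))
        return("'latenciesMs' must be strictly increasing")
    if (anyNA(object@values)) return("'values' must not contain NA")
    TRUE
})

#' Construct an ROIEpochs object
#'
#' @param values 3-D numeric array, trials x vertices x times.
#' @param latenciesMs integer latencies (ms), one per time sample.
#' @param roiLabel,subjectId,conditionLabel,blockId metadata strings.
#' @return An [ROIEpochs-class] object.
#' @export
roiEpochs <- function(values, latenciesMs, roiLabel = NA_character_,
                      subjectId = NA_character_,
                      conditionLabel = NA_character_,
                      blockId = NA_character_) {
    new("ROIEpochs", values = values, latenciesMs = as.integer(latenciesMs),
        roiLabel = as.character(roiLabel), subjectId = as.character(subjectId),
        conditionLabel = as.character(conditionLabel),
        blockId = as.character(blockId))
}

#' Temporal transformation matrix (TTM)
#'
#' Latency-by-latency grid of connectivity scores for one ROI pair. Cell
#' `(i, j)` holds the clamped, direction-averaged explained variance between
#' ROI Y at row latency `i` and ROI X at column latency `j`. The diagonal
#' shows zero-lag dependencies; the lower triangle (`t_Y < t_X`) dependencies
#' in which X leads, the upper triangle dependencies in which Y leads. The
#' two triangles are computed independently and a TTM need not be symmetric.
#'
#' @slot values numeric matrix in `[0, 1]`.
#' @slot latenciesMs common row/column latency axis (ms).
#' @slot roiPair `c(x_label, y_label)`.
#' @slot method `"MDPC"` or `"UDC"`.
#' @export
setClass("TTM",
         representation(values = "matrix",
                        latenciesMs = "integer",
                        roiPair = "character",
                        method = "character"))

setValidity("TTM", function(object) {
    d <- dim(object@values)
    if (d[1L] != d[2L]) return("a TTM must be square")
    if (d[1L] != length(object@latenciesMs))
        return("TTM dimension must match the latency axis")
    if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
        return("TTM values must lie in [0, 1] after clamping")
    if (length(object@roiPair) != 2L) return("'roiPair' must be length 2")
    if (!object@method %in% c("MDPC", "UDC"))
        return("'method' must be 'MDPC' or 'UDC'")
    TRUE
})

#' Inter-regional connectivity matrix (ICM)
#'
#' Block matrix collecting the TTMs (or t-maps) of all ROI pairs: blocks
#' below the block-diagonal hold the multidimensional (MDPC) TTMs, blocks
#' above it hold the transposed unidimensional (UDC) TTMs.
#'
#' @slot values the assembled `(n_roi * n_lat) x (n_roi * n_lat)` matrix;
#'   diagonal blocks are `NA` (a region is not paired with itself).
#' @slot roiLabels ROI ordering along the block axes.
#' @slot latenciesMs within-block latency axis.
#' @export
setClass("ICM",
         representation(values = "matrix",
                        roiLabels = "character",
                        latenciesMs = "integer"))

## ---------------------------------------------------------------------------
## Group statistics
## ---------------------------------------------------------------------------

#' Cluster-based permutation test result for a TTM contrast
#'
#' @slot tMap cell-wise paired t statistics (condition A minus B).
#' @slot clusters list of integer vectors; each vector holds the linear cell
#'   indices (column-major, as in the t-map matrix) of one 4-connected
#'   supra-threshold cluster.
#' @slot clusterP permutation p-value per cluster (proportion of permutation
#'   maxima at least as large as the observed cluster statistic, within the
#'   cluster's tail).
#' @slot sign `"A_gt_B"` or `"B_gt_A"` per cluster.
#' @slot significant logical per cluster at the per-tail alpha level.
#' @slot keptAfterSizeFilter logical per cluster; all `TRUE` until
#'   [sizeFilter()] is applied.
#' @slot tThreshold cell-level t threshold used to form clusters.
#' @slot nPerm number of sign-flip permutations.
#' @slot clusterStat `"count"` or `"mass"`.
#' @export
setClass("ClusterStatResult",
         representation(tMap = "matrix",
                        clusters = "list",
                        clusterP = "numeric",
                        sign = "character",
                        significant = "logical",
                        keptAfterSizeFilter = "logical",
                        tThreshold = "numeric",
                        nPerm = "integer",
                        clusterStat = "character"))

setValidity("ClusterStatResult", function(object) {
    n <- length(object@clusters)
    if (length(object@clusterP) != n || length(object@sign) != n ||
        length(object@keptAfterSizeFilter) != n ||
        length(object@significant) != n)
        return("per-cluster slots must all have one entry per cluster")
    if (n && (any(object@clusterP < 0) || any(object@clusterP > 1)))
        return("cluster p-values must lie in [0, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## Leakage
## ---------------------------------------------------------------------------

#' Resolution matrix plus ROI vertex assignment
#'
#' @slot resolutionMatrix square numeric matrix over all source vertices;
#'   column v is the point-spread function of a unit source at vertex v.
#' @slot roiVertexIndices named list of disjoint integer index sets, one per
#'   ROI.
#' @export
setClass("ResolutionInputs",
         representation(resolutionMatrix = "matrix",
                        roiVertexIndices = "list"))

setValidity("ResolutionInputs", function(object) {
    R <- object@resolutionMatrix
    if (nrow(R) != ncol(R)) return("resolution matrix must be square")
    idx <- object@roiVertexIndices
    if (is.null(names(idx)) || any(!nzchar(names(idx))))
        return("'roiVertexIndices' must be a named list")
    all_idx <- unlist(idx, use.names = FALSE)
    if (any(all_idx < 1L) || any(all_idx > nrow(R)))
        return("ROI vertex indices out of range of the resolution matrix")
    if (anyDuplicated(all_idx))
        return("ROI vertex index sets must be disjoint")
    TRUE
})

#' Construct ResolutionInputs
#'
#' @param resolutionMatrix square matrix, all vertices x all vertices.
#' @param roiVertexIndices named list mapping each ROI label to the integer
#'   indices of its vertices (disjoint across ROIs).
#' @return A [ResolutionInputs-class] object.
#' @export
resolutionInputs <- function(resolutionMatrix, roiVertexIndices) {
    new("ResolutionInputs", resolutionMatrix = as.matrix(resolutionMatrix),
        roiVertexIndices = lapply(roiVertexIndices, as.integer))
}

#' Normalised ROI-to-ROI leakage matrix
#'
#' Column `i` describes how much every ROI leaks into ROI `i`, relative to
#' ROI `i`'s leakage into itself (so the diagonal is 1 by construction).
#'
#' @slot values numeric `n_roi x n_roi`, columns normalised by self-leakage.
#' @slot roiLabels ROI labels along both axes.
#' @slot category matrix of labels among low / low-medium / medium /
#'   medium-high / high, binned at 0.2 steps.
#' @export
setClass("LeakageMatrix",
         representation(values = "matrix",
                        roiLabels = "character",
                        category = "matrix"))

setValidity("LeakageMatrix", function(object) {
    if (any(abs(diag(object@values) - 1) > 1e-12))
        return("diagonal must equal 1 after normalisation")
    if (any(object@values < 0))
        return("leakage values must be non-negative")
    TRUE
})

## ---------------------------------------------------------------------------
## Simulation and synthetic-dataset specifications
## ---------------------------------------------------------------------------

#' Specification of one simulated pattern pair
#'
#' Describes one draw of the three simulation scenarios: independent noise
#' patterns (`"null"`), a shared per-trial amplitude scaled between regions
#' (`"unidimensional"`), or a random sparse linear map between vertex
#' patterns (`"multidimensional"`). Noise is Gaussian with standard
#' deviation `10^noiseStdPow`; the signal standard deviation is fixed at 1,
#' so the SNR in dB is `-20 * noiseStdPow` (see [snrDb()]).
#'
#' @slot scenario one of `"null"`, `"unidimensional"`, `"multidimensional"`.
#' @slot nTrials,nX,nY problem sizes.
#' @slot noiseStdPow base-10 exponent of the noise standard deviation.
#' @slot constant scaling between the regions' shared amplitude
#'   (unidimensional scenario only).
#' @slot sparsityFrac fraction of non-zero entries of the transformation
#'   matrix, in (0, 1] (multidimensional scenario only).
#' @slot seed integer seed for the draw.
#' @export
setClass("ScenarioSpec",
         representation(scenario = "character",
                        nTrials = "integer",
                        nX = "integer",
                        nY = "integer",
                        noiseStdPow = "numeric",
                        constant = "numeric",
                        sparsityFrac = "numeric",
                        seed = "integer"))

setValidity("ScenarioSpec", function(object) {
    if (!object@scenario %in% c("null", "unidimensional", "multidimensional"))
        return("unknown scenario")
    if (object@nTrials < 2L) return("'nTrials' must be >= 2")
    if (object@scenario == "multidimensional" &&
        (object@sparsityFrac <= 0 || object@sparsityFrac > 1))
        return("'sparsityFrac' must lie in (0, 1]")
    TRUE
})

#' Construct a ScenarioSpec
#'
#' @param scenario,nTrials,nX,nY,noiseStdPow,constant,sparsityFrac,seed see
#'   [ScenarioSpec-class].
#' @return A [ScenarioSpec-class] object.
#' @examples
#' scenarioSpec("multidimensional", nTrials = 100, noiseStdPow = -2)
#' @export
scenarioSpec <- function(scenario = c("null", "unidimensional",
                                      "multidimensional"),
                         nTrials = 100L, nX = 5L, nY = 5L,
                         noiseStdPow = 0, constant = 1, sparsityFrac = 1,
                         seed = 0L) {
    new("ScenarioSpec", scenario = match.arg(scenario),
        nTrials = as.integer(nTrials), nX = as.integer(nX),
        nY = as.integer(nY), noiseStdPow = noiseStdPow, constant = constant,
        sparsityFrac = sparsityFrac, seed = as.integer(seed))
}

#' Specification of a synthetic multi-subject dataset
#'
#' Emulates the structure of an event-related EEG/MEG source-space study:
#' several subjects, several labelled ROIs with spatially redundant vertex
#' patterns (noisy copies of a small number of prototype time courses, as
#' produced by the limited spatial resolution of source estimates), two task
#' conditions of which the first may be split into blocks, and optional
#' injected cross-ROI dependencies at chosen latency pairs, either
#' unidimensional (a scaled shared amplitude) or multidimensional (a sparse
#' random linear map).
#'
#' @slot nSubjects number of subjects.
#' @slot rois named integer vector: vertices per ROI label.
#' @slot nTrials trials per condition and block.
#' @slot latenciesMs latency axis (ms).
#' @slot conditions condition labels (first may be blocked).
#' @slot nBlocks blocks per condition, aligned with `conditions`.
#' @slot links data.frame with columns src, dst, srcLatencyMs, dstLatencyMs,
#'   kind ("UD"/"MD"), effectStrength, sparsityFrac.
#' @slot noiseStd additive vertex noise standard deviation.
#' @slot redundancy number of prototype time courses per ROI.
#' @slot seed master seed.
#' @export
setClass("DatasetSpec",
         representation(nSubjects = "integer",
                        rois = "integer",
                        nTrials = "integer",
                        latenciesMs = "integer",
                        conditions = "character",
                        nBlocks = "integer",
                        links = "data.frame",
                        noiseStd = "numeric",
                        redundancy = "integer",
                        seed = "integer"))

setValidity("DatasetSpec", function(object) {
    if (is.null(names(object@rois))) return("'rois' must be named")
    if (length(object@nBlocks) != length(object@conditions))
        return("'nBlocks' must align with 'conditions'")
    lk <- object@links
    if (nrow(lk)) {
        need <- c("src", "dst", "srcLatencyMs", "dstLatencyMs", "kind",
                  "effectStrength", "sparsityFrac")
        if (!all(need %in% names(lk)))
            return(paste("links must have columns:", paste(need, collapse = ", ")))
        if (!all(lk$src %in% names(object@rois)) ||
            !all(lk$dst %in% names(object@rois)))
            return("links reference undeclared ROIs")
        if (!all(lk$srcLatencyMs %in% object@latenciesMs) ||
            !all(lk$dstLatencyMs %in% object@latenciesMs))
            return("link latencies must lie on the latency grid")
        if (!all(lk$kind %in% c("UD", "MD")))
            return("link kind must be 'UD' or 'MD'")
    }
    TRUE
})
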