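## Accessors and show methods. Slot access from user code should go through
## these, not `@`.

#' Extract the numeric values of a container
#'
#' @param x a PatternMatrix, TTM, ICM, ROIEpochs or LeakageMatrix.
#' @return The numeric matrix or array held by the object.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "PatternMatrix", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "TTM", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "ICM", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "ROIEpochs", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "LeakageMatrix", function(x) x@values)

#' Latency axis of a container
#'
#' @param x a TTM, ICM or ROIEpochs object.
#' @return Integer latencies in ms.
#' @export
setGeneric("latencies", function(x) standardGeneric("latencies"))

#' @rdname latencies
#' @export
setMethod("latencies", "TTM", function(x) x@latenciesMs)

#' @rdname latencies
#' @export
setMethod("latencies", "ICM", function(x) x@latenciesMs)

#' @rdname latencies
#' @export
setMethod("latencies", "ROIEpochs", function(x) x@latenciesMs)

#' ROI label(s) of a container
#'
#' @param x a PatternMatrix, ROIEpochs, TTM, ICM or LeakageMatrix.
#' @return Character label(s).
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "PatternMatrix", function(x) x@roiLabel)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "ROIEpochs", function(x) x@roiLabel)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "TTM", function(x) x@roiPair)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "ICM", function(x) x@roiLabels)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "LeakageMatrix", function(x) x@roiLabels)

#' @export
setMethod("dim", "PatternMatrix", function(x) dim(x@values))

#' @export
setMethod("dim", "TTM", function(x) dim(x@values))

#' @export
setMethod("dim", "ROIEpochs", function(x) dim(x@values))

#' Transformation coefficients
#'
#' @param object a [TransformEstimate-class].
#' @param ... unused.
#' @return The coefficient matrix (source vertices x target vertices).
#' @importFrom stats coef
#' @export
setMethod("coef", "TransformEstimate", function(object, ...) object@coefficients)

setMethod("show", "PatternMatrix", function(object) {
    d <- dim(object@values)
    cat(sprintf("PatternMatrix: %d trials x %d vertices", d[1L], d[2L]))
    if (!is.na(object@roiLabel)) cat(sprintf(" [%s]", object@roiLabel))
    if (!is.na(object@latencyMs)) cat(sprintf(" @ %d ms", object@latencyMs))
    cat("\n")
})

setMethod("show", "TTM", function(object) {
    d <- dim(object@values)
    cat(sprintf("TTM (%s): %s -> rows Y=%s, cols X=%s; %dx%d latencies [%d..%d ms]\n",
                object@method, paste(object@roiPair, collapse = " ~ "),
                object@roiPair[2L], object@roiPair[1L], d[1L], d[2L],
                min(object@latenciesMs), max(object@latenciesMs)))
    cat(sprintf("  score range: [%.3f, %.3f]\n",
                min(object@values), max(object@values)))
})

setMethod("show", "ROIEpochs", function(object) {
    d <- dim(object@values)
    cat(sprintf("ROIEpochs '%s': %d trials x %d vertices x %d samples [%d..%d ms]",
                object@roiLabel, d[1L], d[2L], d[3L],
                min(object@latenciesMs), max(object@latenciesMs)))
    meta <- c(subject = object@subjectId, condition = object@conditionLabel,
              block = object@blockId)
    meta <- meta[!is.na(meta)]
    if (length(meta))
        cat(" (", paste(names(meta), meta, sep = "=", collapse = ", "), ")",
            sep = "")
    cat("\n")
})

setMethod("show", "ClusterStatResult", function(object) {
    cat(sprintf("ClusterStatResult: %dx%d t-map, |t| threshold %.3f, %d permutations\n",
                nrow(object@tMap), ncol(object@tMap), object@tThreshold,
                object@nPerm))
    n <- length(object@clusters)
    cat(sprintf("  %d cluster(s); %d significant; %d kept after size filter\n",
                n, sum(object@significant),
                sum(object@significant & object@keptAfterSizeFilter)))
})

setMethod("show", "LeakageMatrix", function(object) {
    cat(sprintf("LeakageMatrix over %d ROIs (columns normalised by self-leakage)\n",
                length(object@roiLabels)))
    print(round(object@values, 3))
})

setMethod("show", "ICM", function(object) {
    cat(sprintf("ICM: %d ROIs x %d latencies per block (%dx%d total);\n",
                length(object@roiLabels), length(object@latenciesMs),
                nrow(object@values), ncol(object@values)))
    cat("  lower-triangle blocks: MDPC TTMs; upper-triangle: transposed UDC TTMs\n")
})
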