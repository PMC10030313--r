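## Synthetic multi-subject datasets with injected cross-ROI dependencies,
## plus the epoch container reader/writer.

#' Construct a synthetic-dataset specification
#'
#' Defaults mimic the shape of a typical event-related EEG/MEG source-space
#' study: 18 subjects, six semantic-network ROIs, a 24-point latency axis
#' from -100 to 475 ms in 25 ms steps, and two task conditions of which the
#' first is recorded in three blocks.
#'
#' @param nSubjects,rois,nTrials,latenciesMs,conditions,nBlocks,links
#'   see [DatasetSpec-class].
#' @param noiseStd,redundancy,seed see [DatasetSpec-class].
#' @return A [DatasetSpec-class].
#' @examples
#' sp <- datasetSpec(nSubjects = 2, rois = c(a = 10, b = 10), nTrials = 30)
#' @export
datasetSpec <- function(nSubjects = 18L,
                        rois = c(lATL = 20L, rATL = 20L, IFG = 20L,
                                 PTC = 20L, AG = 20L, PVA = 20L),
                        nTrials = 50L,
                        latenciesMs = latencyGrid(-100, 500, 25),
                        conditions = c("taskA", "taskB"),
                        nBlocks = c(3L, 1L),
                        links = NULL,
                        noiseStd = 1, redundancy = 4L, seed = 0L) {
    if (is.null(links))
        links <- data.frame(src = character(), dst = character(),
                            srcLatencyMs = integer(), dstLatencyMs = integer(),
                            kind = character(), effectStrength = numeric(),
                            sparsityFrac = numeric())
    storage.mode(rois) <- "integer"
    new("DatasetSpec", nSubjects = as.integer(nSubjects), rois = rois,
        nTrials = as.integer(nTrials),
        latenciesMs = as.integer(latenciesMs),
        conditions = as.character(conditions), nBlocks = as.integer(nBlocks),
        links = links, noiseStd = noiseStd,
        redundancy = as.integer(redundancy), seed = as.integer(seed))
}

#' Describe an injected cross-ROI dependency
#'
#' Helper building one row of the `links` table of a [datasetSpec()]: at
#' the stated latency pair, the destination ROI's pattern is replaced by a
#' transformation of the source ROI's pattern (plus noise) -- a scaled
#' shared amplitude for `kind = "UD"`, a random sparse linear map for
#' `kind = "MD"`.
#'
#' @param src,dst ROI labels.
#' @param srcLatencyMs,dstLatencyMs latencies (must lie on the grid).
#' @param kind `"UD"` or `"MD"`.
#' @param effectStrength scaling of the injected signal relative to unit
#'   source variance.
#' @param sparsityFrac fraction of non-zero entries of the MD map.
#' @return One-row data.frame.
#' @export
injectedLink <- function(src, dst, srcLatencyMs, dstLatencyMs,
                         kind = c("MD", "UD"), effectStrength = 1,
                         sparsityFrac = 1) {
    data.frame(src = src, dst = dst,
               srcLatencyMs = as.integer(srcLatencyMs),
               dstLatencyMs = as.integer(dstLatencyMs),
               kind = match.arg(kind), effectStrength = effectStrength,
               sparsityFrac = sparsityFrac)
}

## Draw the (shared-across-subjects) transformation of an MD link once per
## link from the spec seed, so every subject expresses the same dependency.
.linkTransforms <- function(spec) {
    lk <- spec@links
    out <- vector("list", nrow(lk))
    for (i in seq_len(nrow(lk))) {
        if (lk$kind[i] != "MD") next
        nSrc <- spec@rois[[lk$src[i]]]
        nDst <- spec@rois[[lk$dst[i]]]
        out[[i]] <- withr::with_seed(.childSeed(spec@seed, 900000L + i), {
            nzo <- max(1L, round(lk$sparsityFrac[i] * nSrc * nDst))
            Tm <- matrix(0, nSrc, nDst)
            Tm[sample.int(nSrc * nDst, nzo)] <- stats::rnorm(nzo)
            ## unit-ish output variance before effectStrength scaling
            Tm * (lk$effectStrength[i] / sqrt(max(1, nzo / nDst)))
        })
    }
    out
}

#' Generate a synthetic multi-subject dataset
#'
#' Builds one [ROIEpochs-class] per subject/condition/block/ROI. Each ROI's
#' background activity consists of `redundancy` prototype trial-by-time
#' courses; every vertex is a copy of one prototype plus independent
#' Gaussian noise of standard deviation `noiseStd`, emulating the spatial
#' smoothness (redundancy) of source estimates. At every injected link, the
#' destination ROI's pattern at the destination latency is overwritten by
#' the stated transformation of the source ROI's pattern at the source
#' latency, plus noise; MD transformations are drawn once per link and
#' shared across subjects so group statistics can recover them. The whole
#' dataset is a deterministic function of the spec (same spec + seed gives
#' a byte-identical dataset).
#'
#' @param spec a [datasetSpec()].
#' @return Named list of [ROIEpochs-class] objects, names
#'   `subject.condition.block.roi`.
#' @export
generateDataset <- function(spec) {
    validObject(spec)
    lk <- spec@links
    transforms <- .linkTransforms(spec)
    nT <- spec@nTrials
    lats <- spec@latenciesMs
    nTime <- length(lats)
    out <- list()
    counter <- 0L
    for (s in seq_len(spec@nSubjects)) {
        for (ci in seq_along(spec@conditions)) {
            for (b in seq_len(spec@nBlocks[ci])) {
                counter <- counter + 1L
                epochs <- withr::with_seed(.childSeed(spec@seed, counter), {
                    blockEpochs <- list()
                    for (roi in names(spec@rois)) {
                        nV <- spec@rois[[roi]]
                        proto <- array(stats::rnorm(nT * spec@redundancy * nTime),
                                       c(nT, spec@redundancy, nTime))
                        assign_ <- rep_len(seq_len(spec@redundancy), nV)
                        vals <- proto[, assign_, , drop = FALSE] +
                            spec@noiseStd *
                            array(stats::rnorm(nT * nV * nTime), c(nT, nV, nTime))
                        blockEpochs[[roi]] <- vals
                    }
                    ## injected dependencies overwrite destination slices
                    for (i in seq_len(nrow(lk))) {
                        srcSlice <- blockEpochs[[lk$src[i]]][, ,
                                        match(lk$srcLatencyMs[i], lats)]
                        nDst <- spec@rois[[lk$dst[i]]]
                        dstSig <- if (lk$kind[i] == "UD") {
                            matrix(lk$effectStrength[i] * rowMeans(srcSlice),
                                   nT, nDst)
                        } else {
                            srcSlice %*% transforms[[i]]
                        }
                        blockEpochs[[lk$dst[i]]][, ,
                            match(lk$dstLatencyMs[i], lats)] <-
                            dstSig + spec@noiseStd *
                                matrix(stats::rnorm(nT * nDst), nT)
                    }
                    blockEpochs
                })
                blockId <- if (spec@nBlocks[ci] > 1L)
                    sprintf("block%d", b) else NA_character_
                for (roi in names(spec@rois)) {
                    nm <- paste(sprintf("sub%02d", s), spec@conditions[ci],
                                if (is.na(blockId)) "all" else blockId, roi,
                                sep = ".")
                    out[[nm]] <- roiEpochs(epochs[[roi]], lats, roi,
                                           sprintf("sub%02d", s),
                                           spec@conditions[ci], blockId)
                }
            }
        }
    }
    out
}

## ---------------------------------------------------------------------------
## Epoch container IO
## ---------------------------------------------------------------------------

.EPOCH_FIELDS <- c("values", "latenciesMs", "roiLabel", "subjectId",
                   "conditionLabel", "blockId")

#' Write an epoch collection to a container file
#'
#' Serialises a named list of [ROIEpochs-class] objects to a single
#' container file (R native serialisation of a validated plain-list
#' layout). The round trip through [readEpochs()] is bit-exact.
#'
#' @param epochs named list of [ROIEpochs-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEpochs <- function(epochs, path) {
    records <- lapply(epochs, function(e) {
        stopifnot(is(e, "ROIEpochs"))
        list(values = e@values, latenciesMs = e@latenciesMs,
             roiLabel = e@roiLabel, subjectId = e@subjectId,
             conditionLabel = e@conditionLabel, blockId = e@blockId)
    })
    saveRDS(list(container = "tlmdpc-epochs", version = 1L,
                 records = records), path)
    invisible(path)
}

#' Read an epoch collection from a container file
#'
#' @param path a file written by [writeEpochs()].
#' @return Named list of [ROIEpochs-class] objects.
#' @export
readEpochs <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("cannot read epoch container: ", conditionMessage(e)))
    if (!is.list(obj) || !identical(obj$container, "tlmdpc-epochs"))
        stop("parse error: not a tlmdpc epoch container (missing ",
             "'container' tag)")
    lapply(obj$records, function(rec) {
        miss <- setdiff(.EPOCH_FIELDS, names(rec))
        if (length(miss))
            stop("parse error: record is missing field(s): ",
                 paste(miss, collapse = ", "))
        roiEpochs(rec$values, rec$latenciesMs, rec$roiLabel, rec$subjectId,
                  rec$conditionLabel, rec$blockId)
    })
}
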