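# Latency grids, TTM construction, block averaging, ICM assembly.

test_that("latency grid is half-open with the documented point count", {
    g <- latencyGrid(-100, 500, 25)
    expect_length(g, 24)
    expect_identical(g[1:3], c(-100L, -75L, -50L))
    expect_identical(g[24], 475L)
    expect_identical(latencyGrid(0, 100, 50), c(0L, 50L))
    # counting property over assorted inputs
    for (args in list(c(-50, 50, 10), c(0, 7, 2), c(-3, 3, 5))) {
        expect_length(latencyGrid(args[1], args[2], args[3]),
                      ceiling((args[2] - args[1]) / args[3]))
    }
    expect_error(latencyGrid(0, 100, 0), "positive")
    expect_error(latencyGrid(100, 0, 10), "below")
})

mkEpochs <- function(values, grid, roi, subject = "s1", cond = "c1") {
    roiEpochs(values, grid, roi, subject, cond)
}

test_that("TTM scores self-copies high on the diagonal and nulls near zero", {
    grid <- latencyGrid(0, 75, 25)
    withr::with_seed(31, arr <- array(rnorm(50 * 4 * 3), c(50, 4, 3)))
    ex <- mkEpochs(arr, grid, "x")
    ey <- mkEpochs(arr, grid, "y")   # exact copy
    cfg <- fastCfg(seed = 1)
    tt <- computeTTM(ex, ey, grid, cfg, "MDPC")
    expect_s4_class(tt, "TTM")
    expect_true(all(diag(values(tt)) > 0.99))
    expect_true(all(values(tt) >= 0 & values(tt) <= 1))

    withr::with_seed(32, arr2 <- array(rnorm(50 * 4 * 3), c(50, 4, 3)))
    tn <- computeTTM(ex, mkEpochs(arr2, grid, "y"), grid, cfg, "MDPC")
    expect_lt(max(values(tn)), 0.15)
    expect_lt(mean(values(tn)), 0.05)
})

test_that("swapping the ROI pair transposes the TTM exactly", {
    grid <- latencyGrid(0, 75, 25)
    withr::with_seed(33, {
        ax <- array(rnorm(40 * 3 * 3), c(40, 3, 3))
        ay <- array(rnorm(40 * 5 * 3), c(40, 5, 3))
    })
    ay[, , 2] <- ax[, , 1] %*% matrix(withr::with_seed(34, rnorm(15)), 3) +
        0.2 * withr::with_seed(35, matrix(rnorm(200), 40))
    ex <- mkEpochs(ax, grid, "x"); ey <- mkEpochs(ay, grid, "y")
    cfg <- fastCfg(seed = 2)
    txy <- computeTTM(ex, ey, grid, cfg, "MDPC")
    tyx <- computeTTM(ey, ex, grid, cfg, "MDPC")
    expect_identical(values(txy), t(values(tyx)))
    # the injected cross-latency dependency makes the TTM asymmetric
    expect_false(isTRUE(all.equal(values(txy), t(values(txy)))))
})

test_that("missing grid latencies are reported", {
    grid <- latencyGrid(0, 75, 25)
    withr::with_seed(36, arr <- array(rnorm(30 * 3 * 3), c(30, 3, 3)))
    ex <- mkEpochs(arr, grid, "x")
    expect_error(computeTTM(ex, ex, c(0L, 25L, 60L), fastCfg(), "MDPC"),
                 "60")
})

test_that("block averaging is the cell-wise mean without re-clamping", {
    grid <- latencyGrid(0, 50, 25)
    mk <- function(vals) new("TTM", values = vals, latenciesMs = grid,
                             roiPair = c("a", "b"), method = "MDPC")
    t1 <- mk(matrix(c(0.2, 0, 0, 0.2), 2))
    t2 <- mk(matrix(c(0.4, 0, 0, 0.4), 2))
    t3 <- mk(matrix(c(0.6, 0, 0, 0.6), 2))
    avg <- averageBlocks(list(t1, t2, t3))
    expect_equal(diag(values(avg)), c(0.4, 0.4))
    expect_equal(values(averageBlocks(list(t1, t1, t1))), values(t1),
                 tolerance = 1e-15)
    # independent element-wise oracle
    withr::with_seed(37, vs <- replicate(4, matrix(runif(4), 2),
                                         simplify = FALSE))
    got <- values(averageBlocks(lapply(vs, mk)))
    expect_equal(got, (vs[[1]] + vs[[2]] + vs[[3]] + vs[[4]]) / 4,
                 tolerance = 1e-15)
    bad <- new("TTM", values = matrix(0, 3, 3),
               latenciesMs = latencyGrid(0, 75, 25),
               roiPair = c("a", "b"), method = "MDPC")
    expect_error(averageBlocks(list(t1, bad)), "grids")
})

test_that("ICM assembly places blocks per layout and round-trips exactly", {
    rois <- c("r1", "r2", "r3", "r4", "r5", "r6")
    grid <- latencyGrid(0, 50, 25)
    ttms <- list()
    withr::with_seed(38, {
        for (i in 1:5) for (j in (i + 1):6) for (m in c("MDPC", "UDC")) {
            ttms[[length(ttms) + 1]] <-
                new("TTM", values = matrix(runif(4), 2), latenciesMs = grid,
                    roiPair = c(rois[i], rois[j]), method = m)
        }
    })
    expect_length(ttms, 30)  # 15 pairs per triangle, both methods
    icm <- assembleICM(ttms, roiOrder = rois)
    big <- values(icm)
    expect_identical(dim(big), c(12L, 12L))
    # diagonal blocks empty, all off-diagonal blocks filled
    expect_true(all(is.na(big[1:2, 1:2])))
    expect_identical(sum(!is.na(big)), 30L * 4L)
    # lower-triangle block (r2, r1) is the MDPC TTM of pair (r1, r2)
    md12 <- ttms[[1]]
    expect_identical(big[3:4, 1:2], values(md12))
    # upper-triangle block (r1, r2) is the transposed UDC TTM
    ud12 <- ttms[[2]]
    expect_identical(big[1:2, 3:4], t(values(ud12)))
    # round trip is bit-exact for every stored TTM
    for (tt in ttms) {
        back <- extractTTM(icm, tt@roiPair[1], tt@roiPair[2], tt@method)
        expect_identical(values(back), values(tt))
    }
    # and extraction in the swapped orientation transposes
    sw <- extractTTM(icm, "r2", "r1", "MDPC")
    expect_identical(values(sw), t(values(md12)))
    expect_error(assembleICM(ttms[-1], roiOrder = rois), "missing")
})

test_that("trial equalisation sub-samples reproducibly", {
    grid <- latencyGrid(0, 50, 25)
    withr::with_seed(39, arr <- array(rnorm(30 * 2 * 2), c(30, 2, 2)))
    ep <- mkEpochs(arr, grid, "x")
    a <- equaliseTrials(ep, 12, seed = 5)
    b <- equaliseTrials(ep, 12, seed = 5)
    expect_identical(values(a), values(b))
    expect_identical(dim(a)[1], 12L)
    expect_error(equaliseTrials(ep, 40), "cannot sample")
})
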