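# Ridge transformation estimation and cross-validated explained variance.

test_that("ridge fit recovers exact and shrunk transformations", {
    p <- linearPair(nTrials = 20, nX = 3, nY = 2, seed = 3)

    # identity: Y = X, alpha = 0 -> T is the identity
    fitI <- fitRidgeTransform(p$X, p$X, alpha = 0)
    expect_equal(coef(fitI), diag(3), tolerance = 1e-10)

    # extreme penalty shrinks all coefficients towards zero
    fitBig <- fitRidgeTransform(p$X, p$Y, alpha = 1e12)
    expect_lt(max(abs(coef(fitBig))), 1e-9)

    # noise-free map recovered, checked against an independent OLS solve
    fit0 <- fitRidgeTransform(p$X, p$Y, alpha = 0)
    oracle <- stats::lm.fit(p$X, p$Y)$coefficients
    expect_lt(max(abs(coef(fit0) - p$T0)), 1e-8)
    expect_lt(max(abs(coef(fit0) - oracle)), 1e-8)
})

test_that("ridge fit validates its inputs", {
    p <- linearPair(seed = 4)
    expect_error(fitRidgeTransform(p$X[1:10, ], p$Y), "trial counts")
    expect_error(fitRidgeTransform(p$X, p$Y, alpha = -1), "non-negative")
    # rank-deficient X with alpha = 0 names the singularity
    Xdef <- cbind(p$X[, 1], p$X[, 1], p$X[, 2])
    expect_error(fitRidgeTransform(Xdef, p$Y, alpha = 0), "rank deficient")
})

test_that("prediction is the plain matrix product", {
    p <- linearPair(nTrials = 25, nX = 3, nY = 2, seed = 5)
    fit <- fitRidgeTransform(p$X[1:20, ], p$Y[1:20, ], alpha = 0)
    Xte <- p$X[21:25, ]
    expect_equal(predictPattern(Xte, fit), Xte %*% p$T0, tolerance = 1e-8)

    idFit <- fitRidgeTransform(p$X, p$X, alpha = 0)
    expect_equal(predictPattern(Xte, idFit), Xte, tolerance = 1e-10)

    zero <- new("TransformEstimate", coefficients = matrix(0, 3, 2),
                alpha = 0, direction = "X_to_Y")
    expect_equal(predictPattern(Xte, zero), matrix(0, 5, 2))
    expect_error(predictPattern(Xte[, 1:2], fit), "vertex count")
})

test_that("per-vertex EV matches an independent variance computation", {
    withr::with_seed(6, {
        Y <- matrix(rnorm(200), 50, 4)
        Yhat <- matrix(rnorm(200), 50, 4)
    })
    # perfect prediction
    expect_equal(evPerVertex(Y, Y), rep(1, 4))
    # constant per-column-mean prediction explains nothing
    Ymean <- matrix(colMeans(Y), 50, 4, byrow = TRUE)
    expect_equal(evPerVertex(Y, Ymean), rep(0, 4), tolerance = 1e-12)
    # column-by-column oracle with stats::var
    oracle <- vapply(1:4, function(j)
        1 - stats::var(Y[, j] - Yhat[, j]) / stats::var(Y[, j]), numeric(1))
    expect_equal(evPerVertex(Y, Yhat), oracle, tolerance = 1e-12)
    # degenerate target column is named
    Yz <- Y; Yz[, 3] <- 2
    expect_error(evPerVertex(Yz, Yhat), "3")
})

test_that("meanEV is the arithmetic mean", {
    expect_identical(meanEV(c(1, 1, 1)), 1)
    expect_identical(meanEV(c(0.5, -0.5)), 0)
    withr::with_seed(7, v <- rnorm(31))
    expect_equal(meanEV(v), sum(v) / length(v), tolerance = 1e-15)
    expect_error(meanEV(numeric(0)), "non-empty")
    s <- evScore(c(-0.4, 0.2), clamp = TRUE)
    expect_identical(s@meanEV, 0)
})

test_that("cross-validated EV matches a hand-rolled two-fold computation", {
    withr::with_seed(8, {
        X <- matrix(rnorm(8 * 2), 8)
        Y <- X %*% matrix(c(1, 0.5, -1, 2), 2) +
            0.3 * matrix(rnorm(16), 8)
    })
    cfg <- cvConfig(nFolds = 2, alphaGrid = 0, seed = 11)
    got <- crossvalEV(X, Y, cfg)

    # independent re-computation: same shuffled split, OLS via lm.fit,
    # EV via stats::var
    perm <- withr::with_seed(11, sample.int(8))
    folds <- unname(split(perm, rep_len(1:2, 8)))
    foldEV <- vapply(1:2, function(f) {
        te <- folds[[f]]; tr <- setdiff(1:8, te)
        cmx <- colMeans(X[tr, ]); cmy <- colMeans(Y[tr, ])
        B <- stats::lm.fit(sweep(X[tr, ], 2, cmx), sweep(Y[tr, ], 2, cmy))$coefficients
        Yhat <- sweep(X[te, ], 2, cmx) %*% B + rep(cmy, each = length(te))
        mean(vapply(1:2, function(j)
            1 - stats::var(Y[te, j] - Yhat[, j]) / stats::var(Y[te, j]),
            numeric(1)))
    }, numeric(1))
    expect_equal(got, mean(foldEV), tolerance = 1e-10)
})

test_that("cross-validated EV behaves at the two extremes", {
    # noise-free linear map: essentially perfect
    p <- linearPair(nTrials = 100, nX = 5, nY = 5, seed = 9)
    expect_gte(crossvalEV(p$X, p$Y, cvConfig(seed = 1)), 0.99)
    # independent patterns: near zero after clamping
    n <- nullPair(300, seed = 10)
    expect_lt(bidirectionalEV(n$X, n$Y, cvConfig(seed = 1)), 0.05)
    expect_lt(udcEV(n$X, n$Y, cvConfig(seed = 1)), 0.05)
})

test_that("bidirectional score clamps at zero and is exactly symmetric", {
    n <- nullPair(40, seed = 12)
    cfg <- fastCfg(seed = 2)
    s <- bidirectionalEV(n$X, n$Y, cfg)
    expect_gte(s, 0)
    expect_identical(s, bidirectionalEV(n$Y, n$X, cfg))
    u <- udcEV(n$X, n$Y, cfg)
    expect_identical(u, udcEV(n$Y, n$X, cfg))
    # small independent patterns produce negative raw directional EVs,
    # so the clamped metric is exactly zero here
    expect_identical(s, 0)
})

test_that("unidimensional score matches a hand scalar regression", {
    withr::with_seed(13, {
        x <- rnorm(10)
        X <- matrix(x, 10, 3) + 0.05 * matrix(rnorm(30), 10)
        Y <- matrix(2 * x, 10, 4) + 0.05 * matrix(rnorm(40), 10)
    })
    cfg <- cvConfig(nFolds = 2, alphaGrid = 0, seed = 21)
    got <- udcEV(X, Y, cfg)

    u <- rowMeans(scale(X)); v <- rowMeans(scale(Y))
    perm <- withr::with_seed(21, sample.int(10))
    folds <- unname(split(perm, rep_len(1:2, 10)))
    dir_ <- function(a, b) {
        mean(vapply(1:2, function(f) {
            te <- folds[[f]]; tr <- setdiff(1:10, te)
            fit <- stats::lm(y ~ x, data.frame(x = a[tr], y = b[tr]))
            pred <- stats::predict(fit, data.frame(x = a[te]))
            1 - stats::var(b[te] - pred) / stats::var(b[te])
        }, numeric(1)))
    }
    expect_equal(got, max(0, (dir_(u, v) + dir_(v, u)) / 2),
                 tolerance = 1e-10)
})

test_that("unidimensional score detects a perfect shared amplitude", {
    withr::with_seed(14, x <- rnorm(80))
    X <- matrix(x, 80, 5)
    Y <- 2 * X
    expect_gte(udcEV(X, Y, cvConfig(seed = 3)), 0.99)
})

test_that("EV is invariant to a common scalar when alpha scales with it", {
    p <- linearPair(nTrials = 30, nX = 4, nY = 3, noise = 0.2, seed = 15)
    c0 <- 3.7
    f1 <- fitRidgeTransform(p$X, p$Y, alpha = 2)
    f2 <- fitRidgeTransform(c0 * p$X, c0 * p$Y, alpha = 2 * c0^2)
    expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
    # with standardisation, per-vertex affine rescaling is a no-op
    cfg <- fastCfg(seed = 4)
    scl <- withr::with_seed(16, runif(3, 0.5, 4))
    off <- withr::with_seed(17, rnorm(3))
    Y2 <- sweep(sweep(p$Y, 2, scl, "*"), 2, off, "+")
    expect_equal(bidirectionalEV(p$X, p$Y, cfg),
                 bidirectionalEV(p$X, Y2, cfg), tolerance = 1e-10)
})

test_that("score decreases with added noise on average", {
    cfg <- fastCfg(seed = 5)
    evs <- vapply(1:50, function(s) {
        p <- linearPair(nTrials = 40, nX = 3, nY = 3, seed = 100 + s)
        lo <- bidirectionalEV(p$X, p$Y + 0.2 * matrix(rnorm(120), 40), cfg)
        hi <- bidirectionalEV(p$X, p$Y + 2.0 * matrix(rnorm(120), 40), cfg)
        c(lo, hi)
    }, numeric(2))
    expect_gt(mean(evs[1, ]), mean(evs[2, ]))
    expect_true(all(evs >= 0 & evs <= 1))
})

test_that("both metrics are calibrated near zero on independent patterns", {
    cfg <- cvConfig(seed = 6)
    scores <- vapply(1:100, function(s) {
        n <- nullPair(300, 5, 5, seed = 2000 + s)
        c(md = bidirectionalEV(n$X, n$Y, cfg), ud = udcEV(n$X, n$Y, cfg))
    }, numeric(2))
    expect_lt(mean(scores["md", ]), 0.05)
    expect_lt(mean(scores["ud", ]), 0.05)
})

test_that("fold pooling variant agrees with fold averaging on clean data", {
    p <- linearPair(nTrials = 60, nX = 4, nY = 4, noise = 0.3, seed = 18)
    a <- crossvalEV(p$X, p$Y, cvConfig(seed = 7))
    b <- crossvalEV(p$X, p$Y, cvConfig(seed = 7, pooling = "pooled"))
    expect_lt(abs(a - b), 0.05)
})

test_that("too few trials for the fold scheme is a configuration error", {
    p <- linearPair(nTrials = 12, seed = 19)
    expect_error(crossvalEV(p$X, p$Y, cvConfig(nFolds = 10)),
                 "2 trials per fold")
})
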