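# k-means spatial sub-sampling of redundant vertices.

test_that("standardisation yields exact zero mean and unit variance", {
    withr::with_seed(21, P <- matrix(rnorm(200), 40) * 5 + 2)
    S <- standardisePattern(P)
    # independent moment oracle
    expect_lt(max(abs(apply(S, 2, mean))), 1e-12)
    expect_lt(max(abs(apply(S, 2, stats::var) - 1)), 1e-12)
    # idempotent
    expect_equal(standardisePattern(S), S, tolerance = 1e-12)
    # a three-trial toy column
    s3 <- standardisePattern(matrix(c(1, 2, 3), 3, 1))
    expect_equal(mean(s3), 0)
    expect_equal(stats::var(as.vector(s3)), 1)
    # zero-variance vertex is named
    Pz <- P; Pz[, 2] <- 7
    expect_error(standardisePattern(Pz), "2")
})

test_that("elbow selection finds a true cluster count and falls back on noise", {
    r <- redundantPattern(nTrials = 80, nProto = 6, nVertices = 48,
                          noise = 0.1, seed = 22)
    expect_identical(chooseKElbow(r$values, seed = 1), 6L)
    # unstructured data: flat distortion curve, fallback of 10
    withr::with_seed(23, Pn <- matrix(rnorm(80 * 40), 80))
    expect_identical(chooseKElbow(Pn, seed = 1), 10L)
    # default search range
    f <- formals(chooseKElbow)
    expect_identical(c(f$kMin, f$kMax, f$fallback), c(5L, 13L, 10L))
    expect_error(chooseKElbow(Pn, kMin = 6, kMax = 3), "kMin")
    expect_error(chooseKElbow(Pn[, 1:10], kMax = 13), "exceed")
})

test_that("vertex clustering separates duplicated groups and is a partition", {
    withr::with_seed(24, {
        a <- rnorm(30); b <- rnorm(30)
    })
    b <- b - a * sum(a * b) / sum(a * a)  # orthogonal time courses
    P <- cbind(a, a, a, b, b, b)
    labels <- clusterVertices(P, 2, seed = 1)
    expect_length(labels, 6)
    expect_setequal(unique(labels), 1:2)
    expect_identical(labels[1], labels[2])
    expect_identical(labels[1], labels[3])
    expect_identical(labels[4], labels[5])
    expect_false(labels[1] == labels[4])
    expect_error(clusterVertices(P, 10, seed = 1), "exceeds")
})

test_that("k-means labels attain the exhaustive minimum within-cluster SS", {
    withr::with_seed(25, P <- {
        proto <- matrix(rnorm(12 * 2), 12)
        proto[, c(1, 1, 1, 1, 2, 2, 2, 2)] + 0.3 * matrix(rnorm(96), 12)
    })
    labels <- clusterVertices(P, 2, seed = 2)
    wss <- function(lab) {
        sum(vapply(unique(lab), function(cl) {
            m <- P[, lab == cl, drop = FALSE]
            sum(sweep(m, 1, rowMeans(m))^2)
        }, numeric(1)))
    }
    # enumerate every 2-partition of the 8 vertices
    best <- min(vapply(1:127, function(mask) {
        lab <- as.integer(intToBits(mask))[1:8] + 1L
        wss(lab)
    }, numeric(1)))
    expect_equal(wss(labels), best, tolerance = 1e-8)
})

test_that("cluster representatives are the highest-variance members", {
    # two-member cluster: the higher-variance vertex wins
    P <- cbind(c(1, 2, 3, 4) * 0.5, c(1, 2, 3, 4) * 2)
    expect_identical(pickRepresentatives(P, c(1L, 1L)), 2L)
    # singleton clusters are their own representatives
    expect_identical(pickRepresentatives(P, c(1L, 2L)), c(1L, 2L))
    # random toy versus an independent variance table
    withr::with_seed(26, {
        Q <- matrix(rnorm(20 * 9), 20)
        lab <- sample(1:3, 9, replace = TRUE)
    })
    lab[1:3] <- 1:3  # ensure all labels occupied
    vt <- apply(Q, 2, stats::var)
    oracle <- vapply(1:3, function(cl) {
        mem <- which(lab == cl); mem[which.max(vt[mem])]
    }, integer(1))
    expect_identical(pickRepresentatives(Q, lab), oracle)
})

test_that("sub-sampling recovers prototype count and selects original columns", {
    r <- redundantPattern(nTrials = 70, nProto = 7, nVertices = 100,
                          noise = 0.1, seed = 27)
    res <- subsampleVertices(r$values, seed = 3)
    expect_identical(res@k, 7L)
    S <- standardisePattern(r$values)
    # pure feature selection: each reduced column is an original
    # standardised column, bit for bit
    expect_identical(res@reduced@values,
                     S[, res@representativeIndices, drop = FALSE])
    # representatives cover distinct clusters
    expect_identical(length(unique(res@labels[res@representativeIndices])),
                     7L)
    # width always within the search bounds or the fallback
    expect_true(res@k %in% c(5:13, 10L))
    # re-clustering the reduced separated columns at the same k is a no-op:
    # every representative becomes its own singleton cluster
    lab2 <- clusterVertices(res@reduced@values, res@k, seed = 3)
    expect_identical(sort(unique(lab2)), 1:res@k)
    expect_identical(anyDuplicated(lab2), 0L)
})

test_that("sub-sampling is reproducible and preserves the connectivity score", {
    r <- redundantPattern(seed = 28)
    a <- subsampleVertices(r$values, seed = 9)
    b <- subsampleVertices(r$values, seed = 9)
    expect_identical(a@labels, b@labels)
    expect_identical(a@representativeIndices, b@representativeIndices)

    # reduced-vs-full score gap on redundant expansions of a low-dimensional
    # linear dependency, averaged over seeds
    cfg <- fastCfg(seed = 1)
    gaps <- vapply(1:50, function(s) {
        withr::with_seed(300 + s, {
            L <- matrix(rnorm(60 * 7), 60) * 3       # latent source courses
            T0 <- matrix(rnorm(49), 7)
            X <- L[, rep(1:7, each = 5)] + 0.1 * matrix(rnorm(60 * 35), 60)
            Ysig <- (L %*% T0) / 3
            Y <- Ysig[, rep(1:7, each = 5)] + 0.1 * matrix(rnorm(60 * 35), 60)
        })
        full <- bidirectionalEV(X, Y, cfg)
        redx <- subsampleVertices(X, seed = s)@reduced
        redy <- subsampleVertices(Y, seed = s)@reduced
        abs(bidirectionalEV(redx, redy, cfg) - full)
    }, numeric(1))
    expect_lt(mean(gaps), 0.05)
})
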