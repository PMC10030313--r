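## Internal numeric helpers shared across modules.

## Accept either a PatternMatrix or a plain numeric matrix everywhere the
## metric operates on patterns.
.pm <- function(x) {
    if (is(x, "PatternMatrix")) x@values else as.matrix(x)
}

## Column variances without per-column apply() overhead (n - 1 denominator,
## matching stats::var).
.colVars <- function(m) {
    n <- nrow(m)
    (colSums(m * m) - n * colMeans(m)^2) / (n - 1)
}

## Shuffled, near-balanced fold assignment: returns a list of index vectors.
.foldIndices <- function(n, k, seed) {
    perm <- withr::with_seed(seed, sample.int(n))
    unname(split(perm, rep_len(seq_len(k), n)))
}

## Derive a bounded child seed from a base seed and a counter; keeps all
## seeds comfortably inside 32-bit integer range.
.childSeed <- function(seed, counter) {
    as.integer((as.numeric(seed) * 7919 + counter) %% 2147483647)
}

## Centre columns of m at 'centers' (a numeric vector).
.centerCols <- function(m, centers) {
    m - rep(centers, each = nrow(m))
}
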