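---
title: "Time-lagged multidimensional pattern connectivity: models, choices, limits"
author: "tlmdpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lagged multidimensional pattern connectivity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Functional connectivity between two cortical regions is usually computed
after collapsing each region's source-estimate activity to a single time
course, which discards the information carried by the *pattern* of activity
across the region's vertices. `tlmdpc` measures connectivity between the
full vertex patterns of two regions of interest (ROIs) in event-related
EEG/MEG source estimates: it asks how well the trial-by-vertex pattern of
ROI X at latency $t_X$ predicts the pattern of ROI Y at latency $t_Y$
through a linear transformation, for every pair of latencies.

# The transformation metric

For an ROI pair at one latency pair, let $X$ ($n_t \times n_x$) and $Y$
($n_t \times n_y$) hold the activity of the two regions across $n_t$
trials. On a training subset of trials the transformation is estimated by
ridge regression,

$$ T = (X^\top X + \alpha I)^{-1} X^\top Y, $$

and on held-out trials the prediction $\hat Y = X T$ is scored per target
vertex $j$ by the explained variance

$$ \mathrm{EV}_j = 1 - \frac{\operatorname{var}(Y_j - \hat Y_j)}
                          {\operatorname{var}(Y_j)}, $$

averaged over vertices. The procedure is run with 10-fold cross-validation;
within each training fold the penalty $\alpha$ is chosen by an inner 5-fold
cross-validation over a logarithmic grid $10^{-4} \dots 10^{4}$ (nine
points, applied to standardised data so the grid is scale-free). Because
the metric is undirected, the EV is computed for X predicting Y and for Y
predicting X and the two values averaged; small negative averages, which
arise when the prediction error exceeds the data variance and are not
interpretable as connectivity, are clamped to zero. The final score lies in
$[0, 1]$.

`bidirectionalEV()` implements this score; `fitRidgeTransform()`,
`predictPattern()`, `evPerVertex()`, `meanEV()` and `crossvalEV()` expose
the individual stages.

Decisions taken where the procedure was genuinely open:

* **Fold aggregation.** The per-fold mean EVs are averaged
  (`pooling = "fold"`); pooling residuals across folds before computing EV
  is available via `cvConfig(pooling = "pooled")`. Averaging keeps folds
  exchangeable and matches the reading of the EV as an average over
  cross-validation runs.
* **Clamping point.** Clamping is applied once, to the direction-averaged
  value, not per direction: the direction average is the metric, clamping
  is its final masking step.
* **Intercept.** The ridge model has no explicit intercept; columns are
  demeaned within each training split and the training means are applied
  to the held-out trials, so no information leaks from test to train.
* **Degenerate targets.** A target vertex with zero variance in a test
  fold has no defined EV; the vertex is dropped from that fold's average
  with a warning.
* **Seeds.** Every fold shuffle derives from an explicit integer seed
  (`cvConfig(seed = )`), and the two prediction directions share their
  fold splits, which makes the score exactly invariant to exchanging its
  two arguments.

# The unidimensional counterpart

`udcEV()` is the control condition for the multidimensional claim: each
ROI is collapsed to one value per trial and the identical cross-validated
machinery is applied to the two resulting single-column patterns. The
collapse is applied after per-vertex standardisation.

The default summary is the plain mean across vertices. This choice is
deliberate and load-bearing. A unidimensional method collapsed by the mean
sees a shared-amplitude dependency perfectly, but on a genuinely
multidimensional linear map the two collapsed series are two fixed linear
projections of independent vertex patterns, whose expected squared
correlation is $1/n$ for $n$ vertices — about $0.2$ at five vertices,
$0.07$ at fifteen. That ceiling is exactly the behaviour the simulations
reproduce. A mean of *absolute* vertex values
(`udcEV(collapse = "absmean")`) is also offered, since sign-mixed source
orientations in real source estimates can cancel a plain mean; note that
an absolute-value summary responds to per-trial pattern *magnitude* and
therefore scores far higher (around 0.4) on multidimensional data — it is
no longer a purely unidimensional probe.

# Spatial sub-sampling of vertices

Source estimates are spatially smooth: neighbouring vertices carry largely
redundant copies of the same underlying signal, so transformations between
all vertices are expensive without being more informative. `tlmdpc`
reduces each ROI by *feature selection*, never feature extraction:

1. standardise each vertex column (mean 0, variance 1 across trials);
2. cluster the vertices by k-means, with vertices as observations and
   trials as features, for $k \in [5, 13]$;
3. choose $k$ at the knee of the within-cluster-distortion curve
   (maximum-curvature criterion: both axes normalised to $[0,1]$, the knee
   is the largest gap between the normalised distortion drop and the
   diagonal, requiring a minimum gap of 0.1); when no knee stands out —
   as for an unstructured, essentially linear curve — $k = 10$ is used;
4. keep the highest-variance vertex of each cluster (ties broken by the
   lowest index).

The reduced matrix consists of original standardised columns, so the
estimated transformations remain vertex-to-vertex. k-means uses k-means++
seeding with ten restarts and at most 300 iterations: with plain random
restarts the probability of seeding every well-separated vertex group is
small (the classic merged/split local optimum), and the selection then
silently loses a signal dimension. Clustering is performed independently
at each latency of the analysis grid, keeping the method applicable
sample-by-sample; clustering once over a latency window is possible by
passing a window-averaged pattern.

# Temporal transformation matrices

`computeTTM()` scans all pairs of latencies on a grid — by default
`latencyGrid(-100, 500, 25)`, the half-open 24-point axis from −100 ms to
475 ms in 25 ms steps — and stores the score of (Y at row latency, X at
column latency). The diagonal holds zero-lag dependencies, the lower
triangle dependencies in which X leads, the upper triangle dependencies in
which Y leads; the triangles are computed independently and a TTM need not
be symmetric. Each grid latency uses the single sample at that latency;
averaging a 25 ms bin is available via `binMs`. A condition recorded in
several blocks is computed per block and averaged (`averageBlocks()`), so
unequal trial counts between conditions do not bias the comparison;
`equaliseTrials()` additionally offers seeded trial sub-sampling.
`assembleICM()` collects all ROI pairs into the standard block layout
(multidimensional TTMs below the block diagonal, transposed unidimensional
TTMs above).

# Group statistics

`clusterPermutationTest()` contrasts two within-subject conditions:
cell-wise paired t statistics are thresholded at the two-tailed 5% t
quantile, supra-threshold cells of each sign form 4-connected clusters,
and the null distribution of the per-tail maximal cluster statistic is
built from random sign flips of the per-subject difference maps (5000 by
default) — exact for a paired design. A cluster is significant when its
statistic falls in the upper 2.5% of its tail's null. The cluster
statistic is the cluster *mass* (summed $|t|$) by default: the mass
statistic is continuous, and the shipped checks verify its family-wise
error on null data (200 Monte-Carlo datasets of 18 subjects, 24-point
grids, 1000 flips) lands within $[0.02, 0.08]$ of the nominal 0.05. Cell
count ("cluster size") is available via `clusterStat = "count"`, but the
ties of an integer statistic coarsen its permutation p-values and the
checks show its false-positive rate falls far below the nominal level —
a markedly conservative test. Independently of the inference statistic,
`sizeFilter()`
flags clusters of at most `round(0.02 * gridsize^2)` cells — 12 cells on
the 24-point grid — as possibly spurious. Degenerate zero-variance cells
are capped at $|t| = 10^6$ with a warning rather than propagating
non-finite values.

# Leakage

The limited spatial resolution of EEG/MEG inverse solutions spreads
estimated activity between regions ("leakage"), which can masquerade as
connectivity. Given a source resolution matrix, `leakageMatrix()` draws
random non-homogeneous activations over each source ROI (per-vertex
amplitudes uniform in $(0.5, 1.5)$, all positive so non-homogeneity cannot
cancel by sign), propagates them through the ROI's point-spread functions,
sums absolute estimated activity within each destination ROI, and averages
over 100 repetitions. Columns are normalised by each destination ROI's
self-leakage (diagonal 1), and values are labelled low to high in 0.2-wide
bins. The resolution matrix itself is an input: computing it requires the
forward and inverse operators of a specific recording setup, which is out
of scope here.

# Simulations

Three scenarios, mirroring the questions a new connectivity metric must
answer (`runScenarioGrid()`):

1. **null** — two independent standard-normal patterns; both metrics must
   stay near zero (no false positives). Trials 30–300, 5 or 15 vertices.
2. **unidimensional** — one shared standard-normal amplitude replicated
   across vertices, scaled between regions by a constant from
   $\{-2,\dots,2\}$ (averaged over), plus Gaussian noise of standard
   deviation $10^{p}$ for $p \in [-2, 1.5]$; both metrics must detect it.
3. **multidimensional** — $Y = XT + E$ with standard-normal $X$ and $T$;
   only the multidimensional metric should detect it. The default $T$ is
   dense: the headline SNR curves assume every target vertex carries
   signal, because a target vertex with no incoming coefficient is pure
   noise whose cross-validated EV is systematically *negative* (of order
   $-n_x/n_t$, the relative variance of the prediction's estimation
   error), which caps the attainable mean far below 1. The sparsity
   dimension (10%–100% non-zero entries) can be explored by passing
   `sparsity = seq(0.1, 1, 0.1)`; repetitions then cycle through the grid.

Since signal standard deviation is fixed at 1, the noise exponent maps to
SNR as $-20p$ dB (`snrDb()`). The generators produce pattern pairs without
time axes: the transformation estimate depends only on the pattern
structure, not on the lag, so one pair stands for any latency pair. The
sub-sampling step is bypassed — simulated vertices are generated at target
dimensionality with no redundancy.

Problem sizes in the shipped checks: grid cells use 25 repetitions for the
multidimensional metric and 50 (100 in the acceptance script's ceiling
computation) for the cheap unidimensional metric, against the full
design's 100; these sizes reproduce the qualitative and quantitative
claims — multidimensional mean EV above 0.75 beyond 20 dB, a
unidimensional ceiling near 0.2, null means below 0.05 — with margins
well beyond their Monte-Carlo error.

# Synthetic multi-subject datasets

`generateDataset()` emulates the structure of an event-related source
study: by default 18 subjects, six ROIs, 50 trials, the 24-point latency
axis, and two task conditions of which the first is recorded in three
blocks. Each ROI's background is built from a small number of prototype
trial-by-time courses (four by default); each vertex is a noisy copy of
one prototype, emulating the redundancy of smooth source estimates.
Injected cross-ROI links overwrite the destination pattern at one latency
with a scaled shared amplitude ("UD") or a sparse random linear map
("MD") of the source pattern at another latency; MD maps are drawn once
per link and shared across subjects so group statistics can recover them.
The generator is a deterministic function of its specification.

What it does *not* emulate: realistic evoked waveforms and
autocorrelation in time, inter-subject variability of effect topography,
realistic leakage between ROIs, non-Gaussian noise, and trial-to-trial
nonstationarity. Passing tests on this generator therefore demonstrates
the estimator's statistical behaviour (calibration, sensitivity,
specificity), not performance on any particular real recording.

`writeEpochs()`/`readEpochs()` serialise epoch collections to a single
container file using R native serialisation of a validated plain-list
layout; the round trip is bit-exact. The package deliberately ships no
shell interface — like its relatives in source-space analysis it is driven
from R scripts; the exported functions are the interface.

# Known limitations

* The metric is bivariate and undirected: it cannot separate direct from
  indirect routes, nor infer direction or causality.
* Only linear transformations are modelled; nonlinear pattern
  relationships are approximated at best.
* Leakage can produce spurious dependencies, including at non-zero lags;
  the leakage matrix quantifies but does not remove it.
* Cross-validated EV is a biased estimator at very small test folds
  (ratio-of-variances noise), which depresses scores for target vertices
  with little signal; this is visible in the sparse-transformation
  simulations.
* The elbow criterion needs a genuine knee; on unstructured data it falls
  back to a fixed cluster count rather than adapting.
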