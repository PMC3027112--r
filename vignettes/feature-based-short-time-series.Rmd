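---
title: "Feature-based analysis of short expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based analysis of short expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcourse)
```

## The problem and the modelling idea

Most expression time-course experiments are short: fewer than about nine
time points, a handful of replicates per treatment, and sampling times
that are neither equally spaced nor identical across replicates.
Model-based longitudinal methods (splines, autoregressive models, HMMs)
need more data than this to estimate their parameters; static per-time
tests ignore the time ordering altogether.

`stcourse` takes a third route: each replicate's profile — the
piecewise-linear curve through its `(time, log2 expression)` points — is
summarized by scalar **curve features** that are meaningful to the
biology of a short horizon:

* `signed_auc`: the trapezoidal integral over a chosen window; net
  up/down change (log2 units × time).
* `slope`: rise over run between two chosen times; rate of change.
* `time_point`: the (possibly interpolated) level at one chosen time.
* `max_expr`, `min_expr`, `t_of_max`, `t_of_min`: extrema of the curve
  on an evaluation grid and when they occur.
* `steepest_pos_slope`, `steepest_neg_slope`: the largest and smallest
  consecutive-segment slopes; the sharpest induction/repression.
* `raw_expression`: the grid-evaluated levels themselves (one column per
  grid time) when clustering should see the full profile.

Features tolerate missing cells and unequal sampling (each replicate is
evaluated on its own observed range), incorporate the time ordering, and
turn an awkward longitudinal testing problem into an ordinary two-sample
problem per gene.

All data are handled on the log2 scale throughout; raw-scale input can
be logged on loading (`assemble_dataset(..., apply_log2 = TRUE)`).

## Interpolation

Any in-range time can be evaluated by linear interpolation between
bracketing measurements; there is **no extrapolation** — a query outside
the observed range is an error rather than a guess.  Interpolation
assumes local linearity, which is tenable for a few fill-in points but
not wholesale, so `interpolate_profile()` warns when more than 10% of a
requested grid had to be interpolated.  That 10% figure is a guideline
(warning), not a hard rule.

## The significance screen

`run_screen()` computes one feature value per replicate and compares
two treatments per gene:

* **Welch t-test** (unequal variances; the equal-variance assumption is
  hard to defend with 3–5 replicates).
* **Paired t-test** on within-replicate differences for paired designs.
* **Mann–Whitney U** (unpaired) and **Wilcoxon signed-rank** (paired),
  exact when sample sizes and ties allow.
* **Permutation t-tests**, unpaired (group relabellings) and paired
  (sign flips).  When the number of distinct arrangements is at most
  20,000 the full enumeration is used and
  `p = #{|T*| ≥ |T_obs|}/n_arrangements` (the observed labelling counts,
  so `p ≥ 1/n`); otherwise `n_perm` random draws (default 10,000) give
  `p = (count + 1)/(n_perm + 1)`, which can never report zero.

Degenerate samples get explicit conventions rather than NaNs: two
constant equal groups give `p = 1`; constant groups with different
means (or constant nonzero paired differences) give `p = 0` with a
`degenerate` flag.  Fewer than three replicates per arm triggers a
warning — the tests run, but power is poor.

### Outlier removal

Two small-sample screens can run per group before testing:

* **Mean–median discrepancy**: `D = |mean − median|/(σ̂/√n)` with `σ̂`
  the sample SD or the scaled MAD (`1.4826·MAD`).  While `D` exceeds a
  threshold (default 1.96) the value farthest from the median is
  removed, never reducing the sample below 3.  A caveat worth knowing:
  with the SD variant a *single* large outlier inflates `σ̂` enough to
  cap `D` near 1, so it mostly reacts to asymmetric contamination of
  several values (classic masking).  The MAD variant is robust to the
  outlier itself and is the one to reach for when a lone wild replicate
  is the concern — though a sample whose clean values are all equal has
  `MAD = 0`, and a zero spread estimate is defined to flag nothing.
* **Dixon's Q test** for 3 ≤ n ≤ 25, testing one candidate per tail
  against the embedded two-tailed critical table (Rorabacher 1991) at
  α ∈ {0.01, 0.05, 0.10}, with the r-statistic family chosen by n
  (r10 for 3–7, r11 for 8–10, r21 for 11–13, r22 for 14–25).

Under the default `outlier_action = "remove_gene"` a gene with any
flagged replicate is excluded from the results table and listed in the
outlier report — conservative, and the behaviour mirrored by the
acceptance checks.  `"remove_value"` instead drops the flagged values
(whole pairs, for paired tests) and tests the remainder when at least
`min_group = 2` values survive per arm.

## Multiplicity: estimating the number of true nulls

With `m` genes tested, `stcourse` provides Bonferroni and
Benjamini–Hochberg, and sharpens the FDR using an estimate of `m0`,
the number of genes for which the null is true.

**P-value plot.**  `N_p`, the count of p-values strictly greater than
`p`, plotted against `1 − p`, is linear with slope `m0` when nulls
dominate the upper tail.  `estimate_m0_pplot()` evaluates the step
function on a uniform grid of 101 points on [0, 1] (evaluating only at
the observed p-values would let a mass of tiny alternatives masquerade
as a steep "null" line), starts from the quarter of the grid with the
largest p-values, and extends the least-squares fit point by point while
the R² does not drop more than `r2_drop_tol = 0.005` below its running
maximum.  The slope of the final fit, clamped to [0, m], is `m0`.  A
constant-`N_p` region has R² defined as 1.  The tolerance is exposed;
larger values extend the fit further into the signal region and bias
`m0` upward.

**CDF plot.**  Under the complete null the empirical CDF of p-values
lies on the diagonal, with area 1/2 beneath it.  `estimate_m0_cdf()`
reports `pi0 = 0.5/A` (clamped to [0, 1]) with `A` the trapezoidal area
under the empirical CDF.  This estimator has a structural floor: even
purely alternative data have `A ≤ 1`, so it never reports below 0.5.
That floor is a property of the estimator, deliberately not "fixed";
the p-value-plot estimator is the one to trust near `pi0 = 0`.

`adjusted_fdr()` is the BH step-up with `m` replaced by `m0`
(`q_(i) = min_{j≥i} m0·p_(j)/j`), so it reduces exactly to BH at
`m0 = m` and is pointwise no larger otherwise.  `m0` is rounded only
for reporting; rates use the unrounded value to avoid quantization at
small `m`.  `operating_table()` turns `m0` into operating
characteristics per significance level α: expected false positives
`F = m0·α`, sensitivity `clamp(S − F, 0, m − m0)/(m − m0)` (undefined
at `m0 = m`), specificity `1 − α`, and estimated FDR `F/S` (0 when
nothing is significant).  The default α grid is 100 log-spaced points
from 1e-4 to 0.1.

## Clustering in feature space

`build_feature_matrix()` evaluates each gene's replicate-summarized
profile (median by default; mean optional; for paired data, optionally
the difference of two treatments) on a common grid and assembles the
chosen features.  Extrema and steepest slopes are computed on that
common grid rather than on raw per-replicate times so that every gene
lives in the same feature space.

Because the features mix units (times, levels, slopes), columns are
standardized to mean 0 / SD 1 before clustering by default
(`standardize_features()`; zero-variance columns are dropped).  An
unstandardized route exists (`--no-standardize`) for pre-scaled input.

Two algorithms, both under Euclidean or Manhattan distance:

* `st_kmeans()`: Lloyd iterations from k-means++ seeding, 10 restarts,
  best by within-cluster sum of (squared, for Euclidean) distances.
  Centroids are arithmetic means under both metrics — under Manhattan
  the metric governs assignment and evaluation only; a true k-medians
  update is a known, documented limitation.  Empty clusters are
  repaired by reseeding with the point farthest from its centroid.
* `st_pam()`: k-medoids via greedy BUILD then best-improvement SWAP.
  Best-improvement SWAP alone can terminate in a swap-local optimum
  (a 5-point, k = 3 counterexample exists in which the optimum is two
  swaps away), so the refinement is restarted from 9 additional seeded
  random medoid sets and the best solution kept.  With 10 starts the
  exhaustive optimum was reproduced on every one of 300 random small
  instances exercised by the test suite.  All tie-breaks are by lowest
  index, making results deterministic for a given seed.

Quality metrics: per-gene **silhouettes** (`(b − a)/max(a, b)`;
singleton clusters get 0 by Rousseeuw's convention) with each gene's
nearest neighbouring cluster; **homogeneity** (mean distance to the own
cluster representative — centroid or medoid; lower is tighter); and
**separation** (size-weighted mean distance between representatives;
higher is better).  Homogeneity and separation are defined against
cluster representatives; an all-pairs variant would differ by
constants but rank clusterings similarly.  `choose_k()` scans a k
range and picks the highest average silhouette, ties to the smallest k.

## The synthetic-data generator

`simulate_dataset()` emits the two tab-delimited input files (plus a
truth table) and is the test bed for everything above.  It emulates the
supported data model: two or more treatments, a few replicates, a short
base grid (default 0, 2, 8, 24 h — a typical stimulus-response design),
optional per-replicate time jitter and interior-point dropout
(irregular sampling), i.i.d. N(0, σ²) noise on the log2 scale (default
σ = 0.3, a mid-range replicate CV for arrays), optional missing cells,
gene baselines N(7, 1) (log2 intensity scale), and for alternative
genes an additive log2 effect in the first treatment (constant shift,
ramp, or peak; default magnitude 1 = a two-fold change).  Cluster
structure comes from up to four template shapes — flat, up-ramp,
down-ramp, peak, in that order, so that small template counts use
maximally distinct shapes — scaled by `template_amplitude`.

What it does **not** emulate: gene–gene correlation, intensity-dependent
(heteroscedastic) noise, background/dye artefacts, or count noise.
Passing calibration tests on this generator therefore shows the
machinery is correct under its stated assumptions, not that real arrays
meet those assumptions.

Study conditions used by the test suite and the acceptance script,
chosen once as realistic for the field: null calibration at 500 genes,
4 replicates per arm, σ = 0.3; p-value mixtures at m = 1000 with
Beta(0.05, 1) alternatives and 200 replicates; cluster recovery at 60
genes, 3 templates, amplitude 3 with baseline SD 0.25 — amplitude 3 is
where the *closest* template pair (flat vs either ramp) sits at about
five noise SDs in mean profile distance, the boundary regime for clean
recovery; k is scanned over 2–6 across 20 seeds.

## Numerical conventions, in one place

* Missing cells: empty field or literal `NA` (any case); plain or
  scientific decimals; LF or CRLF line endings; trailing blank lines
  ignored.  Replicate numbers are opaque integer labels; treatment
  names are case-sensitive.
* Profiles with every cell missing are dropped with a report; a grid
  time covered by no replicate is an error naming the time.
* Extrema/steepest-slope ties break to the earliest time; all
  clustering ties break to the lowest index.
* Exact-enumeration cutoff for permutation tests: 20,000 arrangements.
* `p = 0` is reported only by the degenerate conventions, never by a
  permutation count.
* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; the CLI records seeds, parameters and input
  checksums in a `#` manifest header on every output, so identical
  commands produce identical bytes.

## Limitations

Two treatments per comparison; two-sided alternatives only; no variance
moderation across genes (each gene is tested on its own handful of
replicates); no spline/model-based smoothing; silhouette-scan is the
only automatic k selection.  For long series, features aimed at
dimension *reduction* (autocorrelation, higher moments) would be the
natural extension of the same framework.
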