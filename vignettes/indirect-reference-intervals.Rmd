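---
title: "Estimating reference intervals from mixed laboratory data"
author: "ksref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reference intervals from mixed laboratory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksref)
```

## The problem

A reference interval is the central 95% range (2.5th to 97.5th percentile)
of a laboratory analyte in a healthy population. Direct establishment —
recruiting a healthy cohort of 120+ individuals per partition — is
expensive, ethically restricted in children, and confounded by chronic
morbidity in older adults. Indirect methods instead start from routine
results stored in a laboratory information system. Such data mix
*physiological* results (the majority, under the usual assumption of
routine care) with *pathological* ones, and the statistical task is to
recover the physiological distribution from the mixture without ever
labelling individual samples.

`ksref` implements an estimator in the tradition of truncation-point
methods: it assumes

1. the physiological component is a *power-normal* distribution — Gaussian
   after a Box-Cox transform `y = (x^λ − 1)/λ` (log at `λ = 0`) with
   `λ ∈ [0, 1]`, which spans log-normal to Gaussian shapes and therefore
   covers most right-skewed analytes; and
2. a *truncation interval* `T = [t1, t2]` exists inside the observed range
   in which the proportion of pathological results is negligible.

No assumption at all is made about the distribution of pathological
results; they are only assumed to be concentrated outside `T`.

## The objective function

Let the observed results be rounded to a fixed number of decimals and
summarized as a histogram of distinct values with counts (all run times
scale with the number of distinct values, not the number of samples). For
a candidate `(λ, μ, σ, T)` the minimization target is

```
KS = sup |D_T − F_T| / sqrt(n) + p1 + p2
```

where, inside `T`, `D_T` is the conditional empirical CDF of the
transformed data (anchored to 0 at the lower edge of `T` and 1 at its
upper edge), `F_T` is the conditional Gaussian CDF on the same interval,
and `n` is the number of samples inside `T`. `p1` and `p2` are one-sided
penalties outside `T`: with `c = (n/N)/q` the implied physiological
fraction of the dataset (`q` the Gaussian mass on `T`, `N` the total
count), the scaled model CDF `c·Φ` may not exceed the observed CDF below
`T` (`p1`), and the scaled model survival `c·(1 − Φ)` may not exceed the
observed survival above `T` (`p2`); negative excursions are ignored.
This one-sidedness is what makes pathological tail mass penalty-free: a
pile of abnormal results below `t1` only raises the observed CDF there,
which can never activate `p1`. Only a fit that *implies* more
physiological mass outside `T` than was observed at all is punished.

### Discretization conventions

Two numerical conventions matter and both derive from treating the
rounded values as *bin centers* of width `10^-decimals`:

* **Edges, not centers.** The empirical CDF steps at upper bin edges, so
  the Gaussian CDF is evaluated at `x + h/2` (`h` the bin width) and the
  truncation interval spans outer bin edges. Evaluating the model at the
  centers instead forces a spurious mismatch at the lower anchor of `T`
  equal to the first bin's mass, which dominates the objective on large
  datasets and biases `σ` low.
* **Both sides of every jump.** The sup distance between a step CDF and a
  continuous CDF is attained next to a jump, so at each edge both the
  pre-jump and the post-jump empirical level are compared against the
  model. On finely rounded data this is a refinement without visible
  effect; on coarse histograms (an integer-rounded analyte has bins
  holding several percent of the data each) it is essential. With
  one-sided evaluation the model can cut corners between checkpoints, and
  the truncation search then prefers narrow intervals containing a
  handful of fat bins whose few checkpoints a two-parameter Gaussian can
  interpolate almost exactly — an overfit that extrapolates to badly
  shrunken limits. The two-sided sup gives every fit a floor of half the
  largest conditional bin mass inside `T`, which both blocks that overfit
  and naturally favors wide truncation intervals.

The penalties are evaluated at the distinct values strictly outside `T`.
In particular a model whose tails extend beyond the observed range is not
penalized for tail mass beyond the data — a Gaussian always has infinite
support, and when `T` touches the edge of the data there is simply no
observation outside it to compare against.

## The search

The optimization is nested, outermost to innermost:

1. **`λ` (brute force).** Every `λ` in `0, 0.1, …, 1.0`, then a fine pass
   `λ* − 0.09, …, λ* + 0.09` in steps of 0.01 around the coarse winner,
   clamped to `[0, 1]`. Grid search is used because the per-`λ` profile
   is noisy with unpredictable local minima.
2. **`T` (brute force).** Candidate lower limits are the distinct values
   whose percentile rank lies in a window (default 5th–30th percentile);
   candidate upper limits likewise (default 70th–95th). Every admissible
   pair with at least `min_n_inside` samples (default 50) is examined.
   Candidate membership is defined by percentile rank, which is invariant
   under the monotone Box-Cox map, so the *same* sample subsets are
   examined at every `λ` and totals are comparable across the grid.
3. **`(μ, σ)` (Nelder-Mead).** For each `(λ, T)` a two-parameter simplex
   search starts from the robust pair (median, IQR/1.349) of the
   transformed data inside `T`, with one restart from (mean, SD) if the
   iteration cap (500) is hit.

Ties on the objective within `1e-12` prefer the wider truncation interval
(more data), then the smaller `λ` (simpler transform), so the result is
deterministic and independent of input order.

The winning `(λ, μ, σ)` is back-transformed to analyte units:
`lower = inv_boxcox(μ − z·σ, λ)` and `upper = inv_boxcox(μ + z·σ, λ)`
with `z = 1.959964` (kept at full precision rather than the display value
1.96). A fit for which `λ·(μ − z·σ) + 1 ≤ 0` has no finite
back-transformed lower limit; this is reported as an error (an implausible
fit) rather than clamped.

### Performance-relevant numerics

Two refinements keep the brute-force search fast without changing what is
being minimized:

* Consecutive truncation pairs that share a lower limit warm-start the
  simplex from the previous pair's optimum (their optima are very close),
  with a smaller initial simplex; the cold robust start is used at the
  beginning of each row and by the iteration-cap restart. The pair order
  is fixed, so results remain deterministic.
* Besides the objective-spread criterion (`1e-7`), the simplex also stops
  once it has collapsed below `1e-3` times the robust scale in both
  coordinates. The sup-type objective is only piecewise smooth, and
  without this the simplex can spend hundreds of iterations shrinking
  around a kink, changing the limits by amounts far below the rounding
  precision. On a 50,000-sample log-normal analyte with 3-decimal
  rounding these two changes reduce one estimation from several minutes
  to about a minute on one core.

Two early exits make the penalty scans cheap: walking away from `T`, the
running bounds `c·Φ` (downward) and `c·(1 − Φ)` (upward) are monotone, so
each scan stops as soon as the bound falls under the current supremum.

## Uncertainty

Confidence intervals come from a percentile bootstrap: each replicate
resamples the full value multiset with replacement, re-runs the complete
estimator (`λ` included), and the CI bounds are the empirical
`(1 ± level)/2` percentiles (inverse-ECDF convention) of the replicate
limits. The percentile method is used rather than BCa — it is the plain
reading of "bootstrapping of the input dataset". Replicates draw from
per-replicate RNG streams keyed by `(seed, replicate)` (L'Ecuyer-CMRG),
so results are bit-identical for any worker count and execution order.
Failed replicate estimations are excluded and counted; more than 20%
failures aborts with an error rather than returning a CI from a biased
subset.

## The simulation harness

`preset_scenario()` reproduces the estimator's standard validation
conditions:

| analyte | physiological | n per cycle | rounding |
|---|---|---|---|
| "hemoglobin" | Gaussian, μ = 14.0, σ = 0.98 (interval 12.0–16.0 g/dL) | 10,000 | 2 decimals |
| "TSH" | log-normal with 2.5th/97.5th percentiles 0.25–4.0 mU/L | 50,000 | 3 decimals |
| "γ-GT" | log-normal, 10–50 U/L | 25,000 | 0 decimals |

A scenario adds a stated fraction (0–30%) of draws from an abnormal
distribution while holding the total fixed; the shipped abnormal-low
default for hemoglobin is the Gaussian with 95% interval 8.0–12.0 g/dL,
centered on the true lower limit — the hardest abnormal-low placement.
Nonpositive draws are resampled rather than clipped (clipping would
distort the shape near zero, and the estimator requires positive input).
Each cycle draws from a stream keyed by `(seed, cycle)` and the summary
reports the median limits across cycles, their 5th–95th percentile range
(the only percentile reading of a cross-cycle "90% interval" consistent
with on the order of 100 cycles), and optionally the fraction of cycles
inside stated margins.

What the generator does *not* emulate: analytical imprecision and drift,
age/sex structure, repeat measurements from the same patient, and
pathological components with other shapes than the configured
Gaussian/log-normal. Passing the simulation checks therefore shows
parameter recovery under the model's own assumptions plus contamination —
it does not certify performance on any particular real laboratory's data.

## Problem sizes used by the test suite

The packaged checks scale the validation study down to keep a full run
fast: recovery checks use 10 cycles (hemoglobin, and the contaminated
hemoglobin scenario) and 5 cycles (TSH, γ-GT) at the full stated sample
sizes; bootstrap behavior is checked with 40 replicates across 10 seeds
at n = 1,000 plus a CI-width comparison at n = 10,000 with a reduced
truncation-candidate grid; unit tests run on datasets of 1,000–6,000
values with a reduced grid. These sizes are the package's choice of a
fast-but-informative default; the full-scale study (100 cycles) is
available through `run_scenario()` or the `simulate` subcommand.

## Known limitations

* `λ` is searched in `[0, 1]` only: left-skewed analytes are out of
  scope, and for symmetric (truly Gaussian) data the cap at 1 means
  transform-selection noise can only push the fit toward the log side.
  This produces the small inward bias of both limits visible in the
  uncontaminated hemoglobin simulations (median limits approximately
  12.15/15.90 against true 12.08/15.92) and is inherent to the one-sided
  `λ` range; upper limits of right-skewed analytes show more cross-cycle
  volatility for the same reason.
* The one-sided penalties cannot react to a model with too *little* tail
  mass, so a slight downward bias of `σ` (fraction of a percent on finely
  rounded data, larger on coarse histograms) remains.
* Estimation quality degrades when abnormal results are centered on a
  reference limit and exceed roughly 20% of the dataset; this is a
  property of the truncation approach itself, not of the implementation.
* Age-continuous reference intervals are out of scope: the estimator
  handles one homogeneous partition at a time.
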