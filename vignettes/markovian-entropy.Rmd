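---
title: "Markovian entropy for calcium activity time series: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian entropy for calcium activity time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calentropy)
```

## The problem

Calcium imaging of developing neural tissue produces single-cell
fluorescence time series whose dynamics are often irregular: they are not
dominated by cleanly separable spikes, waves or oscillations, so
feature-counting methods capture only part of what the cells are doing.
`calentropy` scores each trace by how *predictable* its transitions
between activity levels are, by representing the trace as a k-th order
n-state Markov process and measuring the Shannon entropy of its estimated
transition structure. Alongside the core measure it ships the three
comparators such a score is usually evaluated against (spike counting,
average signal power, the rescaled-range Hurst exponent), the baseline
correction applied before analysis, and the population statistics used to
compare experimental conditions.

## The measure

For a trace $x_1,\dots,x_T$:

1. **Quantile discretization.** The empirical quantiles at levels
   $j/n$, $j = 1,\dots,n-1$ (linear interpolation between order
   statistics) split the values into $n$ states, giving a symbol sequence
   $s_t \in \{0,\dots,n-1\}$ of the same length. Each state holds a
   near-equal share of the data, so no activity thresholds need to be
   chosen and the symbols depend only on the ranks of the values — any
   strictly increasing transform of the trace leaves them unchanged.
   Values tied with a boundary go to the lower state (a fixed, documented
   convention; the choice only matters for tie-heavy data).
2. **Transition matrix.** Every k-gram-to-next-symbol transition is
   tallied into an $n^k \times n$ count matrix whose rows enumerate all
   k-grams in lexicographic order (oldest symbol most significant), and
   rows are normalized by their sums. Rows whose k-gram never occurs are
   flagged unobserved and left at zero.
3. **Entropy.** Each row contributes $E = -\sum_i p_i \log_2 p_i$ (with
   $0 \log_2 0 := 0$); the row entropies are summed and divided by
   $n^k \log_2 n$, the maximum attainable sum. The result lies in
   $[0, 1]$: 0 for fully deterministic transitions, 1 when every observed
   row is uniform.

Unobserved rows contribute 0 bits while $n^k \log_2 n$ stays in the
denominator — the only reading consistent with that fixed normalization.
The consequence is a *sparseness artifact*: once $n^k \cdot n$ approaches
the number of observed transitions $T - k$, most rows are empty or
single-count and the value is dragged toward 0 for the *more* diverse
population, which can flip the sign of a between-population effect size.
`markov_entropy()` warns in this regime, reports `unobserved_rows`, and
`parameter_sweep()` maps the sign-flip frontier explicitly. On the
synthetic study populations used in the tests (length 900), the flip
appears only at $n^k = 1296$, while truncating traces to 100 points moves
it down to $n^k = 216$ — the frontier is a function of trace length, which
is why small $n$ and $k$ (the defaults are $n = 2$, $k = 1$) are the
recommended operating point for traces of a few hundred points.

The raw per-row bit sums are exposed as `row_entropies`; the headline
`value` is the dimensionless normalized fraction of the maximum, which is
what makes values comparable across experiments when $(n, k)$ are
reported with them.

A constant (dead-cell) trace discretizes to a single state; its entropy
is defined as 0 and flagged `degenerate` rather than raising an error, so
population pipelines survive silent cells.

### What the estimator does and does not recover

`markov_entropy()` is a plug-in estimator: fed the true state path of a
simulated chain it recovers the generating chain's normalized entropy
(`true_entropy()`) with bias below 0.02 at length 900 (verified in the
test suite). Fed the *trace*, it sees the states only through quantile
binning, and binning enforces an exactly equal occupancy split. A
persistent chain's occupancy fluctuates (for a symmetric stay-0.9
two-state chain at length 900 the half-occupancy imbalance has SD of
roughly 45 points), so the forced split mislabels about that many points
per trace *regardless of how small the emission noise is* — binning is
rank-based, so shrinking the noise does not help. Each mislabel
manufactures spurious transitions, and the estimated entropy of such
traces is systematically higher than the generating chain's (about 0.61
versus 0.469 under the conditions above; an independent
re-implementation of the pipeline gives the same number). At stay
probability 0.6 the occupancy barely fluctuates and the bias is within
0.02. This is a property of quantile-based state assignment on strongly
persistent two-level signals, not of the entropy calculation; it is
shared by any implementation of this measure. Comparisons *between*
populations are unaffected in sign and remain very large (|d| > 2 for
stay 0.9 vs 0.6), because the inflation applies to both populations and
does not reorder them.

## Preprocessing: asymmetric least squares baseline

Slow drifts (bleaching, focus, dye loading) are removed before analysis
by subtracting the baseline $z$ minimizing
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$, with
$w_i = p$ where $y_i > z_i$ and $1 - p$ otherwise, iterated from uniform
weights to convergence; each iteration solves the banded system exactly
via a sparse Cholesky factorization. Defaults $\lambda = 10^5$,
$p = 0.01$, 20 iterations: $\lambda$ in the canonical $10^4$–$10^6$ range
passes minute-scale drift into the baseline of a ~900-point trace
sampled at 0.25 Hz while leaving second-scale transients in the residual,
and $p = 0.01$ makes positive excursions nearly weightless so the
baseline tracks the activity floor. The solution is translation
invariant, reproduces constants and straight lines to numerical
precision, and is idempotent to about 1% of the noise scale (the
asymmetric reweighting of an already-detrended trace re-shifts it by a
small offset at the scale of the noise quantiles — exact idempotence is
not a property of the objective). Detrending changes quantile-based
entropy only through rank changes: on trend-free synthetic traces the
before/after difference stays below 0.05.

## The comparator measures

**Spike counting.** An onset is a point at or above `onset_ratio`
(default 1.5, i.e. 150%) times its predecessor; the spike persists while
the trace stays at or above the *onset point's* value and must last at
least `min_duration` points (default 2) to count; scanning resumes after
the spike ends, so spikes never overlap. The onset value is read as the
elevated value at the onset point, not the pre-onset baseline — that is
what makes a two-point duration rule a real constraint rather than a
tautology; the alternative baseline reading would count nearly any decay
tail. Ratio thresholds are undefined where the predecessor is not
strictly positive (routine after detrending); those points are skipped
and counted in a warning. The count is invariant under positive rescaling
but not under additive shifts, and the choice of `onset_ratio` is
genuinely consequential: the test suite constructs two populations
(many small events vs few large ones) whose spike-count effect size
changes sign between ratios 1.5 and 4.

**Average power.** $(1/T)\sum_i X_i^2$, the time-domain form of the
signal's average power by Parseval's theorem.

**Hurst exponent.** One 512-point window is placed uniformly at random
(seeded) in the trace; for each dyadic size $s = 512, 256, \dots, 8$ the
window is tiled from its left edge and the rescaled ranges of the tiles
averaged; $H$ is the OLS slope of $\log_2(\text{mean } R/S)$ on
$\log_2 s$. The regression is in log–log coordinates: a slope on raw
mean $R/S$ versus $\log_2 s$ would not be dimensionally a scaling
exponent and would not give $H \approx 0.5$ for white noise. Within one
window of length $i$, $R_i$ is the range of the cumulative mean-adjusted
series and $S_i$ the standard-deviation series; the mean of $(R/S)_i$ is
the window's statistic, with $S_i = 0$ prefixes skipped. Two forms of
$S_i$ are available: the default `classic` centers the first $i$ points
on their common mean, while `running_mean` centers each term on the
running mean of its own prefix. The running-mean form, which appears in
some descriptions of the procedure, systematically deflates $S_i$ at
small $i$ and biases the white-noise calibration to $H \approx 0.44$;
the classic form gives $H \approx 0.49$ on 900-point white noise and
$H \approx 0.93$ on random walks (500 traces each in the tests), which is
why it is the default. Estimates with $H > 1$ (a known finite-sample
occurrence, ~30% on pure random walks, rare on real traces) are returned
flagged and dropped by the population layer.

## Population statistics

Two per-cell measure distributions are compared by the two-sample
Kolmogorov–Smirnov test (asymptotic two-sided p; sample sizes in scope
are tens to thousands, and measured type-I error at $n = 100$ is ~0.03–0.04
at the 0.05 level) and Cohen's d with pooled $(n-1)$ SD, signed as
mean(A) − mean(B) with A the first-listed population. Bonferroni
adjustment is `min(1, m p)` with `m` always explicit (default 1).
Effect sizes map to star bands lower-inclusively:
\* ≥ 0.20, \*\* ≥ 0.50, \*\*\* ≥ 0.80, \*\*\*\* ≥ 1.00, \*\*\*\*\* ≥ 2.00
(the ≥ convention is used consistently, including at exact edges).

`subsample_separation()` probes how separation depends on sample size by
drawing with-replacement subsamples at each size and recording the mean
and SD of the KS p-values, always alongside an A-vs-A control drawn
twice from the first population; genuinely different populations show a
monotone fall of mean p with size while the control stays high.
`parameter_sweep()` recomputes the entropy effect size over an (n, k)
grid, optionally on truncated traces, and marks cells whose sign differs
from the smallest-(n, k) cell.

## Synthetic ground truth

Three generators emulate the trace classes the measures are meant to
distinguish, each fully seeded (per-cell seeds derive deterministically
from a master seed, so a population is reproducible and extending
`n_cells` preserves the existing cells):

- `gen_chain_trace()`: a known two-or-more-state chain emitting one
  fluorescence level per state plus Gaussian noise; the true state path
  travels with the trace and `true_entropy()` gives the generating
  chain's normalized entropy. Default length 900 points (one hour at
  0.25 Hz); default noise SD 0.05 of a unit level gap, small enough that
  binning errors are dominated by occupancy forcing (above), not noise
  overlap.
- `gen_spike_trace()`: baseline plus Bernoulli-timed transients and
  noise, default length 800 (10 Hz synaptic-style recording), default
  rate 0.01/point and amplitude 3× a unit baseline. Each event rises over
  one sample (60% of amplitude at the event time, peak one sample later)
  before decaying exponentially ($\tau = 3$ points). The brief rise
  reflects sampling-limited onset kinetics and is what makes planted
  events recoverable by a ratio-based counter with a two-point duration
  rule: an instantaneous jump followed by pure decay stays at-or-above
  its own peak for exactly one sample, and under the onset-value
  persistence reading *no* such event could ever be counted. With the
  default kernel, detection is reliable once
  `rise_fraction * amplitude >= 0.5 * baseline`.
- `gen_irregular_trace()`: stationary AR(1) around a mean level, the
  minimal model of irregular progenitor-like activity; `ar = 0` gives
  white noise (entropy ≈ 1, H ≈ 0.5), `ar` near 1 slow predictable
  wandering.

Gaussian noise is used throughout as the minimal choice. What these
generators deliberately do *not* emulate: photon shot noise, bleaching
photophysics beyond the deterministic trend fixtures of `add_trend()`,
GECI/buffering kinetics, or correlated activity between cells. Passing
tests on them therefore validates the estimators' contracts and
calibration, not the biology of any particular preparation.

## Numerical and design choices

- Quantile type 7 (linear interpolation), the default of mainstream
  numeric libraries; documented because tie-heavy data can shift
  boundaries between definitions.
- Monotone-transform invariance of the entropy is exact (integer symbol
  identity), and is asserted exactly in the tests; affine invariance of
  the Hurst estimate is exact in real arithmetic and holds to ~1e-11 in
  floating point, asserted at 1e-8.
- k-gram rows are indexed with the oldest symbol most significant; this
  affects only the ordering of `row_entropies`, never the value.
- Zero pooled SD makes Cohen's d undefined and is a classed error
  (`calentropy_zero_sd`), not an NA, except inside sweep/subsample loops
  where it is caught and recorded as NA.
- Test and acceptance problem sizes — 100–200 cells per population,
  trace length 900, 200 subsampling repetitions, 500 Hurst calibration
  traces, exhaustive binary-trace enumeration to length 12 — were chosen
  as the smallest sizes at which the population phenomena (monotone
  separation, sign-flip frontier, calibration means) are stable across
  seeds.

## Known limitations

- The entropy of strongly persistent two-level signals is inflated by
  quantile binning's forced equal occupancy (quantified above); absolute
  values should be compared only between traces of similar length and
  identical $(n, k)$, and population *differences* are the robust output.
- The unweighted row sum is the measure's definition; it is **not** an
  entropy rate (rows are not weighted by stationary occupancy), and the
  package deliberately does not offer that variant.
- Exact numeric parity with other baseline-correction settings is not
  guaranteed when comparing against externally detrended data; λ and p
  are exposed for that reason.
- The KS p-values are asymptotic; for samples below ~20 per group treat
  them as approximate (the subsampling analysis reports their
  distribution rather than any single value).
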