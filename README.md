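# calentropy

Markovian entropy and companion measures for single-cell calcium
activity time series.

Developing neural tissue shows irregular calcium dynamics that are
poorly captured by counting visually distinct features such as spikes or
waves. `calentropy` scores each fluorescence trace by the
*predictability of its transitions between activity levels*: the trace
is discretized into `n` quantile-binned states, its k-th order
transition matrix is estimated, and each of the `n^k` rows is scored by
the Shannon entropy

    E = -sum_i p_i log2(p_i)

The row entropies are summed and normalized by the maximum `n^k log2(n)`,
giving a value in [0, 1] — 0 for fully predictable transition dynamics,
1 for fully unpredictable. The package also implements the measures this
score is typically evaluated against (amplitude-ratio spike counting,
average power `(1/T) sum X_i^2`, rescaled-range Hurst exponent), the
asymmetric-least-squares baseline correction applied before analysis,
population comparison statistics (two-sample Kolmogorov–Smirnov test,
Cohen's d with effect-size star bands, sample-size subsampling, and
(n, k) parameter sweeps), and seeded synthetic trace generators with
known ground truth. It is aimed at anyone analyzing wide-format CSV
exports of single-cell fluorescence traces, from the R prompt or the
shell.

## Worked example

Two synthetic populations of 100 cells, one driven by a persistent
(stay-probability 0.9) two-state chain and one by a near-random
(stay-probability 0.6) chain — a stand-in for comparing an early,
high-activity developmental stage against a later, more predictable one:

```r
library(calentropy)
stay <- function(p) matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
young <- gen_population(100, seed = 1, gen = gen_chain_trace,
                        P = stay(0.6), name = "early")
old   <- gen_population(100, seed = 2, gen = gen_chain_trace,
                        P = stay(0.9), name = "late")
compare_populations(young, old, measure = "entropy", m_comparisons = 3)
#> entropy: early (n=100) vs late (n=100)
#>   KS D = 1.0000, p = 0 (adjusted 0); Cohen's d = 5.0866 [*****]
```

The early population is far more entropic (positive d = mean(early) −
mean(late), five stars = |d| ≥ 2), the KS distance of 1 shows the two
per-cell entropy distributions do not even overlap, and the p-value is
Bonferroni-adjusted for the 3 pairwise comparisons of a three-stage
design. Per-cell values, fitted transition matrices and simulation from
a fit are all available:

```r
trace_measures(young[1:3], measures = c("entropy", "power"))
#>     cell_id entropy entropy_unobserved entropy_degenerate  power
#> 1 cell_0001  0.9692                  0              FALSE 0.5142
#> 2 cell_0002  0.9773                  0              FALSE 0.5068
#> 3 cell_0003  0.9842                  0              FALSE 0.4956

fit <- markov_entropy(gen_chain_trace(stay(0.9), seed = 7), n = 2, k = 1)
summary(fit)
#> Markovian entropy (n = 2, k = 1): 0.4764
#>
#> Transition probabilities:
#>       0     1
#> 0 0.898 0.102
#> 1 0.102 0.898
#> ...
```

The same analyses are available from the shell over CSV trace tables
(rows = time points, columns = cells; `#` provenance headers are written
and skipped automatically):

```sh
cli=$(Rscript -e 'cat(system.file("cli", "calentropy", package = "calentropy"))')
Rscript $cli simulate chain traces.csv --cells 50 --length 900 --seed 1
Rscript $cli detrend traces.csv detrended.csv --lambda 1e5 --p 0.01
Rscript $cli analyze detrended.csv measures.csv --measure entropy,spikes,power,hurst
Rscript $cli compare a.csv b.csv cmp.csv --measure entropy --bonferroni 3
```

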