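# Evaluate expr with a temporary RNG state when seed is given; the
# caller's .Random.seed is restored afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable per-cell seed derived from a master seed: deterministic, exact in
# double arithmetic, and independent of n_cells so growing a population
# preserves the earlier cells' traces.
.derive_seed <- function(master, i) {
  (as.numeric(master) * 1009 + as.numeric(i) * 9176) %% 2147483647
}

#' Normalized entropy of a known transition matrix
#'
#' The analytic counterpart of [markov_entropy()] at order k = 1: the sum
#' of the Shannon entropies of the rows of a row-stochastic matrix,
#' divided by the maximum `n * log2(n)`. Used as ground truth for chains
#' generated by [gen_chain_trace()].
#'
#' @param P n-by-n row-stochastic matrix (rows sum to 1 within 1e-12).
#' @return scalar in `[0, 1]`.
#' @examples
#' true_entropy(diag(2))                                  # 0
#' true_entropy(matrix(0.5, 2, 2))                        # 1
#' true_entropy(matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)) # 0.4690
#' @export
true_entropy <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("'P' must be a square row-stochastic matrix", call. = FALSE)
  n <- nrow(P)
  sum(.row_entropies(P)) / (n * log2(n))
}

.stationary_dist <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Generate a trace from a known Markov chain
#'
#' Simulates a first-order chain with the given transition matrix, mapping
#' each state to a fluorescence level and adding Gaussian noise. The true
#' symbol path is attached as attribute `"states"`, and the generating
#' chain's normalized entropy is available via [true_entropy()], making
#' these traces the ground-truth fixture for the entropy estimator.
#'
#' @param P n-by-n row-stochastic transition matrix.
#' @param levels strictly increasing fluorescence levels, one per state.
#' @param noise_sd Gaussian noise SD; keep below half the smallest level
#'   gap so quantile binning recovers the states with high probability.
#' @param length trace length (default 900, one hour at 0.25 Hz).
#' @param seed optional integer seed (caller's RNG state restored).
#' @param init_state initial state in `1..n`, or `NULL` (default) to draw
#'   it from the stationary distribution.
#' @return numeric trace with attribute `states` (integer path in `1..n`).
#' @export
gen_chain_trace <- function(P, levels = c(0, 1), noise_sd = 0.05,
                            length = 900L, seed = NULL, init_state = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("'P' must be a square row-stochastic matrix", call. = FALSE)
  if (length(levels) != n || any(diff(levels) <= 0))
    stop("'levels' must be strictly increasing, one per state", call. = FALSE)
  if (noise_sd < 0 || (noise_sd > 0 && n > 1 &&
                       noise_sd >= min(diff(levels)) / 2))
    warning("noise_sd is large relative to the level gaps; ",
            "states may not be recoverable by quantile binning", call. = FALSE)
  .with_seed(seed, {
    states <- integer(length)
    states[1] <- if (is.null(init_state))
      sample.int(n, 1L, prob = .stationary_dist(P)) else as.integer(init_state)
    for (t in 2:length)
      states[t] <- sample.int(n, 1L, prob = P[states[t - 1L], ])
    x <- levels[states] + stats::rnorm(length, sd = noise_sd)
    attr(x, "states") <- states
    x
  })
}

#' Generate a spike-dominated trace
#'
#' Emulates a synaptic-neuron-like recording: a flat baseline with
#' transient events at Bernoulli-random time points, plus Gaussian noise.
#' Each event contributes a kernel with a one-sample rise
#' (`rise_fraction * amplitude` at the event time), the full `amplitude`
#' one sample later, and exponential decay with time constant `decay_tau`
#' thereafter. The brief rise reflects sampling-limited onset kinetics of
#' real calcium transients and gives every event a ratio-detectable onset
#' followed by at least one point at or above it, so an amplitude-ratio
#' spike counter ([count_spikes()]) can recover the planted events; an
#' instantaneous jump followed by pure decay would never satisfy a
#' two-point duration rule. Event times are attached as attribute
#' `"events"`.
#'
#' @param length trace length (default 800 points, as in a 10 Hz / 80 s
#'   synaptic recording).
#' @param baseline resting fluorescence level, > 0.
#' @param spike_rate event probability per time point, in `[0, 1)`;
#'   ignored when `event_times` is given.
#' @param amplitude event peak height above baseline; with the default
#'   kernel the 150\% onset rule triggers reliably once
#'   `rise_fraction * amplitude >= 0.5 * baseline` (a warning marks
#'   amplitudes below `0.5 * baseline`, undetectable in any reading).
#' @param decay_tau exponential decay constant in time points.
#' @param noise_sd Gaussian noise SD.
#' @param seed optional integer seed.
#' @param event_times optional integer vector of planted event onsets
#'   (overrides `spike_rate`), for ground-truth recovery tests.
#' @param rise_fraction fraction of `amplitude` reached at the event time
#'   itself, in (0, 1]; default 0.6.
#' @return numeric trace with attribute `events` (integer event indices).
#' @export
gen_spike_trace <- function(length = 800L, baseline = 1, spike_rate = 0.01,
                            amplitude = 3, decay_tau = 3, noise_sd = 0.02,
                            seed = NULL, event_times = NULL,
                            rise_fraction = 0.6) {
  stopifnot(baseline > 0, spike_rate >= 0, spike_rate < 1,
            amplitude >= 0, decay_tau > 0, noise_sd >= 0,
            rise_fraction > 0, rise_fraction <= 1)
  if (amplitude > 0 && amplitude < 0.5 * baseline)
    warning("amplitude < 0.5 * baseline: events cannot trip a 150% onset rule",
            call. = FALSE)
  .with_seed(seed, {
    events <- if (is.null(event_times)) which(stats::runif(length) < spike_rate)
              else as.integer(event_times)
    if (base::length(events) && (min(events) < 1L || max(events) > length))
      stop("event_times outside the trace", call. = FALSE)
    kern <- amplitude * c(rise_fraction, exp(-(0:ceiling(8 * decay_tau)) / decay_tau))
    transients <- numeric(length)
    for (e in events) {
      idx <- e:min(length, e + base::length(kern) - 1L)
      transients[idx] <- transients[idx] + kern[seq_along(idx)]
    }
    x <- baseline + transients + stats::rnorm(length, sd = noise_sd)
    attr(x, "events") <- events
    x
  })
}

#' Generate an irregular progenitor-like trace
#'
#' Emulates the complex, irregular activity of neural progenitor cells as
#' a stationary AR(1) process around a mean level: positively
#' autocorrelated but with no discrete event structure. `ar_coefficient`
#' near 0 gives white-noise-like (high entropy) traces; values near 1 give
#' slowly wandering, more predictable dynamics.
#'
#' @param length trace length (default 900).
#' @param ar_coefficient AR(1) coefficient in (-1, 1).
#' @param innovation_sd innovation SD, > 0.
#' @param mean_level process mean.
#' @param seed optional integer seed.
#' @return numeric trace.
#' @export
gen_irregular_trace <- function(length = 900L, ar_coefficient = 0.8,
                                innovation_sd = 1, mean_level = 0,
                                seed = NULL) {
  stopifnot(abs(ar_coefficient) < 1, innovation_sd > 0)
  .with_seed(seed, {
    e <- stats::rnorm(length, sd = innovation_sd)
    # stationary start: first point at the marginal SD
    e[1] <- e[1] / sqrt(1 - ar_coefficient^2)
    x <- as.numeric(stats::filter(e, ar_coefficient, method = "recursive"))
    mean_level + x
  })
}

#' Add a slow trend to a trace
#'
#' Test fixture for the baseline correction: adds a deterministic slow
#' component of the kinds seen in imaging data -- a linear drift
#' `magnitude * t/T` or a bleaching-like decay `magnitude * exp(-3 t/T)`.
#'
#' @param x numeric trace.
#' @param kind `"linear"` or `"exponential_decay"`.
#' @param magnitude trend amplitude (0 returns `x` unchanged).
#' @return numeric trace, attributes preserved.
#' @export
add_trend <- function(x, kind = c("linear", "exponential_decay"),
                      magnitude = 1) {
  kind <- match.arg(kind)
  stopifnot(is.finite(magnitude))
  t <- seq_along(x) / length(x)
  trend <- switch(kind, linear = magnitude * t,
                  exponential_decay = magnitude * exp(-3 * t))
  out <- x + trend
  attributes(out) <- attributes(x)
  out
}

#' Generate a population of synthetic traces
#'
#' Builds a [trace_set] of independent traces from one of the generators,
#' deriving each cell's seed deterministically from the master seed and the
#' cell index. Growing `n_cells` therefore extends the population without
#' changing the earlier cells, and the same master seed always reproduces
#' the same set.
#'
#' @param n_cells number of traces, >= 1.
#' @param seed master integer seed.
#' @param gen generating function ([gen_chain_trace()],
#'   [gen_spike_trace()], or [gen_irregular_trace()]); must accept a
#'   `seed` argument.
#' @param ... parameters passed on to `gen`.
#' @param name label for the returned set.
#' @return a [trace_set] with cells `cell_0001 ...`.
#' @examples
#' P <- matrix(c(.9, .1, .1, .9), 2, byrow = TRUE)
#' pop <- gen_population(20, seed = 1, gen = gen_chain_trace, P = P)
#' @export
gen_population <- function(n_cells, seed, gen = gen_irregular_trace, ...,
                           name = "synthetic") {
  stopifnot(n_cells >= 1)
  traces <- lapply(seq_len(n_cells), function(i)
    as.numeric(gen(..., seed = .derive_seed(seed, i))))
  names(traces) <- sprintf("cell_%04d", seq_len(n_cells))
  trace_set(traces, name = name)
}
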