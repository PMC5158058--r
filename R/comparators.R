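#' Count calcium spikes by amplitude ratio
#'
#' Scans the trace left to right. A spike onset is a time point whose value
#' is at least `onset_ratio` times the value at the previous time point
#' (default 150\%); the spike then persists while the trace stays at or
#' above the value attained at the onset point, and ends at the first
#' point that falls below it. Only spikes lasting at least `min_duration`
#' time points (default 2) are counted. Scanning resumes after the spike
#' end, so spikes never overlap. A spike still above its onset value when
#' the trace ends is counted if long enough.
#'
#' The onset ratio is undefined when the previous value is not strictly
#' positive (possible after baseline correction); such points are skipped
#' and their number reported in a warning when any occur.
#'
#' @param x numeric trace, length >= 2.
#' @param onset_ratio ratio threshold, > 1; default 1.5.
#' @param min_duration minimum spike length in time points, >= 1; default 2.
#' @return list with `count` (integer) and `spans`, a two-column matrix of
#'   (onset, end) indices of the counted spikes, where `end` is the last
#'   index at or above the onset value.
#' @examples
#' count_spikes(c(1, 1, 1.6, 1.7, 1.0))$count  # 1
#' count_spikes(c(1, 1, 1.6, 1.0, 1.0))$count  # 0 (too short)
#' @export
count_spikes <- function(x, onset_ratio = 1.5, min_duration = 2L) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be numeric with length >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("'x' contains non-finite values", call. = FALSE)
  stopifnot(onset_ratio > 1, min_duration >= 1)
  L <- length(x)
  spans <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("onset", "end")))
  skipped <- 0L
  t <- 2L
  while (t <= L) {
    if (x[t - 1L] <= 0) {
      skipped <- skipped + 1L
      t <- t + 1L
      next
    }
    if (x[t] >= onset_ratio * x[t - 1L]) {
      v <- x[t]
      e <- t
      while (e < L && x[e + 1L] >= v) e <- e + 1L
      if (e - t + 1L >= min_duration)
        spans <- rbind(spans, c(t, e))
      t <- e + 2L  # first onset test after the end compares x[e+2] to x[e+1]
    } else t <- t + 1L
  }
  if (all(x <= 0))
    warning("all values non-positive; no onset is defined", call. = FALSE)
  else if (skipped > 0L)
    warning("onset test skipped at ", skipped,
            " point(s) with non-positive predecessor", call. = FALSE)
  list(count = nrow(spans), spans = spans)
}

#' Average power of a discrete-time signal
#'
#' The mean of the squared values, \eqn{P = (1/T) \sum_i X_i^2}, the
#' time-domain form of the signal's average power by Parseval's theorem.
#' Homogeneous of degree 2: `average_power(c * x) == c^2 * average_power(x)`.
#'
#' @param x numeric trace, length >= 1.
#' @return nonnegative scalar.
#' @export
average_power <- function(x) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'x' must be numeric with length >= 1", call. = FALSE)
  if (!all(is.finite(x))) stop("'x' contains non-finite values", call. = FALSE)
  mean(x^2)
}

#' Rescaled range of a segment
#'
#' Computes the rescaled-range statistic of one window: with the
#' mean-adjusted series \eqn{Y_i = X_i - E[X]} and cumulative deviate
#' \eqn{Z_i = \sum_{k \le i} Y_k}, the range series is
#' \eqn{R_i = \max(Z_1..Z_i) - \min(Z_1..Z_i)} and the standard-deviation
#' series is \eqn{S_i = \sqrt{(1/i) \sum_{k \le i} (X_k - u_k)^2}}.
#' The returned value is the mean of \eqn{(R/S)_i} over the window.
#'
#' Two variants of \eqn{S_i} are provided. `"classic"` (default) is the
#' conventional rescaled-range form centering all terms on the mean of the
#' first i points, which calibrates correctly (H near 0.5 on white noise);
#' `"running_mean"` centers each term on the running mean \eqn{u_k} of the
#' first k points, a variant found in some descriptions of the procedure
#' that deflates \eqn{S_i} at small i and biases the Hurst slope downward
#' by roughly 0.06 on white noise. Indices with \eqn{S_i = 0} (constant
#' prefixes) are skipped rather than propagating infinities. The statistic
#' is invariant under the affine map \eqn{x \to a x + b}, \eqn{a > 0}.
#'
#' @param x numeric segment, length >= 2, not constant.
#' @param sd_method `"classic"` or `"running_mean"` (see Details).
#' @return positive scalar.
#' @examples
#' rescaled_range(c(1, 2))  # 0.5 / sqrt(0.125) = sqrt(2)
#' @export
rescaled_range <- function(x, sd_method = c("classic", "running_mean")) {
  sd_method <- match.arg(sd_method)
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be numeric with length >= 2", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("constant segment: rescaled range undefined (S = 0)", call. = FALSE)
  i <- seq_along(x)
  Z <- cumsum(x - mean(x))
  R <- cummax(Z) - cummin(Z)
  if (sd_method == "classic") {
    m1 <- cumsum(x) / i
    m2 <- cumsum(x^2) / i
    S <- sqrt(pmax(m2 - m1^2, 0))     # population sd of the first i points
  } else {
    dev <- x - cumsum(x) / i          # each point minus the running mean
    S <- sqrt(cumsum(dev^2) / i)
  }
  keep <- S > 0
  mean(R[keep] / S[keep])
}

#' Hurst exponent by dyadic rescaled-range scaling
#'
#' Estimates the Hurst exponent H of a trace from the scaling of the
#' rescaled range across window sizes. A `max_window`-point window is
#' placed uniformly at random within the trace (seeded); for each dyadic
#' size `s = max_window, max_window/2, ..., min_window` the window is tiled
#' from its left edge into contiguous non-overlapping sub-windows of size
#' `s` and the [rescaled_range()] values are averaged. H is the ordinary
#' least-squares slope of `log2(mean R/S)` against `log2(s)`.
#'
#' H = 0.5 indicates a purely random series, 0.5 < H < 1 persistent
#' dynamics, H < 0.5 antipersistent dynamics. The finite-sample procedure
#' occasionally yields H > 1; such estimates are returned with
#' `excluded = TRUE` so population pipelines can drop them. The estimate is
#' invariant under affine maps `x -> a x + b`, `a > 0`. Constant
#' sub-windows (S = 0 throughout) are dropped from the scale average.
#'
#' @param x numeric trace, length >= `max_window`.
#' @param max_window,min_window largest and smallest dyadic window sizes,
#'   both powers of 2; defaults 512 and 8.
#' @param sd_method passed to [rescaled_range()].
#' @param seed optional integer seed for the window placement; the caller's
#'   RNG state is restored. With a fixed trace and seed the result is
#'   bitwise reproducible.
#' @return list with `H` (the slope), `excluded` (TRUE when H > 1),
#'   `window_start` (index of the sampled window), and `scaling`
#'   (data.frame of window size and mean R/S).
#' @export
hurst_exponent <- function(x, max_window = 512L, min_window = 8L,
                           sd_method = c("classic", "running_mean"),
                           seed = NULL) {
  sd_method <- match.arg(sd_method)
  max_window <- as.integer(max_window); min_window <- as.integer(min_window)
  is_pow2 <- function(w) w >= 1L && bitwAnd(w, w - 1L) == 0L
  if (!is_pow2(max_window) || !is_pow2(min_window) || min_window >= max_window)
    stop("window sizes must be powers of 2 with min_window < max_window",
         call. = FALSE)
  if (!is.numeric(x) || length(x) < max_window)
    stop("trace shorter than max_window (", max_window, ")", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  start <- sample.int(length(x) - max_window + 1L, 1L)
  w <- x[start:(start + max_window - 1L)]
  if (diff(range(w)) == 0)
    stop("sampled window is constant: Hurst exponent undefined", call. = FALSE)

  sizes <- 2L^(log2(max_window):log2(min_window))
  mean_rs <- vapply(sizes, function(s) {
    starts <- seq(1L, max_window, by = s)
    rs <- vapply(starts, function(a) {
      seg <- w[a:(a + s - 1L)]
      if (diff(range(seg)) == 0) NA_real_
      else rescaled_range(seg, sd_method = sd_method)
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))

  ok <- is.finite(mean_rs) & mean_rs > 0
  if (sum(ok) < 2L)
    stop("too few usable scales for the Hurst regression", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log2(sizes[ok])), log2(mean_rs[ok]))
  H <- unname(fit$coefficients[2])
  list(H = H, excluded = H > 1, window_start = start,
       scaling = data.frame(size = sizes, mean_rs = mean_rs))
}
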