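#' Cohen's d effect size
#'
#' Signed standardized mean difference
#' \deqn{d = (\bar A - \bar B) / s, \quad
#'       s = \sqrt{\frac{(|A|-1) s_A^2 + (|B|-1) s_B^2}{|A|+|B|-2}}}
#' with sample (n-1) variances. Positive d means the first population has
#' the larger mean; `cohens_d(a, b) == -cohens_d(b, a)`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return scalar d. A pooled standard deviation of zero (both samples
#'   constant) is an error, signalled with class `"calentropy_zero_sd"`.
#' @examples
#' cohens_d(c(0, 2), c(0, 0))  # 1
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need length >= 2", call. = FALSE)
  na <- length(a); nb <- length(b)
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (s2 <= 0)
    stop(structure(class = c("calentropy_zero_sd", "error", "condition"),
                   list(message = "pooled standard deviation is zero; d undefined",
                        call = sys.call(-1))))
  (mean(a) - mean(b)) / sqrt(s2)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The sup-distance between the two empirical CDFs with the asymptotic
#' two-sided p-value (a thin wrapper over [stats::ks.test()] with
#' `exact = FALSE`; tie warnings are suppressed because measure values such
#' as spike counts tie routinely).
#'
#' @param a,b nonempty numeric samples.
#' @return list with `statistic` (in `[0, 1]`) and `p_value`.
#' @export
ks_2sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be nonempty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Effect-size star band for a Cohen's d value
#'
#' Maps |d| to the conventional qualitative bands, lower-inclusive:
#' `ns` below 0.20, `*` for |d| >= 0.20 (small), `**` >= 0.50 (medium),
#' `***` >= 0.80 (large), and the two extended guideline bands
#' `****` >= 1.00 and `*****` >= 2.00.
#'
#' @param d Cohen's d (vectorized).
#' @return character vector of bands.
#' @export
star_band <- function(d) {
  edges <- c(0.20, 0.50, 0.80, 1.00, 2.00)
  bands <- c("ns", "*", "**", "***", "****", "*****")
  bands[findInterval(abs(d), edges) + 1L]
}

#' Compare two trace populations under one measure
#'
#' Computes a per-cell measure for every trace of two sets and summarizes
#' the separation between the resulting distributions: the two-sample KS
#' statistic and p-value, a Bonferroni-adjusted p (`min(1, m * p)` with `m`
#' given explicitly, never inferred), Cohen's d with the sign convention
#' mean(A) - mean(B), and the effect-size [star_band()]. Hurst estimates
#' flagged for exclusion (H > 1) are dropped before the statistics.
#'
#' @param set_a,set_b [trace_set] objects; `set_a` is the first-listed
#'   population A in the d sign convention.
#' @param measure one of `"entropy"`, `"spikes"`, `"power"`, `"hurst"`.
#' @param m_comparisons Bonferroni multiplicity `m` (default 1; use the
#'   number of pairwise comparisons in your design, e.g. 3 for the three
#'   pairs of a three-condition experiment).
#' @param ... measure parameters forwarded to [trace_measures()].
#' @return object of class `population_comparison`: a one-row data.frame
#'   with columns measure, pop_a, pop_b, n_a, n_b, ks_statistic, p_value,
#'   p_adjusted, cohens_d, star_band.
#' @export
compare_populations <- function(set_a, set_b, measure = "entropy",
                                m_comparisons = 1L, ...) {
  stopifnot(inherits(set_a, "trace_set"), inherits(set_b, "trace_set"),
            m_comparisons >= 1)
  measure <- match.arg(measure, c("entropy", "spikes", "power", "hurst"))
  va <- .measure_values(set_a, measure, ...)
  vb <- .measure_values(set_b, measure, ...)
  if (length(va) < 2L || length(vb) < 2L)
    stop("each population must yield >= 2 usable measure values", call. = FALSE)
  ks <- ks_2sample(va, vb)
  d <- cohens_d(va, vb)
  out <- data.frame(measure = measure, pop_a = set_a$name, pop_b = set_b$name,
                    n_a = length(va), n_b = length(vb),
                    ks_statistic = ks$statistic, p_value = ks$p_value,
                    p_adjusted = min(1, m_comparisons * ks$p_value),
                    cohens_d = d, star_band = star_band(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("population_comparison", "data.frame")
  out
}

.measure_values <- function(ts, measure, ...) {
  tab <- trace_measures(ts, measures = measure, ...)
  v <- tab[[measure]]
  if (measure == "hurst") v <- v[!tab$hurst_excluded]
  v[is.finite(v)]
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d)\n", x$measure, x$pop_a, x$n_a,
              x$pop_b, x$n_b))
  cat(sprintf("  KS D = %.4f, p = %.3g (adjusted %.3g); Cohen's d = %.4f [%s]\n",
              x$ks_statistic, x$p_value, x$p_adjusted, x$cohens_d, x$star_band))
  invisible(x)
}

#' Separation between two measure distributions as a function of sample size
#'
#' Repeatedly draws with-replacement subsamples of each size from two
#' vectors of per-cell measure values, compares each pair of subsamples by
#' the two-sample KS test, and records the mean and SD of the p-values per
#' size. A randomized self-control comparing two subsamples both drawn
#' from the first population is always included: its p-values stay high at
#' every size, while genuinely different populations separate faster as
#' size grows.
#'
#' @param values_a,values_b numeric vectors of per-cell measure values.
#' @param sizes subsample sizes (with replacement, so sizes may exceed the
#'   population sizes).
#' @param reps comparisons per size (the original analysis used 5000;
#'   a few hundred reproduce the shape).
#' @param seed integer seed; results are bit-for-bit reproducible given it.
#' @return data.frame with columns `size`, `comparison` (`"A_vs_B"` or
#'   `"A_vs_A"`), `mean_p`, `sd_p`, `mean_d`, `sd_d`.
#' @export
subsample_separation <- function(values_a, values_b, sizes = c(5, 10, 25, 50),
                                 reps = 200L, seed = 1L) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L, reps >= 1L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  one <- function(pool_b, label) {
    do.call(rbind, lapply(sizes, function(s) {
      p <- numeric(reps); d <- numeric(reps)
      for (r in seq_len(reps)) {
        sa <- sample(values_a, s, replace = TRUE)
        sb <- sample(pool_b, s, replace = TRUE)
        p[r] <- ks_2sample(sa, sb)$p_value
        d[r] <- tryCatch(cohens_d(sa, sb), error = function(e) NA_real_)
      }
      data.frame(size = s, comparison = label,
                 mean_p = mean(p), sd_p = stats::sd(p),
                 mean_d = mean(d, na.rm = TRUE),
                 sd_d = stats::sd(d, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one(values_b, "A_vs_B"), one(values_a, "A_vs_A"))
}

#' Sweep the entropy parameters n and k over two populations
#'
#' Recomputes the Markovian entropy of every trace in two sets at each
#' (n, k) on a grid and records the Cohen's d between the resulting
#' per-cell distributions, optionally on traces truncated to their first
#' `truncate_to` points. The biological sign of d is stable over the
#' well-sampled region of the grid; once `n^k` outgrows what the trace
#' length can populate, sparseness flips the sign -- a technical artifact,
#' and truncating the traces moves that frontier to smaller (n, k).
#'
#' @param set_a,set_b [trace_set] objects.
#' @param n_values,k_values integer grids (n >= 2, k >= 1).
#' @param truncate_to optional length; traces are cut to their first
#'   `truncate_to` points before analysis.
#' @return data.frame with columns `n`, `k`, `cohens_d`, and
#'   `sign_flipped` (TRUE where the sign differs from the d of the
#'   smallest (n, k) cell of the grid). A cell where d is undefined
#'   (zero pooled SD) is NA.
#' @export
parameter_sweep <- function(set_a, set_b, n_values = 2:4, k_values = 1:3,
                            truncate_to = NULL) {
  stopifnot(inherits(set_a, "trace_set"), inherits(set_b, "trace_set"))
  cut_set <- function(ts) {
    if (is.null(truncate_to)) return(ts)
    if (any(lengths(ts$traces) < truncate_to))
      stop("truncate_to exceeds a trace length", call. = FALSE)
    ts$traces <- lapply(ts$traces, function(x) x[seq_len(truncate_to)])
    ts
  }
  set_a <- cut_set(set_a); set_b <- cut_set(set_b)
  ent <- function(ts, n, k) vapply(ts$traces, function(x)
    suppressWarnings(markov_entropy(x, n = n, k = k))$value, numeric(1))
  grid <- expand.grid(n = sort(as.integer(n_values)),
                      k = sort(as.integer(k_values)))
  grid$cohens_d <- mapply(function(n, k) {
    tryCatch(cohens_d(ent(set_a, n, k), ent(set_b, n, k)),
             error = function(e) NA_real_)
  }, grid$n, grid$k)
  ref <- grid$cohens_d[grid$n == min(grid$n) & grid$k == min(grid$k)]
  grid$sign_flipped <- !is.na(grid$cohens_d) & !is.na(ref) &
    sign(grid$cohens_d) != sign(ref) & sign(grid$cohens_d) != 0
  grid
}
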