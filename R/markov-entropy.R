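#' Discretize a trace into n quantile-binned states
#'
#' Converts a continuous fluorescence trace into a symbol sequence over the
#' alphabet `0 .. n-1`. The state boundaries are the empirical quantiles at
#' levels `j/n` for `j = 1 .. n-1` (linear interpolation between order
#' statistics, the conventional type-7 definition), so each state holds a
#' near-equal share of the data and the discretization depends only on the
#' ranks of the values -- any strictly increasing transform of the trace
#' yields the same symbols. A value exactly equal to a boundary is assigned
#' to the lower state.
#'
#' When every value is identical the boundaries coincide and all symbols
#' collapse to a single state; the result is flagged `degenerate`.
#'
#' @param x numeric trace, length >= 2, finite values.
#' @param n number of states, integer >= 2.
#' @return an object of class `symbol_sequence`: a list with `symbols`
#'   (integer vector in `0 .. n-1`, same length as `x`), `n`, and
#'   `degenerate` (TRUE when the symbols collapse to one state).
#' @examples
#' discretize(c(1, 2, 3, 4), n = 2)$symbols  # 0 0 1 1
#' @export
discretize <- function(x, n = 2L) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be numeric with length >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("'x' contains non-finite values", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  b <- stats::quantile(x, probs = seq_len(n - 1L) / n, type = 7, names = FALSE)
  # symbol = number of boundaries strictly below the value (ties -> lower)
  symbols <- findInterval(x, b, left.open = TRUE)
  structure(list(symbols = as.integer(symbols), n = n,
                 degenerate = length(unique(symbols)) == 1L),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat("Symbol sequence: length ", length(x$symbols), ", alphabet 0..",
      x$n - 1L, if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

.gram_labels <- function(n, k) {
  g <- do.call(expand.grid, rev(replicate(k, 0:(n - 1L), simplify = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

#' Estimate the k-gram transition matrix of a symbol sequence
#'
#' Tallies every k-gram-to-next-symbol transition in the sequence into an
#' `n^k`-by-`n` count matrix whose rows enumerate all possible k-grams in
#' lexicographic order (oldest symbol most significant) and whose columns
#' are the next symbol. Rows are then normalized by their sums into the
#' transition probability matrix of the k-th order n-state Markov process
#' maximally likely to have produced the sequence. Rows whose k-gram never
#' occurs in the data carry no observations and are left at zero, flagged
#' `unobserved`.
#'
#' @param seq a `symbol_sequence` from [discretize()], or an integer vector
#'   of symbols in `0 .. n-1` (then `n` must be given).
#' @param k order of the process (k-gram length), integer >= 1; the
#'   sequence must be longer than `k`.
#' @param n alphabet size; taken from `seq` when it is a `symbol_sequence`.
#' @return an object of class `transition_model`: list with `counts`,
#'   `probabilities` (both `n^k` x `n`, rows labelled by k-gram),
#'   `observed` (logical per row), `n`, `k`.
#' @examples
#' s <- discretize(c(1, 9, 1, 9, 1), n = 2)
#' transition_model(s, k = 1)$probabilities
#' @export
transition_model <- function(seq, k = 1L, n = NULL) {
  if (inherits(seq, "symbol_sequence")) {
    n <- seq$n
    sym <- seq$symbols
  } else {
    if (is.null(n)) stop("'n' required when 'seq' is a bare vector", call. = FALSE)
    sym <- as.integer(seq)
    if (any(sym < 0L | sym >= n)) stop("symbols outside 0..n-1", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1", call. = FALSE)
  L <- length(sym)
  if (L <= k) stop("sequence length (", L, ") must exceed k (", k, ")",
                   call. = FALSE)
  nrow <- as.integer(n^k)

  # row index of the k-gram ending just before position t, oldest symbol
  # most significant
  t <- (k + 1L):L
  row <- integer(length(t))
  for (j in seq_len(k)) row <- row * n + sym[t - k + j - 1L]
  idx <- row * n + sym[t]  # 0-based flat index into row-major counts

  cnt <- tabulate(idx + 1L, nbins = nrow * n)
  counts <- matrix(cnt, nrow = nrow, ncol = n, byrow = TRUE)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  labs <- .gram_labels(n, k)
  dimnames(counts) <- dimnames(probs) <- list(labs, as.character(0:(n - 1L)))
  structure(list(counts = counts, probabilities = probs,
                 observed = rs > 0, n = n, k = k),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition model: order k = ", x$k, ", n = ", x$n, " states (",
      sum(x$observed), "/", length(x$observed), " rows observed, ",
      sum(x$counts), " transitions)\n", sep = "")
  print(round(x$probabilities, 3))
  invisible(x)
}

.row_entropies <- function(probs) {
  plogp <- probs * log2(probs)
  plogp[probs == 0] <- 0  # 0 log 0 := 0
  -rowSums(plogp)
}

#' Markovian entropy of a calcium activity time series
#'
#' The package's core estimator. The trace is discretized into `n` quantile
#' states ([discretize()]), its k-th order transition matrix is estimated
#' ([transition_model()]), and each of the `n^k` rows is scored by the
#' Shannon entropy \eqn{E = -\sum_i p_i \log_2 p_i}. The row entropies are
#' summed and divided by \eqn{n^k \log_2 n}, the maximum attainable sum, to
#' give a value in \eqn{[0, 1]}: 0 means every observed transition is
#' deterministic (fully predictable dynamics), 1 means every row is
#' uniform (fully unpredictable). Rows never observed contribute 0 bits
#' while remaining in the denominator, so sparse sampling at large `n^k`
#' drags the value down -- keep `n^k \cdot n` well below the trace length
#' (a warning marks the sparse regime).
#'
#' A degenerate (e.g. constant) trace has no transitions to score; its
#' entropy is defined as 0 and flagged, so population pipelines survive
#' silent cells.
#'
#' @param x numeric trace (length > k) or a `symbol_sequence`.
#' @param n number of states, >= 2 (default 2, the recommended setting for
#'   traces of a few hundred points).
#' @param k process order, >= 1 (default 1).
#' @param warn_sparse warn when `n^k * n` exceeds the number of observed
#'   transitions (default TRUE).
#' @return an object of class `markov_entropy`: list with `value` (the
#'   normalized entropy in `[0,1]`), `row_entropies` (bits, length `n^k`),
#'   `unobserved_rows`, `degenerate`, `n`, `k`, and `model` (the fitted
#'   [transition_model()]). `coef()` returns the transition probability
#'   matrix; `simulate()` draws new symbol sequences from the fitted chain.
#' @examples
#' markov_entropy(rep(c(1, 9), 450), n = 2, k = 1)$value   # 0: alternation
#' markov_entropy(rep(c(1, 1, 9, 9), length.out = 9))$value # 1: coin-flip rows
#' @export
markov_entropy <- function(x, n = 2L, k = 1L, warn_sparse = TRUE) {
  seq <- if (inherits(x, "symbol_sequence")) x else discretize(x, n = n)
  n <- seq$n
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1", call. = FALSE)
  L <- length(seq$symbols)
  if (L <= k) stop("trace length (", L, ") must exceed k (", k, ")",
                   call. = FALSE)
  if (warn_sparse && n^k * n > L - k)
    warning("sparse regime: transition matrix has ", n^k * n,
            " entries but only ", L - k, " transitions observed; ",
            "entropy estimates are unreliable (consider smaller n or k)",
            call. = FALSE)
  model <- transition_model(seq, k = k)
  re <- .row_entropies(model$probabilities)
  value <- sum(re) / (n^k * log2(n))
  if (seq$degenerate) {
    warning("degenerate discretization (single-state trace); entropy set to 0",
            call. = FALSE)
    value <- 0
    re[] <- 0
  }
  structure(list(value = value, row_entropies = re,
                 unobserved_rows = sum(!model$observed),
                 degenerate = seq$degenerate,
                 n = n, k = k, model = model, symbols = seq$symbols),
            class = "markov_entropy")
}

#' @export
print.markov_entropy <- function(x, digits = 4, ...) {
  cat("Markovian entropy (n = ", x$n, ", k = ", x$k, "): ",
      format(x$value, digits = digits),
      if (x$degenerate) "  [degenerate trace]", "\n", sep = "")
  if (x$unobserved_rows > 0)
    cat(x$unobserved_rows, "of", length(x$row_entropies),
        "k-gram rows unobserved\n")
  invisible(x)
}

#' @export
summary.markov_entropy <- function(object, ...) {
  structure(list(fit = object), class = "summary.markov_entropy")
}

#' @export
print.summary.markov_entropy <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nTransition probabilities:\n")
  print(round(f$model$probabilities, 3))
  cat("\nRow entropies (bits):\n")
  print(round(f$row_entropies, 3))
  cat("\nNormalization: sum /", f$n^f$k, "* log2(", f$n, ") =",
      format(f$n^f$k * log2(f$n)), "bits\n")
  invisible(x)
}

#' @export
coef.markov_entropy <- function(object, ...) object$model$probabilities

#' Simulate symbol sequences from a fitted Markovian entropy model
#'
#' Draws new realizations of the fitted k-th order chain. The initial
#' k-gram is sampled from the empirical k-gram frequencies of the data;
#' if simulation wanders into a k-gram whose row was never observed, the
#' next symbol is drawn uniformly (that can only happen from grams created
#' at the simulation boundary, since every observed transition seeds the
#' following gram).
#'
#' @param object a `markov_entropy` fit.
#' @param nsim number of sequences.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param length length of each simulated sequence; defaults to the length
#'   of the original trace.
#' @param ... unused.
#' @return a list of integer symbol vectors (values `0 .. n-1`).
#' @export
simulate.markov_entropy <- function(object, nsim = 1, seed = NULL,
                                    length = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- object$n; k <- object$k
  L <- if (is.null(length)) base::length(object$symbols) else as.integer(length)
  stopifnot(L > k)
  sym <- object$symbols
  # empirical k-gram start frequencies
  t <- k:base::length(sym)
  gram0 <- integer(base::length(t))
  for (j in seq_len(k)) gram0 <- gram0 * n + sym[t - k + j]
  probs <- object$model$probabilities
  observed <- object$model$observed
  replicate(nsim, simplify = FALSE, {
    out <- integer(L)
    g <- sample(gram0, 1L)
    out[seq_len(k)] <- (g %/% n^((k - 1L):0)) %% n
    for (t in (k + 1L):L) {
      p <- if (observed[g + 1L]) probs[g + 1L, ] else rep(1 / n, n)
      s <- sample.int(n, 1L, prob = p) - 1L
      out[t] <- s
      g <- (g * n + s) %% n^k
    }
    out
  })
}

#' Plot a Markovian entropy fit
#'
#' Displays the fitted transition probability matrix as a shaded grid
#' (rows = k-grams, columns = next state) with the per-row entropies in
#' bits alongside.
#'
#' @param x a `markov_entropy` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.markov_entropy <- function(x, ...) {
  probs <- x$model$probabilities
  nr <- nrow(probs)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(probs)), seq_len(nr), t(probs[nr:1, , drop = FALSE]),
                  col = grDevices::grey(seq(1, 0.2, length.out = 64)),
                  axes = FALSE, xlab = "next state", ylab = "k-gram",
                  main = sprintf("P(next | k-gram), n=%d k=%d", x$n, x$k), ...)
  graphics::axis(1, at = seq_len(ncol(probs)), labels = colnames(probs))
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(probs)), las = 1)
  graphics::barplot(rev(x$row_entropies), horiz = TRUE, names.arg = rev(rownames(probs)),
                    las = 1, xlab = "row entropy (bits)",
                    main = sprintf("entropy = %.3f", x$value))
  invisible(x)
}

#' Per-cell measure table for a trace set
#'
#' Applies the selected measures to every trace of a set and returns a
#' tidy per-cell table, the unit of exchange between the trace-level
#' estimators and the population statistics ([compare_populations()]).
#' Hurst estimates greater than 1 are kept in the table but flagged
#' `hurst_excluded`; population statistics drop them.
#'
#' @param ts a [trace_set].
#' @param measures any of `"entropy"`, `"spikes"`, `"power"`, `"hurst"`.
#' @param n,k states and order for the entropy measure.
#' @param onset_ratio,min_duration spike detection parameters, see
#'   [count_spikes()].
#' @param hurst_seed integer seed for the random Hurst window placement;
#'   cell index is added per trace so cells get distinct windows.
#' @param max_window,min_window,hurst_sd Hurst parameters, see
#'   [hurst_exponent()].
#' @return data.frame with `cell_id` and one column per measure (plus
#'   `entropy_unobserved`/`entropy_degenerate` and `hurst_excluded` flags
#'   where relevant).
#' @export
trace_measures <- function(ts, measures = "entropy", n = 2L, k = 1L,
                           onset_ratio = 1.5, min_duration = 2L,
                           hurst_seed = 1L, max_window = 512L,
                           min_window = 8L, hurst_sd = c("classic", "running_mean")) {
  stopifnot(inherits(ts, "trace_set"))
  measures <- match.arg(measures, c("entropy", "spikes", "power", "hurst"),
                        several.ok = TRUE)
  hurst_sd <- match.arg(hurst_sd)
  out <- data.frame(cell_id = names(ts$traces), stringsAsFactors = FALSE)
  if ("entropy" %in% measures) {
    fits <- lapply(ts$traces, function(tr)
      suppressWarnings(markov_entropy(tr, n = n, k = k)))
    out$entropy <- vapply(fits, `[[`, numeric(1), "value")
    out$entropy_unobserved <- vapply(fits, `[[`, numeric(1), "unobserved_rows")
    out$entropy_degenerate <- vapply(fits, `[[`, logical(1), "degenerate")
  }
  if ("spikes" %in% measures)
    out$spikes <- vapply(ts$traces, function(tr)
      count_spikes(tr, onset_ratio = onset_ratio,
                   min_duration = min_duration)$count, numeric(1))
  if ("power" %in% measures)
    out$power <- vapply(ts$traces, average_power, numeric(1))
  if ("hurst" %in% measures) {
    h <- lapply(seq_along(ts$traces), function(i)
      hurst_exponent(ts$traces[[i]], max_window = max_window,
                     min_window = min_window, sd_method = hurst_sd,
                     seed = hurst_seed + i))
    out$hurst <- vapply(h, `[[`, numeric(1), "H")
    out$hurst_excluded <- vapply(h, `[[`, logical(1), "excluded")
  }
  out
}
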