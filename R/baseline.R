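#' Estimate a slowly varying baseline by asymmetric least squares
#'
#' Fits the Eilers-Boelens asymmetric-least-squares (AsLS) baseline: the
#' vector `z` minimizing
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2}
#' where the weights are asymmetric, \eqn{w_i = p} where \eqn{y_i > z_i}
#' and \eqn{1 - p} otherwise, iterated to convergence. A small `p` makes
#' positive excursions (calcium transients) nearly weightless, so the
#' baseline hugs the slowly varying floor of the trace; `lambda` sets the
#' stiffness of that floor via a second-difference roughness penalty.
#'
#' Each iteration solves the banded system
#' \eqn{(W + \lambda D'D) z = W y} exactly (sparse Cholesky), with all
#' weights equal to 1 before the first asymmetric reweighting. Iteration
#' stops when the weight vector stops changing or after `max_iter` rounds.
#'
#' @param y numeric vector of fluorescence values, length >= 4, all finite.
#' @param lambda smoothness penalty, > 0. Default 1e5: for traces of a few
#'   hundred to ~1000 points sampled at fractions of a Hz this passes
#'   minute-scale drift into the baseline while leaving second-scale
#'   transients in the residual.
#' @param p asymmetry weight in (0, 1), default 0.01; the weight given to
#'   points above the current baseline.
#' @param max_iter maximum reweighting iterations, default 20.
#' @param tol convergence threshold on the mean absolute change of the
#'   weight vector, default 1e-6.
#' @return numeric vector, the baseline, same length as `y`.
#' @references Eilers, P.H.C. and Boelens, H.F.M. Baseline correction with
#'   asymmetric least squares smoothing.
#' @seealso [detrend()]
#' @export
asls_baseline <- function(y, lambda = 1e5, p = 0.01, max_iter = 20L,
                          tol = 1e-6) {
  if (!is.numeric(y) || length(y) < 4L)
    stop("'y' must be numeric with length >= 4", call. = FALSE)
  if (!all(is.finite(y))) stop("'y' contains non-finite values", call. = FALSE)
  stopifnot(lambda > 0, p > 0, p < 1, max_iter >= 1, tol > 0)

  m <- length(y)
  # second-difference operator, (m-2) x m
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    C <- DtD + Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(C, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (mean(abs(w_new - w)) < tol && it > 1L) break
    w <- w_new
  }
  z
}

#' Remove the slow baseline trend from traces
#'
#' Subtracts the [asls_baseline()] from each trace. Detrending is applied
#' before all population analyses so that slow drifts (bleaching, focus,
#' dye loading) do not masquerade as differences in activity dynamics.
#' Quantile-based measures such as [markov_entropy()] are largely rank
#' driven and change little under detrending of a trend-free trace;
#' amplitude-based measures ([average_power()], [count_spikes()]) are the
#' ones a residual trend would distort.
#'
#' Detrending is translation invariant -- `detrend(x + c)` equals
#' `detrend(x)` -- and approximately idempotent at the default parameters.
#' Note the output fluctuates around zero, so ratio-based spike detection
#' on detrended traces should re-add a positive offset or rely on the
#' skipped-onset warning of [count_spikes()].
#'
#' @param x a numeric trace or a [trace_set].
#' @inheritParams asls_baseline
#' @return same shape as `x`: a numeric vector, or a [trace_set] with every
#'   trace replaced by its residual from the fitted baseline.
#' @export
detrend <- function(x, lambda = 1e5, p = 0.01, max_iter = 20L, tol = 1e-6) {
  if (inherits(x, "trace_set")) {
    out <- lapply(x$traces, asls_baseline, lambda = lambda, p = p,
                  max_iter = max_iter, tol = tol)
    x$traces <- Map(function(y, z) y - z, x$traces, out)
    return(x)
  }
  x - asls_baseline(x, lambda = lambda, p = p, max_iter = max_iter, tol = tol)
}
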