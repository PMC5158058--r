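test_that("quantile discretization follows the boundary and tie rules", {
  expect_identical(discretize(c(1, 2, 3, 4), 2)$symbols, c(0L, 0L, 1L, 1L))
  d <- discretize(c(5, 5, 5, 5), 2)
  expect_identical(d$symbols, rep(0L, 4))
  expect_true(d$degenerate)
  # rank invariance under strictly increasing transforms, exactly
  set.seed(1)
  for (i in 1:20) {
    x <- runif(50)
    n <- sample(2:5, 1)
    expect_identical(discretize(exp(x), n)$symbols, discretize(x, n)$symbols)
    expect_identical(discretize(3 * x - 10, n)$symbols, discretize(x, n)$symbols)
  }
  expect_error(discretize(c(1, 2), 1), "n")
})

test_that("transition tallies match hand counts and conserve mass", {
  m <- transition_model(discretize(c(1, 9, 1, 9, 1), 2), k = 1)
  expect_identical(unname(m$counts), matrix(c(0L, 2L, 2L, 0L), 2, byrow = TRUE))
  expect_identical(unname(m$probabilities), matrix(c(0, 1, 1, 0), 2, byrow = TRUE))

  m2 <- transition_model(c(0, 0, 1, 1, 0, 0, 1, 1), k = 2, n = 2)
  expect_identical(m2$counts["00", ], c("0" = 0L, "1" = 2L))
  expect_identical(m2$counts["01", ], c("0" = 0L, "1" = 2L))
  expect_identical(m2$counts["10", ], c("0" = 1L, "1" = 0L))
  expect_identical(m2$counts["11", ], c("0" = 1L, "1" = 0L))
  expect_identical(sum(m2$counts), 6L)  # length - k

  # every observed row is a probability distribution
  set.seed(2)
  s <- discretize(runif(200), 3)
  for (k in 1:3) {
    m <- transition_model(s, k = k)
    expect_identical(sum(m$counts), 200L - k)
    rs <- rowSums(m$probabilities)[m$observed]
    expect_true(all(abs(rs - 1) < 1e-12))
    expect_identical(sum(m$observed) + sum(!m$observed), as.integer(3^k))
  }
  expect_error(transition_model(c(0, 1), k = 2, n = 2), "exceed")
  # boundary: length k+1 gives exactly one transition
  expect_identical(sum(transition_model(c(0, 1, 0), k = 2, n = 2)$counts), 1L)
})

test_that("toy traces hit the exact entropy landmarks", {
  expect_identical(markov_entropy(rep(c(1, 9), 450), n = 2, k = 1)$value, 0)
  per4 <- rep(c(1, 1, 9, 9), length.out = 9)
  expect_identical(markov_entropy(per4, n = 2, k = 1)$value, 1)
  expect_identical(suppressWarnings(markov_entropy(per4, n = 2, k = 2))$value, 0)
  # constant trace: degenerate, entropy 0, flagged
  fit <- suppressWarnings(markov_entropy(rep(5, 10)))
  expect_identical(fit$value, 0)
  expect_true(fit$degenerate)
})

test_that("estimator agrees with the naive string-tally oracle on random traces", {
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(20:60, 1))
    k <- sample(1:3, 1)
    expect_equal(suppressWarnings(markov_entropy(x, n = 2, k = k))$value,
                 naive_entropy_n2(x, k), tolerance = 1e-12)
  }
})

test_that("entropy is bounded, normalized consistently, and monotone-invariant", {
  set.seed(4)
  for (i in 1:40) {
    x <- rnorm(80)
    n <- sample(2:4, 1)
    k <- sample(1:2, 1)
    fit <- suppressWarnings(markov_entropy(x, n = n, k = k))
    expect_gte(fit$value, 0)
    expect_lte(fit$value, 1)
    expect_identical(fit$value, sum(fit$row_entropies) / (n^k * log2(n)))
    expect_identical(suppressWarnings(markov_entropy(exp(x), n = n, k = k))$value,
                     fit$value)
  }
})

test_that("iid traces approach maximal entropy; first-order data make k=2 consistent", {
  set.seed(5)
  iid <- mean(vapply(1:50, function(i) markov_entropy(runif(900))$value,
                     numeric(1)))
  expect_gte(iid, 0.995)
  # data from a first-order chain: k=2 rows depend only on the last symbol
  P <- stay_matrix(0.8)
  dif <- vapply(1:30, function(i) {
    x <- as.numeric(gen_chain_trace(P, seed = i))
    markov_entropy(x, k = 2)$value - markov_entropy(x, k = 1)$value
  }, numeric(1))
  expect_lt(abs(mean(dif)), 0.03)
})

test_that("sparse regime is warned about and unobserved rows counted", {
  set.seed(6)
  x <- rnorm(100)
  expect_warning(markov_entropy(x, n = 4, k = 3), "sparse")
  fit <- suppressWarnings(markov_entropy(x, n = 4, k = 3))
  expect_identical(fit$unobserved_rows + sum(fit$model$observed), 64L)
  expect_gt(fit$unobserved_rows, 0)
})

test_that("methods: print, summary, coef, simulate behave", {
  set.seed(7)
  fit <- markov_entropy(as.numeric(gen_chain_trace(stay_matrix(0.9), seed = 1)))
  expect_output(print(fit), "Markovian entropy")
  expect_output(print(summary(fit)), "Transition probabilities")
  expect_identical(coef(fit), fit$model$probabilities)
  sims <- simulate(fit, nsim = 2, seed = 99, length = 500)
  expect_length(sims, 2)
  expect_true(all(vapply(sims, length, integer(1)) == 500L))
  expect_true(all(unlist(sims) %in% 0:1))
  # reproducible given the seed
  expect_identical(simulate(fit, nsim = 1, seed = 99), simulate(fit, nsim = 1, seed = 99))
  # simulated sequences carry the fitted persistence
  m <- transition_model(sims[[1]], k = 1, n = 2)
  expect_gt(m$probabilities["0", "0"], 0.6)
})

test_that("trace_measures assembles a per-cell table", {
  pop <- chain_pop(0.9, 5, seed = 123, length = 600)
  # chain traces hover around level 0, so the spike scan legitimately warns
  # about non-positive predecessors
  tab <- suppressWarnings(
    trace_measures(pop, measures = c("entropy", "spikes", "power", "hurst")))
  expect_identical(nrow(tab), 5L)
  expect_true(all(c("cell_id", "entropy", "spikes", "power", "hurst",
                    "hurst_excluded", "entropy_degenerate") %in% names(tab)))
  expect_true(all(tab$entropy >= 0 & tab$entropy <= 1))
})
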