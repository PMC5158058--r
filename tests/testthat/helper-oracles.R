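# Independent naive entropy oracle for n = 2: string-keyed k-gram tally,
# no shared code with transition_model()/markov_entropy().
naive_entropy_n2 <- function(x, k) {
  med <- stats::quantile(x, 0.5, type = 7, names = FALSE)
  s <- as.integer(x > med)  # ties at the boundary go to the lower state
  L <- length(s)
  grams <- vapply(seq_len(L - k), function(t)
    paste(s[t:(t + k - 1L)], collapse = ""), character(1))
  nxt <- s[(k + 1L):L]
  total <- 0
  for (g in unique(grams)) {
    p <- table(nxt[grams == g]) / sum(grams == g)
    total <- total - sum(p * log2(p))
  }
  total / (2^k * log2(2))
}

# Shared synthetic study populations: a predictable (stay-0.9) and a
# near-random (stay-0.6) two-state chain population.
stay_matrix <- function(p) matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)

chain_pop <- function(stay, n_cells, seed, length = 900L,
                      name = sprintf("stay%.1f", stay)) {
  gen_population(n_cells, seed = seed, gen = gen_chain_trace,
                 P = stay_matrix(stay), length = length, name = name)
}

entropy_values <- function(ts, n = 2L, k = 1L)
  vapply(ts$traces, function(x)
    suppressWarnings(markov_entropy(x, n = n, k = k))$value, numeric(1))
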