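# Small fixtures shared across test files.

# A tiny 4-template world: information in the last position, 6 noise symbols.
tiny_env <- function() {
  build_positional_env("last", n_stimuli = 8, n_templates = 4)
}

# A memory that values "go" strongly on one subsequence key.
memory_with <- function(..., alpha = 0.1, beta = 1) {
  mem <- associative_memory(alpha = alpha, beta = beta)
  w <- list(...)
  for (key in names(w)) {
    assign(key, c(w[[key]], 0), envir = mem$weights)
  }
  mem
}

# Direct Eq-1-style oracle: lifetime utility as the explicit sum of the
# per-step productive probabilities obtained by iterating the recurrence.
utility_by_recurrence_sum <- function(params, depth) {
  f <- fraction_informative(depth, params$r)
  rate <- 1 / (params$tau * params$n^depth)
  u <- 0
  total <- 0
  for (t in seq_len(params$lifespan)) {
    total <- total + u  # u(l, t-1)
    u <- u + rate * (f - u)
  }
  total
}
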