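# Independent oracles used across the suite.

# Brute-force rejection probability of a two-stage plan under the null:
# Monte-Carlo draws of the (interim, final) z-statistics with correlation
# sqrt(t1), rejecting if z1 >= qnorm(1 - a1) or (no interim rejection and
# zf >= qnorm(1 - a2)). Returns the estimate and its standard error.
mc_two_stage_reject <- function(a1, a2, t1, n_draws = 2e6, seed = 42) {
  set.seed(seed)
  rho <- sqrt(t1)
  z1 <- rnorm(n_draws)
  zf <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_draws)
  rej <- z1 >= qnorm(1 - a1) | (z1 < qnorm(1 - a1) & zf >= qnorm(1 - a2))
  p <- mean(rej)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Naive term-by-term partial sum of the descending budget series.
naive_beta_sum <- function(n, alpha = 0.025, C = 0.07720838) {
  s <- 0
  for (j in seq_len(n)) {
    s <- s + C * alpha * log(max(j, 2)) / (j * exp(sqrt(log(j))))
  }
  s
}

# Small staggered event stream with random p-values, for property tests.
random_event_stream <- function(K = 4, seed = 1) {
  set.seed(seed)
  s0 <- (seq_len(K) - 1) * 2
  ev <- data.frame(hypothesis = rep(seq_len(K), 2),
                   stage = rep(c("interim", "final"), each = K),
                   info = c(s0 + 3, s0 + 6),
                   p_value = runif(2 * K, 0.001, 0.6))
  ev <- ev[order(ev$info, ev$hypothesis), ]
  ev$time <- seq_len(nrow(ev))
  analysis_events(ev$hypothesis, ev$stage, ev$time, ev$p_value)
}

rejected_set <- function(log) {
  sort(unique(log$hypothesis[log$decision == "reject"]))
}
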