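# Shared fixtures and independent oracles for the test suite.

ipq18 <- builtin_ipq18()

# Independent closed-form RSM evaluation (plain arithmetic, no package code):
# P(X = k | theta) over k = 0..m with shared thresholds.
oracle_probs <- function(theta, delta, taus) {
  cumtau <- c(0, cumsum(taus))
  k <- seq_along(cumtau) - 1L
  num <- exp(k * (theta - delta) - cumtau)
  num / sum(num)
}

oracle_expected <- function(theta, delta, taus) {
  p <- oracle_probs(theta, delta, taus)
  sum((seq_along(p) - 1L) * p)
}

oracle_variance <- function(theta, delta, taus) {
  p <- oracle_probs(theta, delta, taus)
  k <- seq_along(p) - 1L
  sum(k^2 * p) - sum(k * p)^2
}

# a small three-category bank for edge cases
tiny_bank <- function() {
  new_bank(data.frame(item_id = c("a", "b"), delta = c(-0.5, 0.5)),
           taus = c(-1, 1), metadata = list(name = "tiny"))
}

# draw a random non-extreme response pattern over n items of a bank
random_pattern <- function(bank, n) {
  m <- bank$n_categories - 1L
  ids <- sample(bank$items$item_id, n)
  repeat {
    sc <- sample(0:m, n, replace = TRUE)
    if (!(all(sc == 0L) || all(sc == m))) break
  }
  stats::setNames(sc, ids)
}
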