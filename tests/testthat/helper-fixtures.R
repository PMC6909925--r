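# shared test helpers: tiny networks and independent oracles

# two-concept network A -> B with given weight
two_node_net <- function(w = 1) {
  conceptNetwork(data.frame(source = "A", target = "B", weight = w))
}

# independent fixed-point oracle for a single driven node:
# solves b = tanh(gain * (w * a + mu * b)) on [-1, 1] by root bracketing
scalar_fixed_point <- function(w, a, mu = 1, gain = 1) {
  g <- function(b) tanh(gain * (w * a + mu * b)) - b
  stats::uniroot(g, c(-1, 1), tol = 1e-13)$root
}

# brute-force exact Mann-Whitney oracle: full enumeration of all
# choose(n + m, n) group assignments of the pooled values; two-sided p as
# the total probability of rank-sums at least as far from the null mean
# as observed (midrank scoring, doubled to integers)
brute_force_mw <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  r2 <- as.integer(round(2 * rank(c(a, b))))
  w_obs <- sum(r2[seq_len(n)])
  mu2 <- n * (N + 1L)
  d_obs <- abs(w_obs - mu2)
  sums <- apply(utils::combn(N, n), 2L, function(idx) sum(r2[idx]))
  mean(abs(sums - mu2) >= d_obs - 1e-9)
}

# brute-force Poisson-binomial tail oracle: enumerate all 2^N
# agree/disagree outcome patterns with per-feature success probabilities
brute_force_tail <- function(agreements, probs) {
  N <- length(probs)
  total <- 0
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(N)]
    if (sum(bits) >= agreements)
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
  }
  total
}

# deterministic config used throughout: no replicate noise
quiet_cfg <- function(...) simConfig(noiseSigma = 0, ...)
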