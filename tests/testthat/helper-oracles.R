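# Independent oracles used across test files.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[o][i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive hypergeometric upper tail: sum over k' >= k of
# C(K, k') C(N - K, n - k') / C(N, n)
hyper_oracle <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small trio count experiment shared by classification tests.
small_trio <- function(seed = 11, n_genes = 600, effect_size = 4,
                       dispersion = 0.05) {
  cfg <- trio_sim_config(n_genes = n_genes, effect_size = effect_size,
                         dispersion = dispersion, seed = seed)
  simulate_trio_counts(cfg)
}
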