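# Independent brute-force oracles and tiny fixture builders used across
# the suite. Every oracle re-derives its quantity from first principles,
# never through the package's own code path.

# Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# AUC by explicit pairwise comparison, ties counting one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Passing-Bablok slope: enumerate all pairwise slopes, drop -1, shifted
# median with offset K = #(slopes < -1)
oracle_pb_slope <- function(x, y) {
  S <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) S <- c(S, (y[j] - y[i]) / (x[j] - x[i]))
  S <- sort(S[S != -1])
  N <- length(S)
  K <- sum(S < -1)
  if (N %% 2 == 1) S[(N + 1) / 2 + K] else mean(S[c(N / 2 + K, N / 2 + 1 + K)])
}

# hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# minimal wide cohort: 3 groups, known ages/sexes, no noise structure
toy_cohort <- function(n_per_group = 10, n_proteins = 4, seed = 1) {
  simulate_cohort(simulation_config(
    n_per_group = n_per_group, n_tau = 0, n_tdp = 0,
    n_proteins = n_proteins, category_sizes = c(),
    n_rounds = 1, n_bridging = 0, lod_quantile = 0, seed = seed))
}

# build a differential_result-shaped data.frame by hand
fake_diff <- function(pid, beta, q) {
  data.frame(protein_id = pid, beta = beta, se = 0.1, p = q, q = q,
             n_used = 10L, direction = sign(beta), stringsAsFactors = FALSE)
}
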