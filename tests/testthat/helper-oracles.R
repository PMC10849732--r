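# Independent brute-force oracles used to check the statistical primitives.

# Benjamini-Hochberg step-up by direct application of the definition:
# sort p ascending, q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
bh_stepup_oracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(m * ps[i:n] / (i:n), 1))
  out <- numeric(n)
  out[o] <- q
  out
}

# Two-sample KS D by evaluating both ECDFs on the pooled support.
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Exact two-sided rank-sum p-value by enumerating all C(n, n_a) assignments
# of the pooled (mid)ranks to group a; ties handled through midranks.
ranksum_exact_oracle <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  all_w <- combn(length(r), na, function(idx) sum(r[idx]))
  p_le <- mean(all_w <= obs + 1e-9)
  p_ge <- mean(all_w >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Rank-based AUC: probability a positive outranks a negative.
auc_oracle <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  np <- length(score_pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(score_neg))
}

small_trace_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_fish_per_genotype = 1, n_neurons_per_fish = 6,
             ...)
}
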