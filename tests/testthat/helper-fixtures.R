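# Shared fixtures and independent oracles used across test files.

# Standard read fixture for posterior backends: genes spanning read depths
# and true fractions, generated under the mixture model itself.
standard_pi_fixture <- function(seed = 42) {
  simulate_reads(
    n_genes = 12, reads_per_gene = rep(c(10, 60, 300, 1500), 3),
    pi = rep(c(0.05, 0.3, 0.7), each = 4),
    p_c = 0.02, p_e = 0.001, n_range = c(20L, 200L), seed = seed
  )
}

# Exact two-sided Fisher p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) no more probable than the
# observed one.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Hand-executed two-stage linear step-up adjustment (independent of the
# implementation): BH pass at alpha/(1+alpha) to estimate m0, then BH
# adjusted values rescaled by m0/m.
two_stage_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  bh <- function(p) {
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(1, adj); out
  }
  adj <- bh(p)
  m0 <- max(1, m - sum(adj <= alpha / (1 + alpha)))
  pmin(1, adj * m0 / m)
}

# Small deterministic per-gene seeds for multi-gene fixtures.
derive_seed_for_test <- function(gene, offset) {
  1000L + offset * 100L + as.integer(sub("^g", "", gene))
}

# Total-variation distance between an empirical count sample and a
# probability vector over 0..(length(p)-1).
tv_distance <- function(counts, p) {
  emp <- tabulate(counts + 1L, nbins = length(p)) / length(counts)
  extra <- mean(counts > length(p) - 1L)
  0.5 * (sum(abs(emp - p)) + extra)
}
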