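# Shared fixtures: small configurations and hand-built tables.

# 5-bin toy genome (stratum GC-correction path)
tiny_config <- function(seed = 42, n_healthy = 5, ...) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
             n_healthy = n_healthy, ...)
}

# 300-bin genome: enough bins for the LOESS route, fast to simulate
small_config <- function(seed = 42, n_healthy = 10, ...) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 150e6, chr2 = 150e6),
             n_healthy = n_healthy, ...)
}

# minimal processed profile for baseline fitting
make_profile <- function(md, normalized_count = rep(1, length(md))) {
  data.frame(md = md, normalized_count = normalized_count)
}

# brute-force two-sided exact Wilcoxon p by full enumeration of group
# assignments (independent of wilcox.test)
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# independent hand implementation of BH step-up
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    rank_i <- m - k + 1
    prev <- min(prev, p[i] * m / rank_i)
    q[i] <- prev
  }
  pmin(1, q)
}
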