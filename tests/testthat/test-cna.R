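test_that("GC correction leaves unbiased counts nearly unchanged", {
  set.seed(21)
  n <- 1000
  gc <- runif(n, 0.35, 0.6)
  counts <- rpois(n, 5000)
  corrected <- gc_correct(counts, gc)
  expect_lt(max(abs(corrected - counts) / counts), 0.02)
})

test_that("GC correction removes a smooth multiplicative bias", {
  set.seed(22)
  n <- 1000
  gc <- runif(n, 0.35, 0.6)
  g <- 1 - 0.5 * ((gc - 0.475) / 0.125)^2  # quadratic dip, noiseless
  counts <- 5000 * g
  corrected <- gc_correct(counts, gc)
  expect_lt(stats::sd(corrected) / mean(corrected), 0.01)
  # mean correction factor is 1: total signal preserved
  expect_equal(mean(corrected / counts), 1, tolerance = 1e-9)
})

test_that("a single GC stratum makes the correction the identity", {
  counts <- c(100, 200, 300)
  expect_warning(out <- gc_correct(counts, rep(0.5, 3)), "identity")
  expect_equal(out, counts)
})

test_that("the stratum fallback handles tiny bin sets", {
  # two strata, under the LOESS minimum: per-stratum medians
  counts <- c(100, 110, 90, 200, 220, 180)
  gc <- rep(c(0.4, 0.5), each = 3)
  out <- gc_correct(counts, gc)
  expect_equal(mean(out / counts), 1, tolerance = 1e-9)
  # stratum medians are equalized
  expect_equal(median(out[1:3]), median(out[4:6]))
})

test_that("median normalization scales the median to 1", {
  expect_equal(median_normalize(c(500, 500, 500)), c(1, 1, 1))
  expect_equal(median_normalize(c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(median_normalize(c(10, 20, 30)), median_normalize(c(1, 2, 3)))
  expect_error(median_normalize(c(0, 0, 0)), "zero")
})

test_that("z-scores are standard units against the baseline, strict at 3", {
  # binary-exact values so the z = 3 boundary is hit exactly
  baseline <- data.frame(md_mean = 0.7, md_sd = 0.03,
                         count_mean = c(1, 1, 1),
                         count_sd = c(0.25, 0.25, 0.25),
                         evaluable = c(TRUE, TRUE, FALSE))
  prof <- data.frame(normalized_count = c(1, 1.75, 5))
  out <- cna_zscores(prof, baseline)
  expect_equal(out$z[1], 0)
  expect_identical(out$z[2], 3)
  expect_identical(out$cna_flag[1:2], c(FALSE, FALSE))  # z = 3 not flagged
  expect_true(is.na(out$z[3]) && is.na(out$cna_flag[3]))
  baseline$evaluable <- TRUE
  out2 <- cna_zscores(data.frame(normalized_count = c(1, 1.8125, 0.1875)),
                      baseline)
  expect_identical(out2$cna_flag[2:3], c(TRUE, TRUE))  # both directions
})

test_that("CNA summary is the flagged fraction of evaluable bins", {
  prof <- data.frame(cna_flag = c(rep(TRUE, 100), rep(FALSE, 900)))
  s <- summarize_cna(prof, "S1")
  expect_equal(s$cna_fraction, 0.1)
  expect_error(summarize_cna(data.frame(cna_flag = NA)), "no evaluable")
})

test_that("pipeline path matches brute-force arithmetic on 50 bins", {
  set.seed(23)
  n <- 50
  gc <- rep(c(0.4, 0.6), each = 25)  # two strata: deterministic fallback
  raw <- rpois(n, 2000)
  baseline <- data.frame(count_mean = runif(n, 0.9, 1.1),
                         count_sd = runif(n, 0.02, 0.05),
                         md_mean = 0.7, md_sd = 0.03, evaluable = TRUE)
  prof <- data.frame(normalized_count =
                       median_normalize(gc_correct(raw, gc)))
  out <- cna_zscores(prof, baseline)
  # independent recomputation: stratum medians by hand
  med <- tapply(raw, gc, median)
  fhat <- as.numeric(med[as.character(gc)])
  k <- (1 / fhat) / mean(1 / fhat)
  corr <- raw * k
  norm <- corr / median(corr)
  for (i in seq_len(n)) {
    z_i <- (norm[i] - baseline$count_mean[i]) / baseline$count_sd[i]
    expect_equal(out$z[i], z_i, tolerance = 1e-12)
    expect_identical(out$cna_flag[i], z_i > 3 || z_i < -3)
  }
})

test_that("permuting bins permutes z-scores identically", {
  set.seed(24)
  n <- 200
  gc <- runif(n, 0.35, 0.6)
  raw <- rpois(n, 3000)
  z1 <- median_normalize(gc_correct(raw, gc))
  perm <- sample(n)
  z2 <- median_normalize(gc_correct(raw[perm], gc[perm]))
  expect_equal(z2, z1[perm], tolerance = 1e-9)
})

test_that("amplification score is the mean count ratio over gene bins", {
  baseline <- data.frame(count_mean = rep(1, 10), count_sd = rep(0.05, 10),
                         md_mean = 0.7, md_sd = 0.03, evaluable = TRUE)
  prof <- data.frame(normalized_count = c(rep(1, 7), rep(2, 3)))
  null_score <- amplification_score(prof, baseline, 1:7, gene = "NULL")
  expect_equal(null_score$score, 1)
  amp <- amplification_score(prof, baseline, 8:10, gene = "EGFR")
  expect_equal(amp$score, 2)
  expect_equal(amp$z_mean, 20)
  expect_error(amplification_score(prof, baseline, integer(0)), "empty")
  baseline$evaluable[8:10] <- FALSE
  expect_error(amplification_score(prof, baseline, 8:10, gene = "EGFR"),
               "no evaluable")
})

test_that("a simulated +5 SD segment is fully flagged at high coverage", {
  cfg <- small_config(seed = 9, coverage_mean = 20000, nb_size = 5000,
                      n_healthy = 20, cna_effect_sds = 5)
  reg <- simulate_genome(cfg)
  healthy <- lapply(simulate_healthy(cfg, reg),
                    methcna:::process_bin_sample, registry = reg,
                    config = cfg)
  base <- fit_baseline(healthy, registry = reg)
  pat <- simulate_patient(cfg, reg, group = "on_target", index = 1,
                          hypo_fraction = 0, cna_fraction = 0.1)
  pat <- methcna:::process_bin_sample(pat, reg, cfg)
  out <- cna_zscores(pat, base)
  truth <- attr(pat, "truth")
  expect_gt(length(truth$cna_bins), 0)
  flagged <- out$cna_flag[truth$cna_bins]
  expect_gte(mean(flagged, na.rm = TRUE), 0.95)
})
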