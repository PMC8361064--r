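test_that("a fixed seed makes every generator output identical", {
  cfg <- small_config(seed = 99)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  expect_identical(simulate_healthy(cfg), simulate_healthy(cfg))
  reg <- simulate_genome(cfg)
  p1 <- simulate_patient(cfg, reg, "on_target", index = 2)
  p2 <- simulate_patient(cfg, reg, "on_target", index = 2)
  expect_identical(p1, p2)
  expect_identical(attr(p1, "truth"), attr(p2, "truth"))
  d <- simulate_panel_design(cfg)
  expect_identical(d, simulate_panel_design(cfg))
  expect_identical(simulate_panel(cfg, d, "on_target", 1),
                   simulate_panel(cfg, d, "on_target", 1))
  expect_identical(simulate_umi_families(n_families = 20, seed = 3),
                   simulate_umi_families(n_families = 20, seed = 3))
})

test_that("the GC bias curve is quadratic, off at strength zero", {
  cfg <- small_config(gc_bias_strength = 0)
  gc <- seq(0.35, 0.6, by = 0.05)
  expect_equal(methcna:::gc_bias_curve(gc, cfg), rep(1, length(gc)))
  cfg2 <- small_config(gc_bias_strength = 0.3)
  b <- methcna:::gc_bias_curve(gc, cfg2)
  expect_equal(methcna:::gc_bias_curve(0.475, cfg2), 1)  # centre of range
  expect_equal(b[1], 0.7)  # reduced by the strength at the range edge
  expect_equal(b[length(b)], 0.7)
})

test_that("zero MD noise at high coverage concentrates MD at the mean", {
  cfg <- small_config(seed = 5, md_baseline_sd = 0, cpg_obs_mean = 50000,
                      nb_size = 1e6)
  reg <- simulate_genome(cfg)
  s <- simulate_healthy(cfg, reg, n = 1)[[1]]
  md <- methylation_density(s$meth_c, s$total_c)
  expect_lt(max(abs(md - cfg$md_baseline_mean)), 0.01)
})

test_that("patient truth records carry exact perturbed-bin counts", {
  cfg <- small_config(seed = 12)
  reg <- simulate_genome(cfg)
  pat <- simulate_patient(cfg, reg, "on_target", index = 1,
                          hypo_fraction = 0.2, cna_fraction = 0.2)
  truth <- attr(pat, "truth")
  n <- nrow(reg)
  expect_length(truth$hypo_bins, round(0.2 * n))
  expect_length(truth$cna_bins, round(0.2 * n))
  expect_equal(truth$hypo_fraction_true, length(truth$hypo_bins) / n)
  # the configured overlap share of CNA bins lies in the hypo set
  expect_gte(mean(truth$cna_bins %in% truth$hypo_bins),
             cfg$cna_overlap - 0.05)
  # unperturbed patient: empty truth
  null_pat <- simulate_patient(cfg, reg, "on_target", index = 2,
                               hypo_fraction = 0, cna_fraction = 0,
                               profile = "T790M")
  nt <- attr(null_pat, "truth")
  expect_length(nt$hypo_bins, 0)
  expect_length(nt$cna_bins, 0)
  # off-target patients draw from the healthy model
  off <- attr(simulate_patient(cfg, reg, "off_target", index = 3), "truth")
  expect_equal(off$hypo_fraction_true, 0)
})

test_that("amplification carriers get the focal gene multiplier", {
  cfg <- sim_config(seed = 13, chrom_lengths = c(chr7 = 159345973),
                    n_healthy = 4)
  reg <- simulate_genome(cfg)
  pat <- simulate_patient(cfg, reg, "on_target", index = 1,
                          profile = "EGFR_amp", hypo_fraction = 0,
                          cna_fraction = 0, amp_mult = 2.5)
  truth <- attr(pat, "truth")
  expect_equal(truth$amp_gene, "EGFR_amp")
  expect_equal(truth$amp_mult, 2.5)
  egfr <- gene_regions()$EGFR
  expect_equal(truth$amp_bins,
               bins_overlapping_region(reg, egfr$chrom, egfr$start,
                                       egfr$end))
})

test_that("invalid generator settings are rejected", {
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
  expect_error(sim_config(hypo_effect_sds = -1), "effect sizes")
  expect_error(sim_config(rho_tttr = 1), "rho_tttr")
  expect_error(sim_config(n_regions = 100, n_hyper = 90,
                          n_hypo_regions = 20), "exceed")
  expect_error(sim_config(chrom_lengths = c(chrX = 1e6)) |>
                 simulate_genome(), "chrX")
})

test_that("panel regions with zero observations become missing", {
  cfg <- sim_config(seed = 14, n_regions = 200, n_hyper = 0,
                    n_hypo_regions = 0, panel_cpg_obs = 1)
  d <- simulate_panel_design(cfg)
  counts <- simulate_panel(cfg, d, "healthy", 1)
  m <- region_methylation_matrix(counts)
  zero <- counts$meth_c + counts$unmeth_c == 0
  expect_gt(sum(zero), 0)  # Poisson(1) leaves some regions unobserved
  expect_true(all(is.na(m[1, zero])))
})

test_that("panel design defaults cover 9593 CpG sites over 450 regions", {
  d <- simulate_panel_design(sim_config(seed = 15))
  expect_equal(nrow(d), 450)
  expect_equal(sum(d$n_cpg), 9593)
  expect_equal(sum(d$class == "hyper"), 202)
  expect_equal(sum(d$class == "hypo"), 58)
  # shifted probabilities stay inside [0.02, 0.98]
  expect_true(all(d$on_target_p >= 0.02 & d$on_target_p <= 0.98))
})

test_that("clinical TTTR tracks the CNA fraction at the configured rho", {
  set.seed(71)
  cfg <- sim_config(seed = 16, rho_tttr = 0.9)
  # large synthetic EGFR-amp cohort: sample r concentrates near rho
  rs <- sapply(1:20, function(i) {
    cfg_i <- sim_config(seed = 16 + i, rho_tttr = 0.9)
    pats <- data.frame(patient_id = sprintf("P%d", 1:200),
                       profile = "EGFR_amp", group = "on_target",
                       cna_fraction = runif(200, 0.05, 0.5),
                       stringsAsFactors = FALSE)
    out <- simulate_clinical(cfg_i, pats)
    cor(out$cna_fraction, out$tttr_days)
  })
  expect_gte(mean(rs >= 0.85 & rs <= 0.945), 0.9)
  # null rho: sample r stays small at n = 50
  rs0 <- sapply(1:40, function(i) {
    cfg_i <- sim_config(seed = 100 + i, rho_tttr = 0)
    pats <- data.frame(patient_id = sprintf("P%d", 1:50),
                       profile = "EGFR_amp", group = "on_target",
                       cna_fraction = runif(50, 0.05, 0.5),
                       stringsAsFactors = FALSE)
    out <- simulate_clinical(cfg_i, pats)
    abs(cor(out$cna_fraction, out$tttr_days))
  })
  expect_gte(mean(rs0 < 0.3), 0.85)
})

test_that("TTTR clamping keeps durations positive", {
  cfg <- sim_config(seed = 17, tttr_mean_days = 50, tttr_sd_days = 200)
  pats <- data.frame(patient_id = sprintf("P%d", 1:30), profile = "T790M",
                     group = "on_target", cna_fraction = runif(30),
                     stringsAsFactors = FALSE)
  out <- simulate_clinical(cfg, pats)
  expect_true(all(out$tttr_days >= 30))
})
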