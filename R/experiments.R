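# Calibration and recovery experiments. These are the package's own
# validation studies: each runs the full analysis path on generated data
# and measures a property with a known expectation (null exceedance
# rates, parameter recovery, DMR recall, consensus error suppression).
# They back both the test suite and scripts/acceptance.R.

# A medium genome used by the experiments: three 500 Mb autosomes
# (1500 bins at 1 Mb), large enough for stable rates, small enough to
# keep hundreds of replicates fast.
experiment_chrom_lengths <- function() {
  c(chr1 = 500e6, chr2 = 500e6, chr3 = 500e6)
}

#' Null calibration of the hypomethylation and CNA callers
#'
#' Simulates unperturbed samples against a healthy baseline and measures
#' the mean hypomethylated-bin fraction and CNA-bin fraction. With
#' Gaussian-dominated noise these approach the Gaussian tail expectations
#' Phi(-3) ~ 0.00135 (one-sided) and 2*Phi(-3) ~ 0.0027 (two-sided) as
#' the reference grows; the default reference of 500 subjects makes the
#' Student-t inflation of the +/-3 SD threshold negligible (at the
#' study's n = 20 the same rates are ~3x higher, a property of the
#' estimator, not a bug).
#'
#' @param seed Integer seed.
#' @param n_reference Healthy subjects in the baseline (default 500).
#' @param n_replicates Unperturbed test samples (default 200).
#' @param chrom_lengths Genome to simulate (default three 500 Mb
#'   chromosomes, 1500 bins).
#' @return List: `hypo_fraction_mean`, `cna_fraction_mean`,
#'   `n_replicates`, `n_bins`.
#' @export
null_calibration <- function(seed = 1, n_reference = 500,
                             n_replicates = 200,
                             chrom_lengths = experiment_chrom_lengths()) {
  config <- sim_config(seed = seed, chrom_lengths = chrom_lengths,
                       n_healthy = n_reference)
  registry <- simulate_genome(config)
  healthy <- lapply(simulate_healthy(config, registry),
                    process_bin_sample, registry = registry,
                    config = config)
  baseline <- fit_baseline(healthy, registry = registry)
  hypo <- cna <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    s <- simulate_patient(config, registry, group = "off_target",
                          index = 100000L + i, profile = "MET_amp",
                          amp_mult = 1)
    s <- process_bin_sample(s, registry, config)
    s <- call_hypomethylated(s, baseline)
    s <- cna_zscores(s, baseline)
    hypo[i] <- summarize_methylome(s)$hypo_fraction
    cna[i] <- summarize_cna(s)$cna_fraction
  }
  list(hypo_fraction_mean = mean(hypo), cna_fraction_mean = mean(cna),
       n_replicates = n_replicates, n_bins = nrow(registry))
}

#' Parameter recovery of generator hypo/CNA fractions
#'
#' For each true fraction, simulates one on-target patient whose
#' hypomethylated and CNA bin counts are fixed exactly (fractions
#' specified as counts), at the configured large effect sizes, and runs
#' the full calling path against a fresh 20-subject healthy baseline.
#'
#' @param seed Integer seed.
#' @param fractions True fractions to recover (default the study-scale
#'   set 0.05, 0.2, 0.39).
#' @param n_reference Healthy subjects (default 20, the study design).
#' @param chrom_lengths Genome to simulate.
#' @return Data.frame: `fraction_true`, `hypo_fraction_est`,
#'   `cna_fraction_est`, `hypo_abs_error`, `cna_abs_error`.
#' @export
recovery_experiment <- function(seed = 1,
                                fractions = c(0.05, 0.2, 0.39),
                                n_reference = 20,
                                chrom_lengths = experiment_chrom_lengths()) {
  config <- sim_config(seed = seed, chrom_lengths = chrom_lengths,
                       n_healthy = n_reference)
  registry <- simulate_genome(config)
  healthy <- lapply(simulate_healthy(config, registry),
                    process_bin_sample, registry = registry,
                    config = config)
  baseline <- fit_baseline(healthy, registry = registry)
  res <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    s <- simulate_patient(config, registry, group = "on_target",
                          index = 200000L + i, profile = "T790M",
                          hypo_fraction = f, cna_fraction = f)
    s <- process_bin_sample(s, registry, config)
    s <- call_hypomethylated(s, baseline)
    s <- cna_zscores(s, baseline)
    data.frame(fraction_true = f,
               hypo_fraction_est = summarize_methylome(s)$hypo_fraction,
               cna_fraction_est = summarize_cna(s)$cna_fraction)
  })
  res <- do.call(rbind, res)
  res$hypo_abs_error <- abs(res$hypo_fraction_est - res$fraction_true)
  res$cna_abs_error <- abs(res$cna_fraction_est - res$fraction_true)
  res
}

#' DMR recovery on the study-scale panel design
#'
#' Replicated 11-vs-8 comparisons on a 450-region panel with 202
#' hyper-shifted and 58 hypo-shifted regions at the configured large
#' effects. Measures recall of shifted regions with the correct
#' direction and the false-call rate on null regions.
#'
#' @param seed Integer seed.
#' @param n_replicates Replicate panels (default 3).
#' @return List: `recall_hyper`, `recall_hypo`, `false_call_rate` (means
#'   over replicates), `n_hyper_called`, `n_hypo_called`, `n_called`
#'   (first replicate's counts), `per_replicate` data.frame.
#' @export
dmr_recovery_experiment <- function(seed = 1, n_replicates = 3) {
  per <- lapply(seq_len(n_replicates), function(r) {
    config <- sim_config(seed = seed + 17L * (r - 1L))
    design <- simulate_panel_design(config)
    groups <- rep(c("on_target", "off_target"),
                  c(length(config$on_target_profiles),
                    length(config$off_target_profiles)))
    counts <- do.call(rbind, lapply(seq_along(groups), function(i) {
      simulate_panel(config, design, group = groups[i], index = i,
                     sample_id = sprintf("S%02d", i))
    }))
    pct <- region_methylation_matrix(counts)
    dmr <- call_dmrs(pct, factor(groups, levels = c("on_target",
                                                    "off_target")))
    cls <- design$class[match(dmr$region_id, design$region_id)]
    data.frame(
      recall_hyper = mean(dmr$call[cls == "hyper"] == "hyper"),
      recall_hypo = mean(dmr$call[cls == "hypo"] == "hypo"),
      false_call_rate = mean(dmr$call[cls == "null"] != "none"),
      n_hyper_called = sum(dmr$call == "hyper"),
      n_hypo_called = sum(dmr$call == "hypo"),
      n_called = sum(dmr$call != "none"))
  })
  per <- do.call(rbind, per)
  list(recall_hyper = mean(per$recall_hyper),
       recall_hypo = mean(per$recall_hypo),
       false_call_rate = mean(per$false_call_rate),
       n_hyper_called = per$n_hyper_called[1],
       n_hypo_called = per$n_hypo_called[1],
       n_called = per$n_called[1],
       per_replicate = per)
}

#' UMI consensus error suppression
#'
#' Simulates read families with independent per-base errors, collapses
#' them, and measures the consensus per-base error rate against the
#' truth sequences (an `N` counts as an error).
#'
#' @param seed Integer seed.
#' @param n_families,family_size,read_length,error_rate Generator
#'   settings (defaults: 10000 families of 3 reads, 20 bp, 5% per-base
#'   error).
#' @return List: `consensus_error_rate`, `input_error_rate`,
#'   `n_families`.
#' @export
umi_error_experiment <- function(seed = 1, n_families = 10000,
                                 family_size = 3, read_length = 20,
                                 error_rate = 0.05) {
  fams <- simulate_umi_families(n_families = n_families,
                                family_size = family_size,
                                read_length = read_length,
                                error_rate = error_rate, seed = seed)
  errs <- vapply(fams, function(f) {
    cons <- umi_consensus(f)$consensus
    truth <- strsplit(f$truth, "")[[1]]
    got <- strsplit(cons, "")[[1]]
    sum(got != truth)
  }, numeric(1))
  list(consensus_error_rate = sum(errs) / (n_families * read_length),
       input_error_rate = error_rate, n_families = n_families)
}

#' End-to-end VAF estimation from UMI families
#'
#' Simulates families where a known fraction of fragments carries the
#' alternate allele, injects pre-consensus errors, collapses and
#' estimates the VAF.
#'
#' @param seed Integer seed.
#' @param n_families,family_size,error_rate,vaf_true Generator settings
#'   (defaults: 5000 families of 3, 1% error, 2% true VAF).
#' @return List: `vaf_est_pct`, `vaf_true_pct`, `n_fragments`.
#' @export
vaf_experiment <- function(seed = 1, n_families = 5000, family_size = 3,
                           error_rate = 0.01, vaf_true = 0.02) {
  fams <- simulate_umi_families(n_families = n_families,
                                family_size = family_size,
                                error_rate = error_rate,
                                vaf_true = vaf_true, alt_pos = 10,
                                ref_base = "A", alt_base = "T",
                                seed = seed)
  cons <- collapse_families(fams)
  est <- consensus_vaf(cons, pos = 10, ref = "A", alt = "T",
                       locus = "locus1")
  list(vaf_est_pct = est$vaf, vaf_true_pct = 100 * vaf_true,
       n_fragments = est$total_fragments)
}
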