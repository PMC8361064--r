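# Full pipeline orchestration: generate -> baseline -> methylome -> CNA ->
# panel DMR -> cohort statistics, with TSV/JSON export and a run manifest.

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

# MD + count processing shared by healthy and patient samples.
process_bin_sample <- function(sample, registry, config) {
  sample$md <- methylation_density(sample$meth_c, sample$total_c,
                                   min_cpg_obs = config$min_cpg_obs)
  counts <- process_counts(sample$raw_count, registry$gc_fraction,
                           span = config$loess_span)
  sample$corrected_count <- counts$corrected_count
  sample$normalized_count <- counts$normalized_count
  sample
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the genome and healthy reference, fits the baseline (healthy
#' samples processed through the identical GC-correct / median-normalize
#' path as patients), simulates and analyses the patient cohort
#' (hypomethylation calls, CNA z-scores, focal amplification scores),
#' tests the targeted panel for DMRs between the on- and off-target
#' groups, attaches clinical covariates, and computes the cohort
#' statistics: Mann-Whitney contrasts of hypo/CNA fractions, the
#' cross-sample hypomethylation-CNA Pearson correlation, and the TTTR
#' correlations within the EGFR-amplification group. Any stage failure
#' aborts naming the stage.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all tables are written
#'   as TSV/JSON plus a run manifest, deterministically (two runs with one
#'   config produce byte-identical files).
#' @return A result bundle list: `registry`, `baseline`, `patients`
#'   (records with measured fractions, scores and clinical covariates),
#'   `methylome`, `cna` (per-sample summaries), `profiles` (per-patient
#'   bin tables), `panel` (design, %methylation matrix, DMR results),
#'   `stats`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  registry <- pipeline_stage("genome", simulate_genome(config))

  healthy <- pipeline_stage("healthy_reference", {
    lapply(simulate_healthy(config, registry), process_bin_sample,
           registry = registry, config = config)
  })
  baseline <- pipeline_stage("baseline",
                             fit_baseline(healthy, registry = registry))

  profiles <- c(config$on_target_profiles, config$off_target_profiles)
  groups <- rep(c("on_target", "off_target"),
                c(length(config$on_target_profiles),
                  length(config$off_target_profiles)))
  patients <- pipeline_stage("patients", {
    lapply(seq_along(profiles), function(i) {
      s <- simulate_patient(config, registry, group = groups[i], index = i,
                            profile = profiles[i])
      process_bin_sample(s, registry, config)
    })
  })

  analysed <- pipeline_stage("genome_wide_calls", {
    lapply(patients, function(s) {
      s <- call_hypomethylated(s, baseline,
                               sd_multiplier = config$sd_multiplier)
      cna_zscores(s, baseline, z_cut = config$z_cut)
    })
  })

  records <- pipeline_stage("summaries", {
    do.call(rbind, lapply(seq_along(analysed), function(i) {
      s <- analysed[[i]]
      id <- attr(patients[[i]], "sample_id")
      meth <- summarize_methylome(s, id)
      cna <- summarize_cna(s, id)
      truth <- attr(patients[[i]], "truth")
      amp <- NA_real_
      if (!is.na(truth$amp_gene) && length(truth$amp_bins)) {
        amp <- amplification_score(s, baseline, truth$amp_bins,
                                   gene = sub("_amp", "",
                                              truth$amp_gene))$score
      }
      data.frame(patient_id = id, profile = profiles[i], group = groups[i],
                 n_evaluable_bins = meth$n_evaluable_bins,
                 n_hypo_bins = meth$n_hypo_bins,
                 hypo_fraction = meth$hypo_fraction,
                 n_cna_bins = cna$n_cna_bins,
                 cna_fraction = cna$cna_fraction,
                 amp_score = amp,
                 hypo_fraction_true = truth$hypo_fraction_true,
                 cna_fraction_true = truth$cna_fraction_true,
                 stringsAsFactors = FALSE)
    }))
  })

  panel <- pipeline_stage("panel_dmr", {
    design <- simulate_panel_design(config)
    counts <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      simulate_panel(config, design, group = groups[i], index = i,
                     sample_id = attr(patients[[i]], "sample_id"))
    }))
    pct <- region_methylation_matrix(counts)
    dmr <- call_dmrs(pct, factor(groups[match(rownames(pct),
                                              records$patient_id)],
                                 levels = c("on_target", "off_target")))
    list(design = design, counts = counts, pct_matrix = pct, dmr = dmr)
  })

  records <- pipeline_stage("clinical", {
    simulate_clinical(config, records)
  })

  stats <- pipeline_stage("cohort_stats", {
    on <- records[records$group == "on_target", ]
    off <- records[records$group == "off_target", ]
    egfr_amp <- records[grepl("EGFR_amp", records$profile), ]
    out <- list(
      mw_hypo_p = mann_whitney(on$hypo_fraction, off$hypo_fraction),
      mw_cna_p = mann_whitney(on$cna_fraction, off$cna_fraction),
      hypo_cna_cor = pearson_with_ci(records$hypo_fraction,
                                     records$cna_fraction),
      mean_hypo_pct_on = 100 * mean(on$hypo_fraction),
      mean_hypo_pct_off = 100 * mean(off$hypo_fraction),
      mean_cna_pct_on = 100 * mean(on$cna_fraction),
      mean_cna_pct_off = 100 * mean(off$cna_fraction))
    if (nrow(egfr_amp) >= 3) {
      out$tttr_cna_cor <- pearson_with_ci(egfr_amp$cna_fraction,
                                          egfr_amp$tttr_days)
      out$tttr_hypo_cor <- pearson_with_ci(egfr_amp$hypo_fraction,
                                           egfr_amp$tttr_days)
      if (stats::sd(egfr_amp$amp_score) > 0) {
        out$tttr_amp_cor <- pearson_with_ci(egfr_amp$amp_score,
                                            egfr_amp$tttr_days)
      }
    }
    out
  })

  manifest <- list(package = "methcna",
                   version = as.character(utils::packageVersion("methcna")),
                   seed = config$seed,
                   n_bins = nrow(registry),
                   n_healthy = config$n_healthy,
                   n_patients = length(profiles),
                   n_regions = config$n_regions,
                   parameters = config[setdiff(names(config),
                                               "chrom_lengths")])

  bundle <- list(registry = registry, baseline = baseline,
                 patients = records,
                 profiles = stats::setNames(analysed, records$patient_id),
                 panel = panel, stats = stats,
                 truth = lapply(patients, attr, "truth"),
                 manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

#' Write a pipeline result bundle to disk
#'
#' TSV for all tables, JSON for statistics, truth records and the run
#' manifest. Output is deterministic given the bundle.
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_bin_registry(bundle$registry, fp("bin_registry.tsv"))
  write_baseline(bundle$baseline, fp("baseline.tsv"))
  write_tsv(bundle$patients, fp("patients.tsv"))
  for (id in names(bundle$profiles)) {
    write_tsv(bundle$profiles[[id]], fp(sprintf("profile_%s.tsv", id)))
  }
  write_tsv(bundle$panel$design, fp("panel_design.tsv"))
  write_tsv(bundle$panel$counts, fp("panel_counts.tsv"))
  pct <- data.frame(sample_id = rownames(bundle$panel$pct_matrix),
                    bundle$panel$pct_matrix, check.names = FALSE)
  write_tsv(pct, fp("panel_pct_matrix.tsv"))
  write_tsv(bundle$panel$dmr, fp("dmr_results.tsv"))
  stats_flat <- lapply(bundle$stats, function(s) {
    if (inherits(s, "correlation_result")) unclass(s) else s
  })
  jsonlite::write_json(stats_flat, fp("stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
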