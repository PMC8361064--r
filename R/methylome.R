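# Genome-wide methylome: per-bin methylation density (MD), hypomethylation
# calls against the healthy baseline, and per-sample summary.

#' Per-bin methylation density
#'
#' MD of a bin is the number of methylated cytosines at CpG positions
#' divided by the total number of cytosines observed at CpG positions in
#' that bin. Bins with fewer than `min_cpg_obs` observations are returned
#' as missing rather than as a noisy ratio.
#'
#' @param meth_c Methylated cytosine counts (vectorized).
#' @param total_c Total CpG cytosine counts.
#' @param min_cpg_obs Minimum observations for a defined MD (default 10).
#' @return Numeric vector in `[0,1]`, `NA` below the observation threshold.
#' @examples
#' methylation_density(50, 100)            # 0.5
#' methylation_density(3, 5)               # NA: under default threshold
#' @export
methylation_density <- function(meth_c, total_c, min_cpg_obs = 10) {
  if (length(meth_c) != length(total_c)) {
    stopf("meth_c and total_c must have equal length")
  }
  if (any(meth_c < 0 | total_c < 0, na.rm = TRUE)) {
    stopf("counts must be non-negative")
  }
  if (any(meth_c > total_c, na.rm = TRUE)) {
    stopf("meth_c cannot exceed total_c")
  }
  md <- ifelse(total_c >= min_cpg_obs, meth_c / total_c, NA_real_)
  as.numeric(md)
}

#' Call hypomethylated bins against the healthy baseline
#'
#' A bin is hypomethylated when its MD is strictly lower than the healthy
#' mean minus `sd_multiplier` healthy SDs for that bin. The flag is missing
#' wherever the sample MD is missing or the baseline is non-evaluable.
#'
#' @param profile Data.frame with a per-bin `md` column (and optionally
#'   coordinate columns, checked against the baseline).
#' @param baseline A `reference_baseline` on the same registry.
#' @param sd_multiplier SD multiplier below the mean (default 3).
#' @return `profile` with a logical `hypo_flag` column added.
#' @export
call_hypomethylated <- function(profile, baseline, sd_multiplier = 3) {
  if (!"md" %in% names(profile)) stopf("profile has no 'md' column")
  if (all(c("chrom", "start", "end") %in% names(profile)) &&
      all(c("chrom", "start", "end") %in% names(baseline))) {
    check_same_registry(profile, baseline, "sample profile")
  } else if (nrow(profile) != nrow(baseline)) {
    stopf("profile has %d bins but baseline has %d", nrow(profile),
          nrow(baseline))
  }
  thr <- baseline$md_mean - sd_multiplier * baseline$md_sd
  flag <- profile$md < thr
  flag[!baseline$evaluable | is.na(profile$md)] <- NA
  profile$hypo_flag <- flag
  profile
}

#' Summarize a sample's genome-wide hypomethylation
#'
#' The hypomethylated-bin fraction is computed over evaluable bins only
#' (bins with a defined call), so missingness does not deflate the
#' statistic; the counts are reported alongside the fraction.
#'
#' @param profile Data.frame with a populated `hypo_flag` column.
#' @param sample_id Optional sample label.
#' @return One-row data.frame: `sample_id`, `n_evaluable_bins`,
#'   `n_hypo_bins`, `hypo_fraction`.
#' @export
summarize_methylome <- function(profile, sample_id = NA_character_) {
  if (!"hypo_flag" %in% names(profile)) {
    stopf("profile has no 'hypo_flag' column; run call_hypomethylated first")
  }
  ok <- !is.na(profile$hypo_flag)
  n_eval <- sum(ok)
  if (n_eval == 0) stopf("no evaluable bins; cannot summarize")
  n_hypo <- sum(profile$hypo_flag[ok])
  data.frame(sample_id = sample_id, n_evaluable_bins = n_eval,
             n_hypo_bins = n_hypo, hypo_fraction = n_hypo / n_eval,
             stringsAsFactors = FALSE)
}

#' Read / write a per-sample bin methylation table
#'
#' TSV with columns chrom, start, end, meth_c, total_c (writer adds md and
#' hypo_flag when present).
#'
#' @param x Profile data.frame.
#' @param path File path.
#' @return The profile (reader) or the path invisibly (writer).
#' @export
read_bin_profile <- function(path) {
  read_tsv(path)
}

#' @rdname read_bin_profile
#' @export
write_bin_profile <- function(x, path) {
  write_tsv(x, path)
}
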