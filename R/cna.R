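# Copy-number aberration calling from shallow-sequencing bin counts:
# GC-correct -> median-normalize -> per-bin z-score vs the healthy
# baseline -> |z| > 3 call. The stage order is fixed; healthy subjects are
# processed through the identical path before the baseline is fitted.

#' GC-bias correction of bin read counts
#'
#' Fits a LOESS curve of count on GC fraction and divides each bin's count
#' by the fitted value, rescaled so the mean correction factor over
#' evaluable bins is 1 (total signal is preserved). For small bin sets
#' (< `min_bins` bins or < 3 distinct GC values) a median-per-GC-stratum
#' correction is used instead; with a single GC stratum the correction is
#' the identity, with a warning.
#'
#' @param raw_counts Per-bin read counts.
#' @param gc_fraction Per-bin GC fraction in `[0,1]`.
#' @param span LOESS span (default 0.3).
#' @param min_bins Minimum bins for the LOESS route (default 30).
#' @return Corrected counts, same length as input (`NA` kept as `NA`).
#' @export
gc_correct <- function(raw_counts, gc_fraction, span = 0.3, min_bins = 30) {
  n <- length(raw_counts)
  if (length(gc_fraction) != n) {
    stopf("raw_counts and gc_fraction must have equal length")
  }
  ok <- !is.na(raw_counts) & !is.na(gc_fraction)
  gc_levels <- unique(gc_fraction[ok])
  if (length(gc_levels) <= 1) {
    warnf("all GC fractions identical; GC correction is the identity")
    return(as.numeric(raw_counts))
  }
  fhat <- rep(NA_real_, n)
  if (sum(ok) < min_bins || length(gc_levels) < 3) {
    # stratum fallback: expected count = median of the bin's GC stratum
    med <- tapply(raw_counts[ok], factor(gc_fraction[ok]), stats::median)
    fhat[ok] <- as.numeric(med[as.character(gc_fraction[ok])])
  } else {
    fit <- stats::loess(y ~ gc,
                        data = data.frame(y = raw_counts[ok],
                                          gc = gc_fraction[ok]),
                        span = span, degree = 2)
    fhat[ok] <- stats::predict(fit, data.frame(gc = gc_fraction[ok]))
  }
  fhat[!is.na(fhat) & fhat <= 0] <- NA_real_
  k <- 1 / fhat                       # per-bin correction factor
  k <- k / mean(k[ok], na.rm = TRUE)  # mean correction factor = 1
  as.numeric(raw_counts * k)
}

#' Median normalization of corrected counts
#'
#' Divides every bin by the median corrected count over evaluable bins, so
#' the genome-wide median of the output is 1 and the result is invariant
#' to sequencing depth.
#'
#' @param corrected_counts Per-bin GC-corrected counts.
#' @return Normalized counts.
#' @export
median_normalize <- function(corrected_counts) {
  ok <- !is.na(corrected_counts)
  if (!any(ok)) stopf("no evaluable bins to normalize")
  med <- stats::median(corrected_counts[ok])
  if (!is.finite(med) || med == 0) {
    stopf("median corrected count is zero; cannot normalize")
  }
  corrected_counts / med
}

# Convenience: the fixed correction path raw -> corrected -> normalized.
process_counts <- function(raw_counts, gc_fraction, span = 0.3) {
  corrected <- gc_correct(raw_counts, gc_fraction, span = span)
  list(corrected_count = corrected,
       normalized_count = median_normalize(corrected))
}

#' Per-bin copy-number z-scores and CNA calls
#'
#' z = (normalized count - healthy mean) / healthy SD per bin; missing
#' where the baseline is non-evaluable. A bin is copy-number aberrant when
#' z > `z_cut` or z < -`z_cut` (strict inequalities).
#'
#' @param profile Data.frame with a `normalized_count` column (coordinates
#'   checked against the baseline when present).
#' @param baseline A `reference_baseline` on the same registry.
#' @param z_cut z-score cutoff (default 3).
#' @return `profile` with `z` and `cna_flag` columns added.
#' @export
cna_zscores <- function(profile, baseline, z_cut = 3) {
  if (!"normalized_count" %in% names(profile)) {
    stopf("profile has no 'normalized_count' column")
  }
  if (all(c("chrom", "start", "end") %in% names(profile)) &&
      all(c("chrom", "start", "end") %in% names(baseline))) {
    check_same_registry(profile, baseline, "sample profile")
  } else if (nrow(profile) != nrow(baseline)) {
    stopf("profile has %d bins but baseline has %d", nrow(profile),
          nrow(baseline))
  }
  z <- (profile$normalized_count - baseline$count_mean) / baseline$count_sd
  z[!baseline$evaluable] <- NA_real_
  profile$z <- z
  profile$cna_flag <- z > z_cut | z < -z_cut
  profile
}

#' Summarize a sample's genome-wide CNA burden
#'
#' @param profile Data.frame with a populated `cna_flag` column.
#' @param sample_id Optional sample label.
#' @return One-row data.frame: `sample_id`, `n_evaluable_bins`,
#'   `n_cna_bins`, `cna_fraction` (fraction over evaluable bins).
#' @export
summarize_cna <- function(profile, sample_id = NA_character_) {
  if (!"cna_flag" %in% names(profile)) {
    stopf("profile has no 'cna_flag' column; run cna_zscores first")
  }
  ok <- !is.na(profile$cna_flag)
  n_eval <- sum(ok)
  if (n_eval == 0) stopf("no evaluable bins; cannot summarize")
  n_cna <- sum(profile$cna_flag[ok])
  data.frame(sample_id = sample_id, n_evaluable_bins = n_eval,
             n_cna_bins = n_cna, cna_fraction = n_cna / n_eval,
             stringsAsFactors = FALSE)
}

#' Gene-level amplification score
#'
#' Proxy score for focal amplification of a gene: the mean, over the
#' gene's bins, of the sample's normalized count divided by the healthy
#' mean count, reported together with the mean z over those bins. Under no
#' amplification the score is 1 in expectation; a uniform doubling of the
#' gene's bins gives 2. This is a read-depth ratio, not an allele-specific
#' copy-number estimate, and its absolute scale is not comparable to
#' segmentation-based callers.
#'
#' @param profile Data.frame with `normalized_count` (and `z` if
#'   available).
#' @param baseline A `reference_baseline` on the same registry.
#' @param gene_bins Integer vector of registry row indices covering the
#'   gene.
#' @param gene Optional gene label.
#' @return One-row data.frame: `gene`, `n_bins`, `score`, `z_mean`.
#' @export
amplification_score <- function(profile, baseline, gene_bins,
                                gene = NA_character_) {
  if (length(gene_bins) == 0) stopf("gene_bins is empty")
  ev <- baseline$evaluable[gene_bins] &
    !is.na(profile$normalized_count[gene_bins])
  if (!any(ev)) stopf("no evaluable bin for gene %s", gene)
  idx <- gene_bins[ev]
  ratio <- profile$normalized_count[idx] / baseline$count_mean[idx]
  z <- (profile$normalized_count[idx] - baseline$count_mean[idx]) /
    baseline$count_sd[idx]
  data.frame(gene = gene, n_bins = length(idx), score = mean(ratio),
             z_mean = mean(z), stringsAsFactors = FALSE)
}
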