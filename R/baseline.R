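# Healthy-donor reference baseline: per-bin mean/SD of methylation density
# and of GC-corrected, median-normalized read counts, against which every
# hypomethylation and CNA call is made.

#' Fit the healthy reference baseline
#'
#' Computes the per-bin sample mean and sample SD (n-1 denominator) of
#' methylation density and of normalized read counts across healthy
#' subjects. Each subject profile must already be processed through the
#' same path as the patients (MD from counts, GC correction and median
#' normalization of read counts), so the downstream z-scores are calibrated
#' under the null.
#'
#' Bins where any subject has a missing MD, or where either SD is zero or
#' non-finite, are marked non-evaluable; no hypomethylation or CNA call is
#' made there (a zero SD would mean dividing by zero).
#'
#' @param profiles List of >= 2 per-subject data.frames, each aligned to
#'   the same bin registry and containing columns `md` and
#'   `normalized_count`.
#' @param registry Optional `bin_registry`; coordinates are copied into the
#'   baseline and each profile is checked against it when it carries
#'   coordinate columns.
#' @return A `reference_baseline` data.frame with columns `chrom`, `start`,
#'   `end` (when a registry is given), `md_mean`, `md_sd`, `count_mean`,
#'   `count_sd`, `evaluable`, and attribute `n_subjects`.
#' @export
fit_baseline <- function(profiles, registry = NULL) {
  if (!is.list(profiles) || length(profiles) < 2) {
    stopf("fit_baseline needs >= 2 healthy subjects (SD is undefined for fewer)")
  }
  n_bins <- nrow(profiles[[1]])
  for (p in profiles) {
    if (!all(c("md", "normalized_count") %in% names(p))) {
      stopf("each profile needs 'md' and 'normalized_count' columns")
    }
    if (nrow(p) != n_bins) stopf("profiles are not aligned to one bin registry")
    if (!is.null(registry) && all(c("chrom", "start", "end") %in% names(p))) {
      check_same_registry(p, registry, "healthy profile")
    }
  }
  md <- vapply(profiles, function(p) as.numeric(p$md), numeric(n_bins))
  ct <- vapply(profiles, function(p) as.numeric(p$normalized_count),
               numeric(n_bins))
  md <- matrix(md, nrow = n_bins)
  ct <- matrix(ct, nrow = n_bins)
  md_mean <- rowMeans(md)
  md_sd <- apply(md, 1, stats::sd)
  count_mean <- rowMeans(ct)
  count_sd <- apply(ct, 1, stats::sd)
  evaluable <- !is.na(md_mean) & !is.na(md_sd) & md_sd > 0 &
    !is.na(count_mean) & !is.na(count_sd) & count_sd > 0
  base <- data.frame(md_mean = md_mean, md_sd = md_sd,
                     count_mean = count_mean, count_sd = count_sd,
                     evaluable = evaluable)
  if (!is.null(registry)) {
    base <- cbind(registry[, c("chrom", "start", "end")], base)
  }
  attr(base, "n_subjects") <- length(profiles)
  class(base) <- c("reference_baseline", "data.frame")
  base
}

#' Persist / load a reference baseline as TSV
#'
#' @param baseline A `reference_baseline`.
#' @param path File path.
#' @return `write_baseline` returns the path invisibly; `read_baseline`
#'   returns a `reference_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  write_tsv(as.data.frame(baseline), path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  base <- read_tsv(path)
  base$evaluable <- as.logical(base$evaluable)
  class(base) <- c("reference_baseline", "data.frame")
  base
}
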