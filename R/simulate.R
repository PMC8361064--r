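# Synthetic cfDNA cohort generator. Emulates the study conditions the
# pipeline was built for: a 20-donor healthy reference, on-target patients
# with coupled genome-wide hypomethylation and segmental copy-number
# changes, off-target patients drawn from the healthy model (plus a focal
# MET/HER2 amplification), a 450-region panel hypermethylated in the
# on-target group, UMI read families with injected errors, and clinical
# covariates (TTTR, VAFs, amplification scores) with configurable
# correlation. One integer seed fully determines every output.

#' Simulation configuration
#'
#' Central parameter object for the synthetic cohort. Defaults emulate the
#' study design: hg38 autosomes in 1 Mb bins, 20 healthy reference
#' subjects, mean bin methylation density 0.7 with between-subject SD
#' 0.03, negative-binomial bin counts at shallow-sequencing depth with a
#' quadratic GC bias, an on-target group of 11 patients (5 T790M, 3
#' EGFR_amp, 3 co-occurring) whose hypomethylated-bin fraction is centred
#' on 0.389, an off-target group of 8 (4 MET_amp, 4 HER2_amp) drawn from
#' the healthy model, and a 450-region panel with 202 hyper- and 58
#' hypo-methylated regions in the on-target group.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param chrom_lengths Named autosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @param n_healthy Healthy reference subjects.
#' @param md_baseline_mean,md_baseline_sd Per-bin methylation probability:
#'   each subject-bin draws p ~ Normal(mean, sd) truncated to `[0,1]`.
#' @param cpg_obs_mean Mean CpG cytosine observations per bin (the MD
#'   denominator).
#' @param coverage_mean Mean aligned reads per bin.
#' @param nb_size Negative-binomial size (dispersion) for both count
#'   layers; larger means closer to Poisson.
#' @param gc_range Range of simulated per-bin GC fractions.
#' @param gc_bias_strength Depth of the quadratic GC-bias curve: expected
#'   counts at the GC extremes are reduced by this fraction (0 disables
#'   the bias).
#' @param min_cpg_obs,loess_span,sd_multiplier,z_cut Analysis settings
#'   carried through the pipeline.
#' @param hypo_fraction_mean,hypo_fraction_sd,hypo_fraction_range
#'   Per-patient true hypomethylated-bin fraction for on-target cases:
#'   truncated-normal draw.
#' @param hypo_effect_sds How many healthy SDs the affected bins' MD mean
#'   is shifted down (> 0).
#' @param cna_effect_sds How many healthy count SDs the affected bins'
#'   expected count is shifted (> 0), in either direction per segment.
#' @param cna_overlap Fraction of CNA bins drawn from the patient's
#'   hypomethylated bin set, inducing the hypo-CNA coupling.
#' @param segment_mean_len Mean length (bins) of the geometric perturbed
#'   segments.
#' @param on_target_profiles,off_target_profiles Resistance profiles of
#'   the simulated patients (comma-separated mutation sets).
#' @param n_regions,n_hyper,n_hypo_regions Panel size and the number of
#'   regions shifted up / down in the on-target group.
#' @param panel_cpg_obs Mean CpG observations per panel region per sample.
#' @param hyper_effect,hypo_effect Shift in methylation probability of the
#'   affected regions (> 0).
#' @param rho_tttr Target correlation between the CNA-bin fraction and
#'   time to treatment resistance in EGFR-amplification cases,
#'   in (-1, 1).
#' @param tttr_mean_days,tttr_sd_days TTTR marginal scale.
#' @param amp_score_range True amplification-multiplier range for gene
#'   amplification carriers.
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = hg38_autosome_lengths(),
                       bin_size = 1e6,
                       n_healthy = 20,
                       md_baseline_mean = 0.7,
                       md_baseline_sd = 0.03,
                       cpg_obs_mean = 5000,
                       coverage_mean = 7000,
                       nb_size = 2000,
                       gc_range = c(0.35, 0.60),
                       gc_bias_strength = 0.3,
                       min_cpg_obs = 10,
                       loess_span = 0.3,
                       sd_multiplier = 3,
                       z_cut = 3,
                       hypo_fraction_mean = 0.389,
                       hypo_fraction_sd = 0.12,
                       hypo_fraction_range = c(0.05, 0.70),
                       hypo_effect_sds = 8,
                       cna_effect_sds = 6,
                       cna_overlap = 0.8,
                       segment_mean_len = 20,
                       on_target_profiles = c(rep("T790M", 5),
                                              rep("EGFR_amp", 3),
                                              rep("T790M,EGFR_amp", 3)),
                       off_target_profiles = c(rep("MET_amp", 4),
                                               rep("HER2_amp", 4)),
                       n_regions = 450,
                       n_hyper = 202,
                       n_hypo_regions = 58,
                       panel_cpg_obs = 200,
                       hyper_effect = 0.5,
                       hypo_effect = 0.5,
                       rho_tttr = 0.9,
                       tttr_mean_days = 400,
                       tttr_sd_days = 150,
                       amp_score_range = c(1.5, 3)) {
  cfg <- as.list(environment())
  if (cfg$coverage_mean <= 0) stopf("coverage_mean must be positive")
  if (cfg$cpg_obs_mean <= 0) stopf("cpg_obs_mean must be positive")
  if (cfg$n_healthy < 2) stopf("n_healthy must be >= 2")
  if (cfg$md_baseline_mean < 0 || cfg$md_baseline_mean > 1) {
    stopf("md_baseline_mean must lie in [0,1]")
  }
  if (cfg$md_baseline_sd < 0) stopf("md_baseline_sd must be >= 0")
  if (cfg$hypo_effect_sds <= 0 || cfg$cna_effect_sds <= 0) {
    stopf("effect sizes must be positive")
  }
  if (cfg$hyper_effect <= 0 || cfg$hypo_effect <= 0) {
    stopf("panel effect sizes must be positive")
  }
  if (cfg$cna_overlap < 0 || cfg$cna_overlap > 1) {
    stopf("cna_overlap must lie in [0,1]")
  }
  if (abs(cfg$rho_tttr) >= 1) stopf("rho_tttr must lie in (-1, 1)")
  if (cfg$n_hyper + cfg$n_hypo_regions > cfg$n_regions) {
    stopf("shifted regions exceed panel size")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Quadratic GC-bias curve: 1 at mid-range GC, reduced by
# gc_bias_strength at the extremes of gc_range; floored away from 0.
gc_bias_curve <- function(gc, config) {
  centre <- mean(config$gc_range)
  half <- diff(config$gc_range) / 2
  pmax(0.05, 1 - config$gc_bias_strength * ((gc - centre) / half)^2)
}

# Theoretical coefficient of variation of the negative-binomial bin
# counts; CNA shifts are expressed in these units.
count_cv <- function(config) {
  sqrt(1 / config$coverage_mean + 1 / config$nb_size)
}

#' Simulate the bin registry with GC annotations
#'
#' Tiles the configured chromosomes and draws per-bin GC fractions
#' uniformly on `gc_range` (no FASTA is consulted: GC here is an
#' annotation the corrector must handle, not real sequence content).
#'
#' @param config A [sim_config()].
#' @return A `bin_registry` with populated `gc_fraction`.
#' @export
simulate_genome <- function(config) {
  reg <- build_bin_registry(config$chrom_lengths, config$bin_size)
  reg$gc_fraction <- with_seed(config$seed + 11L, {
    stats::runif(nrow(reg), config$gc_range[1], config$gc_range[2])
  })
  reg
}

# One bin-level sample. md_shift and count_mult are per-bin perturbation
# vectors (0 / 1 for unperturbed bins).
simulate_bin_sample <- function(config, registry, md_shift = 0,
                                count_mult = 1) {
  n <- nrow(registry)
  bias <- gc_bias_curve(registry$gc_fraction, config)
  total_c <- stats::rnbinom(n, mu = config$cpg_obs_mean * bias,
                            size = config$nb_size)
  p <- stats::rnorm(n, config$md_baseline_mean + md_shift,
                    config$md_baseline_sd)
  p <- pmin(1, pmax(0, p))
  meth_c <- stats::rbinom(n, total_c, p)
  raw_count <- stats::rnbinom(n, mu = config$coverage_mean * bias *
                                count_mult, size = config$nb_size)
  out <- registry[, c("chrom", "start", "end")]
  out$meth_c <- meth_c
  out$total_c <- total_c
  out$raw_count <- raw_count
  out
}

#' Simulate the healthy reference cohort
#'
#' Per bin and subject: CpG observations and read counts are negative
#' binomial with a shared smooth GC bias; the methylation probability is
#' Normal(`md_baseline_mean`, `md_baseline_sd`) truncated to `[0,1]`, and
#' methylated counts are binomial given the observations.
#'
#' @param config A [sim_config()].
#' @param registry Registry from [simulate_genome()] (built from config
#'   when omitted).
#' @param n Number of subjects (default `config$n_healthy`).
#' @return List of per-subject count data.frames (attribute `sample_id`).
#' @export
simulate_healthy <- function(config, registry = NULL, n = config$n_healthy) {
  if (is.null(registry)) registry <- simulate_genome(config)
  lapply(seq_len(n), function(i) {
    s <- with_seed(config$seed + 1000L + i,
                   simulate_bin_sample(config, registry))
    attr(s, "sample_id") <- sprintf("H%03d", i)
    s
  })
}

# Draw contiguous segments (geometric lengths) totalling exactly
# n_target bins, avoiding `exclude`.
draw_segments <- function(n_bins, n_target, mean_len, exclude = integer(0)) {
  if (n_target <= 0) return(integer(0))
  sel <- integer(0)
  avail <- setdiff(seq_len(n_bins), exclude)
  if (n_target > length(avail)) stopf("not enough bins for the perturbation")
  while (length(sel) < n_target && length(avail) > 0) {
    s <- avail[sample.int(length(avail), 1)]
    len <- 1 + stats::rgeom(1, 1 / mean_len)
    seg <- s:min(n_bins, s + len - 1)
    seg <- seg[seg %in% avail]
    sel <- c(sel, seg)
    avail <- setdiff(avail, seg)
  }
  sort(sel[seq_len(min(n_target, length(sel)))])
}

#' Simulate one patient sample
#'
#' On-target patients receive a true hypomethylated-bin fraction (drawn
#' from the configured truncated normal unless given), realised as
#' contiguous segments whose methylation mean drops by
#' `hypo_effect_sds * md_baseline_sd`, and an equal-count CNA perturbation
#' in which a `cna_overlap` share of the CNA bins is taken from the
#' hypomethylated segments (coupling the two signals) and expected counts
#' shift by `cna_effect_sds` count-SDs, direction alternating per
#' segment. Off-target patients draw from the healthy model. Carriers of
#' a gene amplification (EGFR/MET/HER2 in the profile) additionally get a
#' focal count multiplier on that gene's bins; for on-target EGFR
#' carriers the multiplier scales with the patient's perturbation burden
#' (amplification and genome instability co-accumulate), for off-target
#' carriers it is an independent draw.
#'
#' The returned profile carries a `truth` attribute recording the
#' perturbed bin sets, the true fractions and the amplification
#' multiplier.
#'
#' @param config A [sim_config()].
#' @param registry Registry from [simulate_genome()].
#' @param group `"on_target"` or `"off_target"`.
#' @param index Patient index (decorrelates patients under one seed).
#' @param profile Resistance profile string (e.g. `"T790M,EGFR_amp"`);
#'   used for the focal amplification and carried into the truth record.
#' @param hypo_fraction,cna_fraction Optional fixed true fractions
#'   (otherwise drawn; `cna_fraction` defaults to the hypo fraction,
#'   coupling the burdens).
#' @param amp_mult Optional fixed focal amplification multiplier.
#' @return Count data.frame as in [simulate_healthy()], with attributes
#'   `sample_id` and `truth`.
#' @export
simulate_patient <- function(config, registry = NULL,
                             group = c("on_target", "off_target"),
                             index = 1, profile = NULL,
                             hypo_fraction = NULL, cna_fraction = NULL,
                             amp_mult = NULL) {
  group <- match.arg(group)
  if (is.null(registry)) registry <- simulate_genome(config)
  n <- nrow(registry)
  if (is.null(profile)) {
    profile <- if (group == "on_target") "T790M" else "MET_amp"
  }
  with_seed(config$seed + 2000L + 7L * index, {
    md_shift <- numeric(n)
    count_mult <- rep(1, n)
    hypo_bins <- integer(0)
    cna_bins <- integer(0)
    cna_sign <- integer(0)
    f_hypo <- 0
    f_cna <- 0
    if (group == "on_target") {
      if (is.null(hypo_fraction)) {
        f_hypo <- stats::rnorm(1, config$hypo_fraction_mean,
                               config$hypo_fraction_sd)
        f_hypo <- min(config$hypo_fraction_range[2],
                      max(config$hypo_fraction_range[1], f_hypo))
      } else {
        f_hypo <- hypo_fraction
      }
      f_cna <- if (is.null(cna_fraction)) f_hypo else cna_fraction
      n_hypo <- round(f_hypo * n)
      n_cna <- round(f_cna * n)
      hypo_bins <- draw_segments(n, n_hypo, config$segment_mean_len)
      md_shift[hypo_bins] <- -config$hypo_effect_sds * config$md_baseline_sd
      n_shared <- round(config$cna_overlap * n_cna)
      n_shared <- min(n_shared, length(hypo_bins))
      shared <- if (n_shared > 0) hypo_bins[seq_len(n_shared)] else integer(0)
      extra <- draw_segments(n, n_cna - length(shared),
                             config$segment_mean_len, exclude = hypo_bins)
      cna_bins <- sort(c(shared, extra))
      if (length(cna_bins)) {
        # direction per contiguous run of perturbed bins
        run_id <- cumsum(c(1, diff(cna_bins) != 1))
        signs <- sample(c(-1, 1), max(run_id), replace = TRUE)
        cna_sign <- signs[run_id]
        shift <- config$cna_effect_sds * count_cv(config)
        count_mult[cna_bins] <- pmax(0.05, 1 + cna_sign * shift)
      }
    }
    amp_gene <- intersect(c("EGFR_amp", "MET_amp", "HER2_amp"),
                          split_muts(profile))
    amp_bins <- integer(0)
    amp_used <- NA_real_
    if (length(amp_gene)) {
      gene <- sub("_amp", "", amp_gene[1])
      region <- gene_regions()[[gene]]
      amp_bins <- bins_overlapping_region(registry, region$chrom,
                                          region$start, region$end)
      if (length(amp_bins)) {
        amp_used <- if (!is.null(amp_mult)) {
          amp_mult
        } else if (group == "on_target" && grepl("EGFR_amp", profile)) {
          # EGFR amplification co-accumulates with the genome-wide
          # perturbation burden: the multiplier scales with the
          # patient's true hypo fraction
          frac <- (f_hypo - config$hypo_fraction_range[1]) /
            diff(config$hypo_fraction_range)
          frac <- min(1, max(0, frac))
          config$amp_score_range[1] + diff(config$amp_score_range) * frac
        } else {
          stats::runif(1, config$amp_score_range[1],
                       config$amp_score_range[2])
        }
        count_mult[amp_bins] <- count_mult[amp_bins] * amp_used
      }
    }
    s <- simulate_bin_sample(config, registry, md_shift, count_mult)
    attr(s, "sample_id") <- sprintf("%s%02d",
                                    if (group == "on_target") "ON" else "OFF",
                                    index)
    attr(s, "truth") <- list(group = group, profile = profile,
                             hypo_bins = hypo_bins, cna_bins = cna_bins,
                             cna_sign = cna_sign,
                             hypo_fraction_true = length(hypo_bins) / n,
                             cna_fraction_true = length(cna_bins) / n,
                             amp_gene = if (length(amp_gene)) amp_gene[1]
                                        else NA_character_,
                             amp_bins = amp_bins, amp_mult = amp_used)
    s
  })
}

#' Canonical gene regions for focal amplification scoring
#'
#' Approximate hg38 loci of the three amplification-prone genes tracked
#' by the pipeline, widened to 1 Mb bin resolution.
#'
#' @return Named list of `list(chrom, start, end)`.
#' @export
gene_regions <- function() {
  list(EGFR = list(chrom = "chr7", start = 55.0e6, end = 55.3e6),
       MET = list(chrom = "chr7", start = 116.6e6, end = 116.8e6),
       HER2 = list(chrom = "chr17", start = 39.6e6, end = 39.8e6))
}

#' Simulate the panel design
#'
#' Draws the 450-region panel: region coordinates, per-region CpG site
#' counts (summing to 9593 under the defaults), the base methylation
#' probability of each region, and the region classes: `n_hyper` regions
#' shifted up and `n_hypo_regions` shifted down in on-target samples,
#' the rest null. Shifted probabilities are clamped to `[0.02, 0.98]`
#' (clamping recorded in the design).
#'
#' @param config A [sim_config()].
#' @return Data.frame: `region_id`, `gene`, `chrom`, `start`, `end`,
#'   `n_cpg`, `class` (hyper/hypo/null), `base_p`, `on_target_p`,
#'   `clamped`.
#' @export
simulate_panel_design <- function(config) {
  n <- config$n_regions
  with_seed(config$seed + 3000L, {
    cls <- rep("null", n)
    cls[seq_len(config$n_hyper)] <- "hyper"
    cls[config$n_hyper + seq_len(config$n_hypo_regions)] <- "hypo"
    cls <- sample(cls)
    base_p <- numeric(n)
    base_p[cls == "hyper"] <- stats::runif(sum(cls == "hyper"), 0.10, 0.35)
    base_p[cls == "hypo"] <- stats::runif(sum(cls == "hypo"), 0.55, 0.85)
    base_p[cls == "null"] <- stats::runif(sum(cls == "null"), 0.10, 0.85)
    on_p <- base_p
    on_p[cls == "hyper"] <- base_p[cls == "hyper"] + config$hyper_effect
    on_p[cls == "hypo"] <- base_p[cls == "hypo"] - config$hypo_effect
    clamped <- on_p < 0.02 | on_p > 0.98
    on_p <- pmin(0.98, pmax(0.02, on_p))
    # CpG sites per region; defaults give the panel's 9593 total
    n_cpg <- rep(9593L %/% n, n)
    extra <- 9593L %% n
    if (n != 450) n_cpg <- rep(21L, n) else
      n_cpg[seq_len(extra)] <- n_cpg[seq_len(extra)] + 1L
    starts <- seq(1e6, by = 2e5, length.out = n)
    data.frame(region_id = sprintf("R%03d", seq_len(n)),
               gene = sprintf("GENE%03d", seq_len(n)),
               chrom = "chr1", start = as.integer(starts),
               end = as.integer(starts + 1000), n_cpg = n_cpg,
               class = cls, base_p = base_p, on_target_p = on_p,
               clamped = clamped, stringsAsFactors = FALSE)
  })
}

#' Simulate per-region panel counts for one sample
#'
#' Per region, the number of CpG observations is Poisson around
#' `panel_cpg_obs` and the methylated count is binomial with the region's
#' group probability (`on_target_p` for on-target samples, `base_p`
#' otherwise -- off-target and healthy samples share the base profile).
#' A region with zero observations yields missing %methylation
#' downstream, never 0%.
#'
#' @param config A [sim_config()].
#' @param design Panel design from [simulate_panel_design()].
#' @param group `"on_target"`, `"off_target"` or `"healthy"`.
#' @param index Sample index.
#' @param sample_id Sample label.
#' @return Long data.frame: `sample_id`, `region_id`, `meth_c`,
#'   `unmeth_c`.
#' @export
simulate_panel <- function(config, design, group = "healthy", index = 1,
                           sample_id = sprintf("S%03d", index)) {
  if (nrow(design) < 1) stopf("panel needs >= 1 region")
  p <- if (group == "on_target") design$on_target_p else design$base_p
  with_seed(config$seed + 4000L + 13L * index, {
    n_obs <- stats::rpois(nrow(design), config$panel_cpg_obs)
    meth <- stats::rbinom(nrow(design), n_obs, p)
    data.frame(sample_id = sample_id, region_id = design$region_id,
               meth_c = meth, unmeth_c = n_obs - meth,
               stringsAsFactors = FALSE)
  })
}

#' Simulate UMI read families with known truth
#'
#' Each family derives from one truth fragment; a configurable fraction
#' of fragments carries the alternate allele at `alt_pos`. Reads copy the
#' truth with independent per-base errors at `error_rate` (a wrong base
#' is substituted uniformly). Error rates of 0.5 or more violate the
#' majority-consensus premise and are rejected.
#'
#' @param n_families Number of families.
#' @param family_size Reads per family (recycled over families).
#' @param read_length Bases per read.
#' @param error_rate Per-base substitution probability in `[0, 0.5)`.
#' @param vaf_true True fraction of fragments carrying the alternate
#'   allele (default 0).
#' @param alt_pos 1-based position of the variant locus.
#' @param ref_base,alt_base Alleles at the locus.
#' @param seed Integer seed.
#' @return List of families `list(umi, reads, truth)`; attribute
#'   `truth_alt` flags alternate-carrying families.
#' @export
simulate_umi_families <- function(n_families = 1000, family_size = 3,
                                  read_length = 20, error_rate = 0.01,
                                  vaf_true = 0, alt_pos = 10,
                                  ref_base = "A", alt_base = "T",
                                  seed = 1) {
  if (error_rate < 0 || error_rate >= 0.5) {
    stopf("error_rate must lie in [0, 0.5): the majority rule needs errors in a minority of reads")
  }
  bases <- c("A", "C", "G", "T")
  sizes <- rep_len(family_size, n_families)
  with_seed(seed, {
    is_alt <- stats::runif(n_families) < vaf_true
    fams <- vector("list", n_families)
    for (i in seq_len(n_families)) {
      truth <- sample(bases, read_length, replace = TRUE)
      truth[alt_pos] <- if (is_alt[i]) alt_base else ref_base
      k <- sizes[i]
      reads <- character(k)
      for (r in seq_len(k)) {
        rd <- truth
        err <- stats::runif(read_length) < error_rate
        if (any(err)) {
          rd[err] <- vapply(rd[err], function(b) {
            sample(setdiff(bases, b), 1)
          }, character(1))
        }
        reads[r] <- paste(rd, collapse = "")
      }
      # UMI encodes the family index in base 4 -> unique 9-mers
      digits <- integer(9)
      v <- i - 1
      for (d in 9:1) {
        digits[d] <- v %% 4
        v <- v %/% 4
      }
      fams[[i]] <- list(umi = paste(bases[digits + 1], collapse = ""),
                        reads = reads,
                        truth = paste(truth, collapse = ""))
    }
    attr(fams, "truth_alt") <- is_alt
    fams
  })
}

#' Simulate clinical covariates for a patient table
#'
#' Adds time to treatment resistance (TTTR), sensitizing and T790M VAFs,
#' and amplification scores. Within the EGFR-amplification carriers the
#' TTTR is drawn so its correlation with `cna_fraction` targets
#' `config$rho_tttr` (the sampling distribution of the realised r at
#' small n is wide); other patients draw TTTR independently. VAF
#' structure follows the cohort's pattern: EGFR-amplification carriers
#' have high sensitizing VAFs proportional to the amplification score,
#' T790M carriers intermediate ones with a lower T790M VAF, and MET/HER2
#' carriers low or absent sensitizing VAFs.
#'
#' @param config A [sim_config()].
#' @param patients Data.frame with columns `patient_id`, `profile`,
#'   `group`, `cna_fraction` (>= 3 EGFR-amplification rows are needed for
#'   the correlated draw; with fewer, TTTR is independent everywhere).
#'   When an `amp_score` column is present (measured focal amplification
#'   scores), it is used for the VAF structure instead of a fresh draw.
#' @return `patients` with `tttr_days`, `amp_score_true`, `vaf_sensitizing`
#'   and `vaf_t790m` columns added.
#' @export
simulate_clinical <- function(config, patients) {
  if (abs(config$rho_tttr) >= 1) stopf("rho_tttr must lie in (-1, 1)")
  n <- nrow(patients)
  muts <- lapply(patients$profile, split_muts)
  has_egfr_amp <- vapply(muts, function(m) "EGFR_amp" %in% m, logical(1))
  has_t790m <- vapply(muts, function(m) "T790M" %in% m, logical(1))
  has_any_amp <- vapply(muts, function(m) any(grepl("_amp", m)), logical(1))
  with_seed(config$seed + 5000L, {
    amp_score <- if ("amp_score" %in% names(patients) &&
                     any(!is.na(patients$amp_score))) {
      # use the measured focal amplification scores when supplied
      ifelse(is.na(patients$amp_score), 1, patients$amp_score)
    } else {
      ifelse(has_any_amp,
             stats::runif(n, config$amp_score_range[1],
                          config$amp_score_range[2]),
             1)
    }
    tttr <- stats::rnorm(n, config$tttr_mean_days, config$tttr_sd_days)
    idx <- which(has_egfr_amp)
    if (length(idx) >= 3) {
      x <- patients$cna_fraction[idx]
      if (stats::sd(x) > 0) {
        zx <- (x - mean(x)) / stats::sd(x)
        rho <- config$rho_tttr
        y <- rho * zx + sqrt(1 - rho^2) * stats::rnorm(length(idx))
        tttr[idx] <- config$tttr_mean_days + config$tttr_sd_days * y
      }
    }
    tttr <- pmax(30, tttr)
    vaf_sens <- numeric(n)
    for (i in seq_len(n)) {
      vaf_sens[i] <-
        if (has_egfr_amp[i]) 10 + 15 * amp_score[i] + stats::rnorm(1, 0, 2)
        else if (has_t790m[i]) stats::runif(1, 2, 15)
        else if (has_any_amp[i]) stats::runif(1, 0, 2)   # MET/HER2: low/lost
        else stats::runif(1, 1, 10)
    }
    vaf_sens <- pmax(0, vaf_sens)
    vaf_t790m <- ifelse(has_t790m,
                        vaf_sens * stats::runif(n, 0.2, 0.8),
                        NA_real_)
    patients$tttr_days <- tttr
    patients$amp_score_true <- amp_score
    patients$vaf_sensitizing <- vaf_sens
    patients$vaf_t790m <- vaf_t790m
    patients
  })
}
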