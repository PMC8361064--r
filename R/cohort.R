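# Patient records and cohort summary tables: mutation profiles, the
# on-target / off-target resistance grouping, and Table-1-style
# count/percentage summaries.

ON_TARGET_MUTS <- c("T790M", "EGFR_amp")
OFF_TARGET_MUTS <- c("MET_amp", "HER2_amp")

split_muts <- function(profile) {
  if (is.na(profile) || !nzchar(profile) || identical(profile, "none")) {
    return(character(0))
  }
  trimws(strsplit(profile, ",", fixed = TRUE)[[1]])
}

#' Assign the on-target / off-target resistance group
#'
#' A case is `on_target` when its resistance-mutation set intersects
#' {T790M, EGFR_amp} (EGFR-dependent resistance); `off_target` when the
#' set is non-empty and contained in {MET_amp, HER2_amp} (bypass
#' amplification); otherwise `unknown` (no detected resistance mutation,
#' or a profile outside both rules), and excluded from group contrasts.
#'
#' @param resistance Character vector of comma-separated resistance
#'   mutation profiles, e.g. `"T790M,EGFR_amp"`; `""` or `"none"` for no
#'   detected resistance mutation.
#' @return Character vector: `"on_target"`, `"off_target"` or
#'   `"unknown"`.
#' @examples
#' assign_resistance_group(c("T790M", "MET_amp", "none"))
#' @export
assign_resistance_group <- function(resistance) {
  vapply(resistance, function(pr) {
    muts <- split_muts(pr)
    if (length(muts) == 0) return("unknown")
    if (any(muts %in% ON_TARGET_MUTS)) return("on_target")
    if (all(muts %in% OFF_TARGET_MUTS)) return("off_target")
    "unknown"
  }, character(1), USE.NAMES = FALSE)
}

count_pct_table <- function(x, category) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "Unknown"
  tab <- table(x)
  data.frame(category = category, level = names(tab),
             n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / length(x), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort summary table
#'
#' Counts and percentages (1 decimal, half-up rounding) per clinical
#' category (sex, histology, stage, TKI regimen, resistance profile), plus
#' the derived cohort statistics: fraction of cases with any resistance
#' mutation, retention of the sensitizing mutation among
#' resistance-positive cases, T790M frequency, and co-occurrence of other
#' resistance mutations among T790M-positive cases. Unknowns are tabulated
#' as `Unknown`; an absent category level is reported as n = 0, 0.0%.
#'
#' @param records Data.frame of patient records with (any of) columns
#'   `sex`, `histology`, `stage`, `tki_regimen`, `resistance` (comma
#'   separated profile), `sensitizing` (`del19`, `L858R`, `rare`,
#'   `none`), `age`.
#' @return List of class `cohort_summary`: `n_total`, `by_category`
#'   (named list of count/pct data.frames), `age` (median/min/max when
#'   present) and `key` (named numeric vector of derived percentages).
#' @export
cohort_summary <- function(records) {
  if (nrow(records) < 1) stopf("at least one patient record is required")
  n <- nrow(records)
  by_cat <- list()
  for (cat in c("sex", "histology", "stage", "tki_regimen")) {
    if (cat %in% names(records)) {
      by_cat[[cat]] <- count_pct_table(records[[cat]], cat)
    }
  }
  key <- c()
  if ("resistance" %in% names(records)) {
    prof <- records$resistance
    prof[is.na(prof) | !nzchar(prof)] <- "none"
    by_cat[["resistance_profile"]] <- count_pct_table(prof,
                                                      "resistance_profile")
    muts <- lapply(prof, split_muts)
    has_res <- vapply(muts, length, integer(1)) > 0
    key["n_resistance_positive"] <- sum(has_res)
    key["pct_resistance_positive"] <-
      round_half_up(100 * sum(has_res) / n, 1)
    t790m <- vapply(muts, function(m) "T790M" %in% m, logical(1))
    key["n_t790m"] <- sum(t790m)
    key["pct_t790m"] <- round_half_up(100 * sum(t790m) / n, 1)
    if (any(t790m)) {
      co <- t790m & vapply(muts, length, integer(1)) > 1
      key["pct_t790m_with_cooccurrence"] <-
        round_half_up(100 * sum(co) / sum(t790m), 1)
    }
    if ("sensitizing" %in% names(records) && any(has_res)) {
      sens <- records$sensitizing[has_res]
      retained <- !is.na(sens) & sens %in% c("del19", "L858R", "rare")
      key["n_sensitizing_retained"] <- sum(retained)
      key["pct_sensitizing_retained"] <-
        round_half_up(100 * sum(retained) / sum(has_res), 1)
    }
  }
  age <- NULL
  if ("age" %in% names(records)) {
    a <- records$age[!is.na(records$age)]
    if (length(a)) {
      age <- c(median = stats::median(a), min = min(a), max = max(a),
               n_unknown = sum(is.na(records$age)))
    }
  }
  structure(list(n_total = n, by_category = by_cat, age = age, key = key),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_total))
  for (nm in names(x$by_category)) {
    cat("\n--", nm, "--\n")
    print(x$by_category[[nm]][, c("level", "n", "pct")], row.names = FALSE)
  }
  if (length(x$key)) {
    cat("\n-- derived --\n")
    for (nm in names(x$key)) cat(sprintf("%s: %s\n", nm, x$key[[nm]]))
  }
  invisible(x)
}

#' Reconstructed 122-patient NSCLC cohort (synthetic joint assignment)
#'
#' Builds a patient-record table whose marginal distributions match the
#' published clinical summary of the 122-patient TKI-resistance cohort:
#' sex (71/48/3 F/M/unknown), histology (85 AC / 4 SCC / 33 unknown),
#' stage (100 III-IV / 22 unknown), TKI regimen, and mutation profiles
#' (23 T790M only, 7 T790M with rare EGFR co-mutations, 4 T790M+PIK3CA,
#' 5 T790M+EGFR_amp, 3 EGFR_amp, 4 MET_amp, 5 HER2_amp, 71 none; 46 of
#' the 51 resistance-positive cases retain del19/L858R). Only the
#' marginals are published: the joint assignment of attributes to
#' individual rows is an arbitrary block layout, so cross-tabulations
#' other than the published ones are not meaningful.
#'
#' @return Data.frame of 122 patient records.
#' @export
example_cohort <- function() {
  n <- 122
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = c(rep("Female", 71), rep("Male", 48), rep(NA, 3)),
    histology = c(rep("AC", 85), rep("SCC", 4), rep(NA, 33)),
    stage = c(rep("III-IV", 100), rep(NA, 22)),
    smoking = c(rep("Yes", 15), rep("No", 33), rep(NA, 74)),
    tki_regimen = c(rep("Erlotinib", 82), rep("Gefitinib", 14),
                    rep("Erlotinib+Gefitinib", 2), rep("Afatinib", 3),
                    rep("Erlotinib+Afatinib", 3), rep("Unknown TKI", 18)),
    stringsAsFactors = FALSE)
  # published age summary: median 61, range 29-77, 2 unknown
  rec$age <- c(29, 77, rep(61, n - 4), NA, NA)
  # mutation profile blocks (published cohort counts)
  rec$resistance <- c(rep("T790M", 23),            # T790M only
                      rep("T790M", 7),             # + rare EGFR co-mutations
                      rep("T790M,PIK3CA", 4),
                      rep("T790M,EGFR_amp", 5),
                      rep("EGFR_amp", 3),
                      rep("MET_amp", 4),
                      rep("HER2_amp", 5),
                      rep("none", 71))
  rec$rare_egfr_comut <- c(rep(FALSE, 23), rep(TRUE, 7), rep(FALSE, 92))
  # sensitizing mutation: 46/51 resistance-positive retain del19 or L858R;
  # the 5 losses sit in the MET/HER2 amplification cases
  rec$sensitizing <- c(rep("del19", 15), rep("L858R", 8),   # T790M only
                       rep("del19", 4), rep("L858R", 3),    # T790M + rare
                       rep("del19", 2), rep("L858R", 2),    # T790M + PIK3CA
                       rep("del19", 3), rep("L858R", 2),    # T790M + EGFR_amp
                       rep("del19", 2), rep("L858R", 1),    # EGFR_amp
                       rep("del19", 2), rep("none", 2),     # MET_amp
                       rep("L858R", 2), rep("none", 3),     # HER2_amp
                       rep("del19", 40), rep("L858R", 31))  # no resistance
  rec$group <- assign_resistance_group(rec$resistance)
  rec
}
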