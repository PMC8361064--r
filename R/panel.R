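# Targeted panel differential methylation: per-region %methylation,
# Wilcoxon rank-sum between groups, Benjamini-Hochberg correction, and
# hyper/hypo DMR calls at |log2FC| > 1 and FDR < 0.05.

#' Per-region methylation percentage
#'
#' %Methylation = 100 * methylated C / (methylated C + unmethylated C),
#' computed from the CpG cytosines recovered on reads mapped to the
#' region. Regions with zero observations are missing, not 0%.
#'
#' @param meth_c Methylated cytosine counts (vectorized).
#' @param unmeth_c Unmethylated cytosine counts.
#' @return Percentages in `[0,100]`, `NA` where both counts are zero.
#' @export
region_methylation <- function(meth_c, unmeth_c) {
  if (length(meth_c) != length(unmeth_c)) {
    stopf("meth_c and unmeth_c must have equal length")
  }
  if (any(meth_c < 0 | unmeth_c < 0, na.rm = TRUE)) {
    stopf("counts must be non-negative")
  }
  tot <- meth_c + unmeth_c
  ifelse(tot > 0, 100 * meth_c / tot, NA_real_)
}

#' Wilcoxon rank-sum two-sided p-value
#'
#' Exact p by enumeration of the rank-sum distribution when the combined
#' sample size is at most `exact_max_n` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#' When every pooled value is identical the test is degenerate and p = 1.
#'
#' @param x,y Numeric vectors (missing values dropped); each group needs
#'   >= 2 non-missing values.
#' @param exact_max_n Largest combined n for the exact route (default 20).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stopf("each group needs >= 2 non-missing values")
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(pooled) <= exact_max_n
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
  min(1, p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity; q-values are capped
#' at 1 and are monotone in sorted p order.
#'
#' @param p P-values in `[0,1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) stopf("p-values must not be missing")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated regions between two groups
#'
#' For each panel region, compares %methylation between the two groups of
#' samples: log2 fold change of group mean percentages (with a pseudocount
#' on both means, so zeros are defined), Wilcoxon rank-sum p, BH q across
#' tested regions, and a call of `hyper` (log2FC > `log2fc_cut` and
#' q < `fdr_cut`), `hypo` (log2FC < -`log2fc_cut` and q < `fdr_cut`) or
#' `none`. Inequalities are strict. The fold change is oriented as group A
#' (first factor level of `groups`) over group B.
#'
#' Regions with missing %methylation in more than `max_missing_frac` of
#' the samples of either group are excluded from testing and reported with
#' the reason; q-values are computed across tested regions only.
#'
#' @param pct Samples x regions matrix (or data.frame) of percentages;
#'   rownames are sample ids, colnames region ids.
#' @param groups Factor or character vector, one label per row of `pct`,
#'   with exactly two levels and >= 2 samples per level.
#' @param log2fc_cut Absolute log2 fold-change cutoff (default 1).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param pseudocount Percentage points added to both group means before
#'   the ratio (default 1).
#' @param max_missing_frac Maximum tolerated per-group missingness
#'   (default 0.5).
#' @return Data.frame, one row per region: `region_id`, `n_A`, `n_B`,
#'   `mean_pct_A`, `mean_pct_B`, `log2fc`, `p`, `q`, `call`, `tested`,
#'   `reason`. Attribute `groups` records the (A, B) level labels.
#' @export
call_dmrs <- function(pct, groups, log2fc_cut = 1, fdr_cut = 0.05,
                      pseudocount = 1, max_missing_frac = 0.5) {
  pct <- as.matrix(pct)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups are required")
  if (length(groups) != nrow(pct)) {
    stopf("one group label per sample row is required")
  }
  if (any(table(groups) < 2)) stopf("each group needs >= 2 samples")
  lev <- levels(groups)
  a_rows <- which(groups == lev[1])
  b_rows <- which(groups == lev[2])
  region_ids <- colnames(pct)
  if (is.null(region_ids)) region_ids <- paste0("region_", seq_len(ncol(pct)))

  res <- data.frame(region_id = region_ids,
                    n_A = NA_integer_, n_B = NA_integer_,
                    mean_pct_A = NA_real_, mean_pct_B = NA_real_,
                    log2fc = NA_real_, p = NA_real_, q = NA_real_,
                    call = "none", tested = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pct))) {
    a <- pct[a_rows, j]
    b <- pct[b_rows, j]
    res$n_A[j] <- sum(!is.na(a))
    res$n_B[j] <- sum(!is.na(b))
    miss_a <- mean(is.na(a))
    miss_b <- mean(is.na(b))
    if (res$n_A[j] == 0 || res$n_B[j] == 0) {
      res$reason[j] <- "group all-missing"
      next
    }
    res$mean_pct_A[j] <- mean(a, na.rm = TRUE)
    res$mean_pct_B[j] <- mean(b, na.rm = TRUE)
    res$log2fc[j] <- log2((res$mean_pct_A[j] + pseudocount) /
                            (res$mean_pct_B[j] + pseudocount))
    if (miss_a > max_missing_frac || miss_b > max_missing_frac) {
      res$reason[j] <- "insufficient coverage"
      next
    }
    if (res$n_A[j] < 2 || res$n_B[j] < 2) {
      res$reason[j] <- "fewer than 2 values in a group"
      next
    }
    res$p[j] <- wilcoxon_rank_sum(a, b)
    res$tested[j] <- TRUE
  }
  tested <- res$tested
  if (any(tested)) {
    res$q[tested] <- bh_adjust(res$p[tested])
    hyper <- tested & res$log2fc > log2fc_cut & res$q < fdr_cut
    hypo <- tested & res$log2fc < -log2fc_cut & res$q < fdr_cut
    res$call[hyper] <- "hyper"
    res$call[hypo] <- "hypo"
  }
  attr(res, "groups") <- lev
  res
}

#' Build the samples x regions %methylation matrix from long counts
#'
#' @param counts Long data.frame with columns `sample_id`, `region_id`,
#'   `meth_c`, `unmeth_c`.
#' @return Numeric matrix, samples in rows (rownames), regions in columns
#'   (colnames), entries %methylation (`NA` where unobserved).
#' @export
region_methylation_matrix <- function(counts) {
  need <- c("sample_id", "region_id", "meth_c", "unmeth_c")
  if (!all(need %in% names(counts))) {
    stopf("counts needs columns: %s", paste(need, collapse = ", "))
  }
  counts$pct <- region_methylation(counts$meth_c, counts$unmeth_c)
  samples <- unique(counts$sample_id)
  regions <- unique(counts$region_id)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(regions),
              dimnames = list(samples, regions))
  m[cbind(match(counts$sample_id, samples),
          match(counts$region_id, regions))] <- counts$pct
  m
}
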