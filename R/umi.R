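# UMI consensus: reads sharing a unique molecular identifier derive from
# one original cfDNA fragment; collapsing each family to a consensus
# sequence eliminates sequencing/PCR errors carried by less than 50% of
# the family's reads. VAF is then the percentage of consensus fragments
# carrying the variant allele.

#' Group tagged reads into UMI families
#'
#' One family per distinct UMI, in deterministic lexicographic UMI order.
#' Reads without a UMI are dropped and counted (attribute
#' `n_dropped_no_umi`).
#'
#' @param reads Data.frame with columns `umi` and `read` (aligned,
#'   equal-length base strings over one locus).
#' @return List of families, each `list(umi =, reads = character())`.
#' @export
group_by_umi <- function(reads) {
  if (!all(c("umi", "read") %in% names(reads))) {
    stopf("reads needs 'umi' and 'read' columns")
  }
  keep <- !is.na(reads$umi) & nzchar(reads$umi)
  dropped <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  umis <- sort(unique(reads$umi), method = "radix")
  fams <- lapply(umis, function(u) {
    list(umi = u, reads = reads$read[reads$umi == u])
  })
  attr(fams, "n_dropped_no_umi") <- dropped
  fams
}

#' Collapse a UMI family to its consensus fragment
#'
#' Per position, the consensus base is the base carried by strictly more
#' than 50% of the family's reads; when no base has a strict majority
#' (including an exact 50/50 tie) the position is `N`. Families smaller
#' than `min_family_size` are discarded (`NULL`).
#'
#' @param family A family from [group_by_umi()] (`list(umi, reads)`) or a
#'   character vector of reads.
#' @param min_family_size Smallest family kept (default 1: every fragment
#'   contributes).
#' @return `list(umi, consensus, family_size)`, or `NULL` when discarded.
#' @examples
#' umi_consensus(c("ACGT", "ACGT", "ACTT"))$consensus  # "ACGT"
#' umi_consensus(c("ACGT", "ACTT"))$consensus          # "ACNT"
#' @export
umi_consensus <- function(family, min_family_size = 1) {
  if (is.character(family)) family <- list(umi = NA_character_, reads = family)
  reads <- family$reads
  if (length(reads) == 0) stopf("family has no reads")
  lens <- unique(nchar(reads))
  if (length(lens) != 1) {
    stopf("reads in a family must have equal length (got lengths %s)",
          paste(lens, collapse = ", "))
  }
  if (length(reads) < min_family_size) return(NULL)
  bases <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                  nrow = length(reads), byrow = TRUE)
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stopf("reads may only contain A, C, G, T, N")
  }
  half <- length(reads) / 2
  cons <- apply(bases, 2, function(col) {
    tab <- table(col)
    top <- which.max(tab)
    if (tab[top] > half) names(tab)[top] else "N"
  })
  list(umi = family$umi, consensus = paste(cons, collapse = ""),
       family_size = length(reads))
}

#' Collapse all families of a locus
#'
#' @param families List of families from [group_by_umi()].
#' @param min_family_size Passed to [umi_consensus()].
#' @return List of consensus fragments (discarded families omitted).
#' @export
collapse_families <- function(families, min_family_size = 1) {
  out <- lapply(families, umi_consensus, min_family_size = min_family_size)
  out[!vapply(out, is.null, logical(1))]
}

#' Variant allele frequency from consensus fragments
#'
#' VAF (%) = 100 * (consensus fragments carrying the alternate base at the
#' locus) / (consensus fragments with a determined base there). Fragments
#' with `N` at the locus are excluded from both numerator and denominator.
#'
#' @param fragments List of consensus fragments (from
#'   [collapse_families()]) or character vector of consensus strings.
#' @param pos 1-based position of the locus within the fragment.
#' @param ref,alt Reference and alternate bases.
#' @param locus Optional locus label.
#' @return One-row data.frame: `locus`, `alt_fragments`,
#'   `total_fragments`, `vaf` (percent).
#' @export
consensus_vaf <- function(fragments, pos, ref, alt, locus = NA_character_) {
  seqs <- if (is.character(fragments)) fragments else {
    vapply(fragments, function(f) f$consensus, character(1))
  }
  if (any(pos > nchar(seqs))) stopf("pos exceeds fragment length")
  base <- substr(seqs, pos, pos)
  informative <- base != "N"
  total <- sum(informative)
  if (total == 0) stopf("no informative fragment at the locus")
  alt_n <- sum(base[informative] == alt)
  data.frame(locus = locus, alt_fragments = alt_n, total_fragments = total,
             vaf = 100 * alt_n / total, stringsAsFactors = FALSE)
}
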