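# Autosomal 1 Mb bin registry: the coordinate system every genome-wide
# statistic is computed on. Coordinates are 0-based half-open (BED
# convention).

AUTOSOMES <- paste0("chr", 1:22)

#' hg38 autosome lengths
#'
#' Chromosome lengths (bp) of the GRCh38 primary assembly autosomes, the
#' default genome for the bin registry. Sex chromosomes are excluded by
#' design: all genome-wide calls are restricted to chr1-chr22.
#'
#' @return Named integer-valued numeric vector, chr1..chr22.
#' @export
hg38_autosome_lengths <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559,
    chr4 = 190214555, chr5 = 181538259, chr6 = 170805979,
    chr7 = 159345973, chr8 = 145138636, chr9 = 138394717,
    chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189,
    chr16 = 90338345, chr17 = 83257441, chr18 = 80373285,
    chr19 = 58617616, chr20 = 64444167, chr21 = 46709983,
    chr22 = 50818468)
}

#' Build the autosomal bin registry
#'
#' Tiles each autosome with fixed-size bins from position 0 to the
#' chromosome length. All bins are `bin_size` long except possibly the last
#' bin of each chromosome. Order is deterministic: chr1..chr22, then start.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp. Names must
#'   be a subset of chr1..chr22; any other label is rejected (sex
#'   chromosomes are refused, not silently dropped).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param gc_fraction Optional per-bin GC fraction in `[0,1]`, recycled or
#'   one value per bin; `NA` if not supplied (no FASTA parsing is done --
#'   GC is an annotation, supplied or simulated).
#' @return A `bin_registry` data.frame with columns `chrom`, `start`,
#'   `end`, `gc_fraction`.
#' @examples
#' build_bin_registry(c(chr1 = 2.5e6), bin_size = 1e6)
#' @export
build_bin_registry <- function(chrom_lengths, bin_size = 1e6,
                               gc_fraction = NULL) {
  if (bin_size <= 0) stopf("bin_size must be positive")
  labs <- names(chrom_lengths)
  if (is.null(labs) || any(!nzchar(labs))) {
    stopf("chrom_lengths must be a named vector (chr1..chr22)")
  }
  bad <- setdiff(labs, AUTOSOMES)
  if (length(bad)) {
    stopf("non-autosomal chromosome label(s): %s (only chr1-chr22 allowed)",
          paste(bad, collapse = ", "))
  }
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  ord <- order(match(labs, AUTOSOMES))
  pieces <- lapply(ord, function(i) {
    len <- chrom_lengths[[i]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = labs[i], start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, len)),
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, pieces)
  rownames(reg) <- NULL
  n <- nrow(reg)
  reg$gc_fraction <- if (is.null(gc_fraction)) NA_real_ else {
    gc <- rep_len(as.numeric(gc_fraction), n)
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
      stopf("gc_fraction must lie in [0,1]")
    }
    gc
  }
  class(reg) <- c("bin_registry", "data.frame")
  reg
}

#' Write / read a bin registry as BED-like TSV
#'
#' Four tab-separated columns (chrom, start, end, gc_fraction) with a
#' header. The writer/reader pair round-trips a registry bit-identically.
#'
#' @param registry A `bin_registry` data.frame.
#' @param path File path.
#' @return `write_bin_registry` returns the path invisibly;
#'   `read_bin_registry` returns a `bin_registry`.
#' @export
write_bin_registry <- function(registry, path) {
  write_tsv(registry[, c("chrom", "start", "end", "gc_fraction")], path)
}

#' @rdname write_bin_registry
#' @export
read_bin_registry <- function(path) {
  reg <- read_tsv(path, colClasses = c("character", "integer", "integer",
                                       "numeric"))
  bad <- setdiff(unique(reg$chrom), AUTOSOMES)
  if (length(bad)) {
    stopf("non-autosomal chromosome label(s) in %s: %s", path,
          paste(bad, collapse = ", "))
  }
  class(reg) <- c("bin_registry", "data.frame")
  reg
}

#' Map a genomic region to registry bin indices
#'
#' @param registry A `bin_registry`.
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open region coordinates.
#' @return Integer vector of row indices of bins overlapping the region.
#' @export
bins_overlapping_region <- function(registry, chrom, start, end) {
  which(registry$chrom == chrom & registry$start < end &
          registry$end > start)
}

# Fail unless two tables share the bin registry, naming the first
# discordant bin.
check_same_registry <- function(a, b, what = "bin table") {
  if (nrow(a) != nrow(b)) {
    stopf("%s has %d bins but baseline/registry has %d", what,
          nrow(a), nrow(b))
  }
  mism <- which(a$chrom != b$chrom | a$start != b$start | a$end != b$end)
  if (length(mism)) {
    i <- mism[1]
    stopf("bin registry mismatch at bin %d: %s:%s-%s vs %s:%s-%s",
          i, a$chrom[i], format(a$start[i], scientific = FALSE),
          format(a$end[i], scientific = FALSE),
          b$chrom[i], format(b$start[i], scientific = FALSE),
          format(b$end[i], scientific = FALSE))
  }
  invisible(TRUE)
}
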