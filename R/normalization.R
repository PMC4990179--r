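#' Estimate the ChIP/control signal-to-noise scaling (NCIS approach)
#'
#' The control library measures background only, while the ChIP library is a
#' mixture of background and enrichment signal; dividing total library sizes
#' therefore over-scales the control. The NCIS idea is to estimate the
#' background scaling from low-signal genomic bins, where the ChIP signal is
#' essentially pure noise.
#'
#' Procedure (fixed-bin variant): the genome is partitioned into
#' non-overlapping bins of `bin_size` bp and reads are assigned to bins by
#' their 5' position. Bins are ranked by total count `t_i = chip_i +
#' control_i`. For increasing threshold `t` over the observed totals, the
#' cumulative ratio `r(t) = sum(chip_i; t_i <= t) / sum(control_i; t_i <= t)`
#' is computed. Adding genuinely signal-free bins leaves `r` flat or
#' decreasing once sorted by total, so the estimate `r_hat` is taken at the
#' smallest threshold where `r` first stops decreasing, provided the bins
#' below it make up at least `background_quantile` of the non-empty bins; if
#' `r` decreases throughout, the ratio over all bins is returned.
#'
#' @param chip,control Either paths to indexed BAM files (then `chrom_sizes`
#'   is required) or integer vectors of per-bin read counts over the same
#'   genome partition.
#' @param bin_size Genome bin width in bp (default 1000, minimum 100).
#' @param background_quantile Minimum fraction of non-empty bins that must
#'   lie at or below the chosen threshold (default 0.75).
#' @param chrom_sizes Named chromosome lengths; needed only for BAM input.
#' @return A `NoiseRatio`: list with `r_hat` (> 0, multiply control coverage
#'   by it before subtracting), `bin_size`, `background_fraction` (fraction
#'   of non-empty bins actually used) and `threshold`.
#' @export
ncis_ratio <- function(chip, control, bin_size = 1000,
                       background_quantile = 0.75, chrom_sizes = NULL) {
  stopifnot(bin_size >= 100, background_quantile > 0,
            background_quantile <= 1)
  if (is.character(chip)) {
    stopifnot(!is.null(chrom_sizes))
    chip <- bin_genome_counts(chip, chrom_sizes, bin_size)
    control <- bin_genome_counts(control, chrom_sizes, bin_size)
  }
  if (length(chip) != length(control)) {
    stop("chip and control bin vectors must align over one genome partition",
         call. = FALSE)
  }
  tot <- chip + control
  keep <- tot > 0
  chip <- chip[keep]
  control <- control[keep]
  tot <- tot[keep]
  n <- length(tot)
  if (n == 0L || sum(control) == 0) {
    stop("cannot estimate ratio: control has no counts in candidate ",
         "background bins", call. = FALSE)
  }
  ord <- order(tot)
  cum_chip <- cumsum(chip[ord])
  cum_ctrl <- cumsum(control[ord])
  # candidate thresholds: last bin of each distinct total
  last <- which(diff(c(tot[ord], Inf)) > 0)
  r <- cum_chip[last] / cum_ctrl[last]
  frac <- last / n
  chosen <- NA_integer_
  if (length(r) > 1L) {
    ok <- which(diff(r) >= 0) + 1L
    ok <- ok[frac[ok] >= background_quantile & is.finite(r[ok])]
    if (length(ok) > 0L) chosen <- ok[1L]
  }
  if (is.na(chosen)) chosen <- length(r)
  if (!is.finite(r[chosen])) {
    stop("cannot estimate ratio: control has no counts in candidate ",
         "background bins", call. = FALSE)
  }
  structure(
    list(r_hat = r[chosen], bin_size = bin_size,
         background_fraction = frac[chosen],
         threshold = tot[ord][last[chosen]]),
    class = "NoiseRatio"
  )
}

#' @export
print.NoiseRatio <- function(x, ...) {
  cat(sprintf(
    "NoiseRatio: r_hat = %.4f (bin %d bp, %.1f%% of non-empty bins, t* = %s)\n",
    x$r_hat, x$bin_size, 100 * x$background_fraction, format(x$threshold)))
  invisible(x)
}

#' Bin genome-wide read counts from a BAM file
#'
#' Reads (mapped, primary) are assigned to non-overlapping `bin_size` bins
#' by their 5' position; the per-bin counts feed [ncis_ratio()].
#'
#' @inheritParams library_size
#' @param chrom_sizes Named chromosome lengths.
#' @param bin_size Bin width in bp.
#' @return Integer vector of counts, one per bin, bins ordered by chromosome
#'   then position.
#' @export
bin_genome_counts <- function(path, chrom_sizes, bin_size = 1000) {
  check_bam(path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag)
  )
  five_prime <- GenomicRanges::resize(GenomicRanges::granges(aln), 1L,
                                      fix = "start")
  seqinfo <- GenomeInfoDb::Seqinfo(names(chrom_sizes),
                                   as.integer(chrom_sizes))
  bins <- GenomicRanges::tileGenome(seqinfo, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  GenomicRanges::countOverlaps(bins, five_prime, ignore.strand = TRUE)
}

#' Subtract scaled control coverage from ChIP coverage
#'
#' `out[p] = max(0, chip[p] - r_hat * control[p])`: the control is scaled by
#' the background ratio so that only the noise component of the ChIP signal
#' is removed; negative residuals are clamped to zero.
#'
#' @param chip_cov,control_cov Equal-length coverage vectors (numeric or
#'   `Rle`).
#' @param r A `NoiseRatio` or a positive scalar.
#' @return Background-corrected coverage, same class as `chip_cov`.
#' @export
subtract_background <- function(chip_cov, control_cov, r) {
  r_hat <- if (inherits(r, "NoiseRatio")) r$r_hat else r
  stopifnot(is.numeric(r_hat), r_hat > 0)
  if (length(chip_cov) != length(control_cov)) {
    stop("chip and control coverage lengths differ (", length(chip_cov),
         " vs ", length(control_cov), ")", call. = FALSE)
  }
  pmax(chip_cov - r_hat * control_cov, 0)
}

#' Convert coverage to reads per million aligned (RPM)
#'
#' @param cov Coverage vector (numeric or `Rle`).
#' @param library_size Number of aligned reads in the library (> 0).
#' @return `cov * 1e6 / library_size`.
#' @export
rpm_normalize <- function(cov, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      library_size <= 0) {
    stop("library_size must be a single positive count", call. = FALSE)
  }
  cov * 1e6 / library_size
}
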