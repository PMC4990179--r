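#' Generate non-overlapping synthetic regions
#'
#' Places `n` regions of fixed width uniformly at random on `n_chrom`
#' chromosomes of equal length, with at least one region width of spacing
#' between neighbours so resized windows stay disjoint. Strands are assigned
#' at random. All placement is reproducible given `seed`.
#'
#' @param n Number of regions (>= 1).
#' @param width Region width in bp.
#' @param n_chrom Number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param seed Optional integer seed.
#' @return List with `regions` (a labelled `GRanges`) and `chrom_sizes`
#'   (named vector).
#' @export
simulate_regions <- function(n, width = 2000, n_chrom = 1,
                             chrom_length = 1e6, seed = NULL) {
  stopifnot(n >= 1, width >= 1, n_chrom >= 1)
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- tabulate(rep_len(seq_len(n_chrom), n), nbins = n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_sizes <- stats::setNames(rep(chrom_length, n_chrom), chroms)
  all_chrom <- character(0)
  all_start0 <- integer(0)
  for (i in seq_len(n_chrom)) {
    ni <- per_chrom[i]
    if (ni == 0L) next
    slack <- chrom_length - ni * 2 * width
    if (slack < 0) {
      stop("regions cannot fit: ", ni, " regions of width ", width,
           " with spacing need ", ni * 2 * width, " bp but chromosome has ",
           chrom_length, call. = FALSE)
    }
    # sorted uniforms + deterministic offsets guarantee >= width spacing
    u <- sort(floor(stats::runif(ni, 0, slack + 1)))
    all_start0 <- c(all_start0, as.integer(u + (seq_len(ni) - 1L) * 2L * width))
    all_chrom <- c(all_chrom, rep(chroms[i], ni))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = all_chrom,
    ranges = IRanges::IRanges(start = all_start0 + 1L, width = width),
    strand = sample(c("+", "-"), n, replace = TRUE),
    name = paste0("region_", seq_len(n)),
    score = NA_real_
  )
  list(regions = region_group(gr, "synthetic"), chrom_sizes = chrom_sizes)
}

#' Parameters of the synthetic ChIP-Seq experiment
#'
#' Describes the generative model used by [simulate_experiment()]: a ChIP
#' library made of uniform Poisson background plus a Gaussian-shaped read
#' pile-up centered in each region, and a matched control carrying
#' background only. The control's background rate is `background_rate`; the
#' ChIP background rate is `control_scale * background_rate`, so
#' `control_scale` is the true value the NCIS estimator should recover.
#'
#' Defaults emulate the structure of a transcription-factor ChIP experiment
#' over four activity classes: no enrichment in the `none` class and
#' increasing peak amplitudes (expected peak reads per region) for
#' `low`/`moderate`/`high`. Rates are set for a miniature genome standing in
#' for pooled, deeply sequenced libraries restricted to the regions of
#' interest: `background_rate = 0.8` reads/bp gives a control depth of
#' about 40x and, with `control_scale = 2`, a ChIP background depth of about
#' 80x at `read_length = 50`, deep enough that clamped background
#' subtraction leaves only a small positive residual (the residual fraction
#' scales as `sqrt((1 + c) / (2 * pi * depth))`).
#'
#' @param amplitudes Named numeric vector of expected peak reads per region
#'   for each region group; a single unnamed value applies to all regions.
#' @param sigma Peak width: SD in bp of the Gaussian placing peak-read 5'
#'   positions around the region center.
#' @param background_rate Control background rate, reads per bp genome-wide.
#' @param control_scale True ChIP/control background scaling `c` (> 0).
#' @param read_length Read length in bp of the error-free synthetic reads.
#' @param seed Seed recorded with the truth.
#' @return A `SimulationTruth` list.
#' @export
simulation_truth <- function(amplitudes = c(none = 0, low = 100,
                                            moderate = 250, high = 500),
                             sigma = 100, background_rate = 0.8,
                             control_scale = 2, read_length = 50,
                             seed = NULL) {
  stopifnot(all(amplitudes >= 0), sigma > 0, background_rate >= 0,
            control_scale > 0, read_length >= 1)
  structure(
    list(amplitudes = amplitudes, sigma = sigma,
         background_rate = background_rate, control_scale = control_scale,
         read_length = as.integer(read_length), seed = seed),
    class = "SimulationTruth"
  )
}

#' Simulate a ChIP + control alignment-file pair with known truth
#'
#' Writes two coordinate-sorted, indexed BAM files. ChIP reads are uniform
#' Poisson background (rate `control_scale * background_rate` per bp) plus,
#' per region, `Poisson(amplitude)` peak reads whose leftmost positions are
#' normal around the region center (SD `sigma`), truncated to the region.
#' Control reads are background only (rate `background_rate`). Reads are
#' single-end, error-free and uniquely mapped — alignment fidelity is not
#' part of the model. The generative parameters are recorded alongside as a
#' YAML truth file.
#'
#' @param regions `GRanges` of uniform width. Group membership per region is
#'   taken from a `group` metadata column when present; otherwise groups are
#'   assigned round-robin from `names(truth$amplitudes)`.
#' @param truth A [simulation_truth()].
#' @param chrom_sizes Named chromosome lengths (from [simulate_regions()]).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param seed Optional integer seed; all randomness flows from it.
#' @return List with `chip`, `control` (BAM paths), `truth`, `truth_file`,
#'   `regions` (the input with the `group` column filled in).
#' @export
simulate_experiment <- function(regions, truth = simulation_truth(),
                                chrom_sizes, dir = tempdir(),
                                prefix = "sim", seed = NULL) {
  stopifnot(inherits(truth, "SimulationTruth"))
  if (!is.null(seed)) set.seed(seed)
  rl <- truth$read_length
  amp <- truth$amplitudes
  group <- regions$group
  if (is.null(group)) {
    group <- if (length(amp) == 1L && is.null(names(amp))) {
      rep("all", length(regions))
    } else {
      rep_len(names(amp), length(regions))
    }
    regions$group <- group
  }
  if (length(amp) == 1L && is.null(names(amp))) {
    amp <- stats::setNames(amp, "all")
  }
  if (!all(group %in% names(amp))) {
    stop("region group without an amplitude: ",
         paste(setdiff(group, names(amp)), collapse = ", "), call. = FALSE)
  }

  background_reads <- function(rate) {
    out <- list()
    for (chrom in names(chrom_sizes)) {
      L <- chrom_sizes[[chrom]]
      k <- stats::rpois(1L, rate * L)
      if (k > 0L) {
        out[[chrom]] <- data.frame(
          chrom = chrom,
          pos = sample.int(max(1L, as.integer(L - rl + 1L)), k, replace = TRUE)
        )
      }
    }
    do.call(rbind, c(out, list(data.frame(chrom = character(),
                                          pos = integer()))))
  }

  chip <- background_reads(truth$control_scale * truth$background_rate)
  peak <- list()
  for (i in seq_along(regions)) {
    lambda <- amp[[group[i]]]
    if (lambda <= 0) next
    k <- stats::rpois(1L, lambda)
    if (k == 0L) next
    s <- BiocGenerics::start(regions)[i]
    e <- BiocGenerics::end(regions)[i]
    center <- floor((s - 1 + e) / 2)
    pos <- round(stats::rnorm(k, mean = center, sd = truth$sigma))
    pos <- pmin(pmax(pos, s), e - rl + 1L)   # truncate reads to the region
    peak[[length(peak) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions))[i], pos = pos
    )
  }
  chip <- rbind(chip, do.call(rbind, peak))
  control <- background_reads(truth$background_rate)

  chip_bam <- write_synthetic_bam(chip, chrom_sizes, rl,
                                  file.path(dir, paste0(prefix, "_chip")))
  control_bam <- write_synthetic_bam(control, chrom_sizes, rl,
                                     file.path(dir, paste0(prefix, "_control")))
  truth$seed <- seed
  truth$n_reads_chip <- nrow(chip)
  truth$n_reads_control <- nrow(control)
  truth_file <- file.path(dir, paste0(prefix, "_truth.yml"))
  yaml::write_yaml(
    list(amplitudes = as.list(amp), sigma = truth$sigma,
         background_rate = truth$background_rate,
         control_scale = truth$control_scale, read_length = rl,
         seed = seed, n_reads_chip = nrow(chip),
         n_reads_control = nrow(control)),
    truth_file
  )
  list(chip = chip_bam, control = control_bam, truth = truth,
       truth_file = truth_file, regions = regions)
}

# reads: data.frame(chrom, pos 1-based leftmost); writes sorted BAM + index
write_synthetic_bam <- function(reads, chrom_sizes, read_length, stem) {
  if (nrow(reads) == 0L) {
    stop("refusing to write an alignment file with zero reads", call. = FALSE)
  }
  reads$chrom <- factor(reads$chrom, levels = names(chrom_sizes))
  reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
            as.integer(chrom_sizes))
  )
  records <- sprintf(
    "read_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
    seq_len(nrow(reads)), as.character(reads$chrom), reads$pos, read_length
  )
  sam <- paste0(stem, ".sam")
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, destination = stem, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
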