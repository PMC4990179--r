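# Shared fixtures and independent oracles for the test suite.
# All BAM fixtures are built in code at test time; nothing binary is stored.

# Write a BAM (+ index) from explicit read placements.
# reads: data.frame(chrom, pos (1-based leftmost), cigar, flag); minimal
# columns chrom + pos default to 50M / flag 0.
make_bam <- function(reads, chrom_sizes, stem = tempfile()) {
  if (is.null(reads$cigar)) reads$cigar <- "50M"
  if (is.null(reads$flag)) reads$flag <- 0L
  if (is.null(reads$qname)) reads$qname <- paste0("read_", seq_len(nrow(reads)))
  reads$chrom <- factor(reads$chrom, levels = names(chrom_sizes))
  ord <- order(reads$chrom, reads$pos)
  reads <- reads[ord, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  records <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                     reads$qname, reads$flag, as.character(reads$chrom),
                     reads$pos, reads$cigar)
  sam <- paste0(stem, ".sam")
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, destination = stem, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Simple GRanges builder in BED (0-based half-open) coordinates.
bed_regions <- function(chrom, start0, end0, strand = "*", name = NULL,
                        score = NA_real_) {
  n <- max(length(chrom), length(start0))
  if (is.null(name)) name <- paste0("region_", seq_len(n))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand, name = name, score = score
  )
}

# Brute-force per-read coverage oracle: depth vector for one region from a
# table of read spans (1-based closed), independent of the Rle machinery.
oracle_region_depth <- function(reads, region_chrom, region_start,
                                region_end, read_length = 50L) {
  width <- region_end - region_start + 1L
  depth <- integer(width)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != region_chrom) next
    r_start <- reads$pos[i]
    r_end <- reads$pos[i] + read_length - 1L
    lo <- max(r_start, region_start)
    hi <- min(r_end, region_end)
    if (lo > hi) next
    off <- (lo - region_start + 1L):(hi - region_start + 1L)
    depth[off] <- depth[off] + 1L
  }
  depth
}

# --- independent brute-force pseudometric oracles (plain loops) -------------

oracle_ratio_area <- function(p1, p2) {
  a1 <- 0; a2 <- 0
  for (i in seq_along(p1)) { a1 <- a1 + p1[i]; a2 <- a2 + p2[i] }
  a1 / a2
}

oracle_argmax_median <- function(p) {
  m <- p[1]
  for (v in p) if (v > m) m <- v
  ties <- c()
  for (i in seq_along(p)) if (p[i] == m) ties <- c(ties, i - 1)
  sort(ties)[ceiling(length(ties) / 2)] / 2 +
    sort(ties)[floor(length(ties) / 2) + 1] / 2
}

oracle_diff_pos_max <- function(p1, p2) {
  oracle_argmax_median(p1) - oracle_argmax_median(p2)
}

oracle_ratio_max_max <- function(p1, p2) max(p1) / max(p2)

oracle_ratio_intersect <- function(p1, p2) {
  num <- 0; den <- 0
  for (i in seq_along(p1)) {
    num <- num + if (p1[i] < p2[i]) p1[i] else p2[i]
    den <- den + if (p1[i] > p2[i]) p1[i] else p2[i]
  }
  num / den
}

oracle_ratio_normalized_intersect <- function(p1, p2) {
  oracle_ratio_intersect(p1 / mean(p1), p2 / mean(p2))
}

# average ranks computed by direct pairwise counting, then the Pearson
# product-moment formula applied to the ranks
oracle_rank <- function(p) {
  n <- length(p)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (p[j] < p[i]) less <- less + 1
      if (p[j] == p[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

oracle_spearman <- function(p1, p2) {
  r1 <- oracle_rank(p1); r2 <- oracle_rank(p2)
  m1 <- mean(r1); m2 <- mean(r2)
  num <- sum((r1 - m1) * (r2 - m2))
  num / sqrt(sum((r1 - m1)^2) * sum((r2 - m2)^2))
}

# Matrix of synthetic coverage-like rows: Gaussian bump + Poisson noise.
sim_profile_matrix <- function(n, width = 20, amplitude = 5, noise = 2) {
  shape <- amplitude * exp(-0.5 * ((seq_len(width) - (width + 1) / 2) /
                                     (width / 6))^2)
  t(replicate(n, stats::rpois(width, shape + noise)))
}
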