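cs1 <- c(chr1 = 100000)

test_that("library_size counts mapped primary records only", {
  reads <- data.frame(chrom = "chr1", pos = c(100L, 300L, 500L),
                      flag = c(0L, 0L, 16L))
  bam <- make_bam(reads, cs1)
  expect_equal(library_size(bam), 3L)

  # unmapped (flag 4) and secondary (flag 256) records are excluded
  mixed <- data.frame(chrom = "chr1", pos = c(100L, 300L, 500L, 700L),
                      flag = c(0L, 4L, 256L, 0L),
                      cigar = c("50M", "*", "50M", "50M"))
  bam2 <- make_bam(mixed, cs1)
  expect_equal(library_size(bam2), 2L)
})

test_that("library_size errors on empty libraries and missing indexes", {
  reads <- data.frame(chrom = "chr1", pos = 100L, flag = 4L, cigar = "*")
  bam <- make_bam(reads, cs1)
  expect_error(library_size(bam), "no aligned reads")

  noindex <- data.frame(chrom = "chr1", pos = 100L)
  bam2 <- make_bam(noindex, cs1)
  file.remove(paste0(bam2, ".bai"))
  expect_error(library_size(bam2), "index")
})

test_that("region_coverage computes depth over read/region overlaps", {
  # one 50 bp read at BED 100-150; region BED 90-160
  bam <- make_bam(data.frame(chrom = "chr1", pos = 101L), cs1)
  regions <- bed_regions("chr1", 90L, 160L)
  trk <- region_coverage(bam, regions)
  v <- as.integer(trk$coverage[[1L]])
  expect_length(v, 70L)
  expect_equal(which(v == 1L), 11:60)  # offsets 10..59, 0-based
  expect_true(all(v[-(11:60)] == 0L))

  # two fully overlapping reads stack additively
  bam2 <- make_bam(data.frame(chrom = "chr1", pos = c(101L, 101L)), cs1)
  v2 <- as.integer(region_coverage(bam2, regions)$coverage[[1L]])
  expect_equal(v2[11:60], rep(2L, 50L))

  # region with no overlapping reads is all zero
  far <- bed_regions("chr1", 5000L, 5070L)
  both <- c(regions, far)
  trk3 <- region_coverage(bam, both)
  expect_true(all(as.integer(trk3$coverage[[2L]]) == 0L))
})

test_that("regions on chromosomes absent from the BAM warn and zero-fill", {
  bam <- make_bam(data.frame(chrom = "chr1", pos = 101L), cs1)
  regions <- bed_regions(c("chr1", "chrX"), c(90L, 90L), c(160L, 160L))
  expect_warning(trk <- region_coverage(bam, regions), "chrX")
  expect_true(all(as.integer(trk$coverage[[2L]]) == 0L))
  expect_equal(sum(as.integer(trk$coverage[[1L]])), 50L)
})

test_that("coverage sums match the brute-force per-read overlap oracle", {
  set.seed(101)
  for (i in 1:8) {
    n_reads <- sample(20:80, 1)
    reads <- data.frame(
      chrom = sample(c("chr1", "chr2"), n_reads, replace = TRUE),
      pos = sample.int(9000L, n_reads, replace = TRUE)
    )
    cs <- c(chr1 = 10000, chr2 = 10000)
    bam <- make_bam(reads, cs)
    regions <- bed_regions(c("chr1", "chr2", "chr1"),
                           c(1000L, 4000L, 8000L),
                           c(1200L, 4200L, 8200L))
    trk <- region_coverage(bam, regions)
    for (j in seq_along(regions)) {
      expected <- oracle_region_depth(
        reads, as.character(GenomicRanges::seqnames(regions))[j],
        BiocGenerics::start(regions)[j], BiocGenerics::end(regions)[j])
      expect_equal(as.integer(trk$coverage[[j]]), expected)
    }
  }
})

test_that("coverage is invariant to read order in the input", {
  set.seed(7)
  reads <- data.frame(chrom = "chr1",
                      pos = sample.int(5000L, 40L, replace = TRUE))
  bam_a <- make_bam(reads, cs1)
  bam_b <- make_bam(reads[sample.int(nrow(reads)), , drop = FALSE], cs1)
  regions <- bed_regions("chr1", c(100L, 2500L), c(600L, 3000L))
  expect_identical(
    lapply(region_coverage(bam_a, regions)$coverage, as.integer),
    lapply(region_coverage(bam_b, regions)$coverage, as.integer)
  )
})

test_that("reads spanning two query windows are not double counted", {
  # read BED 995-1045 overlaps both regions; depth must stay 1
  bam <- make_bam(data.frame(chrom = "chr1", pos = 996L), cs1)
  regions <- bed_regions("chr1", c(900L, 1000L), c(1000L, 1100L))
  trk <- region_coverage(bam, regions)
  expect_true(all(as.integer(trk$coverage[[1L]]) <= 1L))
  expect_true(all(as.integer(trk$coverage[[2L]]) <= 1L))
  expect_equal(sum(as.integer(trk$coverage[[1L]])) +
                 sum(as.integer(trk$coverage[[2L]])), 50L)
})

test_that("optional read extension lengthens the covered span", {
  bam <- make_bam(data.frame(chrom = "chr1", pos = 1001L), cs1)
  regions <- bed_regions("chr1", 900L, 1400L)
  plain <- sum(as.integer(region_coverage(bam, regions)$coverage[[1L]]))
  extended <- sum(as.integer(
    region_coverage(bam, regions, extend = 200)$coverage[[1L]]))
  expect_equal(plain, 50L)
  expect_equal(extended, 200L)
})

test_that("coverage_track enforces the expanded-length contract", {
  rle_ok <- methods::as(list(S4Vectors::Rle(0L, 10L)), "RleList")
  expect_s3_class(coverage_track("s", rle_ok, 100, 10), "CoverageTrack")
  expect_error(coverage_track("s", rle_ok, 100, 12))
})
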