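test_that("read_bed maps BED fields and auto-fills name and strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tr1\t3.5\t+",
               "chr2\t50\t150",
               "chr1\t0\t10\tr3\t1\t-"), bed)
  gr <- read_bed(bed)
  expect_length(gr, 3L)
  expect_equal(as.character(GenomicRanges::seqnames(gr)),
               c("chr1", "chr2", "chr1"))
  expect_equal(BiocGenerics::start(gr) - 1L, c(100L, 50L, 0L))  # 0-based
  expect_equal(BiocGenerics::end(gr), c(200L, 150L, 10L))
  expect_equal(gr$name, c("r1", "region_2", "r3"))
  expect_equal(as.character(BiocGenerics::strand(gr)), c("+", "*", "-"))
  expect_equal(gr$score, c(3.5, NA, 1))
})

test_that("read_bed handles empty files and rejects malformed lines", {
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_length(read_bed(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t300\t200", bad)
  expect_error(read_bed(bad), "line 1")

  nonint <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\tten\t30"), nonint)
  expect_error(read_bed(nonint), "line 2")

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10", short)
  expect_error(read_bed(short), "fewer than 3")
})

test_that("read_bed and write_bed round-trip coordinates and strand", {
  gr <- bed_regions(c("chr1", "chr2", "chr1"), c(0L, 999L, 123L),
                    c(100L, 2999L, 456L), strand = c("+", "-", "*"),
                    score = c(1, 2, 3))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, out)
  back <- read_bed(out)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr))
  expect_equal(as.character(BiocGenerics::strand(back)),
               as.character(BiocGenerics::strand(gr)))
  expect_equal(back$name, gr$name)
})

test_that("read_narrowpeak dispatches on column count", {
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpeak1\t500\t.\t7.5\t10\t8\t50", np)
  gr <- read_narrowpeak(np)
  expect_equal(gr$score, 7.5)  # signalValue, not BED score
  expect_equal(BiocGenerics::start(gr) - 1L, 100L)

  bp <- withr::local_tempfile(fileext = ".broadPeak")
  writeLines("chr1\t100\t200\tpeak1\t500\t+\t4.25\t10\t8", bp)
  gr2 <- read_narrowpeak(bp)
  expect_equal(gr2$score, 4.25)
  expect_equal(as.character(BiocGenerics::strand(gr2)), "+")

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t200\tpeak1\t500\t.\t7.5\t10", bad)
  expect_error(read_narrowpeak(bad), "columns")
})

test_that("resize_regions centers windows and enforces uniform width", {
  cs <- c(chr1 = 100000)
  gr <- bed_regions("chr1", 5000L, 5100L)
  out <- resize_regions(gr, 1000, cs)
  expect_equal(BiocGenerics::start(out) - 1L, 4050L)  # center 5050
  expect_equal(BiocGenerics::end(out), 6050L)
  expect_equal(BiocGenerics::width(out), 2000L)

  # already-centered window of width 2*flank is reproduced
  centered <- bed_regions("chr1", 2000L, 2000L + 2000L)
  expect_equal(BiocGenerics::width(resize_regions(centered, 1000, cs)),
               2000L)
})

test_that("resize_regions drops boundary violations and errors when empty", {
  cs <- c(chr1 = 10000)
  gr <- bed_regions(c("chr1", "chr1"), c(100L, 5000L), c(200L, 5100L))
  expect_warning(out <- resize_regions(gr, 1000, cs), "dropped")
  expect_length(out, 1L)  # first region would start at -850
  expect_true(all(BiocGenerics::width(out) == 2000L))

  lone <- bed_regions("chr1", 100L, 200L)
  expect_warning(expect_error(resize_regions(lone, 1000, cs),
                              "no regions remain"))
})

test_that("orientation reverses minus-strand coverage and is an involution", {
  expect_equal(orient_region_coverage(c(1, 2, 3), "-"), c(3, 2, 1))
  expect_equal(orient_region_coverage(c(1, 2, 3), "+"), c(1, 2, 3))
  expect_equal(orient_region_coverage(c(1, 2, 3), "*"), c(1, 2, 3))
  set.seed(11)
  for (i in 1:10) {
    v <- stats::runif(sample(3:50, 1))
    expect_identical(
      orient_region_coverage(orient_region_coverage(v, "-"), "-"), v)
  }
})

test_that("stratify_by_score forms the zero group plus tertiles", {
  gr <- bed_regions(rep("chr1", 8), seq(0L, 7000L, by = 1000L),
                    seq(100L, 7100L, by = 1000L),
                    score = c(0, 0, 1, 2, 3, 4, 5, 6))
  groups <- stratify_by_score(gr)
  expect_named(groups, c("none", "low", "moderate", "high"))
  expect_equal(sort(groups$none$score), c(0, 0))
  expect_equal(sort(groups$low$score), c(1, 2))
  expect_equal(sort(groups$moderate$score), c(3, 4))
  expect_equal(sort(groups$high$score), c(5, 6))
})

test_that("stratify_by_score breaks ties by region order, sizes differ <= 1", {
  gr <- bed_regions(rep("chr1", 7), seq(0L, 6000L, by = 1000L),
                    seq(100L, 6100L, by = 1000L), score = rep(2, 7))
  groups <- stratify_by_score(gr)
  sizes <- lengths(groups[c("low", "moderate", "high")])
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_equal(sum(sizes), 7L)
  # ties resolved in input order: earliest regions land in 'low'
  expect_equal(groups$low$name, paste0("region_", 1:2))
})

test_that("stratify_by_score partitions its input and validates it", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    score <- stats::rpois(n, 3)
    if (sum(score > 0) < 3) next
    gr <- bed_regions(rep("chr1", n), seq_len(n) * 1000L,
                      seq_len(n) * 1000L + 100L, score = score)
    groups <- stratify_by_score(gr)
    expect_equal(sum(lengths(groups)), n)
    expect_setequal(unlist(lapply(groups, function(g) g$name)), gr$name)
    expect_true(all(groups$none$score == 0))
  }
  few <- bed_regions(rep("chr1", 3), c(0L, 1000L, 2000L),
                     c(100L, 1100L, 2100L), score = c(0, 0, 5))
  expect_error(stratify_by_score(few), "fewer than 3")
  neg <- bed_regions("chr1", 0L, 100L, score = -1)
  expect_error(stratify_by_score(neg), "score")
})
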