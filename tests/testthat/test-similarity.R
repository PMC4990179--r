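test_that("ratio_area compares total areas with a validity guard", {
  expect_equal(metric_value(ratio_area(c(2, 2, 2), c(1, 1, 1))), 2)
  expect_equal(metric_value(ratio_area(c(3, 1), c(3, 1))), 1)
  res <- ratio_area(c(1, 1), c(0, 0))
  expect_false(res$defined)
  expect_match(res$undefined_reason, "area")
})

test_that("diff_pos_max locates peaks with median tie-breaking", {
  p10 <- replace(numeric(20), 11, 5)   # max at 0-based position 10
  p12 <- replace(numeric(20), 13, 5)
  expect_equal(metric_value(diff_pos_max(p10, p12)), -2)
  expect_equal(metric_value(diff_pos_max(p10, p10)), 0)
  # plateau {1,2} (0-based) has median position 1.5
  expect_equal(metric_value(diff_pos_max(c(0, 5, 5, 0), c(9, 1, 1, 1))), 1.5)
  low <- c(0.2, 0.1, 0.1, 0)
  expect_false(diff_pos_max(low, c(0, 5, 0, 0))$defined)
})

test_that("ratio_max_max compares peak heights", {
  expect_equal(metric_value(ratio_max_max(c(0, 8, 1), c(4, 2, 0))), 2)
  expect_equal(metric_value(ratio_max_max(c(1, 3), c(1, 3))), 1)
  expect_false(ratio_max_max(c(1, 5), c(0, 0))$defined)
})

test_that("ratio_intersect is the min/max area ratio", {
  expect_equal(metric_value(ratio_intersect(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(metric_value(ratio_intersect(c(1, 0), c(0, 1))), 0)
  expect_equal(metric_value(ratio_intersect(c(2, 2), c(1, 3))), 0.6)
  expect_false(ratio_intersect(c(0, 0), c(0, 0))$defined)
})

test_that("ratio_normalized_intersect is scale invariant", {
  p <- c(0, 2, 5, 2, 0.5)
  expect_equal(metric_value(ratio_normalized_intersect(p, 10 * p)), 1)
  expect_equal(metric_value(ratio_normalized_intersect(c(2, 0), c(0, 2))), 0)
  # equal means: normalization rescales both curves identically
  expect_equal(metric_value(ratio_normalized_intersect(c(2, 2), c(1, 3))),
               0.6)
  expect_false(ratio_normalized_intersect(c(0, 0), c(1, 2))$defined)
})

test_that("spearman_correlation ranks paired positions", {
  inc1 <- c(1, 3, 7, 20)
  inc2 <- c(0.1, 0.2, 5, 6)
  expect_equal(metric_value(spearman_correlation(inc1, inc2)), 1)
  expect_equal(metric_value(spearman_correlation(inc1, rev(inc2))), -1)
  expect_false(spearman_correlation(inc1, rep(2, 4))$defined)
})

test_that("all six pseudometrics match the brute-force oracles", {
  set.seed(71)
  for (i in 1:200) {
    w <- sample(5:40, 1)
    p1 <- round(stats::rexp(w, 1 / 4), 2) + 1
    p2 <- round(stats::rexp(w, 1 / 4), 2) + 1
    if (i %% 3 == 0) p2[sample(w, 2)] <- p2[sample(w, 2)]  # inject ties
    expect_equal(metric_value(ratio_area(p1, p2)),
                 oracle_ratio_area(p1, p2), tolerance = 1e-12)
    expect_equal(metric_value(diff_pos_max(p1, p2)),
                 oracle_diff_pos_max(p1, p2), tolerance = 1e-12)
    expect_equal(metric_value(ratio_max_max(p1, p2)),
                 oracle_ratio_max_max(p1, p2), tolerance = 1e-12)
    expect_equal(metric_value(ratio_intersect(p1, p2)),
                 oracle_ratio_intersect(p1, p2), tolerance = 1e-12)
    expect_equal(metric_value(ratio_normalized_intersect(p1, p2)),
                 oracle_ratio_normalized_intersect(p1, p2),
                 tolerance = 1e-12)
    expect_equal(metric_value(spearman_correlation(p1, p2)),
                 oracle_spearman(p1, p2), tolerance = 1e-12)
  }
})

test_that("pseudometric symmetries and closed forms hold", {
  set.seed(72)
  for (i in 1:50) {
    w <- sample(4:30, 1)
    p1 <- stats::rexp(w) + 0.5
    p2 <- stats::rexp(w) + 0.5
    expect_equal(metric_value(ratio_intersect(p1, p2)),
                 metric_value(ratio_intersect(p2, p1)))
    expect_equal(metric_value(diff_pos_max(p1, p2)),
                 -metric_value(diff_pos_max(p2, p1)))
    c_scale <- stats::runif(1, 0.1, 5)
    expect_equal(metric_value(ratio_intersect(p1, c_scale * p1)),
                 min(c_scale, 1) / max(c_scale, 1))
    expect_equal(metric_value(ratio_normalized_intersect(p1, c_scale * p1)),
                 1)
    ri <- metric_value(ratio_intersect(p1, p2))
    expect_gte(ri, 0); expect_lte(ri, 1)
    sp <- metric_value(spearman_correlation(p1, p2))
    expect_gte(sp, -1); expect_lte(sp, 1)
  }
})

test_that("length mismatches and negative profiles are rejected", {
  expect_error(ratio_intersect(c(1, 2), c(1, 2, 3)), "length")
  expect_error(spearman_correlation(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("similarity_report tabulates all six metrics", {
  tab <- similarity_report(c(2, 2), c(1, 3), experiment = "e",
                           region_class = "promoters")
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$metric,
                  c("RATIO_AREA", "DIFF_POS_MAX", "RATIO_MAX_MAX",
                    "RATIO_INTERSECT", "RATIO_NORMALIZED_INTERSECT",
                    "SPEARMAN_CORRELATION"))
  expect_equal(tab$value[tab$metric == "RATIO_INTERSECT"], 0.6)
})

test_that("classify_effect applies the 0.85 intersection-ratio rule", {
  flat <- function(v) rep(v, 4)
  gradient <- classify_effect(flat(0.66), flat(1))
  expect_equal(gradient$label, "gradient")
  expect_equal(gradient$ratio_intersect, 0.66)
  at_cutoff <- classify_effect(flat(0.85), flat(1))
  expect_equal(at_cutoff$label, "threshold")   # >= is threshold
  plateau <- classify_effect(flat(0.88), flat(1))
  expect_equal(plateau$label, "threshold")
  expect_equal(classify_effect(flat(0), flat(0))$label, "unclassifiable")
})
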