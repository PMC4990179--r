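#' Profile-similarity pseudometrics
#'
#' Six pseudometrics quantify the resemblance of two equal-length,
#' non-negative enrichment profiles, each sensitive to a different profile
#' feature:
#'
#' * `ratio_area` — total area of the first profile over the second;
#'   amplitude on the whole window.
#' * `diff_pos_max` — offset between the peak positions (argmax) of the two
#'   profiles; binding-site displacement. Ties at the maximum are resolved
#'   by the median of the tied positions.
#' * `ratio_max_max` — peak height of the first over the second; amplitude
#'   at the summit.
#' * `ratio_intersect` — area under the pointwise minimum over the area
#'   under the pointwise maximum; in `[0, 1]`, 1 for identical profiles,
#'   symmetric in its arguments.
#' * `ratio_normalized_intersect` — `ratio_intersect` after dividing each
#'   profile by its own mean; shape similarity regardless of amplitude.
#' * `spearman_correlation` — Spearman rank correlation of the paired
#'   position values (average ranks for ties).
#'
#' Each pseudometric guards against uninformative input with editable
#' validity thresholds (see [pseudometric_thresholds()]): when a profile
#' carries no usable peak or area, the result is returned as *undefined*
#' with an explicit reason rather than an extreme or non-finite number.
#'
#' @param p1,p2 Equal-length non-negative numeric profiles.
#' @param thresholds Validity thresholds, see [pseudometric_thresholds()].
#' @return A `PseudometricResult`: list with `name`, `value` (`NA` when
#'   undefined), `defined`, `undefined_reason`, `thresholds_used`. The bare
#'   number is extracted with [metric_value()].
#' @name pseudometrics
NULL

#' Validity thresholds for the pseudometrics
#'
#' @param min_area Minimum profile area (sum of values, curve units) for
#'   area-ratio computation.
#' @param min_peak Minimum peak height (curve units) for the max-based
#'   pseudometrics.
#' @return Named list of thresholds.
#' @export
pseudometric_thresholds <- function(min_area = 1, min_peak = 1) {
  list(min_area = min_area, min_peak = min_peak)
}

pseudometric_result <- function(name, value, thresholds, reason = NA_character_) {
  structure(
    list(name = name, value = value, defined = !is.na(value),
         undefined_reason = reason, thresholds_used = thresholds),
    class = "PseudometricResult"
  )
}

#' @export
print.PseudometricResult <- function(x, ...) {
  if (x$defined) {
    cat(x$name, "=", format(x$value), "\n")
  } else {
    cat(x$name, "undefined:", x$undefined_reason, "\n")
  }
  invisible(x)
}

#' Extract the numeric value of a pseudometric result
#'
#' @param x A `PseudometricResult` (or a bare number, returned unchanged).
#' @return Numeric scalar, `NA` when the pseudometric was undefined.
#' @export
metric_value <- function(x) {
  if (inherits(x, "PseudometricResult")) x$value else as.numeric(x)
}

check_profiles <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("profiles differ in length (", length(p1), " vs ", length(p2), ")",
         call. = FALSE)
  }
  if (any(p1 < 0) || any(p2 < 0)) {
    stop("pseudometrics are defined on non-negative profiles", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname pseudometrics
#' @export
ratio_area <- function(p1, p2, thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  if (sum(p2) < thresholds$min_area) {
    return(pseudometric_result("RATIO_AREA", NA_real_, thresholds,
                               "area of second profile below min_area"))
  }
  pseudometric_result("RATIO_AREA", sum(p1) / sum(p2), thresholds)
}

# 0-based position of the maximum; median of ties
argmax_position <- function(p) {
  stats::median(which(p == max(p)) - 1)
}

#' @rdname pseudometrics
#' @export
diff_pos_max <- function(p1, p2, thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  if (max(p1) < thresholds$min_peak || max(p2) < thresholds$min_peak) {
    return(pseudometric_result("DIFF_POS_MAX", NA_real_, thresholds,
                               "peak height below min_peak"))
  }
  pseudometric_result("DIFF_POS_MAX",
                      argmax_position(p1) - argmax_position(p2), thresholds)
}

#' @rdname pseudometrics
#' @export
ratio_max_max <- function(p1, p2, thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  if (max(p2) < thresholds$min_peak) {
    return(pseudometric_result("RATIO_MAX_MAX", NA_real_, thresholds,
                               "peak of second profile below min_peak"))
  }
  pseudometric_result("RATIO_MAX_MAX", max(p1) / max(p2), thresholds)
}

#' @rdname pseudometrics
#' @export
ratio_intersect <- function(p1, p2, thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  denom <- sum(pmax(p1, p2))
  if (denom == 0) {
    return(pseudometric_result("RATIO_INTERSECT", NA_real_, thresholds,
                               "both profiles are identically zero"))
  }
  pseudometric_result("RATIO_INTERSECT", sum(pmin(p1, p2)) / denom,
                      thresholds)
}

#' @rdname pseudometrics
#' @export
ratio_normalized_intersect <- function(p1, p2,
                                       thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  m1 <- mean(p1)
  m2 <- mean(p2)
  if (m1 == 0 || m2 == 0) {
    return(pseudometric_result("RATIO_NORMALIZED_INTERSECT", NA_real_,
                               thresholds, "a profile has zero mean"))
  }
  ri <- ratio_intersect(p1 / m1, p2 / m2, thresholds)
  pseudometric_result("RATIO_NORMALIZED_INTERSECT", ri$value, thresholds,
                      ri$undefined_reason)
}

#' @rdname pseudometrics
#' @export
spearman_correlation <- function(p1, p2,
                                 thresholds = pseudometric_thresholds()) {
  check_profiles(p1, p2)
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
    return(pseudometric_result("SPEARMAN_CORRELATION", NA_real_, thresholds,
                               "a profile is constant (zero variance)"))
  }
  pseudometric_result("SPEARMAN_CORRELATION",
                      stats::cor(p1, p2, method = "spearman"), thresholds)
}

#' Compute all six pseudometrics
#'
#' @inheritParams pseudometrics
#' @param experiment,region_class Labels carried into the report.
#' @return Data frame with columns `experiment`, `region_class`, `metric`,
#'   `value`, `defined`, `reason`.
#' @export
similarity_report <- function(p1, p2, thresholds = pseudometric_thresholds(),
                              experiment = "exp", region_class = "regions") {
  fns <- list(ratio_area, diff_pos_max, ratio_max_max, ratio_intersect,
              ratio_normalized_intersect, spearman_correlation)
  res <- lapply(fns, function(f) f(p1, p2, thresholds))
  data.frame(
    experiment = experiment,
    region_class = region_class,
    metric = vapply(res, `[[`, character(1), "name"),
    value = vapply(res, `[[`, numeric(1), "value"),
    defined = vapply(res, `[[`, logical(1), "defined"),
    reason = vapply(res, `[[`, character(1), "undefined_reason")
  )
}

#' Classify recruitment as gradient or threshold effect
#'
#' Compares the profiles of the moderate- and high-activity region groups of
#' one factor. When the two profiles nearly coincide — intersection ratio at
#' or above the cutoff — the factor's occupancy has plateaued before maximal
#' activity: a *threshold* effect. Otherwise occupancy still rises with
#' activity: a *gradient* effect.
#'
#' @param profile_moderate,profile_high Group profiles (equal length,
#'   non-negative), typically moderate- and high-activity classes.
#' @param cutoff Decision constant on RATIO_INTERSECT (default 0.85; values
#'   `>= cutoff` classify as threshold).
#' @param thresholds Validity thresholds for the underlying pseudometric.
#' @return An `EffectClass`: list with `label` (`"threshold"`, `"gradient"`
#'   or `"unclassifiable"`), `ratio_intersect`, `cutoff`.
#' @export
classify_effect <- function(profile_moderate, profile_high, cutoff = 0.85,
                            thresholds = pseudometric_thresholds()) {
  ri <- ratio_intersect(profile_moderate, profile_high, thresholds)
  label <- if (!ri$defined) "unclassifiable" else
    if (ri$value >= cutoff) "threshold" else "gradient"
  structure(
    list(label = label, ratio_intersect = ri$value, cutoff = cutoff,
         undefined_reason = ri$undefined_reason),
    class = "EffectClass"
  )
}

#' @export
print.EffectClass <- function(x, ...) {
  cat("EffectClass:", x$label,
      sprintf("(RATIO_INTERSECT = %s, cutoff = %g)\n",
              format(x$ratio_intersect), x$cutoff))
  invisible(x)
}
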