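#' Assemble a regions x positions coverage matrix
#'
#' Expands the run-length encoded per-region vectors of a `CoverageTrack`
#' into a dense matrix, one row per region, optionally orienting each row
#' 5'->3' (minus-strand rows reversed, see [orient_region_coverage()]).
#'
#' @param track A `CoverageTrack`, or a plain numeric matrix (then `regions`
#'   is ignored and the matrix is wrapped as-is).
#' @param regions The region group the track was computed over; provides the
#'   strand used for orientation.
#' @param orient Reverse minus-strand rows?
#' @param group_label,experiment Labels carried into downstream tables.
#' @param units `"raw"` or `"RPM"`.
#' @return A `CoverageMatrix`: list with `values` (matrix), `group_label`,
#'   `experiment`, `units`, `oriented`, `bin_size`.
#' @export
coverage_matrix <- function(track, regions = NULL, orient = TRUE,
                            group_label = NULL, experiment = "exp",
                            units = c("raw", "RPM")) {
  units <- match.arg(units)
  if (is.matrix(track)) {
    values <- track
    oriented <- FALSE
  } else {
    stopifnot(inherits(track, "CoverageTrack"))
    values <- do.call(rbind, lapply(track$coverage, as.numeric))
    oriented <- FALSE
    if (orient && !is.null(regions)) {
      stopifnot(length(regions) == nrow(values))
      minus <- as.character(BiocGenerics::strand(regions)) == "-"
      if (any(minus)) {
        values[minus, ] <- values[minus, rev(seq_len(ncol(values))),
                                  drop = FALSE]
      }
      oriented <- TRUE
    }
  }
  if (is.null(group_label)) {
    group_label <- if (!is.null(regions)) region_label(regions) else "regions"
  }
  if (any(values < 0)) stop("coverage values must be >= 0", call. = FALSE)
  structure(
    list(values = values, group_label = group_label, experiment = experiment,
         units = units, oriented = oriented, bin_size = 1L),
    class = "CoverageMatrix"
  )
}

matrix_values <- function(m) {
  if (inherits(m, "CoverageMatrix")) m$values else as.matrix(m)
}

#' Bin matrix positions
#'
#' Replaces every run of `bin_size` consecutive positions by its arithmetic
#' mean, per row. Binning damps extreme single-base values before
#' bootstrapping. A trailing partial bin is dropped with a warning.
#'
#' @param m A `CoverageMatrix` (or plain matrix).
#' @param bin_size Positions per bin (>= 1).
#' @return A `CoverageMatrix` with `ncol %/% bin_size` columns.
#' @export
bin_matrix <- function(m, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1 ||
      bin_size != floor(bin_size)) {
    stop("bin_size must be a positive integer", call. = FALSE)
  }
  bin_size <- as.integer(bin_size)
  v <- matrix_values(m)
  nb <- ncol(v) %/% bin_size
  if (nb == 0L) stop("bin_size exceeds matrix width", call. = FALSE)
  if (ncol(v) %% bin_size != 0L) {
    warning("matrix width ", ncol(v), " not divisible by bin_size ",
            bin_size, "; trailing partial bin dropped", call. = FALSE)
    v <- v[, seq_len(nb * bin_size), drop = FALSE]
  }
  if (bin_size > 1L) {
    grp <- rep(seq_len(nb), each = bin_size)
    v <- t(rowsum(t(v), grp, reorder = FALSE)) / bin_size
    dimnames(v) <- NULL
  }
  out <- if (inherits(m, "CoverageMatrix")) m else
    coverage_matrix(matrix_values(m))
  out$values <- v
  out$bin_size <- out$bin_size * bin_size
  out
}

#' Aggregate a coverage matrix into a group profile
#'
#' Column-wise mean or median across regions — the metagene curve for one
#' region group in one experiment.
#'
#' @param m A `CoverageMatrix` (or plain matrix) with >= 1 row.
#' @param estimator `"mean"` or `"median"`. The median of an even number of
#'   rows is the conventional midpoint average.
#' @return Numeric profile of length `ncol(m)`.
#' @export
aggregate_profile <- function(m, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  v <- matrix_values(m)
  if (nrow(v) == 0L) stop("empty coverage matrix", call. = FALSE)
  if (estimator == "mean") colMeans(v) else
    apply(v, 2L, stats::median)
}

#' Bootstrap confidence ribbon around a group profile
#'
#' Resamples matrix rows — regions are the independent sampling units; the
#' positions of one region stay paired — with replacement `B` times,
#' recomputes the estimator curve per resample, and takes per-position
#' percentiles of the `B` curves as the ribbon: the central `level`% of the
#' bootstrap distribution.
#'
#' @param m A `CoverageMatrix` (or plain matrix).
#' @param estimator `"mean"` or `"median"`.
#' @param B Bootstrap replicates (default 1000).
#' @param level Ribbon coverage percentage in (0, 100), default 95.
#' @param seed Optional integer; fixing it makes the ribbon reproducible.
#' @return A `MetageneProfile`: list with `estimator`, `curve` (estimate on
#'   the full data), `ribbon_low`, `ribbon_high`, `level`, `B`,
#'   `n_regions`, `bin_size`, `group_label`, `experiment`, `units`.
#' @export
bootstrap_ribbon <- function(m, estimator = c("mean", "median"), B = 1000,
                             level = 95, seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(B >= 2, level > 0, level < 100)
  if (!is.null(seed)) set.seed(seed)
  v <- matrix_values(m)
  n <- nrow(v)
  if (n == 0L) stop("empty coverage matrix", call. = FALSE)
  curve <- aggregate_profile(v, estimator)
  if (n == 1L) {
    warning("single-region matrix: ribbon has zero width", call. = FALSE)
    low <- high <- curve
  } else {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    if (estimator == "mean") {
      counts <- matrix(0, B, n)
      for (b in seq_len(B)) counts[b, ] <- tabulate(idx[b, ], nbins = n)
      boot <- (counts %*% v) / n
    } else {
      boot <- matrix(0, B, ncol(v))
      for (b in seq_len(B)) {
        boot[b, ] <- apply(v[idx[b, ], , drop = FALSE], 2L, stats::median)
      }
    }
    alpha <- (1 - level / 100) / 2
    qs <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    low <- qs[1L, ]
    high <- qs[2L, ]
  }
  structure(
    list(estimator = estimator, curve = curve, ribbon_low = low,
         ribbon_high = high, level = level, B = B, n_regions = n,
         bin_size = if (inherits(m, "CoverageMatrix")) m$bin_size else 1L,
         group_label = if (inherits(m, "CoverageMatrix")) m$group_label else
           "regions",
         experiment = if (inherits(m, "CoverageMatrix")) m$experiment else
           "exp",
         units = if (inherits(m, "CoverageMatrix")) m$units else "raw"),
    class = "MetageneProfile"
  )
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile [", x$experiment, "/", x$group_label, "]: ",
      x$estimator, " of ", x$n_regions, " regions, ",
      length(x$curve), " bins (bin ", x$bin_size, "), ",
      x$level, "% ribbon from ", x$B, " bootstraps\n", sep = "")
  invisible(x)
}

#' Tabulate metagene profiles
#'
#' Long-format table of curve and ribbon values, one row per (experiment,
#' group, position). Positions are bin centers in bp relative to the region
#' center.
#'
#' @param profiles A `MetageneProfile` or list of them.
#' @param width Unbinned region width in bp; inferred from curve length x
#'   bin size when omitted.
#' @return A data frame with columns `experiment`, `group`, `position`,
#'   `value`, `ci_low`, `ci_high`.
#' @export
profile_table <- function(profiles, width = NULL) {
  if (inherits(profiles, "MetageneProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    nb <- length(p$curve)
    w <- if (is.null(width)) nb * p$bin_size else width
    pos <- (seq_len(nb) - 0.5) * p$bin_size - w / 2
    data.frame(experiment = p$experiment, group = p$group_label,
               position = pos, value = p$curve, ci_low = p$ribbon_low,
               ci_high = p$ribbon_high)
  })
  do.call(rbind, rows)
}
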