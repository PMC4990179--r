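#' Permutation test for a difference between two group profiles
#'
#' Tests whether the profiles of two region groups differ more than expected
#' if group membership were arbitrary. The observed statistic is
#' `metric(profile(A), profile(B))` with a *dissimilarity*-oriented metric
#' (larger = more different). For each of `N` rounds the rows of both
#' matrices are pooled and shuffled without replacement into pseudo-groups
#' of the original sizes, the two profiles are recomputed and the metric
#' re-evaluated. The p-value uses the add-one Monte-Carlo correction
#' `p = (n_extreme + 1) / (N + 1)`, counting ties as extreme, so `p` is
#' never exactly 0.
#'
#' Similarity-oriented metrics (e.g. [ratio_intersect()]) must be flipped
#' with [as_dissimilarity()] before use.
#'
#' @param mA,mB `CoverageMatrix` objects (or plain matrices) of equal width.
#' @param metric Function of two profiles returning a number or a
#'   `PseudometricResult`; larger values mean more different profiles.
#' @param N Number of permutation rounds (default 1000).
#' @param estimator Profile estimator, `"mean"` or `"median"`.
#' @param seed Optional integer for reproducibility.
#' @return A `PermutationResult`: list with `metric_name`, `observed`, `N`
#'   (rounds actually scored), `n_extreme`, `p_value`, `seed`.
#' @export
permutation_test <- function(mA, mB, metric = metric_mean_abs_diff,
                             N = 1000, estimator = c("mean", "median"),
                             seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  vA <- matrix_values(mA)
  vB <- matrix_values(mB)
  if (ncol(vA) != ncol(vB)) {
    stop("matrices differ in width (", ncol(vA), " vs ", ncol(vB), ")",
         call. = FALSE)
  }
  metric_name <- attr(metric, "metric_name")
  if (is.null(metric_name)) metric_name <- deparse(substitute(metric))[1L]
  observed <- metric_value(
    metric(aggregate_profile(vA, estimator), aggregate_profile(vB, estimator))
  )
  if (is.na(observed)) {
    stop("metric is undefined on the observed profiles", call. = FALSE)
  }
  pool <- rbind(vA, vB)
  nA <- nrow(vA)
  n <- nrow(pool)
  stats <- numeric(N)
  for (i in seq_len(N)) {
    perm <- sample.int(n)
    pa <- aggregate_profile(pool[perm[seq_len(nA)], , drop = FALSE],
                            estimator)
    pb <- aggregate_profile(pool[perm[-seq_len(nA)], , drop = FALSE],
                            estimator)
    stats[i] <- metric_value(metric(pa, pb))
  }
  dropped <- sum(is.na(stats))
  if (dropped > 0L) {
    warning(dropped, " permutation round(s) had an undefined metric and ",
            "were excluded", call. = FALSE)
    stats <- stats[!is.na(stats)]
  }
  N_eff <- length(stats)
  n_extreme <- sum(stats >= observed)
  structure(
    list(metric_name = metric_name, observed = observed, N = N_eff,
         n_extreme = n_extreme, p_value = (n_extreme + 1) / (N_eff + 1),
         seed = seed),
    class = "PermutationResult"
  )
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "PermutationResult: %s observed = %s, p = %.4g (%d of %d rounds >= observed)\n",
    x$metric_name, format(x$observed), x$p_value, x$n_extreme, x$N))
  invisible(x)
}

#' Flip a similarity metric into a dissimilarity
#'
#' Wraps a similarity-oriented metric `f` (1 = identical) as `1 - f`, the
#' orientation [permutation_test()] requires. The adapter is recorded in the
#' wrapped metric's name.
#'
#' @param f Metric function of two profiles.
#' @param name Base name for reporting; default taken from the call.
#' @return A dissimilarity metric function.
#' @export
as_dissimilarity <- function(f, name = deparse(substitute(f))[1L]) {
  g <- function(p1, p2) {
    v <- metric_value(f(p1, p2))
    if (is.na(v)) NA_real_ else 1 - v
  }
  attr(g, "metric_name") <- paste0("1-", name)
  g
}

#' Mean absolute difference between two profiles
#'
#' Default dissimilarity for [permutation_test()].
#'
#' @param p1,p2 Equal-length profiles.
#' @return Non-negative scalar, 0 iff the profiles coincide.
#' @export
metric_mean_abs_diff <- structure(
  function(p1, p2) mean(abs(p1 - p2)),
  metric_name = "mean_abs_diff"
)
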