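#' Read and validate a design sheet
#'
#' A design sheet relates alignment files to experiments. The first column,
#' headed `sample`, holds alignment-file paths; every additional column is
#' one named experiment, with cell codes `0` = sample unused, `1` = ChIP,
#' `2` = control. TSV and CSV are auto-detected from the file extension
#' (`.csv` is comma-separated, anything else tab-separated); a header row is
#' mandatory.
#'
#' Validation: codes must be in `{0, 1, 2}`, file paths must be distinct and
#' every experiment needs at least one ChIP sample. An experiment with no
#' control is legal but flagged with a warning — background subtraction is
#' skipped for it downstream.
#'
#' @param path Delimited text file.
#' @return A `DesignSheet`: the validated data frame, with the per-experiment
#'   role lists available through [design_experiments()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop("design sheet not found: '", path, "'", call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_design_sheet(df)
}

#' @rdname read_design
#' @param df Data frame in the same shape as the file (first column
#'   `sample`).
#' @export
as_design_sheet <- function(df) {
  if (ncol(df) < 2L) {
    stop("design sheet needs a 'sample' column plus >= 1 experiment column",
         call. = FALSE)
  }
  if (tolower(names(df)[1L]) != "sample") {
    stop("first design-sheet column must be headed 'sample', got '",
         names(df)[1L], "'", call. = FALSE)
  }
  names(df)[1L] <- "sample"
  if (anyDuplicated(df$sample)) {
    stop("duplicated alignment file in design sheet: '",
         df$sample[duplicated(df$sample)][1L], "'", call. = FALSE)
  }
  codes <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(codes) || anyNA(codes) || !all(codes %in% 0:2)) {
    stop("design codes must be 0 (unused), 1 (ChIP) or 2 (control)",
         call. = FALSE)
  }
  no_chip <- colnames(codes)[colSums(codes == 1) == 0]
  if (length(no_chip) > 0L) {
    stop("experiment '", no_chip[1L], "' has no ChIP sample", call. = FALSE)
  }
  no_ctrl <- colnames(codes)[colSums(codes == 2) == 0]
  for (ex in no_ctrl) {
    warning("experiment '", ex, "' has no control; background removal ",
            "will be skipped for it", call. = FALSE)
  }
  structure(df, class = c("DesignSheet", "data.frame"))
}

#' Per-experiment ChIP / control file lists
#'
#' @param design A `DesignSheet`.
#' @return Named list; each element is `list(chip = <paths>,
#'   control = <paths>)`.
#' @export
design_experiments <- function(design) {
  stopifnot(inherits(design, "DesignSheet"))
  exps <- names(design)[-1L]
  out <- lapply(exps, function(ex) {
    list(chip = design$sample[design[[ex]] == 1],
         control = design$sample[design[[ex]] == 2])
  })
  stats::setNames(out, exps)
}

#' Pool replicate coverage tracks
#'
#' Replicates of one role (ChIP or control) are pooled by summing raw
#' per-base counts; the pooled library size is the sum of the member library
#' sizes. Pooling happens on raw counts, before any normalization, so the
#' pooled track behaves like a single deeper library. The operation is
#' order-independent and associative.
#'
#' @param tracks List of `CoverageTrack`s computed over the same region
#'   group.
#' @return A single pooled `CoverageTrack`.
#' @export
merge_tracks <- function(tracks) {
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  if (length(tracks) == 0L) {
    stop("cannot merge zero coverage tracks", call. = FALSE)
  }
  stopifnot(all(vapply(tracks, inherits, logical(1), "CoverageTrack")))
  widths <- vapply(tracks, `[[`, numeric(1), "region_width")
  nreg <- vapply(tracks, function(t) length(t$coverage), integer(1))
  if (length(unique(widths)) != 1L || length(unique(nreg)) != 1L) {
    stop("tracks to merge must cover the same regions at the same width",
         call. = FALSE)
  }
  cov <- tracks[[1L]]$coverage
  for (t in tracks[-1L]) cov <- cov + t$coverage
  coverage_track(
    sample_id = paste(vapply(tracks, `[[`, character(1), "sample_id"),
                      collapse = "+"),
    coverage = cov,
    library_size = sum(vapply(tracks, `[[`, numeric(1), "library_size")),
    region_width = widths[1L]
  )
}
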