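#' Read genomic regions from a BED file
#'
#' Parses a 3- to 6-column BED file into a [GenomicRanges::GRanges] region
#' group. BED coordinates are 0-based half-open on disk; they are converted
#' to the 1-based closed convention of `GRanges` on import and converted back
#' by [write_bed()], so a read/write cycle round-trips the file exactly.
#'
#' Lines starting with `track`, `browser` or `#` are skipped. A missing name
#' column yields auto-generated identifiers `region_<i>`; a missing strand
#' column yields unstranded (`*`) regions.
#'
#' @param path Path to a BED file.
#' @param label Group label attached to the result (defaults to the file
#'   name without extension). Retrieved with [region_label()].
#' @return A `GRanges` with metadata columns `name` and `score`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tr1\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, label = NULL) {
  fields <- read_region_lines(path)
  if (is.null(label)) {
    label <- tools::file_path_sans_ext(basename(path))
  }
  if (length(fields) == 0L) {
    return(region_group(GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      name = character(), score = numeric()
    ), label))
  }
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in '", path,
         "': fewer than 3 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- parse_coord(fields, 2L, path)
  end0 <- parse_coord(fields, 3L, path)
  check_interval(start0, end0, path)
  name <- ifelse(ncol >= 4L, vapply(fields, `[`, character(1), 4L), NA)
  name[is.na(name) | name == "."] <- paste0("region_", which(is.na(name) | name == "."))
  score <- rep(NA_real_, length(fields))
  has_score <- ncol >= 5L
  score[has_score] <- suppressWarnings(
    as.numeric(vapply(fields[has_score], `[`, character(1), 5L))
  )
  strand <- rep("*", length(fields))
  if (any(ncol >= 6L)) {
    s <- vapply(fields[ncol >= 6L], `[`, character(1), 6L)
    bad_strand <- !s %in% c("+", "-", ".")
    if (any(bad_strand)) {
      stop("malformed BED line ", which(ncol >= 6L)[bad_strand][1L], " in '",
           path, "': strand must be one of '+', '-', '.'", call. = FALSE)
    }
    strand[ncol >= 6L] <- ifelse(s == ".", "*", s)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand, name = name, score = score
  )
  region_group(gr, label)
}

#' Read ENCODE narrowPeak or broadPeak regions
#'
#' Accepts the 10-column narrowPeak and the 9-column broadPeak formats,
#' dispatching on column count. The `signalValue` column (column 7 in both
#' formats) is stored in the `score` metadata column, so peak groups can be
#' stratified by enrichment with [stratify_by_score()].
#'
#' @inheritParams read_bed
#' @return A `GRanges` with metadata columns `name` and `score`
#'   (= signalValue).
#' @export
read_narrowpeak <- function(path, label = NULL) {
  fields <- read_region_lines(path)
  if (is.null(label)) {
    label <- tools::file_path_sans_ext(basename(path))
  }
  if (length(fields) == 0L) {
    return(region_group(GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      name = character(), score = numeric()
    ), label))
  }
  ncol <- lengths(fields)
  ok <- ncol %in% c(9L, 10L)
  if (!all(ok)) {
    stop("malformed narrowPeak/broadPeak line ", which(!ok)[1L], " in '",
         path, "': expected 10 (narrowPeak) or 9 (broadPeak) columns, got ",
         ncol[!ok][1L], call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- parse_coord(fields, 2L, path)
  end0 <- parse_coord(fields, 3L, path)
  check_interval(start0, end0, path)
  name <- vapply(fields, `[`, character(1), 4L)
  name[name == "."] <- paste0("region_", which(name == "."))
  strand <- vapply(fields, `[`, character(1), 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  signal <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 7L)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand, name = name, score = signal
  )
  region_group(gr, label)
}

#' Write a region group to BED
#'
#' Emits 6-column BED, converting back to 0-based half-open coordinates.
#' Unstranded regions are written with strand `.` and missing scores as 0.
#'
#' @param regions A `GRanges` region group.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  score <- regions$score
  if (is.null(score)) score <- rep(NA_real_, length(regions))
  score[is.na(score)] <- 0
  name <- regions$name
  if (is.null(name)) name <- paste0("region_", seq_along(regions))
  strand <- as.character(BiocGenerics::strand(regions))
  strand[strand == "*"] <- "."
  lines <- paste(
    as.character(GenomicRanges::seqnames(regions)),
    BiocGenerics::start(regions) - 1L,
    BiocGenerics::end(regions),
    name, score, strand,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Text file with lines `chrom<TAB>length`.
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' Resize regions to a fixed window around their centers
#'
#' Each region is replaced by the window `[center - flank, center + flank)`
#' (0-based half-open), where the center is the floor of the region midpoint.
#' All output regions share the uniform width `2 * flank` required for
#' coverage-matrix assembly. Regions whose window would extend below position
#' 0 or beyond the chromosome end are dropped with a warning: clamping would
#' break the uniform-width contract.
#'
#' @param regions A `GRanges` region group.
#' @param flank Half-window size in bp (> 0).
#' @param chrom_sizes Named vector of chromosome lengths, e.g. from
#'   [read_chrom_sizes()]. Regions on chromosomes absent from this map are
#'   dropped as out of bounds.
#' @return A `GRanges` of uniform width `2 * flank`.
#' @export
resize_regions <- function(regions, flank, chrom_sizes) {
  stopifnot(is.numeric(flank), length(flank) == 1L, flank > 0)
  flank <- as.integer(flank)
  # centers in the 0-based frame: floor((bed_start + bed_end) / 2)
  center0 <- floor((BiocGenerics::start(regions) - 1 +
                      BiocGenerics::end(regions)) / 2)
  new_start0 <- center0 - flank
  new_end0 <- center0 + flank
  chrom <- as.character(GenomicRanges::seqnames(regions))
  limit <- unname(chrom_sizes[chrom])
  keep <- new_start0 >= 0 & !is.na(limit) & new_end0 <= limit
  if (!all(keep)) {
    warning(sum(!keep), " region(s) dropped: resized window exceeds ",
            "chromosome bounds", call. = FALSE)
  }
  if (!any(keep)) {
    stop("no regions remain after resizing", call. = FALSE)
  }
  out <- regions[keep]
  IRanges::ranges(out) <- IRanges::IRanges(start = new_start0[keep] + 1L,
                                           end = new_end0[keep])
  region_group(out, region_label(regions))
}

#' Orient a per-region coverage vector 5'->3'
#'
#' Minus-strand vectors are reversed so that every region reads in the
#' 5'->3' direction; plus-strand and unstranded vectors pass through.
#' The operation is an involution: applying it twice returns the input.
#'
#' @param cov Numeric (or `Rle`) coverage vector over one region.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return The oriented vector, same class as the input.
#' @export
orient_region_coverage <- function(cov, strand) {
  strand <- as.character(strand)
  stopifnot(length(strand) == 1L, strand %in% c("+", "-", "*"))
  if (strand == "-") rev(cov) else cov
}

#' Stratify regions into four activity groups by score
#'
#' Splits a region group on a per-region activity score (e.g. CAGE tag
#' counts) into four groups: `none` (score exactly 0) and tertiles of the
#' nonzero scores (`low`, `moderate`, `high`). The quantile edges are
#' configurable. Ties are broken by region order so that group sizes differ
#' by at most one; the output partitions the input (disjoint, exhaustive).
#'
#' @param regions A `GRanges` with a non-negative numeric `score` column.
#' @param probs Quantile edges among the nonzero scores separating
#'   low/moderate and moderate/high (default tertiles).
#' @return Named list of four `GRanges`: `none`, `low`, `moderate`, `high`.
#' @export
stratify_by_score <- function(regions, probs = c(1 / 3, 2 / 3)) {
  score <- regions$score
  if (is.null(score) || anyNA(score) || any(score < 0)) {
    stop("every region needs a numeric score >= 0", call. = FALSE)
  }
  stopifnot(length(probs) == 2L, all(probs > 0 & probs < 1), probs[1] < probs[2])
  nz <- which(score > 0)
  if (length(nz) < 3L) {
    stop("fewer than 3 regions with nonzero score; cannot form tertiles",
         call. = FALSE)
  }
  ord <- nz[order(score[nz])]        # stable: ties keep input order
  n <- length(ord)
  cuts <- floor(n * c(0, probs, 1))
  groups <- list(
    none = regions[score == 0],
    low = regions[sort(ord[seq.int(cuts[1] + 1L, cuts[2])])],
    moderate = regions[sort(ord[seq.int(cuts[2] + 1L, cuts[3])])],
    high = regions[sort(ord[seq.int(cuts[3] + 1L, cuts[4])])]
  )
  Map(region_group, groups, names(groups))
}

#' Attach / retrieve a region-group label
#'
#' @param regions A `GRanges`.
#' @param label Group label (character scalar).
#' @return `region_group()` returns the labelled `GRanges`;
#'   `region_label()` the label.
#' @export
region_group <- function(regions, label) {
  S4Vectors::metadata(regions)$label <- as.character(label)
  regions
}

#' @rdname region_group
#' @export
region_label <- function(regions) {
  lab <- S4Vectors::metadata(regions)$label
  if (is.null(lab)) "regions" else lab
}

# -- internal parsing helpers -------------------------------------------------

read_region_lines <- function(path) {
  if (!file.exists(path)) {
    stop("region file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  strsplit(lines[keep], "\t", fixed = TRUE)
}

parse_coord <- function(fields, col, path) {
  raw <- vapply(fields, `[`, character(1), col)
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) | val != floor(val) | val < 0)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in '", path,
         "': non-integer coordinate '", raw[bad[1L]], "'", call. = FALSE)
  }
  as.integer(val)
}

check_interval <- function(start0, end0, path) {
  bad <- which(start0 >= end0)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in '", path, "': start (",
         start0[bad[1L]], ") must be < end (", end0[bad[1L]], ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
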