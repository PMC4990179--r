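#' Count aligned reads in a BAM file
#'
#' Counts mapped, primary, non-supplementary records — the library size used
#' for reads-per-million normalization. Duplicates are counted by default to
#' match raw-coverage semantics; set `include_duplicates = FALSE` to drop
#' records carrying the duplicate flag.
#'
#' @param path Coordinate-sorted, indexed BAM file.
#' @param include_duplicates Count records flagged as PCR/optical duplicates?
#' @return Number of aligned reads (integer).
#' @export
library_size <- function(path, include_duplicates = TRUE) {
  check_bam(path)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE
  )
  n <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(flag = flag)
  )$records
  if (n == 0L) {
    stop("no aligned reads in '", path,
         "': reads-per-million normalization is undefined", call. = FALSE)
  }
  n
}

#' Extract per-region read coverage from a BAM file
#'
#' Computes base-pair depth over every region of a uniform-width region
#' group. Depth at a base is the number of selected reads whose aligned span
#' covers it; reads partially overlapping a region contribute over the
#' overlap only. Coverage spans aligned segments including deletions (CIGAR
#' `D`) and excluding reference skips (`N`) — standard depth semantics.
#' Per-region vectors are stored run-length encoded ([S4Vectors::Rle]), the
#' same compression the coverage is computed in, so storage is proportional
#' to signal complexity rather than region width.
#'
#' Read selection: mapped, primary, non-supplementary records; duplicates
#' retained by default. Optionally each read is extended to `extend` bp from
#' its 5' end to approximate fragment coverage. Paired-end mates each
#' contribute their own aligned span.
#'
#' @param path Coordinate-sorted, indexed BAM file.
#' @param regions Uniform-width `GRanges` region group (see
#'   [resize_regions()]).
#' @param sample_id Identifier stored in the track (defaults to the file
#'   name).
#' @param include_duplicates Keep duplicate-flagged reads?
#' @param extend `NULL` for no extension, or fragment length in bp.
#' @return A `CoverageTrack`: list with `sample_id`, `coverage` (an
#'   [IRanges::RleList], one run-length encoded vector per region, in region
#'   order), `library_size` and `region_width`.
#' @export
region_coverage <- function(path, regions, sample_id = basename(path),
                            include_duplicates = TRUE, extend = NULL) {
  check_bam(path)
  width <- unique(BiocGenerics::width(regions))
  if (length(width) != 1L) {
    stop("regions must share one width; call resize_regions() first",
         call. = FALSE)
  }
  header_chroms <- names(Rsamtools::scanBamHeader(path)[[1]]$targets)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  present <- chrom %in% header_chroms
  if (!all(present)) {
    for (miss in unique(chrom[!present])) {
      warning("chromosome '", miss, "' absent from '", basename(path),
              "'; regions there get zero coverage", call. = FALSE)
    }
  }
  if (any(present)) {
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = if (include_duplicates) NA else FALSE
    )
    keep <- regions[present]
    which <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(keep)),
      ranges = IRanges::ranges(keep)
    ), ignore.strand = TRUE)
    aln <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(flag = flag, which = which,
                                            what = "qname")
    )
    # a read overlapping two query windows is returned once per window
    key <- paste(S4Vectors::mcols(aln)$qname, BiocGenerics::start(aln),
                 GenomicAlignments::cigar(aln), BiocGenerics::strand(aln))
    aln <- aln[!duplicated(key)]
    if (!is.null(extend)) {
      stopifnot(extend >= 1)
      spans <- GenomicRanges::resize(GenomicRanges::granges(aln),
                                     width = as.integer(extend),
                                     fix = "start")
      genome_cov <- GenomicRanges::coverage(spans)
    } else {
      genome_cov <- GenomicRanges::coverage(aln, drop.D.ranges = FALSE)
    }
  }
  vecs <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    if (!present[i] || !chrom[i] %in% names(genome_cov)) {
      vecs[[i]] <- S4Vectors::Rle(0L, width)
      next
    }
    chrom_cov <- genome_cov[[chrom[i]]]
    s <- BiocGenerics::start(regions)[i]
    e <- BiocGenerics::end(regions)[i]
    if (e > length(chrom_cov)) {        # region past last covered base
      pad <- e - length(chrom_cov)
      e <- length(chrom_cov)
      win <- if (s > e) S4Vectors::Rle(0L, 0L) else
        S4Vectors::window(chrom_cov, s, e)
      vecs[[i]] <- c(win, S4Vectors::Rle(0L, pad))
    } else {
      vecs[[i]] <- S4Vectors::window(chrom_cov, s, e)
    }
  }
  names(vecs) <- region_names(regions)
  coverage_track(
    sample_id = sample_id,
    coverage = methods::as(vecs, "RleList"),
    library_size = library_size(path, include_duplicates),
    region_width = width
  )
}

#' Construct a CoverageTrack
#'
#' @param sample_id Sample identifier.
#' @param coverage `RleList` of per-region depth vectors.
#' @param library_size Aligned-read count of the source file(s).
#' @param region_width Common region width (bp).
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(sample_id, coverage, library_size, region_width) {
  stopifnot(all(lengths(coverage) == region_width), library_size >= 1)
  structure(
    list(sample_id = sample_id, coverage = coverage,
         library_size = library_size, region_width = region_width),
    class = "CoverageTrack"
  )
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack '", x$sample_id, "': ", length(x$coverage),
      " regions x ", x$region_width, " bp, library size ",
      x$library_size, "\n", sep = "")
  invisible(x)
}

region_names <- function(regions) {
  nm <- regions$name
  if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
  nm
}

check_bam <- function(path) {
  if (!file.exists(path)) {
    stop("BAM file not found: '", path, "'", call. = FALSE)
  }
  bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(bai))) {
    stop("no index found for '", path,
         "'; create one with Rsamtools::indexBam() or `samtools index`",
         call. = FALSE)
  }
  invisible(TRUE)
}
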