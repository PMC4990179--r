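#' Default analysis configuration
#'
#' Returns the full set of pipeline settings with their defaults; any subset
#' can be overridden via `...` or supplied in a YAML file to
#' [run_metagene()]. Settings mirror the knobs of the individual stages:
#' `flank` (half-window around region centers, bp), `bin_size` (positions
#' per bin), `estimator`, `B` (bootstrap replicates), `level` (ribbon
#' percentage), `ncis_bin_size` (genome bin for the noise ratio),
#' `permutations` (rounds for pairwise group comparison, 0 = skip),
#' `stratify` (split one scored region file into four activity groups),
#' `include_duplicates`, `extend`, `seed`, `out_prefix`.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  config <- list(
    regions = NULL, design = NULL, chrom_sizes = NULL,
    flank = 1000, bin_size = 10, estimator = "mean", B = 1000, level = 95,
    ncis_bin_size = 1000, permutations = 0, stratify = FALSE,
    include_duplicates = TRUE, extend = NULL, seed = NULL, out_prefix = NULL
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0L) {
    stop("unknown config setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  config
}

#' Run the full metagene pipeline
#'
#' Orchestrates every stage: read and resize regions, parse the design
#' sheet, extract per-region coverage, estimate the ChIP/control noise
#' ratio and subtract scaled background (skipped with a warning for
#' experiments without a control), convert to RPM, orient 5'->3', bin,
#' aggregate per group and attach bootstrap ribbons. Optionally runs
#' pairwise permutation tests between group profiles.
#'
#' All randomness (bootstrap, permutations) flows from `config$seed`;
#' rerunning with an identical configuration reproduces the outputs
#' byte-identically.
#'
#' @param config A list from [default_config()], or a path to a YAML file of
#'   overrides. Required entries: `regions` (BED/narrowPeak path, or named
#'   list of paths — one region group each), `design` (design-sheet path, a
#'   data frame, or a `DesignSheet`), `chrom_sizes` (path or named vector).
#' @return A `MetageneAnalysis`: list with `profiles` (list of
#'   `MetageneProfile`), `table` (long-format profile table), `matrices`
#'   (binned RPM `CoverageMatrix` per experiment x group), `noise_ratios`,
#'   `comparisons` (permutation results, if requested), `config`. When
#'   `config$out_prefix` is set, writes `<prefix>_profiles.tsv`,
#'   `<prefix>_metadata.yml` and, with permutations,
#'   `<prefix>_comparisons.tsv`.
#' @export
run_metagene <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- default_config(config)
  for (key in c("regions", "design", "chrom_sizes")) {
    if (is.null(config[[key]])) {
      stop("config is missing required input '", key, "'", call. = FALSE)
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  chrom_sizes <- config$chrom_sizes
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)

  groups <- load_region_groups(config$regions, config$stratify)
  groups <- lapply(groups, resize_regions, flank = config$flank,
                   chrom_sizes = chrom_sizes)

  design <- config$design
  if (is.character(design)) design <- read_design(design)
  if (!inherits(design, "DesignSheet")) design <- as_design_sheet(design)
  experiments <- design_experiments(design)

  profiles <- list()
  matrices <- list()
  noise_ratios <- list()
  for (ex in names(experiments)) {
    roles <- experiments[[ex]]
    has_control <- length(roles$control) > 0L
    if (has_control) {
      chip_bins <- Reduce(`+`, lapply(roles$chip, bin_genome_counts,
                                      chrom_sizes = chrom_sizes,
                                      bin_size = config$ncis_bin_size))
      ctrl_bins <- Reduce(`+`, lapply(roles$control, bin_genome_counts,
                                      chrom_sizes = chrom_sizes,
                                      bin_size = config$ncis_bin_size))
      noise_ratios[[ex]] <- ncis_ratio(chip_bins, ctrl_bins,
                                       bin_size = config$ncis_bin_size)
    } else {
      warning("experiment '", ex, "' has no control; background ",
              "subtraction skipped", call. = FALSE)
    }
    for (g in names(groups)) {
      regions <- groups[[g]]
      chip <- merge_tracks(lapply(
        roles$chip, region_coverage, regions = regions,
        include_duplicates = config$include_duplicates,
        extend = config$extend
      ))
      cov <- chip$coverage
      if (has_control) {
        ctrl <- merge_tracks(lapply(
          roles$control, region_coverage, regions = regions,
          include_duplicates = config$include_duplicates,
          extend = config$extend
        ))
        cov <- methods::as(
          mapply(subtract_background, cov, ctrl$coverage,
                 MoreArgs = list(r = noise_ratios[[ex]]), SIMPLIFY = FALSE),
          "RleList"
        )
      }
      cov <- rpm_normalize(cov, chip$library_size)
      track <- coverage_track(chip$sample_id, cov, chip$library_size,
                              chip$region_width)
      m <- coverage_matrix(track, regions, orient = TRUE, group_label = g,
                           experiment = ex, units = "RPM")
      m <- bin_matrix(m, config$bin_size)
      key <- paste(ex, g, sep = ".")
      matrices[[key]] <- m
      profiles[[key]] <- bootstrap_ribbon(m, estimator = config$estimator,
                                          B = config$B, level = config$level)
    }
  }

  comparisons <- NULL
  if (config$permutations > 0L && length(groups) > 1L) {
    comparisons <- list()
    for (ex in names(experiments)) {
      pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
      for (pr in pairs) {
        key <- paste(ex, pr[1L], "vs", pr[2L], sep = ".")
        comparisons[[key]] <- permutation_test(
          matrices[[paste(ex, pr[1L], sep = ".")]],
          matrices[[paste(ex, pr[2L], sep = ".")]],
          metric = metric_mean_abs_diff, N = config$permutations,
          estimator = config$estimator
        )
      }
    }
  }

  table <- profile_table(profiles, width = 2 * config$flank)
  out <- structure(
    list(profiles = profiles, table = table, matrices = matrices,
         noise_ratios = noise_ratios, comparisons = comparisons,
         config = config),
    class = "MetageneAnalysis"
  )
  if (!is.null(config$out_prefix)) write_analysis(out)
  out
}

#' @export
print.MetageneAnalysis <- function(x, ...) {
  cat("MetageneAnalysis:", length(x$profiles), "profile(s),",
      length(x$noise_ratios), "noise ratio(s)\n")
  for (ex in names(x$noise_ratios)) {
    cat("  ", ex, ": r_hat = ", format(x$noise_ratios[[ex]]$r_hat), "\n",
        sep = "")
  }
  invisible(x)
}

load_region_groups <- function(regions, stratify) {
  read_one <- function(path, label = NULL) {
    if (grepl("\\.(narrowpeak|broadpeak)$", path, ignore.case = TRUE)) {
      read_narrowpeak(path, label)
    } else {
      read_bed(path, label)
    }
  }
  if (is.character(regions) && length(regions) == 1L && is.null(names(regions))) {
    gr <- read_one(regions)
    if (stratify) {
      return(stratify_by_score(gr))
    }
    return(stats::setNames(list(gr), region_label(gr)))
  }
  if (is.character(regions)) {
    labels <- names(regions)
    if (is.null(labels)) {
      labels <- tools::file_path_sans_ext(basename(regions))
    }
    return(stats::setNames(
      Map(read_one, regions, labels), labels
    ))
  }
  if (inherits(regions, "GRanges")) {
    return(stats::setNames(list(regions), region_label(regions)))
  }
  if (is.list(regions)) return(regions)
  stop("unsupported 'regions' input", call. = FALSE)
}

write_analysis <- function(x) {
  prefix <- x$config$out_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$table, paste0(prefix, "_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(
    package = "metaprofiler",
    version = as.character(utils::packageVersion("metaprofiler")),
    r_version = as.character(getRversion()),
    seed = x$config$seed,
    noise_ratios = lapply(x$noise_ratios, function(r)
      list(r_hat = r$r_hat, bin_size = r$bin_size,
           background_fraction = r$background_fraction)),
    config = x$config[!vapply(x$config, is.null, logical(1))]
  )
  yaml::write_yaml(meta, paste0(prefix, "_metadata.yml"))
  if (!is.null(x$comparisons)) {
    comp <- do.call(rbind, lapply(names(x$comparisons), function(k) {
      p <- x$comparisons[[k]]
      data.frame(comparison = k, metric = p$metric_name,
                 observed = p$observed, N = p$N, p_value = p$p_value)
    }))
    utils::write.table(comp, paste0(prefix, "_comparisons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Plot metagene profiles with confidence ribbons
#'
#' One curve plus translucent ribbon per region group; the x-axis is in bp
#' relative to the region center, the y-axis in the profile's units
#' (typically RPM). With four groups the default palette follows the
#' red / green / blue / purple convention for
#' none / low / moderate / high activity classes.
#'
#' @param profiles A `MetageneAnalysis`, a list of `MetageneProfile`s or a
#'   single profile.
#' @param palette Colors, recycled across groups.
#' @param file Optional output path (PNG/SVG/PDF by extension).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_metagene <- function(profiles,
                          palette = c("#E41A1C", "#4DAF4A", "#377EB8",
                                      "#984EA3"),
                          file = NULL) {
  if (inherits(profiles, "MetageneAnalysis")) profiles <- profiles$profiles
  if (inherits(profiles, "MetageneProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles to plot", call. = FALSE)
  lens <- vapply(profiles, function(p) length(p$curve), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles have mismatched curve lengths", call. = FALSE)
  }
  tab <- profile_table(profiles)
  units <- profiles[[1L]]$units
  colors <- rep_len(palette, length(unique(tab$group)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$position, y = .data$value,
    ymin = .data$ci_low, ymax = .data$ci_high,
    color = .data$group, fill = .data$group
  )) +
    ggplot2::geom_ribbon(alpha = 0.3, color = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = colors) +
    ggplot2::scale_fill_manual(values = colors) +
    ggplot2::labs(x = "position relative to region center (bp)",
                  y = paste0("occupancy (", units, ")"),
                  color = "group", fill = "group") +
    ggplot2::theme_bw()
  if (length(unique(tab$experiment)) > 1L) {
    p <- p + ggplot2::facet_wrap(~experiment)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5)
    return(invisible(p))
  }
  p
}

#' Export a coverage matrix for heatmap inspection
#'
#' Writes the regions x bins matrix as TSV, rows ordered by total coverage
#' (descending, default) or kept in input order, and optionally renders a
#' static heatmap image — a file-based stand-in for interactive region
#' browsing.
#'
#' @param m A `CoverageMatrix` (or plain matrix).
#' @param path Output TSV path.
#' @param order `"total"` or `"input"`.
#' @param image Optional PNG path for a rendered heatmap.
#' @return `path`, invisibly.
#' @export
export_heatmap_matrix <- function(m, path, order = c("total", "input"),
                                  image = NULL) {
  order <- match.arg(order)
  v <- matrix_values(m)
  if (nrow(v) == 0L || ncol(v) == 0L) {
    stop("empty coverage matrix", call. = FALSE)
  }
  if (is.null(rownames(v))) rownames(v) <- paste0("region_", seq_len(nrow(v)))
  if (order == "total") {
    v <- v[order(rowSums(v), decreasing = TRUE), , drop = FALSE]
  }
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(image)) {
    grDevices::png(image, width = 800, height = 600)
    graphics::image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                    axes = FALSE, col = grDevices::hcl.colors(64, "Inferno"),
                    xlab = "bin", ylab = "region")
    grDevices::dev.off()
  }
  invisible(path)
}
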