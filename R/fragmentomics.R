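# Fragmentation-profile features: per-bin short/long fragment ratios with
# GC correction, and chromosome-arm z-scores against an external healthy
# reference.
#
# Size windows: short = 100-150 bp, long = 151-220 bp (profile ratios);
# GC correction splits the two size classes at 150 bp with 150 inclusive
# to the short class, matching the ratio windows.

#' Build the analyzable genome bin set
#'
#' Filters a bin annotation table by the GC/mappability rule: bins with
#' average GC below 0.3 or average mappability below 0.9 are excluded
#' (strictly below; boundary values are retained). When `width` is larger
#' than the annotation granularity, consecutive annotation rows within a
#' chromosome arm are aggregated into `width`-sized bins first (GC and
#' mappability averaged).
#'
#' @param annotation Tibble: chrom, start, end, gc, mappability, and
#'   optionally arm (0-based half-open intervals).
#' @param width Target bin width in bp; `NULL` (default) keeps the
#'   annotation granularity.
#' @param min_gc,min_mappability Exclusion thresholds (defaults 0.3, 0.9).
#' @return A `genome_bins` tibble (sorted, non-overlapping, with `bin_id`).
#'   Attributes `n_input` and `n_retained` report the filter outcome.
#' @export
build_bins <- function(annotation, width = NULL, min_gc = 0.3,
                       min_mappability = 0.9) {
  ann <- tibble::as_tibble(annotation)
  req <- c("chrom", "start", "end", "gc", "mappability")
  if (!all(req %in% names(ann))) {
    abort(paste0("annotation needs columns: ", paste(req, collapse = ", ")))
  }
  ann <- dplyr::arrange(ann, .data$chrom, .data$start)
  if (!is.null(width)) {
    grp_arm <- if ("arm" %in% names(ann)) ann$arm else ann$chrom
    ann <- ann |>
      dplyr::mutate(.grp = grp_arm,
                    .bin = floor(.data$start / width)) |>
      dplyr::group_by(.data$chrom, .data$.grp, .data$.bin) |>
      dplyr::summarise(
        arm = dplyr::first(.data$.grp),
        start = min(.data$start), end = max(.data$end),
        gc = mean(.data$gc), mappability = mean(.data$mappability),
        .groups = "drop") |>
      dplyr::select(-".bin", -".grp") |>
      dplyr::arrange(.data$chrom, .data$start)
  }
  # non-overlap check within chromosome
  overlap <- ann |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < head(.data$end, -1)),
                     .groups = "drop")
  if (any(overlap$bad, na.rm = TRUE)) abort("annotation bins overlap")

  n_input <- nrow(ann)
  keep <- ann$gc >= min_gc & ann$mappability >= min_mappability
  bins <- ann[keep, ]
  bins$bin_id <- seq_len(nrow(bins))
  attr(bins, "n_input") <- n_input
  attr(bins, "n_retained") <- nrow(bins)
  class(bins) <- c("genome_bins", class(bins))
  bins
}

#' Count short and long fragments per genome bin
#'
#' Assigns each fragment to the bin containing its midpoint and counts
#' fragments in the short (100-150 bp) and long (151-220 bp) size classes.
#' Fragments outside 100-220 bp, with MAPQ below `min_mapq` (when a `mapq`
#' column is present), overlapping the optional blacklist, or falling
#' outside every retained bin are excluded. When a `weight` column is
#' present (from [gc_correct()]), weighted counts are accumulated instead.
#'
#' @param fragments Tibble: chrom, start, end, length (bp), optionally
#'   mapq, gc, weight (0-based half-open intervals).
#' @param bins A [build_bins()] result.
#' @param short_range,long_range Inclusive length windows.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param blacklist Optional tibble (chrom, start, end); fragments
#'   overlapping any region are dropped.
#' @return Tibble, one row per bin: bin_id, chrom, start, end, gc, arm
#'   (when present), short, long, ratio (`NA` where long = 0).
#' @export
bin_fragments <- function(fragments, bins, short_range = c(100, 150),
                          long_range = c(151, 220), min_mapq = 30,
                          blacklist = NULL) {
  fr <- tibble::as_tibble(fragments)
  if ("mapq" %in% names(fr)) fr <- fr[fr$mapq >= min_mapq, ]
  if (!is.null(blacklist) && nrow(blacklist)) {
    drop <- overlaps_any(fr, blacklist)
    fr <- fr[!drop, ]
  }
  fr <- fr[fr$length >= short_range[1] & fr$length <= long_range[2], ]
  idx <- match_fragment_bins(fr, bins)
  keep <- !is.na(idx)
  fr <- fr[keep, ]
  idx <- idx[keep]
  w <- if ("weight" %in% names(fr)) fr$weight else rep(1, nrow(fr))
  is_short <- fr$length <= short_range[2]
  short <- tapply(w * is_short, factor(idx, levels = seq_len(nrow(bins))),
                  sum, default = 0)
  long <- tapply(w * !is_short, factor(idx, levels = seq_len(nrow(bins))),
                 sum, default = 0)
  out <- tibble::as_tibble(bins[, intersect(
    c("bin_id", "chrom", "arm", "start", "end", "gc"), names(bins))])
  out$short <- as.numeric(short)
  out$long <- as.numeric(long)
  out$ratio <- ifelse(out$long > 0, out$short / out$long, NA_real_)
  out
}

# interval overlap of fragments against a small region table
overlaps_any <- function(fragments, regions) {
  hit <- rep(FALSE, nrow(fragments))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- hit | (fragments$chrom == r$chrom &
                    fragments$start < r$end & fragments$end > r$start)
  }
  hit
}

#' GC-correct fragment counts against a reference target distribution
#'
#' Weights each fragment by `target_freq / observed_freq` of its 1%-wide GC
#' stratum, independently for the short and long size classes (split at
#' `split_at`, inclusive to short). Weighted totals per size class are
#' preserved. An observed stratum absent from the sample but carrying
#' target mass cannot be reweighted; strata observed in the sample but
#' absent from the target get weight 0, with weights capped at `max_weight`
#' and a counted warning.
#'
#' @param fragments Fragment tibble with `length` and `gc`.
#' @param gc_target Target distribution from a healthy reference panel, as
#'   returned by `gc_strata_distribution()` (columns size_class,
#'   gc_stratum, freq).
#' @param split_at Size-class split (default 150, inclusive to short).
#' @param max_weight Cap on per-fragment weights (default 10).
#' @return `fragments` with a `weight` column appended (existing weights
#'   are replaced). Attribute `n_capped` counts capped weights.
#' @export
gc_correct <- function(fragments, gc_target, split_at = 150,
                       max_weight = 10) {
  fr <- tibble::as_tibble(fragments)
  obs <- gc_strata_distribution(fr, split_at = split_at)
  key <- function(cls, stratum) paste0(cls, "@", round(stratum * 100))
  obs_freq <- setNames(obs$freq, key(obs$size_class, obs$gc_stratum))
  tgt_freq <- setNames(gc_target$freq,
                       key(gc_target$size_class, gc_target$gc_stratum))
  cls <- ifelse(fr$length <= split_at, "short", "long")
  stratum <- pmin(floor(fr$gc / 0.01), 99L) * 0.01
  k <- key(cls, stratum)
  w <- unname(tgt_freq[k] / obs_freq[k])
  w[is.na(w)] <- 0  # stratum absent from target
  n_capped <- sum(w > max_weight)
  if (n_capped > 0) {
    warn(sprintf("%d fragment weight(s) capped at %g", n_capped, max_weight))
    w <- pmin(w, max_weight)
  }
  fr$weight <- w
  attr(fr, "n_capped") <- n_capped
  fr
}

#' Chromosome-arm z-scores against a healthy reference
#'
#' Converts per-arm fragment counts to within-sample fractions and centers
#' and scales them by the reference panel's per-arm means and SDs:
#' `z_a = (fraction_a - mean_a) / sd_a` over the 39 autosomal arms.
#'
#' @param arm_counts Tibble with columns `arm` and `count` (or a fragment
#'   tibble plus `annotation` to count from scratch).
#' @param arm_reference Tibble: arm, mean, sd (sd > 0), one row per arm.
#' @param annotation Optional bin annotation when `arm_counts` is a raw
#'   fragment table.
#' @return Tibble: arm, fraction, z.
#' @export
arm_zscores <- function(arm_counts, arm_reference, annotation = NULL) {
  if (!is.null(annotation)) {
    af <- arm_fractions(tibble::as_tibble(arm_counts), annotation)
  } else {
    ac <- tibble::as_tibble(arm_counts)
    stopifnot(all(c("arm", "count") %in% names(ac)))
    af <- tibble::tibble(arm = ac$arm,
                         fraction = ac$count / sum(ac$count))
  }
  ref <- tibble::as_tibble(arm_reference)
  if (!all(af$arm %in% ref$arm)) {
    abort("arm_reference does not cover all arms in the sample")
  }
  if (any(ref$sd <= 0)) {
    abort("arm_reference SDs must be > 0", class = "cfmonitor_config_error")
  }
  m <- ref$mean[match(af$arm, ref$arm)]
  s <- ref$sd[match(af$arm, ref$arm)]
  tibble::tibble(arm = af$arm, fraction = af$fraction,
                 z = (af$fraction - m) / s)
}

#' Arm-level median of copy-number segment log-ratios
#'
#' For each chromosome arm, takes the median log-ratio of the segments from
#' an external copy-number caller that intersect the arm; segments are
#' clipped to the arm extent before the median (a segment spanning the
#' centromere contributes to both arms).
#'
#' @param segments Tibble: chrom, start, end, log_ratio.
#' @param arms Tibble of arm extents: arm, chrom, start, end.
#' @return Tibble: arm, median_log_ratio (`NA` for arms with no segment),
#'   n_segments.
#' @export
arm_level_median <- function(segments, arms) {
  seg <- tibble::as_tibble(segments)
  arms <- tibble::as_tibble(arms)
  purrr::map(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    hit <- seg$chrom == a$chrom & seg$start < a$end & seg$end > a$start
    tibble::tibble(
      arm = a$arm,
      median_log_ratio = if (any(hit)) median(seg$log_ratio[hit]) else NA_real_,
      n_segments = sum(hit))
  }) |> purrr::list_rbind()
}

#' Correlate plasma arm z-scores with tumor arm-level copy number
#'
#' Pearson correlation between a plasma sample's arm z-scores and the
#' matched tumor's arm-level median log-ratios over the shared arms.
#'
#' @param plasma_z Tibble from [arm_zscores()] (arm, z).
#' @param tumor_medians Tibble from [arm_level_median()]
#'   (arm, median_log_ratio).
#' @return Tibble: estimate, p_value, n_arms.
#' @export
plasma_tumor_arm_correlation <- function(plasma_z, tumor_medians) {
  joined <- dplyr::inner_join(tibble::as_tibble(plasma_z),
                              tibble::as_tibble(tumor_medians),
                              by = "arm")
  joined <- joined[complete.cases(joined[, c("z", "median_log_ratio")]), ]
  if (nrow(joined) < 3) abort("fewer than 3 shared arms with data")
  ct <- cor.test(joined$z, joined$median_log_ratio, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n_arms = nrow(joined))
}

#' Full fragmentation profile for one plasma sample
#'
#' Convenience wrapper: GC-corrects the fragments, counts corrected short
#' and long fragments per bin, and computes arm z-scores from the raw
#' (uncorrected) arm representation.
#'
#' @param fragments Fragment tibble (chrom, start, end, length, gc,
#'   optionally mapq).
#' @param bins A [build_bins()] result.
#' @param gc_target Healthy-panel GC target distribution.
#' @param arm_reference Healthy-panel arm means/SDs.
#' @param ... Passed to [bin_fragments()].
#' @return A `fragmentation_profile` list: `bins` (per-bin tibble with
#'   corrected short/long counts and ratio) and `arm_z`.
#' @export
fragmentation_profile <- function(fragments, bins, gc_target,
                                  arm_reference, ...) {
  corrected <- gc_correct(fragments, gc_target)
  per_bin <- bin_fragments(corrected, bins, ...)
  az <- arm_zscores(fragments, arm_reference, annotation = bins)
  structure(list(bins = per_bin, arm_z = az),
            class = "fragmentation_profile")
}

#' @export
print.fragmentation_profile <- function(x, ...) {
  cat(sprintf("<fragmentation_profile> %d bins, median ratio %.3f, %d arms\n",
              nrow(x$bins), median(x$bins$ratio, na.rm = TRUE),
              nrow(x$arm_z)))
  invisible(x)
}

#' @describeIn fragmentation_profile Plot per-bin short/long ratios along
#'   the genome with arm boundaries.
#' @param object A `fragmentation_profile`.
#' @export
autoplot.fragmentation_profile <- function(object, ...) {
  df <- object$bins
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.5) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "genome bin", y = "short/long fragment ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}
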