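# Alignment-free repeat-element kmer landscapes: per-family diagnostic
# kmer counting, reference-time feature selection, within-sample scaling,
# and GC-corrected epigenetic 1-Mb coverage.

#' Construct a repeat kmer reference
#'
#' Validates and classes a diagnostic-kmer table: each feature belongs to a
#' repeat family (LINE, SINE, LTR, satellite, transposable-element classes)
#' and owns a set of kmers of a single fixed length, disjoint across
#' features.
#'
#' @param kmer_table Tibble with columns family, feature, kmer.
#' @return A `repeat_reference` tibble.
#' @export
repeat_reference <- function(kmer_table) {
  kt <- tibble::as_tibble(kmer_table)
  req <- c("family", "feature", "kmer")
  if (!all(req %in% names(kt)) || !nrow(kt)) {
    abort("repeat reference needs non-empty columns family, feature, kmer")
  }
  k <- unique(nchar(kt$kmer))
  if (length(k) != 1L) abort("all kmers must share one length k")
  if (anyDuplicated(kt$kmer)) {
    abort("kmer sets must be disjoint across features")
  }
  attr(kt, "k") <- k
  class(kt) <- c("repeat_reference", class(kt))
  kt
}

#' Simulate a small repeat kmer reference
#'
#' Random diagnostic kmers per feature for the configured repeat families,
#' guaranteed disjoint. Desk-scale stand-in for a genome-derived repeat
#' reference.
#'
#' @param config A [sim_config()].
#' @param features_per_family,kmers_per_feature Panel sizes.
#' @param k Kmer length (default 24).
#' @return A [repeat_reference()].
#' @export
simulate_repeat_reference <- function(config, features_per_family = 3L,
                                      kmers_per_feature = 4L, k = 24L) {
  set.seed(derive_seed(config$seed, 4242L))
  fams <- config$repeat_families$family
  n_kmers <- length(fams) * features_per_family * kmers_per_feature
  kmers <- character(0)
  while (length(kmers) < n_kmers) {
    cand <- vapply(seq_len(n_kmers - length(kmers)), function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))
    kmers <- unique(c(kmers, cand))
  }
  grid <- expand.grid(feature_i = seq_len(features_per_family),
                      family = fams, stringsAsFactors = FALSE)
  tab <- tibble::tibble(
    family = rep(grid$family, each = kmers_per_feature),
    feature = rep(sprintf("%s_%02d", grid$family, grid$feature_i),
                  each = kmers_per_feature),
    kmer = kmers[seq_len(nrow(grid) * kmers_per_feature)])
  repeat_reference(tab)
}

#' Count repeat kmer hits in reads
#'
#' A read increments a feature's count when it contains at least one of the
#' feature's diagnostic kmers; a read hitting kmers of several features
#' increments each of them. Rates are reported per million reads. Uses
#' Biostrings dictionary matching when available, otherwise a fixed-string
#' scan.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param reference A [repeat_reference()].
#' @return A `repeat_landscape` tibble: family, feature, count,
#'   rate_per_million (`NA` with zero reads), reads_total.
#' @export
count_repeat_kmers <- function(reads, reference) {
  if (!inherits(reference, "repeat_reference")) {
    reference <- repeat_reference(reference)
  }
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- as.character(reads)
  n_reads <- length(reads)
  feats <- dplyr::distinct(tibble::as_tibble(reference),
                           .data$family, .data$feature)
  counts <- integer(nrow(feats))
  if (n_reads > 0) {
    use_bs <- requireNamespace("Biostrings", quietly = TRUE)
    if (use_bs) {
      subj <- Biostrings::DNAStringSet(reads)
      dict <- Biostrings::PDict(Biostrings::DNAStringSet(reference$kmer))
      hits <- Biostrings::vwhichPDict(dict, subj)  # per read: kmer indices
      feat_of_kmer <- match(reference$feature, feats$feature)
      for (h in hits) {
        if (length(h)) {
          counts_idx <- unique(feat_of_kmer[h])
          counts[counts_idx] <- counts[counts_idx] + 1L
        }
      }
    } else {
      for (j in seq_len(nrow(feats))) {
        kms <- reference$kmer[reference$feature == feats$feature[j]]
        hit <- rep(FALSE, n_reads)
        for (km in kms) {
          hit <- hit | grepl(km, reads, fixed = TRUE)
        }
        counts[j] <- sum(hit)
      }
    }
  }
  out <- tibble::tibble(
    family = feats$family,
    feature = feats$feature,
    count = counts,
    rate_per_million = if (n_reads > 0) counts / n_reads * 1e6 else NA_real_,
    reads_total = n_reads)
  if (n_reads == 0) attr(out, "no_reads") <- TRUE
  class(out) <- c("repeat_landscape", class(out))
  out
}

#' Select repeat features and scale landscapes within samples
#'
#' Feature selection happens once, on a reference cohort: a feature enters
#' the locked panel when its mean rate across the reference cohort exceeds
#' `min_rate` kmers per million aligned reads (strictly greater). Per
#' sample, panel features are then centered to mean 0 and scaled to SD 1
#' within each repeat family (sample SD, denominator n-1; a family whose
#' features are identical scales to all zeros).
#'
#' @param landscapes Tibble of landscapes across samples: sample_id,
#'   family, feature, rate_per_million.
#' @param panel Optional previously locked character vector of feature
#'   names; when supplied, selection is skipped (scoring never changes a
#'   locked panel).
#' @param min_rate Selection threshold in kmers per million (default 1000).
#' @return List: `panel` (character), `scaled` (tibble sample_id, family,
#'   feature, value).
#' @export
select_and_scale <- function(landscapes, panel = NULL, min_rate = 1000) {
  ls <- tibble::as_tibble(landscapes)
  req <- c("sample_id", "family", "feature", "rate_per_million")
  if (!all(req %in% names(ls))) {
    abort(paste0("landscapes need columns: ", paste(req, collapse = ", ")))
  }
  if (is.null(panel)) {
    panel <- ls |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(mean_rate = mean(.data$rate_per_million),
                       .groups = "drop") |>
      dplyr::filter(.data$mean_rate > min_rate) |>
      dplyr::pull(.data$feature)
  }
  scaled <- ls |>
    dplyr::filter(.data$feature %in% panel) |>
    dplyr::group_by(.data$sample_id, .data$family) |>
    dplyr::mutate(value = {
      v <- .data$rate_per_million
      s <- sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "family", "feature", "value")
  list(panel = sort(panel), scaled = scaled)
}

#' GC-corrected coverage in epigenetic 1-Mb bins
#'
#' Counts fragments per bin from a list of bins with high density of
#' epigenetic marks, applies the fragmentomic GC weighting, and normalizes
#' to the sample total so samples of different depth are comparable.
#'
#' @param fragments Fragment tibble (chrom, start, end, length, gc).
#' @param epi_bins Tibble of bins: chrom, start, end (plus optional
#'   bin_id).
#' @param gc_target Optional GC target distribution; when `NULL` no
#'   correction is applied.
#' @return Tibble: bin_id, chrom, start, end, count (weighted), coverage
#'   (normalized to sum 1).
#' @export
epigenetic_coverage <- function(fragments, epi_bins, gc_target = NULL) {
  fr <- tibble::as_tibble(fragments)
  eb <- tibble::as_tibble(epi_bins)
  if (!"bin_id" %in% names(eb)) eb$bin_id <- seq_len(nrow(eb))
  if (!is.null(gc_target)) {
    fr <- gc_correct(fr, gc_target)
  } else {
    fr$weight <- 1
  }
  idx <- match_fragment_bins(fr, eb)
  keep <- !is.na(idx)
  w <- tapply(fr$weight[keep],
              factor(idx[keep], levels = seq_len(nrow(eb))),
              sum, default = 0)
  eb$count <- as.numeric(w)
  total <- sum(eb$count)
  eb$coverage <- if (total > 0) eb$count / total else NA_real_
  eb
}
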