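# Tumor-informed genome-wide mutant allele fraction (WGMAF) from plasma
# pileup evidence at the patient's somatic variant positions.

#' Consensus filter for per-fragment base evidence
#'
#' A fragment contributes exactly one base call at a variant position iff it
#' is a proper pair at the aligner's maximum mapping quality, not a PCR or
#' optical duplicate, neither mate carries 5 or more uncalled (N) bases,
#' both mates cover the position with base quality >= 30, both called bases
#' are either the reference or the mutant allele, and the two mates agree.
#' Rejections are recorded with the first violated clause as reason.
#'
#' @param calls Tibble of fragment base calls (see
#'   [simulate_plasma_pileup()] for the schema: chrom, pos, fragment_id,
#'   proper_pair, mapq, duplicate_flag, n_bases_r1/r2, r1_base/r2_base,
#'   r1_qual/r2_qual).
#' @param mutations Tibble of passing variants with chrom, pos,
#'   ref_allele, alt_allele (1-based positions).
#' @param max_mapq Mapping quality required for acceptance, the aligner's
#'   maximum (default 42); acceptance requires equality.
#' @param max_n_bases A mate with this many or more uncalled bases
#'   disqualifies the pair (default 5).
#' @param min_base_qual Minimum Phred base quality on both mates
#'   (default 30).
#' @return Tibble, one row per fragment x position: chrom, pos,
#'   `accepted`, `reason` (`NA` when accepted), `consensus_base`,
#'   `is_mutant`. Calls at positions absent from `mutations` error.
#' @export
consensus_filter <- function(calls, mutations, max_mapq = 42,
                             max_n_bases = 5, min_base_qual = 30) {
  calls <- tibble::as_tibble(calls)
  mut <- tibble::as_tibble(mutations)
  if ("pass" %in% names(mut)) mut <- dplyr::filter(mut, .data$pass)
  key_calls <- paste0(calls$chrom, ":", calls$pos)
  key_mut <- paste0(mut$chrom, ":", mut$pos)
  hit <- match(key_calls, key_mut)
  if (anyNA(hit) && nrow(calls)) {
    abort("pileup contains positions absent from the mutation set")
  }
  ref <- mut$ref_allele[hit]
  alt <- mut$alt_allele[hit]

  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  fail <- function(cond, msg) {
    newly <- cond & is.na(reason)
    reason[newly] <<- msg
  }
  fail(!calls$proper_pair, "not a proper pair")
  fail(calls$mapq != max_mapq, "mapping quality below maximum")
  fail(calls$duplicate_flag, "duplicate")
  fail(calls$n_bases_r1 >= max_n_bases | calls$n_bases_r2 >= max_n_bases,
       "too many uncalled bases")
  fail(is.na(calls$r1_base) | is.na(calls$r2_base),
       "mate missing at position")
  fail(calls$r1_qual < min_base_qual | calls$r2_qual < min_base_qual,
       "base quality below 30")
  fail(!(calls$r1_base %in% c("A", "C", "G", "T") &
           calls$r2_base %in% c("A", "C", "G", "T")) |
         calls$r1_base != ref & calls$r1_base != alt |
         calls$r2_base != ref & calls$r2_base != alt,
       "base not ref or alt")
  fail(calls$r1_base != calls$r2_base, "mate disagreement")

  accepted <- is.na(reason)
  tibble::tibble(
    chrom = calls$chrom,
    pos = calls$pos,
    fragment_id = calls$fragment_id,
    accepted = accepted,
    reason = reason,
    consensus_base = ifelse(accepted, calls$r1_base, NA_character_),
    is_mutant = ifelse(accepted, calls$r1_base == alt, NA)
  )
}

#' Compute the genome-wide mutant allele fraction
#'
#' Sums accepted mutant and total base observations across all variant
#' positions genome-wide: `maf = M / T` where `M` is the mutant count and
#' `T` the total accepted count. A sample with no informative coverage
#' (`T = 0`) yields a missing MAF flagged accordingly. The confidence
#' interval is computed on the logit scale and back-transformed (see
#' [logit_interval()]).
#'
#' @param observations Output of [consensus_filter()] (rejected rows are
#'   ignored), or any tibble with `accepted`, `is_mutant`, `chrom`, `pos`.
#' @param level Confidence level (default 0.95).
#' @return A `wgmaf_result` object with fields mutant_count, total_count,
#'   maf, ci_low, ci_high, n_positions_covered, no_coverage.
#' @examples
#' obs <- tibble::tibble(chrom = "chr1", pos = rep(1:3, c(10, 5, 5)),
#'                       accepted = TRUE,
#'                       is_mutant = rep(c(TRUE, FALSE), c(3, 17)))
#' compute_wgmaf(obs)$maf # 0.15
#' @export
compute_wgmaf <- function(observations, level = 0.95) {
  obs <- dplyr::filter(tibble::as_tibble(observations), .data$accepted)
  M <- sum(obs$is_mutant)
  T_ <- nrow(obs)
  n_pos <- dplyr::n_distinct(paste0(obs$chrom, ":", obs$pos))
  if (T_ == 0) {
    res <- list(mutant_count = 0L, total_count = 0L, maf = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_,
                n_positions_covered = 0L, no_coverage = TRUE,
                level = level)
  } else {
    ci <- logit_interval(M, T_, level = level)
    res <- list(mutant_count = as.integer(M), total_count = as.integer(T_),
                maf = M / T_, ci_low = ci[["ci_low"]],
                ci_high = ci[["ci_high"]],
                n_positions_covered = as.integer(n_pos),
                no_coverage = FALSE, level = level)
  }
  structure(res, class = "wgmaf_result")
}

#' @export
print.wgmaf_result <- function(x, ...) {
  if (x$no_coverage) {
    cat("<wgmaf_result> no informative coverage\n")
  } else {
    cat(sprintf("<wgmaf_result> MAF %.4g (%d/%d bases, %d positions), %g%% CI [%.4g, %.4g]\n",
                x$maf, x$mutant_count, x$total_count,
                x$n_positions_covered, 100 * x$level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Probability of observing circulating tumor DNA
#'
#' Closed-form detection probability under independent sampling: with `n`
#' tumor mutations, tumor fraction `f`, and a mean plasma depth of `d`
#' fragments per variant position, the chance that at least one mutant
#' base is observed is `1 - (1 - f)^(n * d)`. At 50 mutations, 1% tumor
#' fraction and depth 3 this exceeds 0.75, the basis of the 50-mutation
#' evaluability threshold.
#'
#' @param n_mutations Number of tumor mutations (vectorized).
#' @param tumor_fraction Tumor fraction in [0, 1] (vectorized).
#' @param depth Mean fragments per variant position (> 0).
#' @return Detection probability in [0, 1].
#' @examples
#' detection_probability(50, 0.01, 3) # ~0.779
#' @export
detection_probability <- function(n_mutations, tumor_fraction, depth) {
  if (any(n_mutations < 0)) abort("`n_mutations` must be >= 0")
  assert_prob(tumor_fraction, "tumor_fraction")
  assert_pos(depth, "depth")
  1 - (1 - tumor_fraction)^(n_mutations * depth)
}

#' Logit-scale confidence interval for a proportion
#'
#' Wald interval computed on the logit scale and back-transformed with the
#' inverse logit. Degenerate counts (`m = 0` or `m = t`) use a 0.5-count
#' continuity adjustment so the interval stays defined (complete molecular
#' responders routinely have zero mutant observations). With `level = 0`
#' the interval collapses to the point estimate.
#'
#' @param m Mutant (success) count.
#' @param t Total count (> 0).
#' @param level Confidence level in [0, 1).
#' @return Named numeric vector `c(ci_low =, ci_high =)`.
#' @examples
#' logit_interval(50, 100)
#' @export
logit_interval <- function(m, t, level = 0.95) {
  if (t <= 0) abort("`t` must be > 0 for an interval", class = "cfmonitor_no_coverage")
  if (m < 0 || m > t) abort("`m` must lie in [0, t]")
  adj <- m == 0 || m == t
  m_a <- m + 0.5 * adj
  t_a <- t + 1 * adj
  p <- m_a / t_a
  if (level <= 0) {
    est <- m / t
    return(c(ci_low = est, ci_high = est))
  }
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / m_a + 1 / (t_a - m_a))
  lo <- inv_logit(logit(p) - z * se)
  hi <- inv_logit(logit(p) + z * se)
  if (m == 0) lo <- 0
  if (m == t) hi <- 1
  c(ci_low = lo, ci_high = hi)
}

#' Correlation between two molecular score series
#'
#' Pearson correlation of paired scores after an optional transform; pairs
#' with a missing value in either series are dropped and counted. Used to
#' compare the genome-wide MAF against an orthogonal targeted-sequencing
#' MAF, typically on the log scale.
#'
#' @param series_a,series_b Paired numeric vectors (length >= 3).
#' @param transform One of "identity", "log10", "logit". For "log10"/
#'   "logit", non-positive (or out-of-(0,1)) values become missing and are
#'   dropped.
#' @return Tibble: estimate (r), p_value, n_used, n_dropped, transform.
#' @export
score_correlation <- function(series_a, series_b,
                              transform = c("identity", "log10", "logit")) {
  transform <- match.arg(transform)
  if (length(series_a) != length(series_b)) {
    abort("series must have equal length")
  }
  tf <- switch(transform,
               identity = identity,
               log10 = function(x) ifelse(x > 0, log10(x), NA_real_),
               logit = function(x) ifelse(x > 0 & x < 1, logit(x), NA_real_))
  a <- tf(as.numeric(series_a))
  b <- tf(as.numeric(series_b))
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) abort("fewer than 3 complete pairs")
  ct <- cor.test(a[keep], b[keep], method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n_used = sum(keep),
    n_dropped = sum(!keep),
    transform = transform)
}

#' @export
tidy.wgmaf_result <- function(x, ...) {
  tibble::tibble(
    mutant_count = x$mutant_count,
    total_count = x$total_count,
    maf = x$maf,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    n_positions_covered = x$n_positions_covered,
    no_coverage = x$no_coverage)
}

#' @export
glance.wgmaf_result <- function(x, ...) {
  tibble::tibble(maf = x$maf, total_count = x$total_count,
                 level = x$level, no_coverage = x$no_coverage)
}
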