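# A/B-compartment comparison of plasma fragmentation profiles and
# extraction of a tumor component from high-burden plasma samples.
#
# A compartment track assigns each 100-kb bin a signed eigenvalue; the
# sign defines the chromatin domain (A = open = positive, B = closed).

#' Identify informative compartment bins
#'
#' A bin is informative when the two reference tracks disagree in domain
#' (eigenvalue sign), or when their eigenvalue difference, z-standardized
#' over all bins, exceeds +/- `z_cut` (default 1.96). Selection is
#' symmetric in track order.
#'
#' @param track_a,track_b Tibbles with columns `bin` and `eigen`, aligned
#'   on the same bins.
#' @param z_cut Z threshold on the standardized eigenvalue difference.
#' @return Tibble: bin, eigen_a, eigen_b, domain_differs, z_diff,
#'   informative.
#' @export
informative_bins <- function(track_a, track_b, z_cut = 1.96) {
  a <- tibble::as_tibble(track_a)
  b <- tibble::as_tibble(track_b)
  if (!identical(a$bin, b$bin)) {
    abort("tracks must be aligned on identical bins")
  }
  diff <- a$eigen - b$eigen
  s <- sd(diff)
  z <- if (is.finite(s) && s > 0) (diff - mean(diff)) / s else
    rep(0, length(diff))
  domain_differs <- sign(a$eigen) != sign(b$eigen)
  tibble::tibble(
    bin = a$bin,
    eigen_a = a$eigen,
    eigen_b = b$eigen,
    domain_differs = domain_differs,
    z_diff = z,
    informative = domain_differs | abs(z) > z_cut)
}

#' Extract the tumor component from plasma profiles
#'
#' Models each plasma profile as a two-source mixture of the healthy
#' median profile and an unknown tumor component with mixing weight `w`
#' (the sample's tumor fraction, e.g. from the genome-wide MAF):
#' `plasma = (1 - w) * healthy + w * component`. Inverting per sample and
#' taking the across-sample median per bin yields the cohort tumor
#' component estimate. Samples with `w = 0` carry no tumor signal and are
#' excluded with a warning; the inversion is exact on noiseless mixtures
#' for any `w` in (0, 1].
#'
#' @param plasma Matrix or tibble of plasma profiles (bins x samples).
#' @param healthy Numeric vector: healthy median profile on the same bins.
#' @param w Numeric vector of per-sample mixing weights in [0, 1].
#' @return List: `component` (per-bin median component), `per_sample`
#'   (bins x samples matrix), `weights_used`.
#' @examples
#' h <- c(1, -1, 0.5)
#' tumor <- c(-1, 1, 0.2)
#' plasma <- 0.7 * h + 0.3 * tumor
#' extract_component(matrix(plasma), h, 0.3)$component # recovers tumor
#' @export
extract_component <- function(plasma, healthy, w) {
  p <- as.matrix(plasma)
  if (nrow(p) != length(healthy)) {
    abort("plasma and healthy profiles must share bins")
  }
  if (ncol(p) != length(w)) abort("one weight per sample required")
  assert_prob(w, "w")
  keep <- w > 0
  if (!any(keep)) abort("no sample with w > 0")
  if (any(!keep)) {
    warn(sprintf("excluding %d sample(s) with w = 0", sum(!keep)))
  }
  p <- p[, keep, drop = FALSE]
  wk <- w[keep]
  # component_s = (plasma_s - (1 - w_s) * healthy) / w_s
  comp <- sweep(p - outer(healthy, 1 - wk), 2, wk, "/")
  list(component = apply(comp, 1, median),
       per_sample = comp,
       weights_used = wk)
}

#' Similarity of a profile to reference compartment tracks
#'
#' Pearson correlation of a plasma profile or extracted component with
#' each reference track over the informative bins, with the tracks ranked
#' by similarity.
#'
#' @param profile Numeric vector over all bins.
#' @param tracks Named list of numeric vectors (reference tracks) over the
#'   same bins.
#' @param informative Logical vector (or [informative_bins()] result)
#'   selecting bins; `NULL` uses all bins.
#' @return Tibble: track, estimate, rank (1 = most similar).
#' @export
track_similarity <- function(profile, tracks, informative = NULL) {
  if (is.data.frame(informative)) informative <- informative$informative
  sel <- informative %||% rep(TRUE, length(profile))
  res <- purrr::imap(tracks, function(tr, nm) {
    tibble::tibble(track = nm,
                   estimate = cor(profile[sel], tr[sel]))
  }) |> purrr::list_rbind()
  res$rank <- rank(-res$estimate, ties.method = "first")
  res
}

#' Z-score a fragmentation profile onto the compartment eigen scale
#'
#' Compartment tracks are signed eigenvalues; a plasma short/long ratio
#' profile is brought to a comparable scale by z-scoring the per-bin
#' ratios across bins.
#'
#' @param ratios Numeric vector of per-bin short/long ratios.
#' @return Z-scored vector (mean 0, SD 1 over non-missing bins).
#' @export
profile_to_eigen_scale <- function(ratios) {
  as.numeric(scale(ratios))
}
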