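#' Autosomal chromosome arms used for arm-level analyses
#'
#' The 39 autosomal arms: p and q arms of chromosomes 1-22, excluding the
#' acrocentric short arms 13p, 14p, 15p, 21p and 22p, which carry almost no
#' uniquely mappable sequence.
#'
#' @return Character vector of 39 arm labels ("1p", "1q", ..., "22q").
#' @export
autosomal_arms <- function() {
  acrocentric <- c("13p", "14p", "15p", "21p", "22p")
  arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  setdiff(arms, acrocentric)
}

default_arm_effects <- function() {
  # Gain/loss pattern typical of pancreatic ductal adenocarcinoma:
  # recurrent gains on 1q, 5p, 7p, 8q; losses on 1p, 3p, 6p, 6q, 9p, 17p, 18q.
  eff <- setNames(rep(0, length(autosomal_arms())), autosomal_arms())
  eff[c("1q", "8q", "5p", "7p")] <- 1
  eff[c("1p", "3p", "6p", "6q", "9p", "17p", "18q")] <- -1
  eff
}

default_repeat_families <- function() {
  # per-family base kmer rates (per million reads) and relative shift per
  # unit tumor fraction; satellites respond most strongly
  tibble::tibble(
    family = c("LINE", "SINE", "LTR", "SAT", "TE"),
    base_rate = c(3000, 2600, 1600, 1400, 1100),
    shift = c(0.5, -0.3, 0.25, 0.9, 0.35)
  )
}

#' Configuration for the synthetic cfDNA monitoring cohort
#'
#' Collects every parameter of the synthetic data generator: cohort size,
#' plasma sequencing depth at variant positions, tumor-fraction trajectories,
#' sequencing artifact rates, fragment-length mixture, per-arm copy-number
#' effect profile, repeat-family kmer shifts, and the survival model coupling
#' outcome to molecular response.
#'
#' Defaults describe the study conditions the package targets: baseline
#' plasma tumor fractions log-normal with median ~4.9%, tumor mutation counts
#' log-uniform between 9 and 20000 (including a hypermutator tail), mean
#' plasma depth of 3 fragments per variant position, cfDNA fragment length
#' modes of 167 bp (healthy) and 145 bp (tumor-derived), and a true hazard
#' ratio of 0.29 between molecular responders and nonresponders.
#'
#' @param seed Integer master seed; all substreams derive from it.
#' @param n_patients Number of patients.
#' @param n_timepoints Plasma draws per patient (first is baseline).
#' @param plasma_depth Mean fragments overlapping each variant position.
#' @param baseline_tf_median,baseline_tf_sdlog Log-normal parameters of the
#'   baseline tumor fraction (median on the natural scale, sdlog on the log
#'   scale).
#' @param responder_fraction Probability a patient is a true responder.
#' @param responder_multiplier,nonresponder_multiplier Named vectors
#'   `c(meanlog=, sdlog=)` for the per-patient log-normal multiplier applied
#'   to the tumor fraction at each successive on-treatment draw.
#' @param n_mutations_range Range of the log-uniform tumor mutation count.
#' @param sequencing_error_rate Per-base substitution probability.
#' @param duplicate_rate,discordant_mate_rate,low_mapq_rate,low_qual_rate,many_n_rate
#'   Rates of injected pileup artifacts (PCR duplicates, improper pairs,
#'   MAPQ below maximum, base quality below 30, mates with >= 5 N bases).
#' @param true_hazard_ratio Hazard ratio of responders vs nonresponders.
#' @param censoring_rate Expected fraction of censored observations.
#' @param median_survival_nonresponder Median overall survival (days) of
#'   nonresponders, anchoring the baseline hazard.
#' @param fragment_length_healthy,fragment_length_tumor Named vectors
#'   `c(mode=, sd=)` in bp for the two fragment-length mixture components.
#' @param fragments_per_sample Genome-wide fragments simulated per plasma
#'   sample (a desk-scale stand-in for tens of millions of real fragments).
#' @param arm_effect_profile Named vector over [autosomal_arms()] with values
#'   in `{-1, 0, 1}` giving the gain/loss direction per arm.
#' @param arm_gain_scale Fractional change of an affected arm's fragment
#'   count at tumor fraction 1.
#' @param arm_z_scale Arm z-score displacement per unit tumor fraction in
#'   summary-level feature simulation.
#' @param repeat_families Tibble with columns `family`, `base_rate` (kmers
#'   per million reads), `shift` (relative rate change per unit tumor
#'   fraction).
#' @param bins_per_arm,bin_width Synthetic genome tiling: bins per arm and
#'   bin width in bp.
#' @param n_reference_healthy Healthy samples in the reference panel.
#' @param n_training_per_class Cancer and non-cancer samples in the labeled
#'   training cohort.
#' @return A `sim_config` object (validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_patients = 4, fragments_per_sample = 2000)
#' cfg$plasma_depth
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 40L,
                       n_timepoints = 5L,
                       plasma_depth = 3,
                       baseline_tf_median = 0.049,
                       baseline_tf_sdlog = 1,
                       responder_fraction = 0.5,
                       responder_multiplier = c(meanlog = log(0.08), sdlog = 0.6),
                       nonresponder_multiplier = c(meanlog = log(1.3), sdlog = 0.4),
                       n_mutations_range = c(9, 20000),
                       sequencing_error_rate = 1e-3,
                       duplicate_rate = 0.05,
                       discordant_mate_rate = 0.02,
                       low_mapq_rate = 0.05,
                       low_qual_rate = 0.02,
                       many_n_rate = 0.01,
                       true_hazard_ratio = 0.29,
                       censoring_rate = 0.1,
                       median_survival_nonresponder = 126,
                       fragment_length_healthy = c(mode = 167, sd = 10),
                       fragment_length_tumor = c(mode = 145, sd = 12),
                       fragments_per_sample = 2e5,
                       arm_effect_profile = default_arm_effects(),
                       arm_gain_scale = 0.5,
                       arm_z_scale = 30,
                       repeat_families = default_repeat_families(),
                       bins_per_arm = 12L,
                       bin_width = 5e5,
                       n_reference_healthy = 20L,
                       n_training_per_class = 60L) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    n_timepoints = as.integer(n_timepoints),
    plasma_depth = plasma_depth,
    baseline_tf_median = baseline_tf_median,
    baseline_tf_sdlog = baseline_tf_sdlog,
    responder_fraction = responder_fraction,
    responder_multiplier = responder_multiplier,
    nonresponder_multiplier = nonresponder_multiplier,
    n_mutations_range = n_mutations_range,
    sequencing_error_rate = sequencing_error_rate,
    duplicate_rate = duplicate_rate,
    discordant_mate_rate = discordant_mate_rate,
    low_mapq_rate = low_mapq_rate,
    low_qual_rate = low_qual_rate,
    many_n_rate = many_n_rate,
    true_hazard_ratio = true_hazard_ratio,
    censoring_rate = censoring_rate,
    median_survival_nonresponder = median_survival_nonresponder,
    fragment_length_healthy = fragment_length_healthy,
    fragment_length_tumor = fragment_length_tumor,
    fragments_per_sample = fragments_per_sample,
    arm_effect_profile = arm_effect_profile,
    arm_gain_scale = arm_gain_scale,
    arm_z_scale = arm_z_scale,
    repeat_families = repeat_families,
    bins_per_arm = as.integer(bins_per_arm),
    bin_width = bin_width,
    n_reference_healthy = as.integer(n_reference_healthy),
    n_training_per_class = as.integer(n_training_per_class)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_pos(cfg$n_patients, "n_patients")
  assert_pos(cfg$n_timepoints, "n_timepoints")
  assert_pos(cfg$plasma_depth, "plasma_depth")
  assert_prob(cfg$baseline_tf_median, "baseline_tf_median")
  assert_pos(cfg$baseline_tf_sdlog, "baseline_tf_sdlog")
  for (p in c("responder_fraction", "sequencing_error_rate", "duplicate_rate",
              "discordant_mate_rate", "low_mapq_rate", "low_qual_rate",
              "many_n_rate", "censoring_rate")) {
    assert_prob(cfg[[p]], p)
  }
  assert_pos(cfg$true_hazard_ratio, "true_hazard_ratio")
  assert_pos(cfg$median_survival_nonresponder, "median_survival_nonresponder")
  for (m in c("fragment_length_healthy", "fragment_length_tumor")) {
    v <- cfg[[m]]
    if (!all(c("mode", "sd") %in% names(v))) {
      abort(sprintf("`%s` needs named elements mode and sd.", m),
            class = "cfmonitor_config_error")
    }
    assert_pos(v[["mode"]], paste0(m, "[mode]"))
    assert_pos(v[["sd"]], paste0(m, "[sd]"))
  }
  if (length(cfg$n_mutations_range) != 2L || any(cfg$n_mutations_range < 1) ||
      diff(cfg$n_mutations_range) < 0) {
    abort("`n_mutations_range` must be an increasing pair >= 1.",
          class = "cfmonitor_config_error")
  }
  assert_pos(cfg$fragments_per_sample, "fragments_per_sample")
  arms <- autosomal_arms()
  if (!all(arms %in% names(cfg$arm_effect_profile))) {
    abort("`arm_effect_profile` must name all 39 autosomal arms.",
          class = "cfmonitor_config_error")
  }
  assert_pos(cfg$bin_width, "bin_width")
  assert_pos(cfg$bins_per_arm, "bins_per_arm")
  if (cfg$n_reference_healthy < 2L) {
    abort("`n_reference_healthy` must be >= 2 to estimate arm SDs.",
          class = "cfmonitor_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients x %d draws, depth %.1f, seed %d\n",
              x$n_patients, x$n_timepoints, x$plasma_depth, x$seed))
  cat(sprintf("  baseline TF median %.3f, HR %.2f, %g fragments/sample\n",
              x$baseline_tf_median, x$true_hazard_ratio,
              x$fragments_per_sample))
  invisible(x)
}

#' Synthetic genome bin annotation
#'
#' Tiles a scaled-down diploid genome of 22 autosomes (39 analyzable arms)
#' into non-overlapping bins carrying per-bin GC content and mappability,
#' the annotation table consumed by [build_bins()]. A small fraction of bins
#' is drawn with low GC or mappability so the bin filter is exercised.
#'
#' @param config A [sim_config()].
#' @param low_quality_fraction Fraction of bins drawn with disqualifying GC
#'   or mappability.
#' @return Tibble with columns chrom, arm, start, end, gc, mappability
#'   (start/end 0-based half-open).
#' @export
synthetic_genome_annotation <- function(config, low_quality_fraction = 0.02) {
  # fixed per config seed; restore the caller's RNG stream afterwards
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(config$seed, 101L))
  arms <- autosomal_arms()
  per_arm <- config$bins_per_arm
  w <- config$bin_width
  ann <- purrr::map(seq_along(arms), function(i) {
    arm <- arms[i]
    chrom <- paste0("chr", sub("[pq]$", "", arm))
    offset <- (match(substr(arm, nchar(arm), nchar(arm)), c("p", "q")) - 1) *
      per_arm * w
    tibble::tibble(
      chrom = chrom,
      arm = arm,
      start = offset + (seq_len(per_arm) - 1) * w,
      end = offset + seq_len(per_arm) * w
    )
  }) |> purrr::list_rbind()
  n <- nrow(ann)
  ann$gc <- pmin(pmax(rnorm(n, 0.45, 0.04), 0.31), 0.65)
  ann$mappability <- pmin(pmax(rnorm(n, 0.96, 0.02), 0.905), 1)
  low <- runif(n) < low_quality_fraction
  if (any(low)) {
    flip_gc <- low & runif(n) < 0.5
    ann$gc[flip_gc] <- runif(sum(flip_gc), 0.15, 0.29)
    ann$mappability[low & !flip_gc] <- runif(sum(low & !flip_gc), 0.5, 0.89)
  }
  ann
}
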