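# Synthetic cohort generator: every input the monitoring pipeline consumes,
# with ground-truth labels retained so downstream stages can be scored.
#
# Reproducibility model: a single master seed fans out to fixed substreams
# (panel, per-patient tumors, per-sample pileups/fragment sets, survival),
# so any patient or sample can be regenerated independently and the whole
# cohort is byte-identical under the same seed.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# stream ids (arbitrary but fixed)
.STREAM <- list(panel = 11L, tumor = 23L, state = 37L, pileup = 53L,
                fragments = 71L, survival = 89L, features = 97L)

sample_seed <- function(config, stream, patient = 0L, timepoint = 0L) {
  derive_seed(config$seed,
              stream * 1000003L + patient * 1009L + timepoint * 101L)
}

#' Simulate the external reference panel
#'
#' Generates the three reference resources the tumor-independent pipeline
#' needs: (1) a GC target distribution of fragment counts per 1%-wide GC
#' stratum, separately for short and long fragments, from healthy plasma
#' samples; (2) per-arm fragment-fraction means and SDs over the 39
#' autosomal arms; (3) a labeled training cohort of cancer and non-cancer
#' feature vectors for ensemble fitting.
#'
#' @param config A [sim_config()]; `n_reference_healthy` (default 20)
#'   controls the healthy panel size.
#' @return A `cfm_reference_panel` list with elements `bins` (annotation),
#'   `gc_target`, `arm_reference`, `training`, and `healthy_profiles`.
#' @examples
#' cfg <- sim_config(seed = 1, fragments_per_sample = 5000,
#'                   n_training_per_class = 10)
#' panel <- simulate_reference_panel(cfg)
#' nrow(panel$arm_reference) # 39
#' @export
simulate_reference_panel <- function(config) {
  validate_sim_config(config)
  ann <- synthetic_genome_annotation(config)
  n_healthy <- config$n_reference_healthy

  healthy <- purrr::map(seq_len(n_healthy), function(i) {
    simulate_fragment_set(tumor_fraction = 0, config = config,
                          annotation = ann,
                          seed = sample_seed(config, .STREAM$panel, i))
  })

  frags <- purrr::map(healthy, "fragments")

  # GC target distribution: pooled healthy fragment frequencies per stratum
  pooled <- dplyr::bind_rows(frags)
  gc_target <- gc_strata_distribution(pooled, split_at = 150)

  # arm reference: mean/SD of per-sample arm fractions
  arm_frac <- purrr::imap(frags, function(fr, i) {
    af <- arm_fractions(fr, ann)
    af$sample_id <- i
    af
  }) |> purrr::list_rbind()
  arm_reference <- arm_frac |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(mean = mean(.data$fraction), sd = sd(.data$fraction),
                     .groups = "drop")
  if (any(!is.finite(arm_reference$sd)) || any(arm_reference$sd <= 0)) {
    abort("Reference panel produced non-positive arm SDs; increase panel size or fragment count.",
          class = "cfmonitor_config_error")
  }

  # labeled training cohort in the summary-level feature space
  n_tr <- config$n_training_per_class
  set.seed(sample_seed(config, .STREAM$panel, 999L))
  tf_cancer <- rlnorm(n_tr, meanlog = log(config$baseline_tf_median),
                      sdlog = config$baseline_tf_sdlog)
  tf_cancer <- pmin(tf_cancer, 1)
  training <- purrr::map(seq_len(2 * n_tr), function(i) {
    cancer <- i <= n_tr
    f <- if (cancer) tf_cancer[i] else 0
    feats <- simulate_sample_features(
      f, config, seed = sample_seed(config, .STREAM$features, i))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("train_%03d", i),
                     label = if (cancer) "cancer" else "non-cancer",
                     true_tumor_fraction = f),
      feats)
  }) |> purrr::list_rbind()

  structure(
    list(bins = ann, gc_target = gc_target, arm_reference = arm_reference,
         training = training, healthy_profiles = frags,
         seed = config$seed),
    class = "cfm_reference_panel")
}

#' @export
print.cfm_reference_panel <- function(x, ...) {
  cat("<cfm_reference_panel>\n")
  cat(sprintf("  %d healthy samples, %d arms, %d labeled training samples\n",
              length(x$healthy_profiles), nrow(x$arm_reference),
              nrow(x$training)))
  invisible(x)
}

# per-arm fragment fractions of a fragment table
arm_fractions <- function(fragments, annotation) {
  arms <- autosomal_arms()
  # assign fragments to arms via the annotation bin their midpoint falls in
  idx <- match_fragment_bins(fragments, annotation)
  arm <- annotation$arm[idx]
  tab <- table(factor(arm, levels = arms))
  tibble::tibble(arm = arms, fraction = as.numeric(tab) / sum(tab))
}

# midpoint bin assignment against an annotation table; NA when outside
match_fragment_bins <- function(fragments, annotation) {
  mid <- (fragments$start + fragments$end) / 2
  idx <- rep(NA_integer_, nrow(fragments))
  for (ch in unique(annotation$chrom)) {
    ann_ch <- annotation[annotation$chrom == ch, ]
    sel <- which(fragments$chrom == ch)
    if (!length(sel)) next
    pos <- findInterval(mid[sel], ann_ch$start)
    ok <- pos >= 1 & pos <= nrow(ann_ch) & mid[sel] < ann_ch$end[pmax(pos, 1)]
    idx[sel[ok]] <- which(annotation$chrom == ch)[pos[ok]]
  }
  idx
}

# empirical fragment-count distribution over 1%-wide GC strata, split into
# short/long size classes at `split_at` (short = length <= split_at)
gc_strata_distribution <- function(fragments, split_at = 150) {
  strata <- seq(0, 1, by = 0.01)
  fragments |>
    dplyr::mutate(
      size_class = dplyr::if_else(.data$length <= split_at, "short", "long"),
      gc_stratum = pmin(floor(.data$gc / 0.01), 99L) * 0.01) |>
    dplyr::count(.data$size_class, .data$gc_stratum, name = "count") |>
    dplyr::group_by(.data$size_class) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Simulate a patient's tumor mutation candidates
#'
#' Produces the pre-filter candidate pool a somatic caller would emit: true
#' somatic single-base substitutions that satisfy every post-caller filter,
#' plus injected artifact classes each constructed to violate exactly one
#' filter rule. Ground-truth labels (`is_true_somatic`, `artifact_class`)
#' are retained.
#'
#' Artifact classes: `caller_fail`, `low_alt_reads`, `low_tumor_maf`,
#' `low_normal_coverage`, `normal_alt_reads`, `normal_tier2_maf`,
#' `population_af`, `population_qc`.
#'
#' @param config A [sim_config()].
#' @param patient_id Integer patient index (its own RNG substream).
#' @param n_true Number of true somatic variants; default drawn log-uniform
#'   over `config$n_mutations_range`.
#' @param n_artifacts Number of injected artifact candidates (spread evenly
#'   over the artifact classes).
#' @return Tibble of candidate variants (one row per candidate).
#' @export
simulate_patient_tumor <- function(config, patient_id, n_true = NULL,
                                   n_artifacts = NULL) {
  validate_sim_config(config)
  set.seed(sample_seed(config, .STREAM$tumor, patient_id))
  if (is.null(n_true)) {
    r <- log(config$n_mutations_range)
    n_true <- round(exp(runif(1, r[1], r[2])))
  }
  if (is.null(n_artifacts)) n_artifacts <- max(8L, round(n_true * 0.3))

  n <- n_true + n_artifacts
  ann <- synthetic_genome_annotation(config)
  w <- config$bin_width
  # unique positions by construction: global offsets sampled w/o replacement
  off <- sample(nrow(ann) * w, n)
  bin_idx <- (off - 1) %/% w + 1
  pos <- ann$start[bin_idx] + (off - 1) %% w + 1  # 1-based

  classes <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE,
                    prob = c(0.12, 0.08, 0.45, 0.05, 0.2, 0.1))
  ref <- substr(classes, 1, 1)
  alt <- substr(classes, 3, 3)

  # clean values satisfying every filter rule
  tumor_total <- rpois(n, 60) + 30L
  vaf <- runif(n, 0.15, 0.6)
  tumor_alt <- pmax(rbinom(n, tumor_total, vaf),
                    pmax(3L, ceiling(0.10 * tumor_total)))
  normal_t1_total <- 30L + rpois(n, 15)
  normal_t1_alt <- rep(0L, n)
  normal_t2_total <- normal_t1_total + rpois(n, 8)
  normal_t2_alt <- pmin(rbinom(n, normal_t2_total, 0.01),
                        floor(0.05 * normal_t2_total))
  pop_af <- ifelse(runif(n) < 0.9, NA_real_, runif(n, 0, 9e-5))

  cand <- tibble::tibble(
    chrom = ann$chrom[bin_idx],
    pos = as.integer(pos),
    ref_allele = ref,
    alt_allele = alt,
    caller_pass = TRUE,
    tumor_tier1_alt = as.integer(tumor_alt),
    tumor_tier1_total = as.integer(tumor_total),
    normal_tier1_alt = normal_t1_alt,
    normal_tier1_total = as.integer(normal_t1_total),
    normal_tier2_alt = as.integer(normal_t2_alt),
    normal_tier2_total = as.integer(normal_t2_total),
    population_af = pop_af,
    population_qc_pass = TRUE,
    substitution_class = classes,
    is_true_somatic = c(rep(TRUE, n_true), rep(FALSE, n_artifacts)),
    artifact_class = NA_character_
  )

  if (n_artifacts > 0) {
    art_classes <- c("caller_fail", "low_alt_reads", "low_tumor_maf",
                     "low_normal_coverage", "normal_alt_reads",
                     "normal_tier2_maf", "population_af", "population_qc")
    assign <- rep(art_classes, length.out = n_artifacts)
    rows <- n_true + seq_len(n_artifacts)
    cand$artifact_class[rows] <- assign
    for (k in seq_along(rows)) {
      i <- rows[k]
      cand[i, ] <- corrupt_candidate(cand[i, ], assign[k])
    }
  }

  cand
}

# make one candidate violate exactly the named rule, leaving others passing
corrupt_candidate <- function(row, class) {
  switch(class,
    caller_fail = { row$caller_pass <- FALSE },
    low_alt_reads = {
      # alt in {1,2} while keeping tumor MAF >= 10%
      row$tumor_tier1_total <- 15L
      row$tumor_tier1_alt <- 2L
    },
    low_tumor_maf = {
      row$tumor_tier1_total <- 80L
      row$tumor_tier1_alt <- 4L  # 5% < 10%, but >= 3 reads
    },
    low_normal_coverage = {
      row$normal_tier1_total <- sample(10:29, 1)
    },
    normal_alt_reads = {
      row$normal_tier1_alt <- sample(1:3, 1)
    },
    normal_tier2_maf = {
      row$normal_tier2_alt <- as.integer(ceiling(0.08 * row$normal_tier2_total))
    },
    population_af = {
      row$population_af <- 10^runif(1, log10(1.1e-4), log10(1e-2))
    },
    population_qc = {
      row$population_qc_pass <- FALSE
    },
    abort(sprintf("unknown artifact class '%s'", class))
  )
  row
}

#' Simulate a patient's true state
#'
#' Draws the ground truth for one patient: baseline tumor fraction,
#' responder status, the per-timepoint tumor-fraction trajectory (baseline
#' fraction multiplied per on-treatment draw by the patient's response
#' multiplier), the tumor mutation set, and blood-draw days relative to
#' treatment start (baseline draw 3 days before).
#'
#' @param config A [sim_config()].
#' @param patient_id Integer patient index.
#' @param n_true,n_artifacts Passed to [simulate_patient_tumor()].
#' @return A `cfm_patient_state` list: `patient_id`, `responder`,
#'   `tumor_fraction` (length `n_timepoints`), `draw_day`, `mutations`.
#' @export
simulate_patient_state <- function(config, patient_id, n_true = NULL,
                                   n_artifacts = NULL) {
  validate_sim_config(config)
  set.seed(sample_seed(config, .STREAM$state, patient_id))
  responder <- runif(1) < config$responder_fraction
  f0 <- min(rlnorm(1, log(config$baseline_tf_median),
                   config$baseline_tf_sdlog), 1)
  mult_par <- if (responder) config$responder_multiplier else
    config$nonresponder_multiplier
  m <- rlnorm(1, mult_par[["meanlog"]], mult_par[["sdlog"]])
  tt <- config$n_timepoints
  f <- pmin(f0 * m^(seq_len(tt) - 1), 1)
  draw_day <- c(-3, 14 + 42 * (seq_len(tt - 1) - 1))[seq_len(tt)]
  mutations <- simulate_patient_tumor(config, patient_id, n_true, n_artifacts)
  structure(
    list(patient_id = patient_id, responder = responder,
         tumor_fraction = f, draw_day = draw_day, mutations = mutations),
    class = "cfm_patient_state")
}

#' @export
print.cfm_patient_state <- function(x, ...) {
  cat(sprintf("<cfm_patient_state> patient %s (%s), %d draws, baseline TF %.3g, %d candidate variants\n",
              x$patient_id, if (x$responder) "responder" else "nonresponder",
              length(x$tumor_fraction), x$tumor_fraction[1],
              nrow(x$mutations)))
  invisible(x)
}

#' Simulate plasma pileup evidence at a patient's variant positions
#'
#' Realizes the per-fragment base evidence the consensus pileup consumes.
#' The fragment count at each true variant position is Poisson with mean
#' `plasma_depth`; each fragment carries the mutant allele with probability
#' equal to the timepoint's true tumor fraction. Sequencing errors flip each
#' mate's base independently; PCR duplicates, improper pairs, sub-maximum
#' MAPQ, low base qualities and N-rich mates are injected at the configured
#' rates and flagged in truth columns.
#'
#' @param state A [simulate_patient_state()] result.
#' @param timepoint Draw index (1 = baseline).
#' @param config A [sim_config()].
#' @return Tibble of fragment base calls, one row per fragment x position,
#'   with truth columns `true_allele` and `injected_artifact`.
#' @export
simulate_plasma_pileup <- function(state, timepoint, config) {
  stopifnot(inherits(state, "cfm_patient_state"))
  if (timepoint < 1 || timepoint > length(state$tumor_fraction)) {
    abort("`timepoint` outside the patient's draws.")
  }
  set.seed(sample_seed(config, .STREAM$pileup, state$patient_id, timepoint))
  f <- state$tumor_fraction[timepoint]
  muts <- dplyr::filter(state$mutations, .data$is_true_somatic)
  if (!nrow(muts)) {
    return(empty_pileup())
  }
  depth <- rpois(nrow(muts), config$plasma_depth)
  idx <- rep(seq_len(nrow(muts)), depth)
  n <- length(idx)
  if (!n) return(empty_pileup())

  ref <- muts$ref_allele[idx]
  alt <- muts$alt_allele[idx]
  is_mut <- runif(n) < f
  true_base <- ifelse(is_mut, alt, ref)

  err <- config$sequencing_error_rate
  flip <- function(base) {
    do_flip <- runif(n) < err
    out <- base
    if (any(do_flip)) {
      out[do_flip] <- vapply(base[do_flip], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    out
  }
  r1 <- flip(true_base)
  r2 <- flip(true_base)

  dup <- runif(n) < config$duplicate_rate
  discordant <- runif(n) < config$discordant_mate_rate
  low_mapq <- runif(n) < config$low_mapq_rate
  low_qual <- runif(n) < config$low_qual_rate
  many_n <- runif(n) < config$many_n_rate

  qual1 <- ifelse(low_qual, sample(10:29, n, replace = TRUE), 37L)
  qual2 <- ifelse(low_qual, sample(10:29, n, replace = TRUE), 37L)

  tibble::tibble(
    chrom = muts$chrom[idx],
    pos = muts$pos[idx],
    fragment_id = sprintf("p%st%df%06d", state$patient_id, timepoint,
                          seq_len(n)),
    proper_pair = !discordant,
    mapq = ifelse(low_mapq, sample(10:41, n, replace = TRUE), 42L),
    duplicate_flag = dup,
    n_bases_r1 = ifelse(many_n, 5L + rpois(n, 2), rbinom(n, 2, 0.02)),
    n_bases_r2 = rbinom(n, 2, 0.02),
    r1_base = r1,
    r2_base = r2,
    r1_qual = as.integer(qual1),
    r2_qual = as.integer(qual2),
    true_allele = ifelse(is_mut, "alt", "ref"),
    injected_artifact = dup | discordant | low_mapq | low_qual | many_n
  )
}

empty_pileup <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), fragment_id = character(),
    proper_pair = logical(), mapq = integer(), duplicate_flag = logical(),
    n_bases_r1 = integer(), n_bases_r2 = integer(),
    r1_base = character(), r2_base = character(),
    r1_qual = integer(), r2_qual = integer(),
    true_allele = character(), injected_artifact = logical())
}

#' Simulate a genome-wide plasma fragment set
#'
#' Draws fragments whose lengths follow a two-component normal mixture
#' (healthy mode vs tumor mode, mixture weight = tumor fraction), whose
#' genomic placement follows the per-arm copy-number effect profile scaled
#' by tumor fraction, and whose per-family repeat-kmer counts shift with
#' tumor fraction. MAPQ below 30 is injected at `low_mapq_rate` so the
#' fragmentomics filters are exercised.
#'
#' @param state A `cfm_patient_state`, or `NULL` when `tumor_fraction` is
#'   given directly.
#' @param timepoint Draw index (used with `state`).
#' @param config A [sim_config()].
#' @param tumor_fraction Tumor fraction override (used without `state`).
#' @param annotation Genome bin annotation; defaults to
#'   [synthetic_genome_annotation()].
#' @param n_fragments Number of fragments; defaults to
#'   `config$fragments_per_sample`.
#' @param seed RNG seed override (defaults to the per-sample substream).
#' @return List with `fragments` (tibble: chrom, start, end, length, gc,
#'   mapq) and `repeat_counts` (tibble: family, count, reads_total).
#' @export
simulate_fragment_set <- function(state = NULL, timepoint = 1L, config,
                                  tumor_fraction = NULL, annotation = NULL,
                                  n_fragments = NULL, seed = NULL) {
  validate_sim_config(config)
  if (is.null(tumor_fraction)) {
    stopifnot(inherits(state, "cfm_patient_state"))
    tumor_fraction <- state$tumor_fraction[timepoint]
    if (is.null(seed)) {
      seed <- sample_seed(config, .STREAM$fragments, state$patient_id,
                          timepoint)
    }
  }
  if (is.null(seed)) seed <- sample_seed(config, .STREAM$fragments, 0L, 0L)
  assert_prob(tumor_fraction, "tumor_fraction")
  set.seed(seed)
  if (is.null(annotation)) annotation <- synthetic_genome_annotation(config)
  n <- n_fragments %||% config$fragments_per_sample
  f <- tumor_fraction

  # bin sampling weights: width x arm copy-number effect
  eff <- config$arm_effect_profile[annotation$arm]
  wt <- (annotation$end - annotation$start) *
    pmax(1 + eff * config$arm_gain_scale * f, 0.05)
  bin_idx <- sample.int(nrow(annotation), n, replace = TRUE,
                        prob = wt / sum(wt))

  tumor_frag <- runif(n) < f
  len_h <- config$fragment_length_healthy
  len_t <- config$fragment_length_tumor
  length <- ifelse(tumor_frag,
                   rnorm(n, len_t[["mode"]], len_t[["sd"]]),
                   rnorm(n, len_h[["mode"]], len_h[["sd"]]))
  length <- as.integer(pmax(pmin(round(length), 400), 60))

  start <- annotation$start[bin_idx] +
    floor(runif(n) * pmax(config$bin_width - length, 1))
  gc <- pmin(pmax(annotation$gc[bin_idx] + rnorm(n, 0, 0.03), 0.05), 0.95)

  low_mapq <- runif(n) < config$low_mapq_rate
  mapq <- ifelse(low_mapq, sample(0:29, n, replace = TRUE), 60L)

  fragments <- tibble::tibble(
    chrom = annotation$chrom[bin_idx],
    start = as.numeric(start),
    end = as.numeric(start + length),
    length = length,
    gc = gc,
    mapq = as.integer(mapq),
    tumor_derived = tumor_frag
  )

  fam <- config$repeat_families
  lam <- n * fam$base_rate / 1e6 * pmax(1 + fam$shift * f, 0)
  repeat_counts <- tibble::tibble(
    family = fam$family,
    count = rpois(nrow(fam), lam),
    reads_total = n
  )

  list(fragments = fragments, repeat_counts = repeat_counts,
       tumor_fraction = f)
}

#' Simulate survival outcomes coupled to molecular response
#'
#' Event times follow a proportional-hazards exponential model: the
#' nonresponder hazard is anchored at `median_survival_nonresponder` and
#' responders' hazard is multiplied by `true_hazard_ratio`. Independent
#' exponential censoring achieves the configured expected censoring
#' fraction; `censoring_rate = 1` censors every observation.
#'
#' @param states List of `cfm_patient_state` objects, or a tibble with
#'   columns `patient_id` and `responder`.
#' @param config A [sim_config()].
#' @param seed RNG seed override.
#' @return Tibble: patient_id, responder, os_days, os_event (1 = death).
#' @export
simulate_survival <- function(states, config, seed = NULL) {
  validate_sim_config(config)
  if (is.data.frame(states)) {
    df <- tibble::as_tibble(states[, c("patient_id", "responder")])
  } else {
    df <- tibble::tibble(
      patient_id = purrr::map_dbl(states, "patient_id"),
      responder = purrr::map_lgl(states, "responder"))
  }
  set.seed(seed %||% sample_seed(config, .STREAM$survival))
  n <- nrow(df)
  base_rate <- log(2) / config$median_survival_nonresponder
  rate <- base_rate * ifelse(df$responder, config$true_hazard_ratio, 1)
  t_event <- rexp(n, rate)
  cr <- config$censoring_rate
  if (cr >= 1) {
    df$os_days <- pmax(rexp(n, rate), 1 / 24)
    df$os_event <- 0L
  } else if (cr <= 0) {
    df$os_days <- pmax(t_event, 1 / 24)
    df$os_event <- 1L
  } else {
    # competing exponential censoring: P(censor first) = rc/(rc + re)
    rate_c <- rate * cr / (1 - cr)
    t_cens <- rexp(n, rate_c)
    df$os_days <- pmax(pmin(t_event, t_cens), 1 / 24)
    df$os_event <- as.integer(t_event <= t_cens)
  }
  df
}

#' Simulate summary-level molecular features for one sample
#'
#' Emits the wide feature vector consumed by the ensemble model: per-bin
#' short/long fragmentation ratios (`ratio_*`), arm z-scores (`armz_*`),
#' repeat-family kmer rates (`rep_<FAMILY>_*`), and epigenetic 1-Mb bin
#' coverages (`epi_*`). Effect loadings are fixed functions of the config
#' seed, so all samples of a cohort share the same signal directions; the
#' effect magnitude scales with the tumor fraction.
#'
#' @param tumor_fraction True tumor fraction in [0, 1].
#' @param config A [sim_config()].
#' @param seed RNG seed for the sample's noise draw.
#' @param n_ratio_bins,n_epi_bins,features_per_family Feature-space sizes.
#' @return One-row tibble of named features.
#' @export
simulate_sample_features <- function(tumor_fraction, config, seed,
                                     n_ratio_bins = 100L, n_epi_bins = 50L,
                                     features_per_family = 8L) {
  assert_prob(tumor_fraction, "tumor_fraction")
  f <- tumor_fraction
  # fixed loadings per config seed
  set.seed(derive_seed(config$seed, 7777L))
  ratio_load <- rnorm(n_ratio_bins, 0, 0.3)
  epi_load <- rnorm(n_epi_bins, 0, 0.5)
  fam <- config$repeat_families
  rep_dir <- matrix(sample(c(-1, 1), nrow(fam) * features_per_family,
                           replace = TRUE),
                    nrow = nrow(fam))

  set.seed(seed)
  ratios <- 0.25 + ratio_load * f + rnorm(n_ratio_bins, 0, 0.03)
  armz <- config$arm_effect_profile[autosomal_arms()] *
    config$arm_z_scale * f + rnorm(length(autosomal_arms()))
  epi <- 1 + epi_load * f + rnorm(n_epi_bins, 0, 0.05)
  reps <- purrr::map(seq_len(nrow(fam)), function(j) {
    base <- fam$base_rate[j] * seq(0.6, 1.4,
                                   length.out = features_per_family)
    rate <- base * (1 + fam$shift[j] * rep_dir[j, ] * f) *
      exp(rnorm(features_per_family, 0, 0.02))
    setNames(rate, sprintf("rep_%s_%02d", fam$family[j],
                           seq_len(features_per_family)))
  })
  vals <- c(
    setNames(ratios, sprintf("ratio_%03d", seq_len(n_ratio_bins))),
    setNames(armz, paste0("armz_", autosomal_arms())),
    unlist(reps),
    setNames(epi, sprintf("epi_%03d", seq_len(n_epi_bins)))
  )
  tibble::as_tibble(as.list(vals))
}

#' Simulate a full monitoring cohort table
#'
#' Generates patient states, survival outcomes and a per-draw cohort table
#' carrying true tumor fractions, a noisy tumor-fraction score (`tf_score`),
#' draw days, and clinical covariates, ready for timepoint selection and
#' landmark/Cox analyses.
#'
#' @param config A [sim_config()].
#' @param score_noise_sdlog Log-normal noise on `tf_score` around the true
#'   tumor fraction.
#' @return List with `states`, `survival`, and `cohort` (one row per draw).
#' @export
simulate_cohort <- function(config, score_noise_sdlog = 0.15) {
  validate_sim_config(config)
  states <- purrr::map(seq_len(config$n_patients), function(i) {
    simulate_patient_state(config, i, n_true = 200L, n_artifacts = 40L)
  })
  surv <- simulate_survival(states, config)
  set.seed(sample_seed(config, .STREAM$survival, 1L, 1L))
  cohort <- purrr::map(states, function(st) {
    tt <- length(st$tumor_fraction)
    tibble::tibble(
      patient_id = st$patient_id,
      timepoint = seq_len(tt),
      draw_day = st$draw_day,
      true_tumor_fraction = st$tumor_fraction,
      responder_truth = st$responder)
  }) |> purrr::list_rbind()
  cohort$tf_score <- pmin(
    cohort$true_tumor_fraction *
      exp(rnorm(nrow(cohort), 0, score_noise_sdlog)) +
      abs(rnorm(nrow(cohort), 0, 1e-4)),
    1)
  n <- config$n_patients
  covars <- tibble::tibble(
    patient_id = seq_len(n),
    age = sample(35:80, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    ecog_ps = sample(0:1, n, replace = TRUE),
    mgps = sample(0:2, n, replace = TRUE),
    weight_loss_5pct = runif(n) < 0.3,
    bilirubin_high = runif(n) < 0.05,
    treatment_arm = sample(c("arm1", "arm2"), n, replace = TRUE)
  )
  cohort <- cohort |>
    dplyr::left_join(surv, by = "patient_id") |>
    dplyr::left_join(covars, by = "patient_id")
  list(states = states, survival = surv, cohort = cohort)
}
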