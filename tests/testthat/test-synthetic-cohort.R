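# Synthetic cohort generator: determinism, label completeness, and
# statistical faithfulness of the simulated inputs.

test_that("identical seeds give byte-identical outputs", {
  cfg <- small_cfg(seed = 11)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$gc_target, p2$gc_target)
  expect_identical(p1$arm_reference, p2$arm_reference)
  expect_identical(p1$training, p2$training)

  st1 <- simulate_patient_state(cfg, 3, n_true = 50, n_artifacts = 10)
  st2 <- simulate_patient_state(cfg, 3, n_true = 50, n_artifacts = 10)
  expect_identical(st1$mutations, st2$mutations)
  expect_identical(st1$tumor_fraction, st2$tumor_fraction)
  expect_identical(simulate_plasma_pileup(st1, 2, cfg),
                   simulate_plasma_pileup(st2, 2, cfg))
  fs1 <- simulate_fragment_set(st1, 1, cfg, n_fragments = 2000)
  fs2 <- simulate_fragment_set(st2, 1, cfg, n_fragments = 2000)
  expect_identical(fs1$fragments, fs2$fragments)
  expect_identical(fs1$repeat_counts, fs2$repeat_counts)
})

test_that("patients are reproducible independently of each other", {
  cfg <- small_cfg(seed = 12)
  direct <- simulate_patient_state(cfg, 5, n_true = 30, n_artifacts = 8)
  # generating other patients first must not perturb patient 5
  invisible(simulate_patient_state(cfg, 1, n_true = 20, n_artifacts = 4))
  again <- simulate_patient_state(cfg, 5, n_true = 30, n_artifacts = 8)
  expect_identical(direct$mutations, again$mutations)
})

test_that("reference panel has full arm coverage, positive SDs, both labels", {
  cfg <- sim_config(seed = 21, fragments_per_sample = 8000,
                    n_reference_healthy = 20, n_training_per_class = 5)
  panel <- simulate_reference_panel(cfg)
  expect_length(panel$healthy_profiles, 20)
  expect_equal(nrow(panel$arm_reference), 39)
  expect_true(all(panel$arm_reference$sd > 0))
  expect_setequal(unique(panel$training$label), c("cancer", "non-cancer"))
  # GC target is a distribution per size class
  sums <- tapply(panel$gc_target$freq, panel$gc_target$size_class, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("invalid generator parameters are rejected as configuration errors", {
  expect_error(sim_config(fragment_length_healthy = c(mode = 167, sd = 0)),
               class = "cfmonitor_config_error")
  expect_error(sim_config(sequencing_error_rate = -0.1),
               class = "cfmonitor_config_error")
  expect_error(sim_config(plasma_depth = 0),
               class = "cfmonitor_config_error")
  expect_error(sim_config(n_reference_healthy = 1),
               class = "cfmonitor_config_error")
})

test_that("true variants pass all filters; each artifact violates exactly one rule", {
  cfg <- small_cfg(seed = 31)
  cand <- simulate_patient_tumor(cfg, 1, n_true = 100, n_artifacts = 50)
  expect_equal(nrow(cand), 150)
  filt <- apply_somatic_filters(cand)
  expect_equal(sum(filt$pass), 100)
  expect_true(all(filt$pass == filt$is_true_somatic))
  rule_cols <- grep("^rule_", names(filt), value = TRUE)
  viol <- rowSums(!as.matrix(filt[rule_cols]))
  expect_true(all(viol[!filt$is_true_somatic] == 1))
  expect_true(all(viol[filt$is_true_somatic] == 0))
})

test_that("zero artifacts means every candidate passes", {
  cfg <- small_cfg(seed = 32)
  cand <- simulate_patient_tumor(cfg, 2, n_true = 40, n_artifacts = 0)
  expect_true(all(apply_somatic_filters(cand)$pass))
})

test_that("population-frequency artifacts fail only that rule", {
  cfg <- small_cfg(seed = 33)
  cand <- simulate_patient_tumor(cfg, 1, n_true = 10, n_artifacts = 16)
  filt <- apply_somatic_filters(cand)
  pop <- dplyr::filter(filt, artifact_class == "population_af")
  expect_gt(nrow(pop), 0)
  expect_true(all(pop$population_af > 1e-4))
  expect_true(all(pop$fail_reasons == "population frequency"))
})

test_that("pileup mutant content tracks the true tumor fraction", {
  cfg0 <- small_cfg(seed = 41, sequencing_error_rate = 0,
                    duplicate_rate = 0, discordant_mate_rate = 0,
                    low_mapq_rate = 0, low_qual_rate = 0, many_n_rate = 0)
  st <- simulate_patient_state(cfg0, 1, n_true = 200, n_artifacts = 0)
  st$tumor_fraction[1] <- 0
  pu0 <- simulate_plasma_pileup(st, 1, cfg0)
  expect_true(all(pu0$true_allele == "ref"))
  expect_true(all(pu0$r1_base != "N"))

  cfg30 <- small_cfg(seed = 42, plasma_depth = 30,
                     sequencing_error_rate = 0, duplicate_rate = 0,
                     discordant_mate_rate = 0, low_mapq_rate = 0,
                     low_qual_rate = 0, many_n_rate = 0)
  st2 <- simulate_patient_state(cfg30, 2, n_true = 200, n_artifacts = 0)
  st2$tumor_fraction[1] <- 0.5
  pu <- simulate_plasma_pileup(st2, 1, cfg30)
  frac <- mean(pu$true_allele == "alt")
  se <- sqrt(0.5 * 0.5 / nrow(pu))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("fully discordant pileups are rejected wholesale downstream", {
  cfg <- small_cfg(seed = 43, discordant_mate_rate = 1)
  st <- simulate_patient_state(cfg, 1, n_true = 50, n_artifacts = 0)
  pu <- simulate_plasma_pileup(st, 1, cfg)
  cons <- consensus_filter(pu, st$mutations)
  expect_true(all(!cons$accepted))
})

test_that("fragment length mixture follows the configured modes", {
  cfg <- small_cfg(seed = 51)
  fs0 <- simulate_fragment_set(config = cfg, tumor_fraction = 0,
                               n_fragments = 20000, seed = 511)
  expect_lt(abs(median(fs0$fragments$length) - 167), 2)
  fs1 <- simulate_fragment_set(config = cfg, tumor_fraction = 1,
                               n_fragments = 20000, seed = 512)
  expect_lt(abs(median(fs1$fragments$length) - 145), 2)
})

test_that("arm effect profile shifts arm representation with tumor fraction", {
  panel <- cached_panel()
  cfg <- sim_config(seed = 301, fragments_per_sample = 20000,
                    n_reference_healthy = 8, n_training_per_class = 30)
  fs <- simulate_fragment_set(config = cfg, tumor_fraction = 0.3,
                              annotation = panel$bins,
                              n_fragments = 50000, seed = 513)
  z <- arm_zscores(fs$fragments, panel$arm_reference,
                   annotation = panel$bins)
  expect_gt(z$z[z$arm == "8q"], 0)
  expect_lt(z$z[z$arm == "18q"], 0)
})

test_that("empirical mixture weight converges to the tumor fraction", {
  cfg <- small_cfg(seed = 52)
  f <- 0.3
  for (n in c(2000, 20000, 100000)) {
    fs <- simulate_fragment_set(config = cfg, tumor_fraction = f,
                                n_fragments = n, seed = 514 + n)
    emp <- mean(fs$fragments$tumor_derived)
    expect_lt(abs(emp - f), 3 * sqrt(f * (1 - f) / n))
  }
})

test_that("repeat kmer counts shift with tumor fraction as configured", {
  cfg <- small_cfg(seed = 53)
  reps <- function(f, s) {
    simulate_fragment_set(config = cfg, tumor_fraction = f,
                          n_fragments = 50000, seed = s)$repeat_counts
  }
  r0 <- purrr::map(1:20, ~reps(0, 600 + .x)) |> purrr::list_rbind()
  r1 <- purrr::map(1:20, ~reps(0.5, 700 + .x)) |> purrr::list_rbind()
  m0 <- tapply(r0$count, r0$family, mean)
  m1 <- tapply(r1$count, r1$family, mean)
  fam <- cfg$repeat_families
  for (i in seq_len(nrow(fam))) {
    expected_ratio <- 1 + fam$shift[i] * 0.5
    expect_equal(unname(m1[fam$family[i]] / m0[fam$family[i]]),
                 expected_ratio, tolerance = 0.1)
  }
})

test_that("survival generator is null-calibrated and respects censoring", {
  cfg_null <- small_cfg(seed = 61, true_hazard_ratio = 1,
                        censoring_rate = 0)
  pvals <- vapply(1:200, function(i) {
    df <- tibble::tibble(patient_id = 1:60,
                         responder = rep(c(TRUE, FALSE), 30))
    sv <- simulate_survival(df, cfg_null, seed = 6100 + i)
    sd_ <- survival::survdiff(
      survival::Surv(os_days, os_event) ~ responder, data = sv)
    stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1))
  # p-values uniform under the null
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  cfg_cens <- small_cfg(seed = 62, censoring_rate = 1)
  sv <- simulate_survival(tibble::tibble(patient_id = 1:30,
                                         responder = rep(c(TRUE, FALSE), 15)),
                          cfg_cens)
  expect_true(all(sv$os_event == 0))
  expect_true(all(sv$os_days > 0))
  grp <- tibble::tibble(time = sv$os_days, event = sv$os_event,
                        group = sv$responder)
  expect_error(km_logrank(grp, time, event, group),
               class = "cfmonitor_no_events")
})
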