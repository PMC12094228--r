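# Bin construction, fragment binning, GC correction, arm z-scores and
# segment-table summaries.

toy_annotation <- function() {
  tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 5),
    arm = rep(c("1p", "2p"), each = 5),
    start = rep(seq(0, 4e6, by = 1e6), 2),
    end = rep(seq(1e6, 5e6, by = 1e6), 2),
    gc = c(0.45, 0.25, 0.5, 0.3, 0.42, 0.25, 0.55, 0.4, 0.44, 0.48),
    mappability = rep(0.95, 10))
}

test_that("bins below the GC/mappability thresholds are excluded, boundary retained", {
  ann <- toy_annotation()
  bins <- build_bins(ann)
  expect_equal(nrow(bins), 8)        # two bins at gc 0.25 dropped
  expect_true(0.3 %in% bins$gc)      # gc exactly 0.3 retained (< rule)
  expect_equal(attr(bins, "n_input"), 10)

  all_pass <- dplyr::mutate(ann, gc = 0.5)
  expect_equal(nrow(build_bins(all_pass)), 10)

  low_map <- dplyr::mutate(ann, gc = 0.5,
                           mappability = c(rep(0.95, 9), 0.89))
  expect_equal(nrow(build_bins(low_map)), 9)
})

test_that("fragment size classes split at the documented boundaries", {
  bins <- build_bins(dplyr::mutate(toy_annotation(), gc = 0.5))
  frag <- function(len) {
    tibble::tibble(chrom = "chr1", start = 100, end = 100 + len,
                   length = len, gc = 0.5, mapq = 60L)
  }
  f150 <- bin_fragments(frag(150), bins)
  expect_equal(sum(f150$short), 1)
  expect_equal(sum(f150$long), 0)
  f151 <- bin_fragments(frag(151), bins)
  expect_equal(sum(f151$short), 0)
  expect_equal(sum(f151$long), 1)
  f90 <- bin_fragments(frag(90), bins)
  expect_equal(sum(f90$short) + sum(f90$long), 0)
  f221 <- bin_fragments(frag(221), bins)
  expect_equal(sum(f221$short) + sum(f221$long), 0)
})

test_that("binning equals a brute-force recount and conserves fragments", {
  cfg <- small_cfg(seed = 91)
  ann <- synthetic_genome_annotation(cfg)
  bins <- build_bins(ann)
  fs <- simulate_fragment_set(config = cfg, tumor_fraction = 0.2,
                              annotation = ann, n_fragments = 1000,
                              seed = 911)
  fr <- fs$fragments
  prof <- bin_fragments(fr, bins)

  # independent recount: midpoint containment per bin, same filters
  keep <- fr$mapq >= 30 & fr$length >= 100 & fr$length <= 220
  fr2 <- fr[keep, ]
  mid <- (fr2$start + fr2$end) / 2
  short_o <- long_o <- numeric(nrow(bins))
  n_assigned <- 0
  for (i in seq_len(nrow(bins))) {
    inbin <- fr2$chrom == bins$chrom[i] & mid >= bins$start[i] &
      mid < bins$end[i]
    n_assigned <- n_assigned + sum(inbin)
    short_o[i] <- sum(inbin & fr2$length <= 150)
    long_o[i] <- sum(inbin & fr2$length >= 151)
  }
  expect_equal(prof$short, short_o)
  expect_equal(prof$long, long_o)
  # every retained fragment in exactly one bin
  expect_equal(sum(prof$short) + sum(prof$long), n_assigned)

  # order invariance
  prof2 <- bin_fragments(fr[sample(nrow(fr)), ], bins)
  expect_equal(prof2$short, prof$short)
  expect_equal(prof2$long, prof$long)
})

test_that("MAPQ and blacklist filters drop fragments before binning", {
  bins <- build_bins(dplyr::mutate(toy_annotation(), gc = 0.5))
  fr <- tibble::tibble(chrom = "chr1", start = c(100, 200, 2e6),
                       end = c(250, 350, 2e6 + 150),
                       length = 150L, gc = 0.5, mapq = c(60L, 29L, 60L))
  prof <- bin_fragments(fr, bins)
  expect_equal(sum(prof$short), 2)   # MAPQ 29 dropped
  bl <- tibble::tibble(chrom = "chr1", start = 1.9e6, end = 2.2e6)
  prof_bl <- bin_fragments(fr, bins, blacklist = bl)
  expect_equal(sum(prof_bl$short), 1)
})

test_that("GC correction is the identity when observed equals target", {
  cfg <- small_cfg(seed = 92)
  fs <- simulate_fragment_set(config = cfg, tumor_fraction = 0,
                              n_fragments = 5000, seed = 921)
  fr <- fs$fragments
  target <- cfmonitor:::gc_strata_distribution(fr)
  corrected <- gc_correct(fr, target)
  expect_true(all(abs(corrected$weight - 1) < 1e-12))
})

test_that("single-stratum weights equal the target mass ratio", {
  fr <- tibble::tibble(chrom = "chr1", start = 0, end = 140,
                       length = rep(120L, 50), gc = 0.455)
  target <- tibble::tibble(
    size_class = c("short", "short"),
    gc_stratum = c(0.45, 0.46),
    freq = c(0.3, 0.7))
  corrected <- gc_correct(fr, target)
  expect_true(all(abs(corrected$weight - 0.3) < 1e-12))
})

test_that("weights for strata absent from the target are zero; large weights capped", {
  fr <- tibble::tibble(chrom = "chr1", start = 0, end = 140,
                       length = rep(120L, 10),
                       gc = c(rep(0.455, 9), 0.805))
  target <- tibble::tibble(size_class = "short", gc_stratum = 0.45,
                           freq = 1)
  corrected <- expect_silent(gc_correct(fr, target))
  expect_equal(corrected$weight[10], 0)
  expect_lt(abs(corrected$weight[1] - 1 / 0.9), 1e-12)
})

test_that("arm z-scores are definitional against the reference", {
  ref <- tibble::tibble(arm = c("1p", "1q"), mean = c(0.5, 0.5),
                        sd = c(0.01, 0.02))
  at_mean <- tibble::tibble(arm = c("1p", "1q"), count = c(50, 50))
  z <- arm_zscores(at_mean, ref)
  expect_equal(z$z, c(0, 0))
  one_sd <- tibble::tibble(arm = c("1p", "1q"), count = c(51, 49))
  z2 <- arm_zscores(one_sd, ref)
  expect_equal(z2$z[1], 1)           # fraction .51 = mean + 1 x sd
  expect_error(arm_zscores(at_mean, dplyr::mutate(ref, sd = 0)),
               class = "cfmonitor_config_error")
})

test_that("arm-level medians clip segments to arm extents", {
  arms <- tibble::tibble(arm = c("1p", "1q"), chrom = "chr1",
                         start = c(0, 5e6), end = c(5e6, 10e6))
  one <- tibble::tibble(chrom = "chr1", start = 0, end = 5e6,
                        log_ratio = 0.5)
  expect_equal(arm_level_median(one, arms)$median_log_ratio, c(0.5, NA))

  three <- tibble::tibble(chrom = "chr1",
                          start = c(0, 1e6, 3e6), end = c(1e6, 3e6, 5e6),
                          log_ratio = c(-1, 0, 1))
  expect_equal(arm_level_median(three, arms)$median_log_ratio[1], 0)

  # a centromere-spanning segment contributes to both arms
  multi <- tibble::tibble(chrom = "chr1",
                          start = c(0, 4e6, 6e6),
                          end = c(4e6, 6e6, 10e6),
                          log_ratio = c(-0.4, 0.1, 0.8))
  res <- arm_level_median(multi, arms)
  expect_equal(res$median_log_ratio, c(median(c(-0.4, 0.1)),
                                       median(c(0.1, 0.8))))
  expect_equal(res$n_segments, c(2L, 2L))
})

test_that("plasma-tumor arm correlation behaves definitionally", {
  z <- tibble::tibble(arm = autosomal_arms(),
                      z = seq(-1.9, 1.9, length.out = 39))
  med <- tibble::tibble(arm = autosomal_arms(),
                        median_log_ratio = z$z)
  expect_equal(plasma_tumor_arm_correlation(z, med)$estimate, 1)
  med_neg <- dplyr::mutate(med, median_log_ratio = -median_log_ratio)
  expect_equal(plasma_tumor_arm_correlation(z, med_neg)$estimate, -1)

  set.seed(1)
  med_r <- dplyr::mutate(med, median_log_ratio = rnorm(39))
  manual <- cor(z$z, med_r$median_log_ratio)
  expect_equal(plasma_tumor_arm_correlation(z, med_r)$estimate, manual)
})

test_that("ratio dispersion across bins grows with tumor burden", {
  cfg <- small_cfg(seed = 93)
  lo <- simulate_sample_features(0.02, cfg, seed = 931)
  hi <- simulate_sample_features(0.3, cfg, seed = 931)
  ratio_cols <- grep("^ratio_", names(lo), value = TRUE)
  expect_gt(var(as.numeric(hi[1, ratio_cols])),
            var(as.numeric(lo[1, ratio_cols])))
})
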