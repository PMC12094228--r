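# Shared fixtures, all generated in code. Heavy objects are built once per
# test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(seed = 101, ...) {
  sim_config(seed = seed, fragments_per_sample = 5000,
             n_reference_healthy = 4, n_training_per_class = 12, ...)
}

# reference panel at small desk scale, built once
cached_panel <- function() {
  if (is.null(.fixtures$panel)) {
    .fixtures$panel <- simulate_reference_panel(
      sim_config(seed = 301, fragments_per_sample = 20000,
                 n_reference_healthy = 8, n_training_per_class = 30))
  }
  .fixtures$panel
}

cached_model <- function() {
  if (is.null(.fixtures$model)) {
    panel <- cached_panel()
    .fixtures$model <- train_artemis_delfi(
      panel$training[, -(1:3)], panel$training$label, seed = 301)
  }
  .fixtures$model
}

# a clean candidate variant passing every filter rule
clean_candidate <- function(chrom = "chr1", pos = 1000L) {
  tibble::tibble(
    chrom = chrom, pos = pos, ref_allele = "C", alt_allele = "T",
    caller_pass = TRUE,
    tumor_tier1_alt = 12L, tumor_tier1_total = 60L,
    normal_tier1_alt = 0L, normal_tier1_total = 40L,
    normal_tier2_alt = 1L, normal_tier2_total = 45L,
    population_af = NA_real_, population_qc_pass = TRUE,
    substitution_class = "C>T")
}

# a pileup call row accepted by every consensus clause
clean_call <- function(chrom = "chr1", pos = 1000L, base = "T",
                       fragment_id = "f1") {
  tibble::tibble(
    chrom = chrom, pos = pos, fragment_id = fragment_id,
    proper_pair = TRUE, mapq = 42L, duplicate_flag = FALSE,
    n_bases_r1 = 0L, n_bases_r2 = 0L,
    r1_base = base, r2_base = base, r1_qual = 35L, r2_qual = 31L)
}

# independent brute-force consensus + WGMAF recount (test oracle; written
# against the documented contract, not the package implementation)
oracle_wgmaf <- function(calls, mutations) {
  m <- 0L
  t <- 0L
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    mu <- mutations[mutations$chrom == row$chrom &
                      mutations$pos == row$pos, ]
    ok <- row$proper_pair && row$mapq == 42 && !row$duplicate_flag &&
      row$n_bases_r1 < 5 && row$n_bases_r2 < 5 &&
      !is.na(row$r1_base) && !is.na(row$r2_base) &&
      row$r1_qual >= 30 && row$r2_qual >= 30 &&
      row$r1_base %in% c(mu$ref_allele, mu$alt_allele) &&
      row$r2_base %in% c(mu$ref_allele, mu$alt_allele) &&
      row$r1_base == row$r2_base
    if (ok) {
      t <- t + 1L
      if (row$r1_base == mu$alt_allele) m <- m + 1L
    }
  }
  list(m = m, t = t, maf = if (t > 0) m / t else NA_real_)
}
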