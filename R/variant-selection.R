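# Post-caller somatic filter chain for tumor/normal candidate variants.
#
# A candidate passes iff it passed the upstream caller AND
#   (i)   >= 3 mutant tier-1 reads in the tumor
#   (ii)  tier-1 tumor MAF >= 10%
#   (iii) >= 30x tier-1 coverage in the matched normal
#   (iv)  zero mutant tier-1 reads in the matched normal
#   (v)   tier-2 normal MAF <= 5%
# and is absent from the population database above 1 in 10,000 and passes
# the database's quality filters. All thresholds are inclusive as written.

FILTER_RULES <- c(
  caller = "caller PASS",
  min_alt_reads = "min mutant reads",
  tumor_maf = "tumor tier1 MAF",
  normal_coverage = "normal tier1 coverage",
  normal_alt = "normal mutant reads",
  normal_tier2_maf = "normal tier2 MAF",
  population_af = "population frequency",
  population_qc = "population QC"
)

required_candidate_cols <- function() {
  c("chrom", "pos", "ref_allele", "alt_allele", "caller_pass",
    "tumor_tier1_alt", "tumor_tier1_total", "normal_tier1_alt",
    "normal_tier1_total", "normal_tier2_alt", "normal_tier2_total",
    "population_af", "population_qc_pass")
}

#' Apply the somatic filter chain to candidate variants
#'
#' Evaluates each of the eight pass conditions independently (the chain is a
#' pure conjunction, so rule order is irrelevant) and records every violated
#' rule per candidate. A ratio whose denominator is zero evaluates as a
#' failure of that rule with reason "undefined ratio". A missing
#' `population_af` means the variant is not in the population database, so
#' the frequency rule passes.
#'
#' Only single-base substitutions are handled; candidates whose ref or alt
#' allele is not a single A/C/G/T are dropped with a counted warning.
#'
#' @param candidates Tibble with the columns of
#'   `required_candidate_cols()` (extra columns are carried through).
#' @param min_alt_reads Minimum mutant tier-1 tumor reads (default 3).
#' @param min_tumor_maf Minimum tier-1 tumor MAF (default 0.10).
#' @param min_normal_coverage Minimum tier-1 normal coverage (default 30).
#' @param max_normal_tier2_maf Maximum tier-2 normal MAF (default 0.05).
#' @param max_population_af Maximum population allele frequency
#'   (default 1e-4, i.e. 1 in 10,000).
#' @return The input tibble with logical per-rule columns (`rule_*`), a
#'   `pass` column, and `fail_reasons` (";"-separated, `NA` when passing).
#'   Attribute `n_rejected_non_sbs` counts dropped non-substitution records.
#' @examples
#' cand <- simulate_patient_tumor(sim_config(seed = 1), 1,
#'                                n_true = 5, n_artifacts = 3)
#' filt <- apply_somatic_filters(cand)
#' table(filt$pass)
#' @export
apply_somatic_filters <- function(candidates,
                                  min_alt_reads = 3,
                                  min_tumor_maf = 0.10,
                                  min_normal_coverage = 30,
                                  max_normal_tier2_maf = 0.05,
                                  max_population_af = 1e-4) {
  missing <- setdiff(required_candidate_cols(), names(candidates))
  if (length(missing)) {
    abort(paste0("candidate table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  candidates <- tibble::as_tibble(candidates)

  sbs <- candidates$ref_allele %in% c("A", "C", "G", "T") &
    candidates$alt_allele %in% c("A", "C", "G", "T") &
    candidates$ref_allele != candidates$alt_allele
  n_non_sbs <- sum(!sbs)
  if (n_non_sbs > 0) {
    warn(sprintf("dropped %d non-single-base-substitution candidate(s)",
                 n_non_sbs))
    candidates <- candidates[sbs, ]
  }

  neg <- any(candidates$tumor_tier1_alt < 0 |
               candidates$tumor_tier1_total < 0 |
               candidates$normal_tier1_alt < 0 |
               candidates$normal_tier1_total < 0 |
               candidates$normal_tier2_alt < 0 |
               candidates$normal_tier2_total < 0, na.rm = TRUE)
  if (isTRUE(neg)) abort("read counts must be non-negative")

  tumor_maf <- safe_ratio(candidates$tumor_tier1_alt,
                          candidates$tumor_tier1_total)
  normal2_maf <- safe_ratio(candidates$normal_tier2_alt,
                            candidates$normal_tier2_total)

  out <- candidates |>
    dplyr::mutate(
      rule_caller = .data$caller_pass %in% TRUE,
      rule_min_alt_reads = .data$tumor_tier1_alt >= min_alt_reads,
      rule_tumor_maf = !is.na(tumor_maf) & tumor_maf >= min_tumor_maf,
      rule_normal_coverage = .data$normal_tier1_total >= min_normal_coverage,
      rule_normal_alt = .data$normal_tier1_alt == 0,
      rule_normal_tier2_maf = !is.na(normal2_maf) &
        normal2_maf <= max_normal_tier2_maf,
      rule_population_af = is.na(.data$population_af) |
        .data$population_af <= max_population_af,
      rule_population_qc = .data$population_qc_pass %in% TRUE
    )
  rule_cols <- paste0("rule_", names(FILTER_RULES))
  rule_mat <- as.matrix(out[rule_cols])
  out$pass <- rowSums(!rule_mat) == 0
  reasons <- apply(!rule_mat, 1, function(v) {
    if (!any(v)) return(NA_character_)
    paste(FILTER_RULES[v], collapse = "; ")
  })
  # annotate undefined ratios explicitly
  und_t <- is.na(tumor_maf) & !is.na(candidates$tumor_tier1_total)
  und_n <- is.na(normal2_maf)
  reasons[und_t & !is.na(reasons)] <-
    sub("tumor tier1 MAF", "tumor tier1 MAF (undefined ratio)",
        reasons[und_t & !is.na(reasons)])
  reasons[und_n & !is.na(reasons)] <-
    sub("normal tier2 MAF", "normal tier2 MAF (undefined ratio)",
        reasons[und_n & !is.na(reasons)])
  out$fail_reasons <- reasons
  attr(out, "n_rejected_non_sbs") <- n_non_sbs
  out
}

safe_ratio <- function(num, den) {
  ifelse(is.na(den) | den == 0, NA_real_, num / den)
}

#' Decide patient evaluability for tumor-informed monitoring
#'
#' A patient is evaluable when the tumor mutation set retains at least
#' `min_mutations` passing variants (boundary inclusive), enough to detect
#' circulating tumor DNA at low tumor fractions.
#'
#' @param x A filtered candidate tibble from [apply_somatic_filters()] (its
#'   `pass` column is counted) or a single mutation count.
#' @param min_mutations Evaluability threshold (default 50).
#' @return Logical flag.
#' @examples
#' evaluability(50) # TRUE
#' evaluability(49) # FALSE
#' @export
evaluability <- function(x, min_mutations = 50) {
  n <- if (is.data.frame(x)) sum(x$pass) else as.numeric(x)
  n >= min_mutations
}

#' Tally the mutation spectrum of a passing variant set
#'
#' Counts passing variants per pyrimidine-context substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G). Variants whose reference allele is a
#' purine are mapped to the reverse-complement class.
#'
#' @param variants Tibble with `ref_allele`/`alt_allele` (and optionally a
#'   `pass` column; only passing rows are tallied when present).
#' @return Tibble with columns `substitution_class` and `n` (all six
#'   classes always present; counts sum to the number of variants tallied).
#' @export
mutation_spectrum <- function(variants) {
  if ("pass" %in% names(variants)) {
    variants <- dplyr::filter(variants, .data$pass)
  }
  if (!nrow(variants)) {
    return(tibble::tibble(substitution_class = SUBSTITUTION_CLASSES, n = 0L))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- variants$ref_allele
  alt <- variants$alt_allele
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp[variants$ref_allele[purine]]
  alt[purine] <- comp[variants$alt_allele[purine]]
  cls <- paste0(ref, ">", alt)
  tab <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  tibble::tibble(substitution_class = SUBSTITUTION_CLASSES,
                 n = as.integer(tab))
}
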