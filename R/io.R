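# File interfaces: candidate variants as VCF (1-based; tier read counts in
# per-sample FORMAT fields, population allele frequency as an INFO tag),
# fragments as 6-column BED-like TSV (0-based half-open), pileup evidence
# and cohort tables as TSV.

#' Write candidate variants as VCF
#'
#' Emits a minimal VCF 4.2 with TUMOR and NORMAL sample columns carrying
#' tier-1/tier-2 alt and total read counts (FORMAT `T1A:T1T:T2A:T2T`), the
#' population allele frequency as an INFO tag, a `POPQC_FAIL` INFO flag for
#' variants failing the population database's quality filters, and FILTER
#' PASS/`caller_fail`.
#'
#' @param candidates Candidate tibble (see `required_candidate_cols()`).
#' @param path Output path.
#' @param pop_af_tag INFO tag name for the population allele frequency.
#' @return `path`, invisibly.
#' @export
write_candidate_vcf <- function(candidates, path, pop_af_tag = "POP_AF") {
  cand <- tibble::as_tibble(candidates)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cfmonitor",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population allele frequency\">",
            pop_af_tag),
    "##INFO=<ID=POPQC_FAIL,Number=0,Type=Flag,Description=\"Failed population database quality filters\">",
    "##FILTER=<ID=caller_fail,Description=\"Failed upstream somatic caller filters\">",
    "##FORMAT=<ID=T1A,Number=1,Type=Integer,Description=\"Tier 1 alt reads\">",
    "##FORMAT=<ID=T1T,Number=1,Type=Integer,Description=\"Tier 1 total reads\">",
    "##FORMAT=<ID=T2A,Number=1,Type=Integer,Description=\"Tier 2 alt reads\">",
    "##FORMAT=<ID=T2T,Number=1,Type=Integer,Description=\"Tier 2 total reads\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  info <- ifelse(is.na(cand$population_af), ".",
                 sprintf("%s=%.6g", pop_af_tag, cand$population_af))
  qcflag <- ifelse(cand$population_qc_pass, "", "POPQC_FAIL")
  info <- ifelse(qcflag == "", info,
                 ifelse(info == ".", qcflag, paste(info, qcflag, sep = ";")))
  tumor <- sprintf("%d:%d:.:.", cand$tumor_tier1_alt, cand$tumor_tier1_total)
  normal <- sprintf("%d:%d:%d:%d", cand$normal_tier1_alt,
                    cand$normal_tier1_total, cand$normal_tier2_alt,
                    cand$normal_tier2_total)
  body <- paste(cand$chrom, cand$pos, ".", cand$ref_allele,
                cand$alt_allele, ".",
                ifelse(cand$caller_pass, "PASS", "caller_fail"),
                info, "T1A:T1T:T2A:T2T", tumor, normal, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read candidate variants from VCF
#'
#' Parses a tumor/normal VCF into the candidate-variant schema:
#' `caller_pass` from FILTER == PASS, tier read counts from the TUMOR and
#' NORMAL FORMAT fields, population allele frequency from a configurable
#' INFO tag, population QC from the absence of a `POPQC_FAIL` flag.
#' Multi-allelic records are split into biallelic candidates; indels are
#' rejected with a counted warning.
#'
#' @param path VCF file.
#' @param pop_af_tag INFO tag holding the population allele frequency.
#' @return Candidate tibble; attribute `n_rejected_indels` counts dropped
#'   non-SBS records.
#' @export
read_candidate_vcf <- function(path, pop_af_tag = "POP_AF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  gt <- v@gt
  fmt_get <- function(sample, key) {
    keys <- strsplit(gt[, "FORMAT"], ":")
    vals <- strsplit(gt[, sample], ":")
    vapply(seq_along(keys), function(i) {
      j <- match(key, keys[[i]])
      if (is.na(j)) return(NA_integer_)
      x <- vals[[i]][j]
      if (is.na(x) || x == ".") NA_integer_ else as.integer(x)
    }, integer(1))
  }
  info <- as.character(v@fix[, "INFO"])
  info[is.na(info)] <- "."
  info_num <- function(tag) {
    m <- stringr::str_match(info, paste0("(?:^|;)", tag, "=([^;]+)"))[, 2]
    as.numeric(m)
  }
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    caller_pass = fix$FILTER %in% c("PASS", "."),
    tumor_tier1_alt = fmt_get("TUMOR", "T1A"),
    tumor_tier1_total = fmt_get("TUMOR", "T1T"),
    normal_tier1_alt = fmt_get("NORMAL", "T1A"),
    normal_tier1_total = fmt_get("NORMAL", "T1T"),
    normal_tier2_alt = fmt_get("NORMAL", "T2A"),
    normal_tier2_total = fmt_get("NORMAL", "T2T"),
    population_af = info_num(pop_af_tag),
    population_qc_pass = !str_detect(info, "POPQC_FAIL"))
  # split multi-allelic records into biallelic candidates
  out <- out |>
    dplyr::mutate(alt_allele = strsplit(.data$alt_allele, ",")) |>
    tidyr::unnest("alt_allele")
  sbs <- nchar(out$ref_allele) == 1 & nchar(out$alt_allele) == 1 &
    out$ref_allele %in% c("A", "C", "G", "T") &
    out$alt_allele %in% c("A", "C", "G", "T")
  n_indels <- sum(!sbs)
  if (n_indels) {
    warn(sprintf("rejected %d non-single-base-substitution record(s)",
                 n_indels))
    out <- out[sbs, ]
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_p <- ifelse(out$ref_allele %in% c("A", "G"),
                  comp[out$ref_allele], out$ref_allele)
  alt_p <- ifelse(out$ref_allele %in% c("A", "G"),
                  comp[out$alt_allele], out$alt_allele)
  out$substitution_class <- paste0(ref_p, ">", alt_p)
  attr(out, "n_rejected_indels") <- n_indels
  out
}

#' Write and read fragment tables as BED-like TSV
#'
#' Six columns (chrom, start, end, length, gc, mapq), 0-based half-open
#' coordinates, tab-separated with a header line.
#'
#' @param fragments Fragment tibble.
#' @param path File path.
#' @return `path` (write) or a fragment tibble (read).
#' @export
write_fragments_tsv <- function(fragments, path) {
  cols <- intersect(c("chrom", "start", "end", "length", "gc", "mapq"),
                    names(fragments))
  utils::write.table(as.data.frame(fragments[cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}
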