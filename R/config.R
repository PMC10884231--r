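#' Curation thresholds and policies
#'
#' All numeric policies used by the curation stages live in one configuration
#' object so a run is fully described by (inputs, config, seed).
#'
#' @param min_independent_reports minimum number of independent evidence
#'   reports required to confirm a candidate (default 2).
#' @param major_truncation_nt missing nucleotides at one end at or beyond
#'   which a V candidate is excluded as majorly truncated (default 25).
#' @param minor_truncation_max_nt maximum extension length that may be based
#'   on the endings of similar alleles (default 2). Genomic, AIRR-consensus
#'   and IARC-recommended donors may exceed this.
#' @param min_airr_individuals minimum number of distinct individuals behind
#'   an AIRR-seq inference for it to count as one (corroborated) report
#'   (default 2).
#' @param min_airr_individuals_novel_genomic minimum individual count for a
#'   single genomic study to confirm a previously unreported (novel) sequence
#'   on its own (default 6).
#' @param min_genomic_individuals minimum individual count for a single
#'   genomic study to confirm a previously reported sequence on its own
#'   (default 2).
#' @param haplotype_purity fraction of an allele's anchored reads that must
#'   sit on one anchor-J haplotype for assignment to that haplotype
#'   (default 0.95).
#' @param haplotype_min_reads minimum anchored reads per V allele before any
#'   haplotype assignment is attempted (default 10).
#' @param haplotype_mutation_cap maximum V mutation count for a rearrangement
#'   to inform haplotyping (default 0, i.e. unmutated reads only).
#' @param proximal_freq_hi per-individual expression frequency (percent of
#'   the productive VJ repertoire) at or above which a kappa gene is called
#'   proximal (default 4.0).
#' @param distal_freq_lo frequency (percent) at or below which expression is
#'   consistent with a distal location (default 0.6).
#' @param d_central_margin_nt number of nucleotides at each end of an IGHD
#'   gene considered too exonuclease-exposed to carry allele-defining
#'   information (default 3).
#' @param iarc_auto_confirm if `TRUE`, an IARC affirmation confirms a
#'   candidate on its own; by default it counts as one report like any other
#'   (default `FALSE`).
#' @param seed integer seed recorded with the configuration.
#' @return a `curation_config` object (named list).
#' @examples
#' curation_config()
#' curation_config(haplotype_purity = 0.9)
#' @export
curation_config <- function(min_independent_reports = 2L,
                            major_truncation_nt = 25L,
                            minor_truncation_max_nt = 2L,
                            min_airr_individuals = 2L,
                            min_airr_individuals_novel_genomic = 6L,
                            min_genomic_individuals = 2L,
                            haplotype_purity = 0.95,
                            haplotype_min_reads = 10L,
                            haplotype_mutation_cap = 0L,
                            proximal_freq_hi = 4.0,
                            distal_freq_lo = 0.6,
                            d_central_margin_nt = 3L,
                            iarc_auto_confirm = FALSE,
                            seed = 1L) {
  cfg <- list(
    min_independent_reports = as.integer(min_independent_reports),
    major_truncation_nt = as.integer(major_truncation_nt),
    minor_truncation_max_nt = as.integer(minor_truncation_max_nt),
    min_airr_individuals = as.integer(min_airr_individuals),
    min_airr_individuals_novel_genomic = as.integer(min_airr_individuals_novel_genomic),
    min_genomic_individuals = as.integer(min_genomic_individuals),
    haplotype_purity = as.numeric(haplotype_purity),
    haplotype_min_reads = as.integer(haplotype_min_reads),
    haplotype_mutation_cap = as.integer(haplotype_mutation_cap),
    proximal_freq_hi = as.numeric(proximal_freq_hi),
    distal_freq_lo = as.numeric(distal_freq_lo),
    d_central_margin_nt = as.integer(d_central_margin_nt),
    iarc_auto_confirm = isTRUE(iarc_auto_confirm),
    seed = as.integer(seed)
  )
  if (!(cfg$haplotype_purity > 0.5 && cfg$haplotype_purity <= 1)) {
    abort("haplotype_purity must satisfy 0.5 < purity <= 1")
  }
  if (!(cfg$proximal_freq_hi > cfg$distal_freq_lo && cfg$distal_freq_lo > 0)) {
    abort("frequency bands must satisfy proximal_freq_hi > distal_freq_lo > 0")
  }
  if (cfg$min_independent_reports < 1L) abort("min_independent_reports must be >= 1")
  if (cfg$major_truncation_nt <= cfg$minor_truncation_max_nt) {
    abort("major_truncation_nt must exceed minor_truncation_max_nt")
  }
  structure(cfg, class = "curation_config")
}

#' @export
print.curation_config <- function(x, ...) {
  cat("<curation_config>\n")
  for (nm in names(x)) cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
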