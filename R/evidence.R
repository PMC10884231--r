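# Evidence evaluation: a candidate enters the Source Set only when its
# reported sequence is supported by independent evidence under these rules:
#   (a) genomic studies from different laboratories are independent reports;
#   (b) repeated reports from one laboratory collapse to a single report,
#       unless a genomic report unequivocally covers multiple individuals,
#       in which case that single study suffices on its own;
#   (c) AIRR-seq inferences count as one report only when seen in enough
#       distinct individuals AND corroborated by an unrearranged GenBank
#       record;
#   (d) an IARC affirmation counts as one report (configurably, as
#       sufficient on its own);
#   (e) a GenBank unrearranged record alone is a corroborator, not a report.
# IGHD expression (AIRR) evidence is additionally subject to the central-
# nucleotide admissibility rules.

#' Count independent evidence reports for one candidate
#'
#' Applies the independence rules to a candidate's typed evidence items and
#' decides confirmation. A single genomic study confirms on its own when its
#' individual count reaches `min_genomic_individuals` (or
#' `min_airr_individuals_novel_genomic` for novel sequences with no prior
#' report, recognised by temporary-name markers such as "NL" or "*i").
#'
#' @param evidence tibble of evidence items (`kind`, `study_id`,
#'   `laboratory`, `n_individuals`, `mapped_locus`, `accession`).
#' @param config a [curation_config()].
#' @param novel is the candidate a previously unreported (novel) sequence?
#' @param airr_admissible may AIRR-seq evidence be counted for this
#'   candidate? (`FALSE` for IGHD alleles failing the central-nucleotide
#'   rules.)
#' @param name candidate name, used in the rationale strings.
#' @return one-row tibble: `candidate_name`, `confirmed`,
#'   `independent_report_count`, `rationale` (list-column of strings naming
#'   the counted reports and applied rules).
#' @examples
#' ev <- tibble::tibble(
#'   kind = c("genomic_study", "genomic_study"),
#'   study_id = c("s1", "s2"), laboratory = c("labA", "labB"),
#'   n_individuals = c(1L, 1L), mapped_locus = NA_character_,
#'   accession = NA_character_
#' )
#' count_independent_reports(ev)
#' @export
count_independent_reports <- function(evidence, config = curation_config(),
                                      novel = FALSE, airr_admissible = TRUE,
                                      name = NA_character_) {
  res <- count_reports_core(validate_evidence(evidence), config, novel,
                            airr_admissible)
  tibble(
    candidate_name = name,
    confirmed = res$confirmed,
    independent_report_count = res$count,
    rationale = list(res$rationale)
  )
}

# Core of the independence rules over a validated evidence table; returns a
# plain list to keep per-candidate overhead low on large collections.
count_reports_core <- function(evidence, config, novel = FALSE,
                               airr_admissible = TRUE) {
  usable <- (!is.na(evidence$n_individuals) & evidence$n_individuals >= 1L) |
    evidence$kind %in% c("iarc_affirmation", "genbank_unrearranged")
  kind <- evidence$kind[usable]
  study <- evidence$study_id[usable]
  lab <- evidence$laboratory[usable]
  n_ind <- evidence$n_individuals[usable]
  accession <- evidence$accession[usable]

  rationale <- character(0)
  count <- 0L
  confirmed_alone <- FALSE

  genomic <- which(kind == "genomic_study")
  if (length(genomic) > 0) {
    labs <- unique(lab[genomic])
    count <- count + length(labs)
    rationale <- c(rationale, sprintf(
      "genomic reports from %d independent laborator%s (%s)",
      length(labs), if (length(labs) == 1) "y" else "ies",
      paste(labs, collapse = ", ")
    ))
    threshold <- if (novel) config$min_airr_individuals_novel_genomic else
      config$min_genomic_individuals
    multi <- genomic[n_ind[genomic] >= threshold]
    if (length(multi) > 0) {
      confirmed_alone <- TRUE
      rationale <- c(rationale, sprintf(
        "multi-individual genomic exception: %s reports %d individuals (threshold %d%s)",
        study[multi[[1]]], n_ind[multi[[1]]], threshold,
        if (novel) ", novel sequence" else ""
      ))
    }
  }

  airr <- which(kind == "airr_inference")
  genbank <- which(kind == "genbank_unrearranged")
  if (length(airr) > 0) {
    enough <- any(n_ind[airr] >= config$min_airr_individuals)
    if (!airr_admissible) {
      rationale <- c(rationale, "AIRR-seq evidence inadmissible for this candidate")
    } else if (enough && length(genbank) > 0) {
      count <- count + 1L
      rationale <- c(rationale, sprintf(
        "AIRR-seq inference in %d individuals corroborated by GenBank %s",
        max(n_ind[airr]), accession[genbank[[1]]] %||% "record"
      ))
    } else if (!enough) {
      rationale <- c(rationale, sprintf(
        "AIRR-seq inference not counted: fewer than %d individuals",
        config$min_airr_individuals
      ))
    } else {
      rationale <- c(rationale, "AIRR-seq inference not counted: no unrearranged GenBank corroboration")
    }
  }

  iarc <- which(kind == "iarc_affirmation")
  if (length(iarc) > 0) {
    count <- count + 1L
    rationale <- c(rationale, sprintf("IARC affirmation (%s)", study[iarc[[1]]]))
    if (config$iarc_auto_confirm) confirmed_alone <- TRUE
  }

  if (length(genbank) > 0 && length(airr) == 0) {
    rationale <- c(rationale, "GenBank unrearranged record is a corroborator only")
  }

  list(
    confirmed = count >= config$min_independent_reports || confirmed_alone,
    count = count,
    rationale = rationale
  )
}

#' IGHD expression-evidence admissibility
#'
#' Exonuclease trimming obscures IGHD gene ends in expressed rearrangements,
#' so AIRR-seq genotypes can only confirm centrally located gene- and
#' allele-defining nucleotides. Expression evidence is admissible for a D
#' allele only when every distinguishing position lies at least
#' `d_central_margin_nt` from both ends, the allele is long enough to have a
#' confirmable centre, and the allele is not a member of an
#' identical-sequence pair (expression cannot attribute reads to either
#' member).
#'
#' @param allele_length length of the D allele in nucleotides.
#' @param distinguishing_positions 0-based offsets of the nucleotides that
#'   separate this allele from all of its same-length relatives; empty means
#'   nothing is confirmable.
#' @param identical_pair_member is the allele one of an identical-sequence
#'   gene pair?
#' @param config a [curation_config()].
#' @return single logical.
#' @examples
#' d_expression_admissible(17, 8)        # central position: admissible
#' d_expression_admissible(17, 16)       # terminal position: not admissible
#' @export
d_expression_admissible <- function(allele_length, distinguishing_positions,
                                    identical_pair_member = FALSE,
                                    config = curation_config()) {
  m <- config$d_central_margin_nt
  if (identical_pair_member) return(FALSE)
  if (length(distinguishing_positions) == 0) return(FALSE)
  if (allele_length <= 2L * m + 1L) return(FALSE)
  all(distinguishing_positions >= m &
        distinguishing_positions <= allele_length - 1L - m)
}

# 0-based positions at which `sequence` differs from every same-length
# relative; NULL when there are no same-length relatives.
d_distinguishing_positions <- function(sequence, relatives) {
  relatives <- relatives[nchar(relatives) == nchar(sequence)]
  if (length(relatives) == 0) return(NULL)
  s <- utf8ToInt(sequence)
  diff_all <- rep(TRUE, length(s))
  for (r in relatives) diff_all <- diff_all & (s != utf8ToInt(r))
  which(diff_all) - 1L
}

# Candidate novelty: temporary designations with no prior report use "NL"
# gene labels or IARC-style "*iNN" allele suffixes.
is_novel_name <- function(name) {
  grepl("NL", allele_gene(name)) | grepl("\\*i[0-9]*$", name)
}

#' Confirm candidates against the evidence independence rules
#'
#' Maps [count_independent_reports()] over a candidate collection, applying
#' the IGHD expression-admissibility pre-filter to AIRR evidence of D
#' candidates (relatives are the other structurally passing D candidates of
#' the same length; a D candidate with no same-length relative keeps its
#' AIRR evidence, since length alone is gene-defining).
#'
#' @param candidates candidate tibble with nested `evidence`.
#' @param config a [curation_config()].
#' @return tibble with one row per candidate: `candidate_name`, `confirmed`,
#'   `independent_report_count`, `rationale`.
#' @export
confirm_candidates <- function(candidates, config = curation_config()) {
  is_d <- candidates$chain == "IGH-D"
  admissible <- rep(TRUE, nrow(candidates))
  if (any(is_d)) {
    d_seq <- candidates$sequence[is_d]
    dup <- duplicated(d_seq) | duplicated(d_seq, fromLast = TRUE)
    adm_d <- map_lgl(seq_along(d_seq), function(i) {
      pos <- d_distinguishing_positions(d_seq[i], d_seq[-i])
      if (is.null(pos)) return(!dup[i])
      d_expression_admissible(nchar(d_seq[i]), pos, dup[i], config)
    })
    admissible[is_d] <- adm_d
  }
  novel <- is_novel_name(candidates$name)
  res <- map(seq_len(nrow(candidates)), function(i) {
    count_reports_core(validate_evidence(candidates$evidence[[i]]), config,
                       novel = novel[i], airr_admissible = admissible[i])
  })
  tibble(
    candidate_name = candidates$name,
    confirmed = map_lgl(res, "confirmed"),
    independent_report_count = map_int(res, "count"),
    rationale = map(res, "rationale")
  )
}

#' Build the Source Set from structurally passing, confirmed candidates
#'
#' Source Set entries report sequences exactly as they were reported: no
#' extension or collapse happens here. Structurally sound but unconfirmed
#' candidates are exported to an audit list so they can be re-evaluated when
#' new evidence accumulates.
#'
#' @param candidates candidate tibble with nested `evidence`.
#' @param structural_verdicts output of [structural_filter()] for the same
#'   candidates.
#' @param config a [curation_config()].
#' @return an `ig_source_build` list: `source_set` (entry tibble),
#'   `unconfirmed` (audit tibble), `confirmation` (full verdict tibble).
#' @seealso [build_reference_set()]
#' @export
build_source_set <- function(candidates, structural_verdicts,
                             config = curation_config()) {
  stopifnot(identical(candidates$name, structural_verdicts$name))
  passing <- structural_verdicts$passed
  conf <- confirm_candidates(candidates[passing, ], config)
  keep <- conf$confirmed
  kept <- candidates[passing, ][keep, ]
  verd <- structural_verdicts[passing, ][keep, ]
  entries <- new_entries(
    name = kept$name,
    sequence = kept$sequence,
    chain = kept$chain,
    locus = kept$putative_locus,
    is_orf = ifelse(is.na(verd$is_orf), TRUE, verd$is_orf),
    representative_accession = map_chr(kept$evidence, function(e) {
      acc <- e$accession[!is.na(e$accession) & nzchar(e$accession)]
      if (length(acc) > 0) acc[[1]] else NA_character_
    })
  )
  unconfirmed <- conf[!keep, ] %>%
    mutate(rationale = semicolon_join(.data$rationale))
  structure(
    list(
      source_set = validate_entries(entries),
      unconfirmed = unconfirmed,
      confirmation = conf
    ),
    class = "ig_source_build"
  )
}

#' @export
print.ig_source_build <- function(x, ...) {
  cat(sprintf(
    "<ig_source_build> %d confirmed entries, %d unconfirmed (audit list)\n",
    nrow(x$source_set), nrow(x$unconfirmed)
  ))
  invisible(x)
}
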