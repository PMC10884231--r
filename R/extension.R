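# Extension of truncated Source Set sequences for the Reference Set.
# Donor priority: IARC recommendation > genomic > AIRR consensus > endings
# of similar alleles; similar-allele donors are limited to one or two
# nucleotides, while the other donor kinds may repair longer deficits.
# Source Sets are never modified; every applied extension is flagged on the
# entry and listed in the release notes.

DONOR_PRIORITY <- c("iarc_recommendation", "genomic", "airr_consensus",
                    "similar_allele")

# Majority ending among the sound full-length alleles of the same gene;
# ties broken by lowest allele number. Returns NA when no same-gene allele
# is long enough.
similar_allele_ending <- function(entry_name, end, n_missing, entries) {
  gene <- allele_gene(entry_name)
  sibs <- entries[allele_gene(entries$name) == gene & entries$name != entry_name, ]
  need <- nchar(entries$sequence[entries$name == entry_name][[1]]) + n_missing
  sibs <- sibs[nchar(sibs$sequence) >= need, ]
  if (nrow(sibs) == 0) return(NA_character_)
  endings <- if (end == "3p") {
    substr(sibs$sequence, nchar(sibs$sequence) - n_missing + 1L, nchar(sibs$sequence))
  } else {
    substr(sibs$sequence, 1L, n_missing)
  }
  tab <- tibble(ending = endings, allele_num = allele_number(sibs$name)) %>%
    group_by(.data$ending) %>%
    summarise(votes = n(), best = min(.data$allele_num, na.rm = TRUE),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$votes), .data$best, .data$ending)
  tab$ending[[1]]
}

#' Plan extensions for truncated Source Set entries
#'
#' Entries shorter at an end than the longest allele of their gene
#' (fallback: their family, then the family exemplar) are flagged, and a
#' donor ending is chosen by fixed priority: IARC recommendation, then
#' genomic, then AIRR consensus, then the majority ending of similar
#' (same-gene) alleles. Similar-allele donors are capped at
#' `minor_truncation_max_nt` nucleotides; genomic/AIRR/IARC donors may
#' repair longer deficits (major truncations were already excluded
#' upstream). A flagged entry with no usable donor is left unextended with a
#' warning.
#'
#' @param entries Source Set entry tibble.
#' @param donors optional donor tibble (`name`, `end` in `"5p"/"3p"`,
#'   `nucleotides`, `kind` in
#'   `iarc_recommendation/genomic/airr_consensus/similar_allele`).
#' @param config a [curation_config()].
#' @param exemplars optional per-family exemplar tibble used as a length
#'   fallback.
#' @return plan tibble: `name`, `end`, `nucleotides`, `donor`, `missing_nt`.
#' @seealso [apply_extensions()]
#' @export
plan_extensions <- function(entries, donors = NULL, config = curation_config(),
                            exemplars = NULL) {
  entries <- as_tibble(entries)
  donors <- donors %||% tibble(name = character(0), end = character(0),
                               nucleotides = character(0), kind = character(0))
  if (nrow(donors) > 0) {
    bad_kind <- setdiff(unique(donors$kind), DONOR_PRIORITY)
    if (length(bad_kind) > 0) {
      abort(sprintf("unknown donor kind(s): %s", paste(bad_kind, collapse = ", ")))
    }
  }
  v_rows <- which(is_v_chain(entries$chain))
  if (length(v_rows) == 0) {
    return(tibble(name = character(0), end = character(0),
                  nucleotides = character(0), donor = character(0),
                  missing_nt = integer(0)))
  }
  vc <- entries[v_rows, c("name", "sequence")]
  sound <- tibble(
    name = vc$name,
    gene = allele_gene(vc$name),
    family = gene_family(allele_gene(vc$name)),
    sound = TRUE
  )
  ex <- exemplars %||% tibble(family = character(0), sequence = character(0))
  comps <- truncation_comparisons(vc, sound, ex)
  plans <- list()
  for (i in seq_along(v_rows)) {
    tr <- truncation_core(vc$sequence[i], comps[[i]]$sequence, config)
    if (tr$class == "none" || grepl("^major", tr$class)) next
    for (end in c("5p", "3p")) {
      n_missing <- if (end == "5p") tr$missing_5p else tr$missing_3p
      if (n_missing == 0L) next
      cand <- donors[donors$name == vc$name[i] & donors$end == end, ]
      cand <- cand[cand$kind != "similar_allele" |
                     nchar(cand$nucleotides) <= config$minor_truncation_max_nt, ]
      chosen <- NULL
      if (nrow(cand) > 0) {
        cand <- cand[order(match(cand$kind, DONOR_PRIORITY)), ]
        chosen <- list(nucleotides = cand$nucleotides[[1]], kind = cand$kind[[1]])
      } else if (n_missing <= config$minor_truncation_max_nt) {
        ending <- similar_allele_ending(vc$name[i], end, n_missing, entries)
        if (!is.na(ending)) {
          chosen <- list(nucleotides = ending, kind = "similar_allele")
        }
      }
      if (is.null(chosen)) {
        warn(sprintf(
          "no usable %s donor for truncated entry %s (%d nt missing); left unextended",
          end, vc$name[i], n_missing
        ))
        next
      }
      plans[[length(plans) + 1L]] <- list(
        name = vc$name[i], end = end,
        nucleotides = chosen$nucleotides[[1]],
        donor = chosen$kind[[1]],
        missing_nt = as.integer(n_missing)
      )
    }
  }
  if (length(plans) == 0) {
    return(tibble(name = character(0), end = character(0),
                  nucleotides = character(0), donor = character(0),
                  missing_nt = integer(0)))
  }
  tibble(
    name = map_chr(plans, "name"),
    end = map_chr(plans, "end"),
    nucleotides = map_chr(plans, "nucleotides"),
    donor = map_chr(plans, "donor"),
    missing_nt = map_int(plans, "missing_nt")
  )
}

#' Apply extension plans to entries
#'
#' Prepends/appends the planned donor nucleotides, sets `extended_5p` /
#' `extended_3p` and `extension_donor`, and never alters interior
#' nucleotides: stripping `extended_5p` leading and `extended_3p` trailing
#' characters recovers the pre-extension sequence exactly.
#'
#' @param entries entry tibble.
#' @param plans plan tibble from [plan_extensions()]. A plan naming an
#'   absent entry is an error.
#' @return extended entry tibble.
#' @export
apply_extensions <- function(entries, plans) {
  entries <- as_tibble(entries)
  missing_entries <- setdiff(plans$name, entries$name)
  if (length(missing_entries) > 0) {
    abort(sprintf("extension plan(s) reference absent entries: %s",
                  paste(missing_entries, collapse = ", ")))
  }
  for (i in seq_len(nrow(plans))) {
    row <- which(entries$name == plans$name[i])
    nt <- plans$nucleotides[i]
    assert_nucleotides(nt, "donor nucleotides")
    if (plans$end[i] == "5p") {
      entries$sequence[row] <- paste0(nt, entries$sequence[row])
      entries$extended_5p[row] <- entries$extended_5p[row] + nchar(nt)
    } else {
      entries$sequence[row] <- paste0(entries$sequence[row], nt)
      entries$extended_3p[row] <- entries$extended_3p[row] + nchar(nt)
    }
    current <- entries$extension_donor[row]
    entries$extension_donor[row] <- if (current == "none") plans$donor[i] else {
      DONOR_PRIORITY[min(match(c(current, plans$donor[i]), DONOR_PRIORITY))]
    }
  }
  validate_entries(entries)
}

#' Strip recorded extensions from entries
#'
#' Inverse of [apply_extensions()]: removes `extended_5p` leading and
#' `extended_3p` trailing nucleotides, recovering the Source Set sequence.
#'
#' @param entries extended entry tibble.
#' @return entry tibble with original sequences and cleared extension flags.
#' @export
strip_extensions <- function(entries) {
  entries <- as_tibble(entries)
  entries$sequence <- substr(
    entries$sequence,
    entries$extended_5p + 1L,
    nchar(entries$sequence) - entries$extended_3p
  )
  entries$extended_5p <- 0L
  entries$extended_3p <- 0L
  entries$extension_donor <- "none"
  validate_entries(entries)
}

#' Write the extension plan audit table
#'
#' @param plans plan tibble from [plan_extensions()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_extension_plans <- function(plans, path) {
  readr::write_tsv(plans, path, progress = FALSE)
  invisible(path)
}
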