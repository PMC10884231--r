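# Readers and writers for the pipeline's file dialects:
#   - candidate FASTA + evidence TSV (one row per evidence item)
#   - AIRR-rearrangement-style TSV
#   - GermlineSet-style JSON + annotated FASTA + plain-text release notes
#
# FASTA header dialect for emitted sets: `>name|paralog=a,b|alias=c` with
# empty segments omitted.

EVIDENCE_KINDS <- c("genomic_study", "airr_inference", "iarc_affirmation",
                    "genbank_unrearranged")

empty_evidence <- function() {
  tibble(
    kind = character(0), study_id = character(0), laboratory = character(0),
    n_individuals = integer(0), mapped_locus = character(0),
    accession = character(0)
  )
}

validate_evidence <- function(evidence) {
  evidence <- as_tibble(evidence)
  needed <- names(empty_evidence())
  missing_cols <- setdiff(needed, names(evidence))
  for (col in missing_cols) evidence[[col]] <- if (col == "n_individuals") NA_integer_ else NA_character_
  evidence$n_individuals <- as.integer(evidence$n_individuals)
  bad_kind <- !evidence$kind %in% EVIDENCE_KINDS
  if (any(bad_kind)) {
    abort(sprintf("unknown evidence kind(s): %s",
                  paste(unique(evidence$kind[bad_kind]), collapse = ", ")))
  }
  no_lab <- evidence$kind == "genomic_study" &
    (is.na(evidence$laboratory) | !nzchar(evidence$laboratory))
  if (any(no_lab)) abort("genomic_study evidence items must carry a laboratory identifier")
  evidence[, needed]
}

#' Read candidate alleles from FASTA plus an evidence table
#'
#' Candidate allele sequences are read from `fasta_path`; typed evidence
#' reports are read from the delimited table at `evidence_table_path`
#' (tab-separated; one row per (sequence, evidence item); columns
#' `sequence_name`, `kind`, `study_id`, `laboratory`, `n_individuals`,
#' `mapped_locus`, `accession`). Each evidence row must name a FASTA record;
#' a row naming an absent sequence is a hard error. FASTA order is preserved
#' and candidates without evidence rows carry empty evidence.
#'
#' @param fasta_path path to a nucleotide FASTA of candidate alleles; record
#'   names are allele designations (`gene*allele`).
#' @param evidence_table_path path to the evidence TSV, or `NULL` for no
#'   evidence.
#' @return a tibble with one row per candidate: `name`, `sequence`, `chain`,
#'   `putative_locus` and a nested `evidence` list-column of tibbles.
#' @seealso [structural_filter()], [build_source_set()]
#' @export
read_candidates <- function(fasta_path, evidence_table_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\|.*$", "", names(seqs))
  candidates <- tibble(
    name = nm,
    sequence = toupper(as.character(seqs))
  )
  evidence <- if (is.null(evidence_table_path)) {
    NULL
  } else {
    raw <- readr::read_tsv(
      evidence_table_path,
      col_types = readr::cols(
        sequence_name = readr::col_character(),
        kind = readr::col_character(),
        study_id = readr::col_character(),
        laboratory = readr::col_character(),
        n_individuals = readr::col_integer(),
        mapped_locus = readr::col_character(),
        accession = readr::col_character()
      ),
      progress = FALSE
    )
    if (!"sequence_name" %in% names(raw)) {
      abort("evidence table must carry a sequence_name column")
    }
    mutate(validate_evidence(raw), .name = raw$sequence_name)
  }
  if (!is.null(evidence) && nrow(evidence) > 0) {
    orphan <- setdiff(evidence$.name, candidates$name)
    if (length(orphan) > 0) {
      rows <- which(evidence$.name %in% orphan)
      abort(sprintf(
        "evidence row(s) %s name sequence(s) absent from the FASTA: %s",
        paste(head(rows, 5L), collapse = ", "),
        paste(head(orphan, 5L), collapse = ", ")
      ))
    }
  }
  as_candidates(candidates, evidence)
}

# Assemble the canonical candidate tibble from a name/sequence table and a
# long evidence table keyed by `.name`.
as_candidates <- function(candidates, evidence = NULL) {
  candidates <- as_tibble(candidates)
  assert_nucleotides(candidates$sequence, "candidate sequence")
  if (anyDuplicated(candidates$name)) {
    abort(sprintf("candidate names must be unique (duplicated: %s)",
                  paste(unique(candidates$name[duplicated(candidates$name)]), collapse = ", ")))
  }
  if (!"chain" %in% names(candidates)) candidates$chain <- chain_of(candidates$name)
  if (any(is.na(candidates$chain))) {
    abort("could not derive chain from candidate name(s); expected IG[HKL][VDJ] prefixes")
  }
  if (is.null(evidence)) evidence <- empty_evidence() %>% mutate(.name = character(0))
  ev_split <- split(select(evidence, -".name"), factor(evidence$.name, levels = candidates$name))
  candidates$evidence <- map(candidates$name, function(nm) {
    e <- ev_split[[nm]]
    if (is.null(e)) empty_evidence() else as_tibble(e)
  })
  if (!"putative_locus" %in% names(candidates)) {
    candidates$putative_locus <- map_chr(candidates$evidence, function(e) {
      loc <- e$mapped_locus[!is.na(e$mapped_locus) & nzchar(e$mapped_locus)]
      if (length(loc) > 0) loc[[1]] else "unlocated"
    })
  }
  candidates[, c("name", "sequence", "chain", "putative_locus", "evidence")]
}

#' Read and write AIRR-style rearrangement tables
#'
#' Rearrangement tables are tab-separated with columns `sequence_id`,
#' `individual_id`, `v_call`, `d_call`, `j_call`, `v_mutation_count`,
#' `productive` (additional columns are preserved).
#'
#' @param path file path.
#' @return `read_rearrangements()` returns a tibble of rearrangement records.
#' @export
read_rearrangements <- function(path) {
  rec <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("sequence_id", "individual_id", "v_call", "j_call")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    abort(sprintf("rearrangement table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"d_call" %in% names(rec)) rec$d_call <- NA_character_
  if (!"v_mutation_count" %in% names(rec)) rec$v_mutation_count <- 0L
  if (!"productive" %in% names(rec)) rec$productive <- TRUE
  rec$d_call <- as.character(rec$d_call)
  rec$v_mutation_count <- as.integer(rec$v_mutation_count)
  rec$productive <- as.logical(rec$productive)
  as_tibble(rec)
}

#' @rdname read_rearrangements
#' @param rearrangements tibble of rearrangement records.
#' @export
write_rearrangements <- function(rearrangements, path) {
  readr::write_tsv(rearrangements, path, progress = FALSE)
  invisible(path)
}

# Germline set entries -----------------------------------------------------

SCHEMA_VERSION <- "igrefset-germline-set-1.0"

new_entries <- function(name, sequence, chain, locus = "unlocated",
                        is_orf = TRUE, representative_accession = NA_character_) {
  tibble(
    name = name, sequence = sequence, chain = chain, locus = locus,
    is_orf = is_orf,
    extended_3p = 0L, extended_5p = 0L, extension_donor = "none",
    paralogs = rep(list(character(0)), length(name)),
    aliases = rep(list(character(0)), length(name)),
    representative_accession = representative_accession
  )
}

validate_entries <- function(entries) {
  entries <- as_tibble(entries)
  if (anyDuplicated(entries$name)) {
    abort(sprintf("duplicate entry names: %s",
                  paste(unique(entries$name[duplicated(entries$name)]), collapse = ", ")))
  }
  assert_nucleotides(entries$sequence, "entry sequence")
  ext <- entries$extended_3p + entries$extended_5p
  bad <- (ext > 0) != (entries$extension_donor != "none")
  if (any(bad)) {
    abort("extended_3p + extended_5p > 0 must hold exactly when extension_donor != 'none'")
  }
  inside <- unlist(entries$paralogs)
  clash <- intersect(inside, entries$name)
  if (length(clash) > 0) {
    abort(sprintf("paralog alias(es) also present as standalone entries: %s",
                  paste(clash, collapse = ", ")))
  }
  entries
}

set_fasta_header <- function(entries) {
  para <- map_chr(entries$paralogs, function(p)
    if (length(p) > 0) paste0("paralog=", paste(p, collapse = ",")) else "")
  alias <- map_chr(entries$aliases, function(a)
    if (length(a) > 0) paste0("alias=", paste(a, collapse = ",")) else "")
  parts <- cbind(entries$name, para, alias)
  apply(parts, 1L, function(r) paste(r[nzchar(r)], collapse = "|"))
}

release_notes_text <- function(entries, version_label) {
  extended <- filter(entries, .data$extension_donor != "none")
  groups <- filter(entries, map_int(.data$paralogs, length) > 0)
  lines <- c(
    sprintf("Reference Set release notes — %s", version_label),
    sprintf("entries: %d", nrow(entries)),
    "",
    "extended:"
  )
  if (nrow(extended) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(lines, sprintf(
      "  %s: +%d nt 5', +%d nt 3' (donor: %s)",
      extended$name, extended$extended_5p, extended$extended_3p,
      extended$extension_donor
    ))
  }
  lines <- c(lines, "", "collapsed paralog groups:")
  if (nrow(groups) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(lines, sprintf(
      "  %s = %s", groups$name,
      map_chr(groups$paralogs, paste, collapse = " = ")
    ))
  }
  lines
}

#' Write a versioned germline set (FASTA + JSON + release notes)
#'
#' Emits the set in three forms: an annotated FASTA whose headers carry
#' paralog/alias metadata (`>name|paralog=a,b|alias=c`), a JSON document with
#' the full per-entry metadata and the caller-supplied version label, and
#' plain-text release notes listing every extended entry (with donor and
#' length) and every collapsed paralog group.
#'
#' @param entries validated germline-set entry tibble (see
#'   [build_reference_set()]).
#' @param version_label caller-supplied version string; the tool never
#'   invents version numbers.
#' @param fasta_path,json_path,notes_path output paths (`NULL` to skip one).
#' @return invisibly, a one-row tibble summarising the release.
#' @seealso [read_reference_set()]
#' @export
write_reference_set <- function(entries, version_label, fasta_path = NULL,
                                json_path = NULL, notes_path = NULL) {
  entries <- validate_entries(entries)
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(entries$sequence)
    names(x) <- set_fasta_header(entries)
    Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  }
  if (!is.null(json_path)) {
    payload <- list(
      schema_version = SCHEMA_VERSION,
      version_label = version_label,
      n_entries = nrow(entries),
      entries = map(seq_len(nrow(entries)), function(i) {
        e <- entries[i, ]
        list(
          name = e$name, sequence = e$sequence, chain = e$chain,
          locus = e$locus, is_orf = e$is_orf,
          extended_3p = e$extended_3p, extended_5p = e$extended_5p,
          extension_donor = e$extension_donor,
          paralogs = as.list(e$paralogs[[1]]),
          aliases = as.list(e$aliases[[1]]),
          representative_accession = e$representative_accession
        )
      })
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null")
  }
  if (!is.null(notes_path)) {
    writeLines(release_notes_text(entries, version_label), notes_path)
  }
  invisible(tibble(
    version_label = version_label,
    n_entries = nrow(entries),
    n_extended = sum(entries$extension_donor != "none"),
    n_paralog_groups = sum(map_int(entries$paralogs, length) > 0)
  ))
}

#' Read a germline set back from its JSON form
#'
#' The JSON emitted by [write_reference_set()] round-trips losslessly: all
#' entry fields, including extension flags and paralog/alias lists, are
#' restored.
#'
#' @param json_path path to a germline-set JSON document.
#' @return a list with `entries` (tibble) and `version_label`.
#' @export
read_reference_set <- function(json_path) {
  payload <- jsonlite::read_json(json_path)
  if (!identical(payload$schema_version, SCHEMA_VERSION)) {
    abort(sprintf("unsupported schema_version: %s", payload$schema_version %||% "<missing>"))
  }
  entries <- bind_rows(map(payload$entries, function(e) {
    tibble(
      name = e$name, sequence = e$sequence, chain = e$chain, locus = e$locus,
      is_orf = isTRUE(e$is_orf),
      extended_3p = as.integer(e$extended_3p),
      extended_5p = as.integer(e$extended_5p),
      extension_donor = e$extension_donor,
      paralogs = list(as.character(unlist(e$paralogs))),
      aliases = list(as.character(unlist(e$aliases))),
      representative_accession = e$representative_accession %||% NA_character_
    )
  }))
  list(entries = validate_entries(entries), version_label = payload$version_label)
}

#' Write candidate inputs (FASTA + evidence TSV)
#'
#' Emits a candidate tibble back into the file dialect consumed by
#' [read_candidates()]; used by the synthetic-data module and the demo
#' pipeline.
#'
#' @param candidates candidate tibble with nested `evidence`.
#' @param fasta_path,evidence_table_path output paths.
#' @return invisibly, the FASTA path.
#' @export
write_candidates <- function(candidates, fasta_path, evidence_table_path) {
  x <- Biostrings::DNAStringSet(candidates$sequence)
  names(x) <- candidates$name
  Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  ev <- tidyr::unnest(
    select(candidates, "name", "evidence"), "evidence"
  ) %>% rename(sequence_name = "name")
  if (nrow(ev) == 0) {
    ev <- tibble(sequence_name = character(0)) %>%
      dplyr::bind_cols(empty_evidence())
  }
  readr::write_tsv(ev, evidence_table_path, progress = FALSE)
  invisible(fasta_path)
}
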