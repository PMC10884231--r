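# Orchestration: Source Set -> Reference Set (extension planning, extension,
# exact-paralog collapse), versioned emission, version diffs, and comparison
# against an external reference directory.

#' Build a Reference Set from a Source Set
#'
#' Pipeline order: extension planning, extension, exact-paralog collapse.
#' The Source Set itself is never modified. The entry count satisfies
#' `|reference| = |source| - collapsed duplicates`.
#'
#' @param source_set Source Set entry tibble (see [build_source_set()]).
#' @param donors optional donor tibble for [plan_extensions()].
#' @param overrides optional representative overrides for
#'   [collapse_paralogs()].
#' @param config a [curation_config()].
#' @param exemplars optional per-family exemplar tibble (length fallback for
#'   truncation flagging).
#' @param version_label version string recorded in the release notes.
#' @return an `ig_reference_build` list: `reference_set`, `plans`,
#'   `release_notes` (character lines), `source_size`, `version_label`.
#' @seealso [glance.ig_reference_build()], [write_reference_set()]
#' @export
build_reference_set <- function(source_set, donors = NULL, overrides = NULL,
                                config = curation_config(), exemplars = NULL,
                                version_label = "unversioned") {
  source_set <- validate_entries(source_set)
  plans <- plan_extensions(source_set, donors, config, exemplars)
  extended <- apply_extensions(source_set, plans)
  reference <- collapse_paralogs(extended, overrides)
  structure(
    list(
      reference_set = reference,
      plans = plans,
      release_notes = release_notes_text(reference, version_label),
      source_size = nrow(source_set),
      version_label = version_label
    ),
    class = "ig_reference_build"
  )
}

#' @export
print.ig_reference_build <- function(x, ...) {
  cat(sprintf(
    "<ig_reference_build> %s: %d source entries -> %d reference entries (%d extended, %d collapsed)\n",
    x$version_label, x$source_size, nrow(x$reference_set),
    sum(x$reference_set$extension_donor != "none"),
    x$source_size - nrow(x$reference_set)
  ))
  invisible(x)
}

#' Compare a built set against an external comparator
#'
#' Comparison is by exact nucleotide sequence (names may differ between
#' naming systems). Both sides are reduced to their distinct sequences
#' first, mirroring the paralog-collapsed representation; orphons (names
#' containing `"/OR"`) are excluded. The three partitions are disjoint and
#' exhaustive.
#'
#' @param built_set entry tibble of the built set (needs `name`,
#'   `sequence`).
#' @param comparator_set comparator tibble (`name`, `sequence`).
#' @return an `ig_set_comparison` list: counts `shared_n`, `built_only_n`,
#'   `comparator_only_n` and name-list tibbles `shared`, `built_only`,
#'   `comparator_only`.
#' @export
compare_sets <- function(built_set, comparator_set) {
  drop_orphons <- function(x) filter(as_tibble(x), !grepl("/OR", .data$name))
  collapse_seq <- function(x) {
    x %>%
      group_by(.data$sequence) %>%
      summarise(names = list(sort(.data$name)), .groups = "drop")
  }
  b <- collapse_seq(drop_orphons(built_set))
  m <- collapse_seq(drop_orphons(comparator_set))
  shared_seq <- intersect(b$sequence, m$sequence)
  part <- function(x, seqs) {
    filter(x, .data$sequence %in% seqs) %>%
      mutate(name = map_chr(.data$names, paste, collapse = "=")) %>%
      select("name", "sequence")
  }
  structure(
    list(
      shared_n = length(shared_seq),
      built_only_n = nrow(b) - length(shared_seq),
      comparator_only_n = nrow(m) - length(shared_seq),
      shared = part(b, shared_seq),
      built_only = part(b, setdiff(b$sequence, shared_seq)),
      comparator_only = part(m, setdiff(m$sequence, shared_seq))
    ),
    class = "ig_set_comparison"
  )
}

#' @export
print.ig_set_comparison <- function(x, ...) {
  cat(sprintf(
    "<ig_set_comparison> shared %d | built-only %d | comparator-only %d\n",
    x$shared_n, x$built_only_n, x$comparator_only_n
  ))
  invisible(x)
}

#' Diff two versions of a germline set
#'
#' Entries are matched by name. Modified entries report which fields changed
#' and whether the sequence itself changed.
#'
#' @param set_v1,set_v2 entry tibbles of the two versions.
#' @return list with `added`, `removed` (character vectors) and `modified`
#'   (tibble: `name`, `sequence_changed`, `fields` list-column).
#' @export
diff_versions <- function(set_v1, set_v2) {
  v1 <- validate_entries(set_v1)
  v2 <- validate_entries(set_v2)
  added <- setdiff(v2$name, v1$name)
  removed <- setdiff(v1$name, v2$name)
  common <- intersect(v1$name, v2$name)
  fields <- c("sequence", "chain", "locus", "is_orf", "extended_3p",
              "extended_5p", "extension_donor", "paralogs", "aliases",
              "representative_accession")
  modified <- list()
  for (nm in common) {
    a <- v1[v1$name == nm, ]
    b <- v2[v2$name == nm, ]
    changed <- fields[map_lgl(fields, function(f) !identical(a[[f]][[1]], b[[f]][[1]]))]
    if (length(changed) > 0) {
      modified[[length(modified) + 1L]] <- tibble(
        name = nm,
        sequence_changed = "sequence" %in% changed,
        fields = list(changed)
      )
    }
  }
  list(
    added = added,
    removed = removed,
    modified = if (length(modified) > 0) bind_rows(modified) else
      tibble(name = character(0), sequence_changed = logical(0), fields = list())
  )
}

#' Run the full curation pipeline on candidate files
#'
#' Reads candidates and evidence, applies the structural gates, confirms
#' against the evidence rules, builds the Reference Set and writes every
#' artifact (Source/Reference Set FASTA + JSON, structural and confirmation
#' audit TSVs, extension plan TSV, release notes, stage-count JSON) into
#' `output_dir`. Per-stage counts are logged to stderr.
#'
#' @param fasta_path,evidence_path candidate inputs (see
#'   [read_candidates()]).
#' @param output_dir output directory (created if absent).
#' @param exemplars_path optional TSV of family exemplars (`family`,
#'   `sequence`, `cys1_start`, `cys2_start`); required for V candidates.
#' @param donors_path optional donor TSV (`name`, `end`, `nucleotides`,
#'   `kind`).
#' @param overrides optional character vector of representative overrides.
#' @param config a [curation_config()].
#' @param version_label version string for the emitted sets.
#' @return invisibly, a named list of stage counts.
#' @export
run_pipeline <- function(fasta_path, evidence_path, output_dir,
                         exemplars_path = NULL, donors_path = NULL,
                         overrides = NULL, config = curation_config(),
                         version_label = "v1") {
  for (p in c(fasta_path, evidence_path, exemplars_path, donors_path)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  candidates <- read_candidates(fasta_path, evidence_path)
  exemplars <- if (!is.null(exemplars_path)) {
    readr::read_tsv(exemplars_path, col_types = readr::cols(), progress = FALSE)
  }
  donors <- if (!is.null(donors_path)) {
    readr::read_tsv(donors_path, col_types = readr::cols(), progress = FALSE)
  }
  verdicts <- structural_filter(candidates, exemplars, config)
  src <- build_source_set(candidates, verdicts, config)
  build <- build_reference_set(
    src$source_set, donors = donors, overrides = overrides,
    config = config, exemplars = exemplars, version_label = version_label
  )
  out <- function(f) file.path(output_dir, f)
  write_verdicts(verdicts, out("structural_verdicts.tsv"))
  readr::write_tsv(src$unconfirmed, out("unconfirmed.tsv"), progress = FALSE)
  write_reference_set(src$source_set, paste0(version_label, "-source"),
                      out("source_set.fasta"), out("source_set.json"), NULL)
  write_reference_set(build$reference_set, version_label,
                      out("reference_set.fasta"), out("reference_set.json"),
                      out("release_notes.txt"))
  write_extension_plans(build$plans, out("extension_plans.tsv"))
  counts <- list(
    candidates = nrow(candidates),
    structural_rejected = sum(!verdicts$passed),
    unconfirmed = nrow(src$unconfirmed),
    source_set = nrow(src$source_set),
    extended = nrow(build$plans),
    reference_set = nrow(build$reference_set)
  )
  jsonlite::write_json(counts, out("stage_counts.json"), auto_unbox = TRUE)
  message(paste(sprintf("%s: %d", names(counts), unlist(counts)), collapse = " | "))
  invisible(counts)
}

#' Run the synthetic end-to-end demonstration
#'
#' Generates a ground-truth locus, emits noisy candidate reports through the
#' file dialects, runs the full pipeline on them, simulates a repertoire and
#' phases it by the anchor J gene, writing all artifacts to `output_dir`.
#'
#' @param output_dir output directory.
#' @param seed integer seed driving every random draw.
#' @param config a [curation_config()].
#' @return invisibly, the stage-count list from [run_pipeline()] augmented
#'   with repertoire counts.
#' @export
run_demo <- function(output_dir, seed = 42L, config = curation_config()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  locus <- generate_locus(seed = seed)
  reports <- generate_reports(locus, seed = seed + 1L)
  out <- function(f) file.path(output_dir, f)
  write_candidates(reports$candidates, out("candidates.fasta"), out("evidence.tsv"))
  readr::write_tsv(locus$exemplars, out("exemplars.tsv"), progress = FALSE)
  readr::write_tsv(reports$donors, out("donors.tsv"), progress = FALSE)
  counts <- run_pipeline(
    out("candidates.fasta"), out("evidence.tsv"), output_dir,
    exemplars_path = out("exemplars.tsv"), donors_path = out("donors.tsv"),
    config = config, version_label = sprintf("demo-seed%d", seed)
  )
  rep <- simulate_repertoire(locus, n_individuals = 6L,
                             reads_per_individual = 600L,
                             config = config, seed = seed + 2L)
  write_rearrangements(rep, out("rearrangements.tsv"))
  asg <- haplotype_all(rep, anchor_gene = locus$anchor_j_gene, config = config)
  readr::write_tsv(asg, out("haplotype_assignments.tsv"), progress = FALSE)
  counts$repertoire_reads <- nrow(rep)
  counts$haplotyped_v_alleles <- length(unique(asg$v_allele))
  message(sprintf("repertoire: %d reads | haplotyped V alleles: %d",
                  counts$repertoire_reads, counts$haplotyped_v_alleles))
  invisible(counts)
}
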