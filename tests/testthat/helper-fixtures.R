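# Small in-code fixtures shared across the test files.

make_evidence <- function(...) {
  items <- list(...)
  dplyr::bind_rows(items)
}

genomic_item <- function(lab, n = 1L, study = paste0("study-", lab),
                         acc = NA_character_) {
  tibble::tibble(kind = "genomic_study", study_id = study, laboratory = lab,
                 n_individuals = as.integer(n), mapped_locus = NA_character_,
                 accession = acc)
}

airr_item <- function(n) {
  tibble::tibble(kind = "airr_inference", study_id = "airr-study",
                 laboratory = NA_character_, n_individuals = as.integer(n),
                 mapped_locus = NA_character_, accession = NA_character_)
}

iarc_item <- function() {
  tibble::tibble(kind = "iarc_affirmation", study_id = "iarc-1",
                 laboratory = NA_character_, n_individuals = 1L,
                 mapped_locus = NA_character_, accession = NA_character_)
}

genbank_item <- function(acc = "GB0001") {
  tibble::tibble(kind = "genbank_unrearranged", study_id = acc,
                 laboratory = NA_character_, n_individuals = 1L,
                 mapped_locus = NA_character_, accession = acc)
}

# A tiny validated entry tibble.
toy_entries <- function(names, sequences, chain = "IGH-V") {
  igrefset:::new_entries(name = names, sequence = sequences, chain = chain)
}

# A deterministic exemplar with known cysteine codon positions.
toy_exemplar <- function(seed = 11L, v_length = 296L) {
  set.seed(seed)
  ex <- igrefset:::make_exemplar(v_length)
  tibble::tibble(family = "IGHV1", sequence = ex$sequence,
                 cys1_start = ex$cys1_start, cys2_start = ex$cys2_start)
}
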