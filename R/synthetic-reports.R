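# Noisy multi-source candidate reports over a ground-truth locus. Error
# modes mirror the historical failure modes of germline gene reporting:
# substitution errors from early sequencing, stop codons and cysteine
# knockouts, short 3' truncations from mistaking the V/RSS boundary, and
# major truncations. Erroneous candidates receive single-source evidence
# only, real alleles receive independently confirmable evidence, so the
# curation rules can be scored against the generator's truth labels.

ev_genomic <- function(study, lab, n = 1L, locus = NA_character_,
                       acc = NA_character_) {
  tibble(kind = "genomic_study", study_id = study, laboratory = lab,
         n_individuals = as.integer(n), mapped_locus = locus, accession = acc)
}

ev_airr <- function(study, n) {
  tibble(kind = "airr_inference", study_id = study, laboratory = NA_character_,
         n_individuals = as.integer(n), mapped_locus = NA_character_,
         accession = NA_character_)
}

ev_iarc <- function(study) {
  tibble(kind = "iarc_affirmation", study_id = study,
         laboratory = NA_character_, n_individuals = 1L,
         mapped_locus = NA_character_, accession = NA_character_)
}

ev_genbank <- function(acc) {
  tibble(kind = "genbank_unrearranged", study_id = acc,
         laboratory = NA_character_, n_individuals = 1L,
         mapped_locus = NA_character_, accession = acc)
}

# Rotating multi-source evidence patterns for real alleles.
confirmed_evidence <- function(i, acc, locus = NA_character_) {
  switch((i - 1L) %% 4L + 1L,
    bind_rows(ev_genomic("genomic-A", "lab_A", 1L, locus, acc),
              ev_genomic("genomic-B", "lab_B", 1L, locus)),
    ev_genomic("genomic-C", "lab_C", 12L, locus, acc),
    bind_rows(ev_genomic("genomic-A", "lab_A", 1L, locus, acc),
              ev_airr("airr-repertoire-study", 5L),
              ev_genbank(acc)),
    bind_rows(ev_iarc(sprintf("iarc-affirmation-%d", i)),
              ev_genomic("genomic-B", "lab_B", 1L, locus, acc))
  )
}

# Rotating single-source / inadequate evidence patterns.
unconfirmed_evidence <- function(i, acc) {
  switch((i - 1L) %% 4L + 1L,
    ev_genomic("genomic-A", "lab_A", 1L, acc = acc),
    ev_airr("airr-repertoire-study", 4L),
    ev_genbank(acc),
    bind_rows(ev_genomic("legacy-1990", "lab_legacy", 1L),
              ev_genomic("legacy-1992", "lab_legacy", 1L))
  )
}

#' Error-profile for synthetic candidate reports
#'
#' Per-allele probabilities of each reporting error mode. Substitution,
#' stop-codon, cysteine-knockout and major-truncation errors emit an
#' additional erroneous candidate (single-source evidence); a minor
#' truncation instead corrupts the real allele's reported sequence by
#' dropping its last one or two nucleotides (with a genomic donor recording
#' the true ending).
#'
#' @param substitution,stop_codon,cys_knockout,major_truncation per-allele
#'   probability of emitting that erroneous extra candidate.
#' @param minor_truncation per-allele probability that the real report is
#'   3'-truncated by 1--2 nt.
#' @return named list of rates.
#' @export
report_error_profile <- function(substitution = 0.10, stop_codon = 0.05,
                                 cys_knockout = 0.05, minor_truncation = 0.15,
                                 major_truncation = 0.05) {
  list(substitution = substitution, stop_codon = stop_codon,
       cys_knockout = cys_knockout, minor_truncation = minor_truncation,
       major_truncation = major_truncation)
}

#' Generate noisy candidate reports from a ground-truth locus
#'
#' Every true allele (V alleles, anchor J alleles, D alleles) is reported
#' with multi-source evidence; error modes from `error_profile` add
#' single-source erroneous candidates or truncate real reports. Every
#' emitted candidate carries a truth label for downstream scoring.
#'
#' @param locus an `ig_locus` from [generate_locus()].
#' @param error_profile a [report_error_profile()].
#' @param seed integer seed.
#' @return list: `candidates` (tibble with nested `evidence`), `donors`
#'   (extension donor tibble), `labels` (tibble `name`, `truth`), `locus`.
#' @export
generate_reports <- function(locus, error_profile = report_error_profile(),
                             seed = 1L) {
  set.seed(seed)
  v_len <- locus$v_length
  rows <- list(); ev <- list(); donors <- list(); labels <- list()
  err_counter <- 0L
  add <- function(name, sequence, truth, locus_label, evidence) {
    rows[[length(rows) + 1L]] <<- tibble(
      name = name, sequence = sequence,
      putative_locus = if (is.null(locus_label) || is.na(locus_label))
        "unlocated" else locus_label
    )
    ev[[length(ev) + 1L]] <<- mutate(evidence, .name = name)
    labels[[length(labels) + 1L]] <<- tibble(name = name, truth = truth)
  }
  err_name <- function(gene) {
    err_counter <<- err_counter + 1L
    sprintf("%s*9%02d", gene, err_counter)
  }

  i <- 0L
  for (r in seq_len(nrow(locus$alleles))) {
    a <- locus$alleles[r, ]
    i <- i + 1L
    acc <- sprintf("SYN%05d", r)
    truth <- if (a$is_pseudogene) "pseudogene" else "real"
    reported <- a$sequence
    if (!a$is_pseudogene && runif(1) < error_profile$minor_truncation) {
      k <- sample(1:2, 1L)
      reported <- substr(a$sequence, 1L, v_len - k)
      donors[[length(donors) + 1L]] <- tibble(
        name = a$name, end = "3p",
        nucleotides = substr(a$sequence, v_len - k + 1L, v_len),
        kind = "genomic"
      )
      truth <- "real_truncated"
    }
    add(a$name, reported, truth, a$locus_position, confirmed_evidence(i, acc))

    if (!a$is_pseudogene) {
      ex <- locus$exemplars[locus$exemplars$family == a$family, ]
      if (runif(1) < error_profile$substitution) {
        add(err_name(a$gene), mutate_variant(a$sequence, 1L, cys_protect(ex)),
            "erroneous_substitution", NA, unconfirmed_evidence(i, acc))
      }
      if (runif(1) < error_profile$stop_codon) {
        bad <- paste0(substr(a$sequence, 1L, 150L), "TGA",
                      substr(a$sequence, 154L, v_len))
        add(err_name(a$gene), bad, "erroneous_stop", NA,
            unconfirmed_evidence(i + 1L, acc))
      }
      if (runif(1) < error_profile$cys_knockout) {
        bad <- paste0(substr(a$sequence, 1L, ex$cys1_start - 1L), "AGT",
                      substr(a$sequence, ex$cys1_start + 3L, v_len))
        add(err_name(a$gene), bad, "erroneous_cys", NA,
            unconfirmed_evidence(i + 2L, acc))
      }
      if (runif(1) < error_profile$major_truncation) {
        add(err_name(a$gene), substr(a$sequence, 1L, v_len - 30L),
            "erroneous_major_truncation", NA, unconfirmed_evidence(i + 3L, acc))
      }
    }
  }
  for (r in seq_len(nrow(locus$anchor_j_alleles))) {
    i <- i + 1L
    add(locus$anchor_j_alleles$name[r], locus$anchor_j_alleles$sequence[r],
        "real", NA, confirmed_evidence(1L, sprintf("SYNJ%04d", r)))
  }
  for (r in seq_len(nrow(locus$d_alleles))) {
    i <- i + 1L
    add(locus$d_alleles$name[r], locus$d_alleles$sequence[r],
        "real", NA, confirmed_evidence(1L, sprintf("SYND%04d", r)))
  }

  donors <- if (length(donors) > 0) bind_rows(donors) else
    tibble(name = character(0), end = character(0),
           nucleotides = character(0), kind = character(0))
  list(
    candidates = as_candidates(bind_rows(rows), bind_rows(ev)),
    donors = donors,
    labels = bind_rows(labels),
    locus = locus
  )
}

#' Ground-truth functional sequences of a locus
#'
#' The distinct full-length sequences a perfect curation run should recover
#' in its Reference Set: all functional V alleles plus the anchor J and D
#' alleles.
#'
#' @param locus an `ig_locus`.
#' @return character vector of distinct sequences.
#' @export
locus_truth_sequences <- function(locus) {
  unique(c(
    locus$alleles$sequence[!locus$alleles$is_pseudogene],
    locus$anchor_j_alleles$sequence,
    locus$d_alleles$sequence
  ))
}
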