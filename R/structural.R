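# Structural gates applied before any evidence is weighed:
#   - open-reading-frame classification (in-frame stop codons)
#   - presence of the two conserved cysteines framing the V-domain fold
#   - exclusion of major 5'/3' truncations
#   - the gene-level gate: a gene survives only if at least one of its
#     alleles is an ORF carrying both conserved cysteines (non-ORF alleles
#     of surviving genes are retained)
# D and J candidates are exempt from ORF/cysteine/truncation checks and pass
# unless their sequence is empty.

#' Classify open reading frames
#'
#' A sequence is an ORF when its coding span (full codons read from
#' `reading_frame`) contains no stop codon (TAA/TAG/TGA). Germline V inputs
#' are exon-start-anchored, so frame 0 is the default.
#'
#' @param sequence character vector of nucleotide sequences.
#' @param reading_frame 0, 1 or 2: offset of the first codon.
#' @return tibble with one row per sequence: `is_orf` and `stop_codons`, a
#'   list-column of 1-based codon indices of in-frame stops.
#' @examples
#' classify_orf(c("TGTGCA", "ATGTAAGGG"))
#' @export
classify_orf <- function(sequence, reading_frame = 0L) {
  if (!reading_frame %in% 0:2) abort("reading_frame must be 0, 1 or 2")
  stops <- map(sequence, function(s) which(codon_split(s, reading_frame) %in% STOP_CODONS))
  tibble(
    sequence = sequence,
    is_orf = map_int(stops, length) == 0L,
    stop_codons = stops
  )
}

#' Check the two conserved cysteines against a family exemplar
#'
#' Each candidate is placed onto a family exemplar that carries annotated
#' positions (1-based nucleotide starts) of the two conserved cysteine
#' codons. A cysteine is present when the candidate codon mapped to the
#' exemplar position is TGT or TGC. Same-length and end-truncated candidates
#' are placed by anchored matching; others fall back to global pairwise
#' alignment.
#'
#' @param sequence character vector of candidate sequences.
#' @param exemplar single exemplar sequence for the gene family.
#' @param cys_positions integer vector of length 2: 1-based start positions
#'   of the first and second conserved cysteine codons in the exemplar.
#' @return tibble with `first_present` and `second_present` logical columns.
#' @export
check_conserved_cysteines <- function(sequence, exemplar, cys_positions) {
  if (length(cys_positions) != 2L) abort("cys_positions must have length 2")
  if (any(cys_positions < 1L | cys_positions + 2L > nchar(exemplar))) {
    abort("cys_positions fall outside the exemplar sequence")
  }
  codon_at <- function(seq, pos) {
    d <- anchored_offset(seq, exemplar)
    if (!is.na(d)) {
      lo <- pos - d
      if (lo >= 1L && lo + 2L <= nchar(seq)) return(substr(seq, lo, lo + 2L))
      return(NA_character_)
    }
    m <- align_map(seq, exemplar)
    idx <- m[pos:(pos + 2L)]
    if (anyNA(idx) || any(diff(idx) != 1L)) return(NA_character_)
    substr(seq, idx[1], idx[3])
  }
  first <- map_chr(sequence, codon_at, pos = cys_positions[1])
  second <- map_chr(sequence, codon_at, pos = cys_positions[2])
  tibble(
    first_present = !is.na(first) & first %in% CYS_CODONS,
    second_present = !is.na(second) & second %in% CYS_CODONS
  )
}

#' Classify apparent 5'/3' truncations against a comparison allele
#'
#' The candidate is compared with the longest allele of its gene (fallback:
#' its family). Missing nucleotides at an end classify the candidate as
#' majorly truncated (missing >= `major_truncation_nt`, excluded) or as
#' carrying a shorter, extendable truncation. A candidate at least as long as
#' the comparison is `"none"` with count 0.
#'
#' @param sequence candidate sequence (single string).
#' @param comparison comparison allele sequence (single string).
#' @param config a [curation_config()].
#' @return one-row tibble: `class` (none/minor_5p/minor_3p/major_5p/major_3p),
#'   `missing_nt` (count at the classified end), `missing_5p`, `missing_3p`.
#' @examples
#' cfg <- curation_config()
#' classify_truncation("ACGTACG", "ACGTACGTA", cfg)
#' @export
classify_truncation <- function(sequence, comparison, config = curation_config()) {
  res <- truncation_core(sequence, comparison, config)
  tibble(class = res$class, missing_nt = res$missing_nt,
         missing_5p = res$missing_5p, missing_3p = res$missing_3p)
}

# list-returning core of classify_truncation (hot path on large fixtures)
truncation_core <- function(sequence, comparison, config) {
  ls <- nchar(sequence); lc <- nchar(comparison)
  m5 <- 0L; m3 <- 0L
  if (ls < lc) {
    hit <- regexpr(sequence, comparison, fixed = TRUE)
    if (hit > 0L) {
      m5 <- as.integer(hit) - 1L
      m3 <- lc - (as.integer(hit) - 1L) - ls
    } else {
      d <- anchored_offset(sequence, comparison)
      if (!is.na(d)) {
        m5 <- d
        m3 <- lc - d - ls
      } else {
        aln <- Biostrings::pairwiseAlignment(
          pattern = sequence, subject = comparison, type = "overlap",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 2, mismatch = -3, baseOnly = TRUE
          ),
          gapOpening = 5, gapExtension = 2
        )
        m5 <- max(BiocGenerics::start(Biostrings::subject(aln)) - 1L, 0L)
        m3 <- max(lc - BiocGenerics::end(Biostrings::subject(aln)), 0L)
      }
    }
  }
  if (m5 == 0L && m3 == 0L) {
    cls <- "none"; missing <- 0L
  } else {
    end3 <- m3 >= m5
    missing <- if (end3) m3 else m5
    major <- missing >= config$major_truncation_nt
    cls <- paste0(if (major) "major_" else "minor_", if (end3) "3p" else "5p")
  }
  list(class = cls, missing_nt = missing, missing_5p = m5, missing_3p = m3)
}

# Per-candidate soundness (ORF + both cysteines) for V candidates, mapped
# through per-family exemplars. `exemplars` is a tibble with columns
# `family`, `sequence`, `cys1_start`, `cys2_start`.
v_soundness <- function(candidates, exemplars) {
  fam <- gene_family(allele_gene(candidates$name))
  orf <- classify_orf(candidates$sequence)
  first <- logical(nrow(candidates)); second <- logical(nrow(candidates))
  for (f in unique(fam)) {
    ex <- exemplars[exemplars$family == f, ]
    if (nrow(ex) == 0) {
      abort(sprintf("no family exemplar supplied for family %s", f))
    }
    idx <- which(fam == f)
    cys <- check_conserved_cysteines(
      candidates$sequence[idx], ex$sequence[[1]],
      c(ex$cys1_start[[1]], ex$cys2_start[[1]])
    )
    first[idx] <- cys$first_present
    second[idx] <- cys$second_present
  }
  tibble(
    name = candidates$name,
    gene = allele_gene(candidates$name),
    family = fam,
    is_orf = orf$is_orf,
    stop_codons = orf$stop_codons,
    has_cys1 = first,
    has_cys2 = second,
    sound = orf$is_orf & first & second
  )
}

#' Gene-level gate on candidate alleles
#'
#' A gene is kept only if at least one of its alleles is an ORF that carries
#' both conserved cysteines; all alleles of dropped genes are rejected, while
#' non-ORF alleles of kept genes are retained (and flagged). This removes
#' most pseudogenes without evaluating functionality.
#'
#' @param candidates candidate tibble (`name`, `sequence`; V chains only).
#' @param exemplars per-family exemplar tibble (`family`, `sequence`,
#'   `cys1_start`, `cys2_start`).
#' @return tibble with one row per gene: `gene`, `keep`, `n_alleles`,
#'   `n_sound`.
#' @export
gene_level_gate <- function(candidates, exemplars) {
  sound <- v_soundness(candidates, exemplars)
  sound %>%
    group_by(.data$gene) %>%
    summarise(
      keep = any(.data$sound),
      n_alleles = n(),
      n_sound = sum(.data$sound),
      .groups = "drop"
    )
}

# Comparison allele for truncation classification: the longest other sound
# allele of the same gene (ties: lowest allele number), falling back to the
# longest sound allele of the family ("other highly similar genes"), then to
# the family exemplar. A candidate with no longer comparison is compared to
# itself (verdict "none"): a genuinely short lone allele is not flagged by
# its own length.
truncation_comparisons <- function(candidates, sound, exemplars) {
  name <- candidates$name
  sequence <- candidates$sequence
  len <- nchar(sequence)
  gene <- sound$gene
  family <- sound$family
  ok <- sound$sound
  num <- allele_number(name)
  num[is.na(num)] <- .Machine$integer.max
  # pre-rank the pool so the best comparison is the first qualifying index
  rank_ord <- order(-len, num, name)
  ex_seq <- setNames(exemplars$sequence, exemplars$family)
  map(seq_along(name), function(i) {
    for (scope_vec in list(gene, family)) {
      pool <- rank_ord[ok[rank_ord] & scope_vec[rank_ord] == scope_vec[i] &
                         len[rank_ord] > len[i] & name[rank_ord] != name[i]]
      if (length(pool) > 0) {
        j <- pool[[1]]
        return(list(name = name[j], sequence = sequence[j]))
      }
    }
    ex <- ex_seq[family[i]]
    if (!is.na(ex) && nchar(ex) > len[i]) {
      return(list(name = paste0("exemplar:", family[i]), sequence = unname(ex)))
    }
    list(name = name[i], sequence = sequence[i])
  })
}

#' Apply all structural gates to a candidate collection
#'
#' V candidates are checked for ORF status, conserved cysteines (against
#' per-family exemplars), and truncation relative to the longest sound allele
#' of their gene (fallback family). The gene-level gate then drops genes with
#' no sound allele. A candidate passes when its gene is kept and it carries
#' no major truncation. All applicable rejection reasons are recorded,
#' independent of evaluation order. D and J candidates pass unless empty.
#'
#' @param candidates candidate tibble from [read_candidates()] or
#'   [as_candidates()]; mixed chains allowed.
#' @param exemplars per-family exemplar tibble (required when V candidates
#'   are present).
#' @param config a [curation_config()].
#' @return verdict tibble: `name`, `chain`, `gene`, `passed`, `reasons`
#'   (list-column), `is_orf`, `has_cys1`, `has_cys2`, `truncation_class`,
#'   `missing_nt`, `comparison_name`.
#' @seealso [write_verdicts()] for the TSV audit form.
#' @export
structural_filter <- function(candidates, exemplars = NULL,
                              config = curation_config()) {
  candidates <- as_tibble(candidates)
  if (is.null(candidates$chain)) candidates$chain <- chain_of(candidates$name)
  is_v <- is_v_chain(candidates$chain)

  out <- tibble(
    name = candidates$name,
    chain = candidates$chain,
    gene = allele_gene(candidates$name),
    passed = nzchar(candidates$sequence),
    reasons = rep(list(character(0)), nrow(candidates)),
    is_orf = NA,
    has_cys1 = NA,
    has_cys2 = NA,
    truncation_class = "none",
    missing_nt = 0L,
    comparison_name = NA_character_
  )

  if (any(is_v)) {
    if (is.null(exemplars)) abort("V candidates require per-family exemplars")
    vc <- candidates[is_v, ]
    sound <- v_soundness(vc, exemplars)
    comps <- truncation_comparisons(vc, sound, exemplars)
    trunc_res <- map(seq_len(nrow(vc)), function(i) {
      truncation_core(vc$sequence[i], comps[[i]]$sequence, config)
    })
    trunc <- list(
      class = map_chr(trunc_res, "class"),
      missing_nt = map_int(trunc_res, "missing_nt")
    )
    gate <- sound %>%
      group_by(.data$gene) %>%
      summarise(keep = any(.data$sound), .groups = "drop")
    kept <- gate$keep[match(sound$gene, gate$gene)]
    major <- grepl("^major_", trunc$class)
    passed <- kept & !major
    reasons <- map(seq_len(nrow(vc)), function(i) {
      if (passed[i]) return(character(0))
      r <- character(0)
      if (!kept[i]) r <- c(r, "no_orf_allele_in_gene")
      if (!sound$is_orf[i]) r <- c(r, "stop_codon")
      if (!sound$has_cys1[i]) r <- c(r, "missing_first_cysteine")
      if (!sound$has_cys2[i]) r <- c(r, "missing_second_cysteine")
      if (major[i]) r <- c(r, paste0(sub("^minor", "major", trunc$class[i]), "_truncation"))
      unique(r)
    })
    out$passed[is_v] <- passed
    out$reasons[is_v] <- reasons
    out$is_orf[is_v] <- sound$is_orf
    out$has_cys1[is_v] <- sound$has_cys1
    out$has_cys2[is_v] <- sound$has_cys2
    out$truncation_class[is_v] <- trunc$class
    out$missing_nt[is_v] <- trunc$missing_nt
    out$comparison_name[is_v] <- map_chr(comps, "name")
  }
  if (any(!is_v)) {
    empty <- !nzchar(candidates$sequence[!is_v])
    out$reasons[!is_v][empty] <- list("empty_sequence")
  }
  out
}

#' Write the structural verdict audit table
#'
#' One row per candidate, reasons semicolon-joined, for audit alongside the
#' emitted sets.
#'
#' @param verdicts output of [structural_filter()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_verdicts <- function(verdicts, path) {
  flat <- verdicts %>% mutate(reasons = semicolon_join(.data$reasons))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
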