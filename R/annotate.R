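# A deliberately naive read annotator, reproducing the behaviour of
# downstream tools that assign each rearrangement to the reference allele
# with the highest identity over the aligned V span and break ties by the
# lowest allele number. Reads are V-region-anchored (full 5' coverage), so
# the alignment is the ungapped placement of each reference allele at the
# read start.

#' Naively annotate reads against a reference set
#'
#' Scores each read against every reference allele by the number of
#' identical nucleotides over the aligned span (the reference length, or
#' the read length if shorter) and assigns the best-scoring allele. Ties
#' are broken by lowest allele number, then lexicographic gene name.
#'
#' @param reads character vector of read sequences (V region first).
#' @param reference_set tibble with `name` and `sequence` columns.
#' @return tibble: `read_id`, `best_call`, `score` (matching nucleotides),
#'   `mismatches` (aligned-span mismatches against the best call), `tie`
#'   (was the top score shared?).
#' @export
naive_annotate <- function(reads, reference_set) {
  ref <- as_tibble(reference_set)
  if (nrow(ref) == 0) abort("reference_set is empty")
  ord <- order(allele_number(ref$name), allele_gene(ref$name), ref$name)
  ref <- ref[ord, ]
  read_ints <- map(reads, utf8ToInt)
  read_len <- lengths(read_ints)
  n <- length(reads)
  scores <- matrix(0L, nrow = n, ncol = nrow(ref))
  spans <- matrix(0L, nrow = n, ncol = nrow(ref))
  for (j in seq_len(nrow(ref))) {
    r <- utf8ToInt(ref$sequence[j])
    lr <- length(r)
    for (i in seq_len(n)) {
      span <- min(lr, read_len[i])
      scores[i, j] <- sum(read_ints[[i]][seq_len(span)] == r[seq_len(span)])
      spans[i, j] <- span
    }
  }
  best_j <- apply(scores, 1L, which.max)  # first max = tie-break order
  top <- scores[cbind(seq_len(n), best_j)]
  tie <- rowSums(scores == top) > 1L
  tibble(
    read_id = seq_len(n),
    best_call = ref$name[best_j],
    score = top,
    mismatches = spans[cbind(seq_len(n), best_j)] - top,
    tie = tie
  )
}

#' Demonstrate the truncated-reference misassignment artifact
#'
#' Simulates reads from a carrier of a single V allele (*01) whose
#' reference entry is 3'-truncated by two nucleotides, while a second
#' allele (*02) of the same gene, differing at one internal position and
#' sharing the true 3' end, is full length — the geometry in which a
#' truncated reference sequence causes downstream tools to split one
#' allele's reads between two alleles. Read 3' ends are trimmed by
#' geometric amounts (exonuclease) and followed by random junction
#' nucleotides. The same reads are annotated against the truncated and the
#' extended reference; with the truncated entry a substantial minority of
#' reads is misassigned to *02 (each such alignment carrying at least one
#' mismatch), and extension eliminates the misassignment.
#'
#' @param n_reads number of simulated reads (default 10000).
#' @param seed integer seed.
#' @param v_length V length (default 296).
#' @param trim_p geometric parameter of 3'-end trimming (default 1/3).
#' @param junction_length random junction nucleotides appended to each read
#'   (default 24).
#' @return tibble with one row per reference condition
#'   (`"truncated"`, `"extended"`): `n_reads`, `n_misassigned`,
#'   `fraction_misassigned`, `n_misassigned_with_mismatch`.
#' @export
truncation_artifact_demo <- function(n_reads = 10000L, seed = 1L,
                                     v_length = 296L, trim_p = 1 / 3,
                                     junction_length = 24L) {
  set.seed(seed)
  true01 <- rand_dna(v_length)
  sub_pos <- v_length %/% 2L
  allele02 <- true01
  substr(allele02, sub_pos, sub_pos) <-
    setdiff(c("A", "C", "G", "T"), substr(true01, sub_pos, sub_pos))[1]
  ref_truncated <- tibble(
    name = c("IGHV4-38-2*01", "IGHV4-38-2*02"),
    sequence = c(substr(true01, 1L, v_length - 2L), allele02)
  )
  ref_extended <- tibble(
    name = c("IGHV4-38-2*01", "IGHV4-38-2*02"),
    sequence = c(true01, allele02)
  )
  trims <- pmin(rgeom(n_reads, trim_p), v_length %/% 2L)
  reads <- map_chr(trims, function(t) {
    paste0(substr(true01, 1L, v_length - t), rand_dna(junction_length + t))
  })
  summarise_run <- function(ref, label) {
    ann <- naive_annotate(reads, ref)
    mis <- filter(ann, .data$best_call == "IGHV4-38-2*02")
    tibble(
      reference = label,
      n_reads = n_reads,
      n_misassigned = nrow(mis),
      fraction_misassigned = nrow(mis) / n_reads,
      n_misassigned_with_mismatch = sum(mis$mismatches >= 1L)
    )
  }
  bind_rows(
    summarise_run(ref_truncated, "truncated"),
    summarise_run(ref_extended, "extended")
  )
}
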