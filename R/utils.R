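# Name parsing and small sequence helpers shared across stages.

STOP_CODONS <- c("TAA", "TAG", "TGA")
CYS_CODONS <- c("TGT", "TGC")
CHAIN_LEVELS <- c("IGH-V", "IGH-D", "IGH-J", "IGK-V", "IGK-J", "IGL-V", "IGL-J")

#' Parse allele designations
#'
#' Allele designations follow the field's `gene*allele` convention
#' (e.g. `"IGHV4-38-2*01"`, temporary names such as `"IGHV4-NL1*01"` or
#' `"IGKV3-15*i02"` permitted). `allele_gene()` strips the allele suffix,
#' `allele_number()` extracts the numeric part of the allele suffix (NA when
#' there is none), and `gene_family()` returns the family label, treating a
#' distal-duplication "D" marker (IGHV1-69D, IGKV3D-15) as part of the same
#' family as its non-D partner.
#'
#' @param name character vector of allele designations.
#' @return character (or integer) vector, one element per input name.
#' @examples
#' allele_gene("IGHV1-69D*01")
#' allele_number("IGKV3-15*i02")
#' gene_family("IGKV3D-15")
#' @export
allele_gene <- function(name) sub("\\*.*$", "", name)

#' @rdname allele_gene
#' @export
allele_number <- function(name) {
  suffix <- ifelse(grepl("\\*", name), sub("^[^*]*\\*", "", name), "")
  digits <- gsub("[^0-9]", "", suffix)
  ifelse(nzchar(digits), suppressWarnings(as.integer(digits)), NA_integer_)
}

#' @rdname allele_gene
#' @param gene character vector of gene names (no allele suffix).
#' @export
gene_family <- function(gene) {
  base <- sub("-.*$", "", gene)
  sub("D$", "", base)
}

# Distal-duplication genes carry a "D" after the gene or family number:
# IGHV1-69D, IGHV3-23D, IGKV3D-15.
is_distal_gene <- function(gene) grepl("[0-9]D(-|$)", gene)

# IGHV4-38-2*01 -> "IGH-V"; works for all seven supported chains.
chain_of <- function(name) {
  locus <- substr(name, 1L, 3L)
  segment <- substr(name, 4L, 4L)
  ok <- locus %in% c("IGH", "IGK", "IGL") & segment %in% c("V", "D", "J")
  out <- paste0(locus, "-", segment)
  out[!ok] <- NA_character_
  out
}

is_v_chain <- function(chain) grepl("-V$", chain)

assert_nucleotides <- function(sequence, what = "sequence") {
  bad <- !nzchar(sequence) | grepl("[^ACGT]", sequence)
  if (any(bad)) {
    abort(sprintf(
      "%s must be non-empty and restricted to A/C/G/T (offending entries: %s)",
      what, paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  invisible(sequence)
}

# Split into codons starting at `frame` (0-based offset); trailing partial
# codon is dropped.
codon_split <- function(sequence, frame = 0L) {
  body <- substr(sequence, frame + 1L, nchar(sequence))
  n_codons <- nchar(body) %/% 3L
  if (n_codons == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n_codons)
  substring(body, starts, starts + 2L)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Map candidate positions onto an exemplar/comparison sequence. Returns the
# 0-based offset of candidate position 1 within the exemplar when an anchored
# (end-aligned, gap-free) placement explains the pair, otherwise NA. The
# anchored fast path covers same-length variants and end-truncated sequences;
# callers fall back to pairwise alignment when it fails.
anchored_offset <- function(sequence, exemplar, max_mismatch_frac = 0.25) {
  ls <- nchar(sequence); le <- nchar(exemplar)
  if (ls > le) return(NA_integer_)
  offsets <- unique(c(0L, le - ls))
  best <- NA_integer_; best_frac <- Inf
  for (d in offsets) {
    frac <- hamming(sequence, substr(exemplar, d + 1L, d + ls)) / ls
    if (frac < best_frac) { best_frac <- frac; best <- d }
  }
  if (best_frac <= max_mismatch_frac) best else NA_integer_
}

# Alignment-based position map: integer vector m with m[i] = candidate
# position aligned to exemplar position i (NA at gaps). Global alignment.
align_map <- function(sequence, exemplar) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = sequence, subject = exemplar, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE
    ),
    gapOpening = 5, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  m <- rep(NA_integer_, nchar(exemplar))
  pi <- 0L; si <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") {
      si <- si + 1L
      if (p[k] != "-") m[si] <- pi
    }
  }
  m
}

semicolon_join <- function(x) map_chr(x, function(v) paste(v, collapse = ";"))
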