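# Exact-paralog collapse: identical nucleotide sequences present under more
# than one name (IGHV1-69/IGHV1-69D, proximal/distal kappa duplicates,
# IGLJ2/IGLJ3) are retained once, with the dropped names recorded as
# paralogs of the retained entry.

# Representative ranking within one identical-sequence group:
#   (1) explicit override, (2) non-distal ("D"-free) gene over its distal
#   duplicate, (3) lexicographically smallest gene, lowest allele number.
pick_representative <- function(names, overrides) {
  hit <- intersect(overrides, names)
  if (length(hit) > 0) return(hit[[1]])
  ord <- order(
    is_distal_gene(allele_gene(names)),
    allele_gene(names),
    allele_number(names),
    names
  )
  names[ord][[1]]
}

#' Collapse exact paralogs into single entries
#'
#' Entries sharing an identical nucleotide sequence (within a chain) are
#' collapsed to one entry. The representative is chosen by explicit override
#' first, then by preferring the non-"D"-suffixed gene (IGHV1-69 over
#' IGHV1-69D, proximal IGKV3-15 over distal IGKV3D-15), then by
#' lexicographically smallest gene and lowest allele number. Dropped names
#' are appended to the representative's `paralogs`; aliases are merged. The
#' multiset of names (entries plus paralog lists) is conserved, and the
#' operation is idempotent.
#'
#' @param entries germline-set entry tibble (post-extension sequences).
#' @param preference_overrides character vector of entry names to prefer as
#'   representatives of their groups. Naming a sequence absent from
#'   `entries` is an error.
#' @return collapsed entry tibble.
#' @examples
#' e <- igrefset:::new_entries(
#'   name = c("IGHV1-69*01", "IGHV1-69D*01"),
#'   sequence = c("CAGGTG", "CAGGTG"), chain = "IGH-V"
#' )
#' collapse_paralogs(e)$paralogs
#' @export
collapse_paralogs <- function(entries, preference_overrides = NULL) {
  entries <- as_tibble(entries)
  overrides <- preference_overrides %||% character(0)
  missing_override <- setdiff(overrides, entries$name)
  if (length(missing_override) > 0) {
    abort(sprintf("preference override(s) name absent entries: %s",
                  paste(missing_override, collapse = ", ")))
  }
  key <- paste(entries$chain, entries$sequence, sep = ":")
  groups <- split(seq_len(nrow(entries)), key)
  keep_rows <- integer(0)
  extra_paralogs <- list()
  extra_aliases <- list()
  for (g in groups) {
    nms <- entries$name[g]
    rep_name <- pick_representative(nms, overrides)
    rep_row <- g[nms == rep_name]
    keep_rows <- c(keep_rows, rep_row)
    dropped <- g[nms != rep_name]
    extra_paralogs[[as.character(rep_row)]] <-
      unique(c(unlist(entries$paralogs[dropped]), entries$name[dropped]))
    extra_aliases[[as.character(rep_row)]] <-
      unique(unlist(entries$aliases[dropped]))
  }
  keep_rows <- sort(keep_rows)
  out <- entries[keep_rows, ]
  out$paralogs <- map2(out$paralogs, as.character(keep_rows), function(p, row) {
    unique(c(p, extra_paralogs[[row]]))
  })
  out$aliases <- map2(out$aliases, as.character(keep_rows), function(a, row) {
    unique(c(a, extra_aliases[[row]]))
  })
  validate_entries(out)
}
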