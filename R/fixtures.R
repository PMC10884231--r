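# Deterministic candidate fixtures whose category composition mirrors the
# curated human IG candidate corpora: per chain, a fixed number of
# candidates partitioned into structurally rejected, structurally sound but
# unconfirmed, confirmed, exact-duplicate pairs and short-truncated
# sequences. The pipeline's category counts on these fixtures are arithmetic
# consequences of the curation rules.

FIXTURE_COMPOSITION <- list(
  IGHV = list(n_total = 295L, n_reject = 67L, n_unconfirmed = 22L,
              n_dup_pairs = 8L, n_trunc_sib = 29L, n_trunc_family = 0L),
  IGKV = list(n_total = 102L, n_reject = 24L, n_unconfirmed = 7L,
              n_dup_pairs = 5L, n_trunc_sib = 0L, n_trunc_family = 0L),
  IGLV = list(n_total = 115L, n_reject = 20L, n_unconfirmed = 14L,
              n_dup_pairs = 0L, n_trunc_sib = 0L, n_trunc_family = 3L),
  IGHD = list(n_total = 34L, n_unconfirmed = 1L, n_identical_pairs = 2L),
  IGHJ = list(n_total = 8L, n_unconfirmed = 1L, n_identical_pairs = 0L),
  IGKJ = list(n_total = 7L, n_unconfirmed = 0L, n_identical_pairs = 0L),
  IGLJ = list(n_total = 10L, n_unconfirmed = 0L, n_identical_pairs = 1L)
)

#' Generate a candidate fixture mirroring a curated chain's composition
#'
#' Builds a deterministic candidate collection for one chain whose category
#' composition (total candidates, structural rejects, unconfirmed, exact
#' duplicate pairs, short truncations) matches the corresponding human IG
#' candidate corpus; see `igrefset:::FIXTURE_COMPOSITION` for the numbers.
#' Structural rejects cycle through defect types (stop codon, first/second
#' cysteine knockout, major 3'/5' truncation); unconfirmed candidates cycle
#' through inadequate evidence patterns; confirmed candidates cycle through
#' independently confirmable patterns. Duplicate pairs are identical
#' sequences under proximal/distal ("D") gene names; truncated candidates
#' come with donor endings.
#'
#' @param chain one of `"IGHV"`, `"IGKV"`, `"IGLV"`, `"IGHD"`, `"IGHJ"`,
#'   `"IGKJ"`, `"IGLJ"`.
#' @param seed integer seed.
#' @return list: `candidates` (tibble with nested `evidence`), `exemplars`,
#'   `donors`, `labels` (tibble `name`, `category`).
#' @export
candidate_fixture <- function(chain = c("IGHV", "IGKV", "IGLV", "IGHD",
                                        "IGHJ", "IGKJ", "IGLJ"),
                              seed = 1L) {
  chain <- match.arg(chain)
  comp <- FIXTURE_COMPOSITION[[chain]]
  if (grepl("V$", chain)) {
    v_fixture(chain, comp, seed)
  } else if (chain == "IGHD") {
    d_fixture(comp, seed)
  } else {
    j_fixture(chain, comp, seed)
  }
}

fixture_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list(); env$ev <- list(); env$labels <- list()
  env$donors <- list(); env$seen <- character(0)
  env$add <- function(name, sequence, category, evidence) {
    env$rows[[length(env$rows) + 1L]] <- tibble(name = name, sequence = sequence)
    env$ev[[length(env$ev) + 1L]] <- mutate(evidence, .name = name)
    env$labels[[length(env$labels) + 1L]] <- tibble(name = name, category = category)
    env$seen <- c(env$seen, sequence)
  }
  env$add_donor <- function(name, end, nucleotides, kind) {
    env$donors[[length(env$donors) + 1L]] <- tibble(
      name = name, end = end, nucleotides = nucleotides, kind = kind
    )
  }
  env$result <- function(exemplars = NULL) {
    list(
      candidates = as_candidates(bind_rows(env$rows), bind_rows(env$ev)),
      exemplars = exemplars,
      donors = if (length(env$donors) > 0) bind_rows(env$donors) else
        tibble(name = character(0), end = character(0),
               nucleotides = character(0), kind = character(0)),
      labels = bind_rows(env$labels)
    )
  }
  env
}

v_fixture <- function(prefix, comp, seed) {
  set.seed(seed)
  n_ordinary <- comp$n_total - comp$n_reject - comp$n_unconfirmed -
    2L * comp$n_dup_pairs - 2L * comp$n_trunc_sib - 2L * comp$n_trunc_family
  stopifnot(n_ordinary >= 4L)
  v_len <- 296L
  n_families <- 4L
  exemplars <- bind_rows(map(seq_len(n_families), function(f) {
    ex <- make_exemplar(v_len)
    tibble(family = paste0(prefix, f), sequence = ex$sequence,
           cys1_start = ex$cys1_start, cys2_start = ex$cys2_start)
  }))
  acc <- fixture_accumulator()
  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    fam <- paste0(prefix, (gene_counter - 1L) %% n_families + 1L)
    list(gene = paste0(fam, "-", gene_counter + 10L), fam = fam)
  }
  ex_of <- function(fam) exemplars[exemplars$family == fam, ]
  fresh <- function(fam, protect_extra = integer(0)) {
    ex <- ex_of(fam)
    unique_variant(ex$sequence, 4L,
                   c(cys_protect(ex), protect_extra), acc$seen)
  }
  acc_id <- local({ k <- 0L; function() { k <<- k + 1L; sprintf("FIX%05d", k) } })

  # ordinary confirmed singletons
  for (i in seq_len(n_ordinary)) {
    g <- new_gene()
    acc$add(paste0(g$gene, "*01"), fresh(g$fam), "confirmed",
            confirmed_evidence(i, acc_id()))
  }
  # exact duplicate pairs (proximal/distal naming)
  for (k in seq_len(comp$n_dup_pairs)) {
    g <- new_gene()
    s <- fresh(g$fam)
    dup_gene <- if (grepl("^IGK", prefix)) {
      sub("^([A-Z]+[0-9]+)-", "\\1D-", g$gene)
    } else {
      paste0(g$gene, "D")
    }
    acc$add(paste0(g$gene, "*01"), s, "confirmed_pair",
            confirmed_evidence(k, acc_id()))
    acc$add(paste0(dup_gene, "*01"), s, "confirmed_pair",
            confirmed_evidence(k + 1L, acc_id()))
  }
  # short 3' truncations with a full-length sibling allele
  for (k in seq_len(comp$n_trunc_sib)) {
    g <- new_gene()
    ex <- ex_of(g$fam)
    tail_protect <- (v_len - 1L):v_len
    full01 <- fresh(g$fam, tail_protect)
    full02 <- unique_variant(full01, 2L, c(cys_protect(ex), tail_protect),
                             acc$seen)
    miss <- if (k <= 2L) 1L else 2L
    reported02 <- substr(full02, 1L, v_len - miss)
    acc$add(paste0(g$gene, "*01"), full01, "confirmed",
            confirmed_evidence(k, acc_id()))
    acc$add(paste0(g$gene, "*02"), reported02, "confirmed_truncated",
            confirmed_evidence(k + 2L, acc_id()))
    donor_kind <- if (k == 1L) "iarc_recommendation" else
      if (k == 2L) NA_character_ else "genomic"  # NA: similar-allele fallback
    if (!is.na(donor_kind)) {
      acc$add_donor(paste0(g$gene, "*02"), "3p",
                    substr(full02, v_len - miss + 1L, v_len), donor_kind)
    }
  }
  # substantial (but sub-major) truncations repaired from genomic/AIRR
  # endings; the truncation cuts into the second-cysteine codon, so the
  # truncated allele survives only through its full-length sibling
  for (k in seq_len(comp$n_trunc_family)) {
    g <- new_gene()
    ex <- ex_of(g$fam)
    full01 <- fresh(g$fam)
    full02 <- unique_variant(full01, 2L, cys_protect(ex), acc$seen)
    miss <- 8L + k
    acc$add(paste0(g$gene, "*01"), full01, "confirmed",
            confirmed_evidence(k, acc_id()))
    acc$add(paste0(g$gene, "*02"), substr(full02, 1L, v_len - miss),
            "confirmed_truncated", confirmed_evidence(k + 1L, acc_id()))
    acc$add_donor(paste0(g$gene, "*02"), "3p",
                  substr(full02, v_len - miss + 1L, v_len),
                  if (k %% 2L == 1L) "genomic" else "airr_consensus")
  }
  # structurally sound but unconfirmed
  for (k in seq_len(comp$n_unconfirmed)) {
    g <- new_gene()
    acc$add(paste0(g$gene, "*01"), fresh(g$fam), "unconfirmed",
            unconfirmed_evidence(k, acc_id()))
  }
  # structural rejects, cycling defect types
  for (k in seq_len(comp$n_reject)) {
    g <- new_gene()
    ex <- ex_of(g$fam)
    base <- fresh(g$fam)
    defect <- (k - 1L) %% 5L + 1L
    seqd <- switch(defect,
      paste0(substr(base, 1L, 117L), "TAA", substr(base, 121L, v_len)),
      paste0(substr(base, 1L, ex$cys1_start - 1L), "AGT",
             substr(base, ex$cys1_start + 3L, v_len)),
      paste0(substr(base, 1L, ex$cys2_start - 1L), "AGT",
             substr(base, ex$cys2_start + 3L, v_len)),
      substr(base, 1L, v_len - 30L),
      substr(base, 31L, v_len)
    )
    category <- c("reject_stop", "reject_cys1", "reject_cys2",
                  "reject_major_3p", "reject_major_5p")[defect]
    acc$add(paste0(g$gene, "*01"), seqd, category,
            confirmed_evidence(k, acc_id()))
  }
  acc$result(exemplars)
}

d_fixture <- function(comp, seed) {
  set.seed(seed)
  acc <- fixture_accumulator()
  two_labs <- function(i, acc_id) bind_rows(
    ev_genomic("genomic-D1", "lab_D1", 1L, acc = acc_id),
    ev_genomic("genomic-D2", "lab_D2", 1L)
  )
  # the admissibility-limited candidate pair: same length, terminal-only
  # difference; *03 has only single-study genomic support plus expression
  # evidence its terminal nucleotide cannot carry
  d22_01 <- rand_dna(31L)
  d22_03 <- paste0(substr(d22_01, 1L, 30L),
                   setdiff(c("A", "C", "G", "T"), substr(d22_01, 31L, 31L))[1])
  acc$add("IGHD2-2*01", d22_01, "confirmed", two_labs(1L, "FIXD001"))
  acc$add("IGHD2-2*03", d22_03, "unconfirmed", bind_rows(
    ev_genomic("genomic-D1", "lab_D1", 1L, acc = "FIXD002"),
    ev_airr("airr-repertoire-study", 5L),
    ev_genbank("FIXD002")
  ))
  # identical-sequence gene pairs
  pair_names <- list(c("IGHD4-4*01", "IGHD4-11*01"),
                     c("IGHD5-5*01", "IGHD5-18*01"))
  pair_len <- c(16L, 20L)
  for (k in seq_len(comp$n_identical_pairs)) {
    s <- rand_dna(pair_len[k])
    while (s %in% acc$seen) s <- rand_dna(pair_len[k])
    acc$add(pair_names[[k]][1], s, "confirmed_pair", two_labs(k, sprintf("FIXD1%02d", k)))
    acc$add(pair_names[[k]][2], s, "confirmed_pair", two_labs(k, sprintf("FIXD2%02d", k)))
  }
  n_rest <- comp$n_total - 2L - 2L * comp$n_identical_pairs
  for (k in seq_len(n_rest)) {
    s <- rand_dna(sample(12:28, 1L))
    while (s %in% acc$seen) s <- rand_dna(sample(12:28, 1L))
    acc$add(sprintf("IGHD6-%d*01", k), s, "confirmed",
            two_labs(k, sprintf("FIXD3%02d", k)))
  }
  acc$result(NULL)
}

j_fixture <- function(prefix, comp, seed) {
  set.seed(seed)
  acc <- fixture_accumulator()
  pair_member2_seq <- NULL
  for (k in seq_len(comp$n_total)) {
    name <- sprintf("%s%d*01", prefix, k)
    if (comp$n_identical_pairs > 0L && k == 3L) {
      s <- pair_member2_seq  # identical to gene 2 (e.g. IGLJ2*01/IGLJ3*01)
      category <- "confirmed_pair"
    } else {
      s <- rand_dna(55L)
      while (s %in% acc$seen) s <- rand_dna(55L)
      category <- "confirmed"
      if (comp$n_identical_pairs > 0L && k == 2L) {
        pair_member2_seq <- s
        category <- "confirmed_pair"
      }
    }
    unconfirmed <- k > comp$n_total - comp$n_unconfirmed
    acc$add(name, s,
            if (unconfirmed) "unconfirmed" else category,
            if (unconfirmed) unconfirmed_evidence(1L, sprintf("FIXJ%03d", k))
            else confirmed_evidence(if (k %% 2L) 1L else 4L, sprintf("FIXJ%03d", k)))
  }
  acc$result(NULL)
}

#' Construct a comparator set fixture around a built Reference Set
#'
#' Builds an external-comparator fixture sharing all but a defined novel
#' subset of the built set's sequences and adding a defined number of
#' comparator-only sequences, mirroring how an independently maintained
#' reference directory overlaps a freshly curated set.
#'
#' @param reference_set built entry tibble (`name`, `sequence`).
#' @param n_novel number of built sequences withheld from the comparator
#'   (these become "built-only"; default 8).
#' @param n_comparator_only number of additional comparator-only sequences
#'   (default 156).
#' @param seed integer seed for the comparator-only sequences.
#' @return comparator tibble (`name`, `sequence`).
#' @export
comparator_fixture <- function(reference_set, n_novel = 8L,
                               n_comparator_only = 156L, seed = 1L) {
  set.seed(seed)
  ref <- arrange(as_tibble(reference_set), .data$name)
  stopifnot(nrow(ref) > n_novel)
  shared <- ref[-seq_len(n_novel), ]
  extra_seq <- character(0)
  while (length(extra_seq) < n_comparator_only) {
    s <- rand_dna(296L)
    if (!s %in% ref$sequence && !s %in% extra_seq) {
      extra_seq <- c(extra_seq, s)
    }
  }
  tibble(
    name = c(paste0("CMP|", shared$name),
             sprintf("CMP-ONLY-%03d*01", seq_len(n_comparator_only))),
    sequence = c(shared$sequence, extra_seq)
  )
}
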