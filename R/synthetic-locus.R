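# Ground-truth locus generation and repertoire simulation. The generator
# emulates the structure the curation rules assume: gene families sharing an
# exemplar, pseudogenes carrying stop codons or cysteine knockouts, exact
# paralog pairs (proximal/distal for kappa), an anchor J gene with two
# alleles for haplotyping, and D genes short enough for exonuclease trimming
# to obscure their ends.

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exemplar: stop-free codon sequence with TGT at the two conserved-cysteine
# codons; V lengths need not be codon multiples (alleles end mid-codon).
make_exemplar <- function(v_length = 296L, cys1_codon = 23L, cys2_codon = 96L) {
  n_codons <- v_length %/% 3L
  stopifnot(cys2_codon <= n_codons)
  codons <- sample(NONSTOP_CODONS, n_codons, replace = TRUE)
  codons[c(cys1_codon, cys2_codon)] <- "TGT"
  seq <- paste(codons, collapse = "")
  extra <- v_length - 3L * n_codons
  if (extra > 0L) seq <- paste0(seq, rand_dna(extra))
  list(
    sequence = seq,
    cys1_start = 3L * (cys1_codon - 1L) + 1L,
    cys2_start = 3L * (cys2_codon - 1L) + 1L
  )
}

# Substitute `n_subs` positions, avoiding `protect`ed positions and never
# creating an in-frame stop codon at the mutated site.
mutate_variant <- function(sequence, n_subs, protect = integer(0)) {
  chars <- strsplit(sequence, "")[[1]]
  eligible <- setdiff(seq_along(chars), protect)
  pos <- sample(eligible, n_subs)
  for (p in pos) {
    repeat {
      new <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      old <- chars[p]
      chars[p] <- new
      codon_start <- p - (p - 1L) %% 3L
      codon <- paste(chars[codon_start:min(codon_start + 2L, length(chars))],
                     collapse = "")
      if (nchar(codon) < 3L || !codon %in% STOP_CODONS) break
      chars[p] <- old
    }
  }
  paste(chars, collapse = "")
}

# A variant guaranteed distinct from everything in `existing`.
unique_variant <- function(sequence, n_subs, protect, existing) {
  repeat {
    v <- mutate_variant(sequence, n_subs, protect)
    if (!v %in% existing) return(v)
  }
}

cys_protect <- function(ex) c(ex$cys1_start:(ex$cys1_start + 2L),
                              ex$cys2_start:(ex$cys2_start + 2L))

#' Generate a ground-truth immunoglobulin locus
#'
#' Builds a reproducible toy locus: functional V genes (every third gene
#' carries two alleles, as required for haplotype analysis), pseudogenes
#' with injected stop codons or conserved-cysteine knockouts, exact paralog
#' pairs constrained to identical sequences (labelled proximal/distal for
#' the kappa chain), an anchor J gene with two alleles, and (for the heavy
#' chain) a panel of short D genes.
#'
#' @param chain `"IGK"`, `"IGH"` or `"IGL"`.
#' @param n_functional number of functional V genes (default 12).
#' @param n_pseudogenes number of pseudogene V genes (default 4).
#' @param n_paralog_pairs number of exact paralog pairs added as duplicated
#'   partners of functional genes (default 2).
#' @param v_length V gene length in nucleotides (default 296).
#' @param seed integer seed; the locus is identical for identical seeds.
#' @return an `ig_locus` list: `alleles` (tibble: `name`, `gene`, `family`,
#'   `sequence`, `is_pseudogene`, `locus_position`), `paralog_pairs`,
#'   `proximal_distal_pairs`, `anchor_j_gene`, `anchor_j_alleles`,
#'   `d_alleles`, `exemplars`, `chain`, `v_length`, `seed`.
#' @export
generate_locus <- function(chain = c("IGK", "IGH", "IGL"),
                           n_functional = 12L, n_pseudogenes = 4L,
                           n_paralog_pairs = 2L, v_length = 296L,
                           seed = 1L) {
  chain <- match.arg(chain)
  set.seed(seed)
  prefix <- paste0(chain, "V")
  n_families <- 3L
  exemplars <- bind_rows(map(seq_len(n_families), function(f) {
    ex <- make_exemplar(v_length)
    tibble(family = paste0(prefix, f), sequence = ex$sequence,
           cys1_start = ex$cys1_start, cys2_start = ex$cys2_start)
  }))
  seen <- character(0)
  alleles <- list()
  add_allele <- function(name, gene, family, sequence, is_pseudogene, pos) {
    alleles[[length(alleles) + 1L]] <<- tibble(
      name = name, gene = gene, family = family, sequence = sequence,
      is_pseudogene = is_pseudogene, locus_position = pos
    )
    seen <<- c(seen, sequence)
  }
  fam_of <- function(i) paste0(prefix, (i - 1L) %% n_families + 1L)
  ex_row <- function(fam) exemplars[exemplars$family == fam, ]
  gene_counter <- 0L
  new_gene <- function(fam) {
    gene_counter <<- gene_counter + 1L
    paste0(fam, "-", gene_counter + 10L)
  }

  # functional genes; every third carries a second allele
  functional_genes <- character(n_functional)
  for (i in seq_len(n_functional)) {
    fam <- fam_of(i)
    ex <- ex_row(fam)
    gene <- new_gene(fam)
    functional_genes[i] <- gene
    protect <- cys_protect(ex)
    a1 <- unique_variant(ex$sequence, 4L, protect, seen)
    add_allele(paste0(gene, "*01"), gene, fam, a1, FALSE, sprintf("pos%02d", i))
    if (i %% 3L == 0L) {
      a2 <- unique_variant(a1, 2L, protect, seen)
      add_allele(paste0(gene, "*02"), gene, fam, a2, FALSE, sprintf("pos%02d", i))
    }
  }

  # exact paralog pairs: duplicate the first pair-eligible functional genes
  pair_rows <- list()
  pd_rows <- list()
  for (k in seq_len(n_paralog_pairs)) {
    src_gene <- functional_genes[k]
    src <- bind_rows(alleles) %>% filter(.data$gene == src_gene)
    dup_gene <- if (chain == "IGK") {
      sub("^([A-Z]+[0-9]+)-", "\\1D-", src_gene)
    } else {
      paste0(src_gene, "D")
    }
    kappa_pair <- chain == "IGK"
    for (i in seq_len(nrow(src))) {
      add_allele(
        sub(src_gene, dup_gene, src$name[i], fixed = TRUE), dup_gene,
        src$family[i], src$sequence[i], FALSE,
        if (kappa_pair) "distal" else paste0(src$locus_position[i], "D")
      )
    }
    if (kappa_pair) {
      idx <- which(map_chr(alleles, ~ .x$gene[1]) == src_gene)
      for (j in idx) alleles[[j]]$locus_position <- "proximal"
      pd_rows[[k]] <- tibble(proximal = src_gene, distal = dup_gene)
    }
    pair_rows[[k]] <- tibble(gene_a = src_gene, gene_b = dup_gene)
  }

  # pseudogenes: alternating stop-codon and cysteine-knockout defects
  for (i in seq_len(n_pseudogenes)) {
    fam <- fam_of(i)
    ex <- ex_row(fam)
    gene <- new_gene(fam)
    base <- unique_variant(ex$sequence, 4L, cys_protect(ex), seen)
    seqd <- if (i %% 2L == 1L) {
      # stop codon at codon 40
      paste0(substr(base, 1L, 117L), "TAA", substr(base, 121L, nchar(base)))
    } else {
      # knock out the second conserved cysteine
      paste0(substr(base, 1L, ex$cys2_start - 1L), "AGT",
             substr(base, ex$cys2_start + 3L, nchar(base)))
    }
    add_allele(paste0(gene, "*01"), gene, fam, seqd, TRUE,
               sprintf("psi%02d", i))
  }

  anchor_gene <- switch(chain, IGH = "IGHJ6", IGK = "IGKJ2", IGL = "IGLJ2")
  j1 <- rand_dna(60L)
  j2 <- mutate_variant(j1, 3L)
  anchor_j <- tibble(
    name = paste0(anchor_gene, c("*01", "*02")),
    sequence = c(j1, j2)
  )

  d_alleles <- if (chain == "IGH") {
    tibble(
      name = paste0("IGHD", 1:5, "-", c(1L, 2L, 3L, 4L, 5L), "*01"),
      sequence = map_chr(c(16L, 18L, 21L, 16L, 23L), rand_dna)
    )
  } else {
    tibble(name = character(0), sequence = character(0))
  }

  structure(
    list(
      alleles = bind_rows(alleles),
      paralog_pairs = if (length(pair_rows) > 0) bind_rows(pair_rows) else
        tibble(gene_a = character(0), gene_b = character(0)),
      proximal_distal_pairs = if (length(pd_rows) > 0) bind_rows(pd_rows) else
        tibble(proximal = character(0), distal = character(0)),
      anchor_j_gene = anchor_gene,
      anchor_j_alleles = anchor_j,
      d_alleles = d_alleles,
      exemplars = exemplars,
      chain = chain,
      v_length = v_length,
      seed = seed
    ),
    class = "ig_locus"
  )
}

#' @export
print.ig_locus <- function(x, ...) {
  cat(sprintf(
    "<ig_locus %s> %d alleles over %d genes (%d pseudogenes), %d paralog pairs, anchor %s\n",
    x$chain, nrow(x$alleles), length(unique(x$alleles$gene)),
    sum(x$alleles$is_pseudogene), nrow(x$paralog_pairs), x$anchor_j_gene
  ))
  invisible(x)
}

#' Simulate a rearrangement repertoire from a ground-truth locus
#'
#' Each individual receives two haplotypes (one allele per functional gene
#' per haplotype) and is heterozygous at the anchor J gene, with anchor
#' allele *01 on haplotype 1. Every record draws one haplotype, a V gene by
#' expression propensity, the haplotype's V allele, and the same haplotype's
#' anchor J allele (perfect V--J linkage; `linkage_noise` flips a fraction
#' to the opposite anchor). For kappa loci the proximal member of each
#' duplicated pair receives an expression share above the proximal
#' frequency band and the distal member a share below the distal band. For
#' the heavy chain, D segments are drawn uniformly and trimmed at each end
#' by independent geometric amounts (mean `≈ (1-p)/p` nt), so
#' full-length D observations are a minority.
#'
#' @param locus an `ig_locus` from [generate_locus()].
#' @param n_individuals number of simulated individuals (default 20).
#' @param reads_per_individual records per individual (default 1500).
#' @param config a [curation_config()] (recorded, not used for drawing).
#' @param linkage_noise probability that a record's J call comes from the
#'   opposite haplotype (default 0).
#' @param d_trim_p geometric parameter for per-end D trimming (default 1/3,
#'   mean 2 nt per end).
#' @param proximal_share,distal_share expected repertoire share (percent)
#'   of each proximal / distal pair gene (defaults 5.5 and 0.35).
#' @param seed integer seed.
#' @return a rearrangement tibble (`sequence_id`, `individual_id`,
#'   `v_call`, `d_call`, `j_call`, `v_mutation_count`, `productive`, and for
#'   heavy chains `d_trim_5p`, `d_trim_3p`) with attributes
#'   `individuals` (haplotype table: `individual_id`, `gene`, `hap1`,
#'   `hap2`) and `true_haplotype` (integer vector, one per record).
#' @export
simulate_repertoire <- function(locus, n_individuals = 20L,
                                reads_per_individual = 1500L,
                                config = curation_config(),
                                linkage_noise = 0, d_trim_p = 1 / 3,
                                proximal_share = 5.5, distal_share = 0.35,
                                seed = 1L) {
  set.seed(seed)
  functional <- filter(locus$alleles, !.data$is_pseudogene)
  genes <- unique(functional$gene)
  proximal <- locus$proximal_distal_pairs$proximal
  distal <- locus$proximal_distal_pairs$distal
  other <- setdiff(genes, c(proximal, distal))
  weights <- setNames(numeric(length(genes)), genes)
  weights[proximal] <- proximal_share
  weights[distal] <- distal_share
  weights[other] <- (100 - sum(weights)) / length(other)

  hap_tables <- list()
  records <- list()
  truth <- list()
  anchor <- locus$anchor_j_alleles$name
  for (i in seq_len(n_individuals)) {
    ind <- sprintf("I%03d", i)
    hap <- bind_rows(map(genes, function(g) {
      pool <- functional$name[functional$gene == g]
      tibble(individual_id = ind, gene = g,
             hap1 = sample(pool, 1L),
             hap2 = sample(pool, 1L))
    }))
    hap_tables[[i]] <- hap
    n <- reads_per_individual
    h <- sample(1:2, n, replace = TRUE)
    g <- sample(genes, n, replace = TRUE, prob = weights[genes])
    v <- ifelse(h == 1L, hap$hap1[match(g, hap$gene)], hap$hap2[match(g, hap$gene)])
    flip <- runif(n) < linkage_noise
    j <- anchor[ifelse(flip, 3L - h, h)]
    rec <- tibble(
      sequence_id = sprintf("%s_R%05d", ind, seq_len(n)),
      individual_id = ind,
      v_call = v,
      d_call = NA_character_,
      j_call = j,
      v_mutation_count = 0L,
      productive = TRUE
    )
    if (nrow(locus$d_alleles) > 0) {
      rec$d_call <- sample(locus$d_alleles$name, n, replace = TRUE)
      rec$d_trim_5p <- rgeom(n, d_trim_p)
      rec$d_trim_3p <- rgeom(n, d_trim_p)
    }
    records[[i]] <- rec
    truth[[i]] <- h
  }
  out <- bind_rows(records)
  attr(out, "individuals") <- bind_rows(hap_tables)
  attr(out, "true_haplotype") <- unlist(truth)
  out
}
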