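# Inference of genomic location from AIRR-seq rearrangement tables.
# In an individual heterozygous at an anchor J gene (commonly IGHJ6 for the
# heavy locus, IGKJ2 for kappa), each low-mutation rearrangement is phased
# by its J allele; a V allele consistently co-occurring with one J allele
# sits on that chromosomal haplotype. An unmapped allele that always
# opposes a mapped allele of the same gene across informative individuals
# can be placed at that gene's locus. Kappa proximal/distal placement is
# additionally informed by expression frequency bands, and by locus
# exclusion in individuals homozygous for one member of a duplicated pair.

#' Phase one individual's V alleles by anchor-J heterozygosity
#'
#' Restricted to records with `v_mutation_count <=` the configured cap
#' (default 0, unmutated). The individual must carry exactly two distinct
#' alleles of `anchor_gene`; otherwise the individual is skipped with a
#' message and `NULL` is returned. Each V allele is assigned to haplotype 1
#' or 2 when at least `haplotype_min_reads` anchored reads support it and
#' the majority haplotype holds at least `haplotype_purity` of them; an
#' adequately covered allele failing purity is called `"both"`, an
#' under-covered one `"unassigned"`.
#'
#' @param rearrangements rearrangement tibble for one individual
#'   (`individual_id`, `v_call`, `j_call`, `v_mutation_count`).
#' @param anchor_gene anchor J gene name (e.g. `"IGHJ6"`, `"IGKJ2"`).
#' @param config a [curation_config()].
#' @return an `ig_haplotype_assignment`: tibble with `individual_id`,
#'   `anchor_gene`, `anchor_allele_1`, `anchor_allele_2`, `v_allele`,
#'   `count_on_anchor1`, `count_on_anchor2`, `assigned_haplotype`
#'   (`"1"`, `"2"`, `"both"`, `"unassigned"`); or `NULL` when the anchor is
#'   homozygous or absent.
#' @export
haplotype_individual <- function(rearrangements, anchor_gene,
                                 config = curation_config()) {
  rec <- as_tibble(rearrangements)
  ind <- unique(rec$individual_id)
  if (length(ind) != 1L) abort("haplotype_individual() expects records from one individual")
  rec <- filter(rec, .data$v_mutation_count <= config$haplotype_mutation_cap)
  rec <- filter(rec, allele_gene(.data$j_call) == anchor_gene)
  anchors <- sort(unique(rec$j_call))
  if (length(anchors) != 2L) {
    inform(sprintf(
      "individual %s skipped: %s at anchor %s",
      ind, if (length(anchors) < 2L) "homozygous or absent" else "more than two alleles",
      anchor_gene
    ))
    return(NULL)
  }
  counts <- rec %>%
    count(.data$v_call, .data$j_call) %>%
    tidyr::pivot_wider(names_from = "j_call", values_from = "n", values_fill = 0L)
  n1 <- counts[[anchors[1]]]
  n2 <- counts[[anchors[2]]]
  total <- n1 + n2
  purity <- pmax(n1, n2) / pmax(total, 1L)
  assigned <- dplyr::case_when(
    total < config$haplotype_min_reads ~ "unassigned",
    purity >= config$haplotype_purity & n1 >= n2 ~ "1",
    purity >= config$haplotype_purity ~ "2",
    TRUE ~ "both"
  )
  out <- tibble(
    individual_id = ind,
    anchor_gene = anchor_gene,
    anchor_allele_1 = anchors[1],
    anchor_allele_2 = anchors[2],
    v_allele = counts$v_call,
    count_on_anchor1 = as.integer(n1),
    count_on_anchor2 = as.integer(n2),
    assigned_haplotype = assigned
  )
  class(out) <- c("ig_haplotype_assignment", class(out))
  out
}

#' Phase every individual in a rearrangement table
#'
#' @param rearrangements rearrangement tibble covering multiple individuals.
#' @inheritParams haplotype_individual
#' @return row-bound `ig_haplotype_assignment` tibble (individuals with an
#'   uninformative anchor are skipped).
#' @export
haplotype_all <- function(rearrangements, anchor_gene,
                          config = curation_config()) {
  pieces <- rearrangements %>%
    group_by(.data$individual_id) %>%
    dplyr::group_split() %>%
    map(haplotype_individual, anchor_gene = anchor_gene, config = config)
  out <- bind_rows(keep(pieces, Negate(is.null)))
  class(out) <- c("ig_haplotype_assignment", class(out))
  out
}

#' Infer co-location of an unmapped allele from haplotype opposition
#'
#' A location call is issued only when, in every informative individual, the
#' unmapped allele sits on one haplotype while a mapped allele of the same
#' gene sits on the other. Contradictory individuals (both alleles phased to
#' the same haplotype) veto the call. The call never contradicts an explicit
#' mapped locus already attached to the allele.
#'
#' @param assignments combined haplotype assignments ([haplotype_all()]).
#' @param unmapped_allele allele designation to place.
#' @param mapped_alleles named character vector: mapped allele designation ->
#'   locus label.
#' @param known_locus locus already attached to the unmapped allele, if any;
#'   a call matching it is returned, a conflicting inference is suppressed.
#' @return a one-row `LocusCall` tibble (`allele_name`, `inferred_locus`,
#'   `method`, `supporting_individuals` list-column) or `NULL`.
#' @export
infer_colocation <- function(assignments, unmapped_allele, mapped_alleles,
                             known_locus = NA_character_) {
  asg <- as_tibble(assignments)
  phased <- filter(asg, .data$assigned_haplotype %in% c("1", "2"))
  supporting <- character(0)
  locus_votes <- character(0)
  for (ind in unique(phased$individual_id)) {
    p <- filter(phased, .data$individual_id == ind)
    un <- filter(p, .data$v_allele == unmapped_allele)
    mp <- filter(p, .data$v_allele %in% names(mapped_alleles))
    if (nrow(un) != 1L || nrow(mp) == 0L) next
    if (any(mp$assigned_haplotype == un$assigned_haplotype)) {
      inform(sprintf(
        "individual %s contradicts co-location of %s: same haplotype as a mapped allele",
        ind, unmapped_allele
      ))
      return(NULL)
    }
    supporting <- c(supporting, ind)
    locus_votes <- c(locus_votes, unname(mapped_alleles[mp$v_allele]))
  }
  if (length(supporting) == 0L) return(NULL)
  locus <- unique(locus_votes)
  if (length(locus) != 1L) {
    inform(sprintf("conflicting mapped loci for %s: %s",
                   unmapped_allele, paste(locus, collapse = ", ")))
    return(NULL)
  }
  if (!is.na(known_locus) && known_locus != "unlocated" && known_locus != locus) {
    inform(sprintf(
      "inferred locus %s for %s conflicts with recorded locus %s; no call",
      locus, unmapped_allele, known_locus
    ))
    return(NULL)
  }
  tibble(
    allele_name = unmapped_allele,
    inferred_locus = locus,
    method = "haplotype_cotrans",
    supporting_individuals = list(supporting)
  )
}

#' Classify a kappa gene as proximal or distal by expression frequency
#'
#' Proximal-locus kappa genes are expressed at markedly higher frequencies
#' than their distal counterparts. Per-individual frequencies (percent of
#' the productive VJ repertoire) are aggregated by the median: at or above
#' `proximal_freq_hi` the gene is called `proximal`; at or below
#' `distal_freq_lo` it is `distal_consistent`; between the bands (or with no
#' expressing individuals) it is `ambiguous`. The classification is monotone
#' in the frequencies.
#'
#' @param frequencies numeric vector of per-individual expression
#'   frequencies (percent), or a tibble with columns `gene` and `frequency`
#'   for several genes at once.
#' @param config a [curation_config()].
#' @return an `ig_frequency_classification` tibble: `gene` (absent for a
#'   bare vector), `n_individuals`, `median_frequency`, `classification`.
#' @examples
#' classify_proximal_distal(c(4.5, 5.1, 4.2))
#' classify_proximal_distal(c(0.3, 0.5))
#' @export
classify_proximal_distal <- function(frequencies, config = curation_config()) {
  if (is.numeric(frequencies)) {
    frequencies <- tibble(gene = NA_character_, frequency = frequencies)
  }
  out <- frequencies %>%
    group_by(.data$gene) %>%
    summarise(
      n_individuals = sum(!is.na(.data$frequency)),
      median_frequency = median(.data$frequency, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(classification = dplyr::case_when(
      .data$n_individuals == 0L ~ "ambiguous",
      .data$median_frequency >= config$proximal_freq_hi ~ "proximal",
      .data$median_frequency <= config$distal_freq_lo ~ "distal_consistent",
      TRUE ~ "ambiguous"
    ))
  class(out) <- c("ig_frequency_classification", class(out))
  out
}

#' Per-individual gene expression frequencies
#'
#' Frequencies are percentages of each individual's productive VJ
#' repertoire, the denominator used by the proximal/distal bands.
#'
#' @param rearrangements rearrangement tibble.
#' @return tibble: `individual_id`, `gene`, `n_records`, `frequency`
#'   (percent).
#' @export
gene_frequencies <- function(rearrangements) {
  rec <- filter(as_tibble(rearrangements), .data$productive)
  rec %>%
    mutate(gene = allele_gene(.data$v_call)) %>%
    count(.data$individual_id, .data$gene, name = "n_records") %>%
    group_by(.data$individual_id) %>%
    mutate(frequency = 100 * .data$n_records / sum(.data$n_records)) %>%
    ungroup()
}

#' Place an unmapped allele by locus exclusion
#'
#' In an individual who expresses the unmapped allele while carrying two
#' doses (an apparently homozygous genotype) of one member of a
#' proximal/distal gene pair, the occupied locus is excluded and the
#' unmapped allele is assigned to the other member's locus. Heterozygosity
#' at the pair member yields no call.
#'
#' @param genotype per-individual genotype tibble: `individual_id`,
#'   `allele_name`, `copies` (haplotype doses, 0--2).
#' @param unmapped_allele allele designation to place.
#' @param gene_pair named character vector of length 2 mapping the pair's
#'   gene names to their loci, e.g.
#'   `c("IGKV3-15" = "proximal", "IGKV3D-15" = "distal")`.
#' @return a one-row `LocusCall` tibble or `NULL`.
#' @export
locus_exclusion <- function(genotype, unmapped_allele, gene_pair) {
  if (length(gene_pair) != 2L || is.null(names(gene_pair))) {
    abort("gene_pair must be a named character vector of length 2 (gene -> locus)")
  }
  gt <- as_tibble(genotype)
  gt$gene <- allele_gene(gt$allele_name)
  supporting <- character(0)
  loci <- character(0)
  for (ind in unique(gt$individual_id)) {
    g <- filter(gt, .data$individual_id == ind)
    if (!unmapped_allele %in% g$allele_name[g$copies > 0]) next
    for (member in names(gene_pair)) {
      doses <- g %>% filter(.data$gene == member) %>% pull("copies")
      occupied <- length(doses) == 1L && doses == 2L
      if (occupied) {
        other <- setdiff(names(gene_pair), member)
        supporting <- c(supporting, ind)
        loci <- c(loci, unname(gene_pair[other]))
      }
    }
  }
  if (length(supporting) == 0L) return(NULL)
  locus <- unique(loci)
  if (length(locus) != 1L) return(NULL)
  tibble(
    allele_name = unmapped_allele,
    inferred_locus = locus,
    method = "locus_exclusion",
    supporting_individuals = list(unique(supporting))
  )
}
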