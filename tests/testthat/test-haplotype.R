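cfg <- curation_config()

# hand-built individual: anchor IGKJ2 heterozygote with three V alleles
toy_individual <- function(counts) {
  # counts: named list v_allele -> c(on_anchor1, on_anchor2)
  rec <- purrr::imap(counts, function(n, v) {
    tibble::tibble(
      sequence_id = paste0(v, seq_len(sum(n))),
      individual_id = "I1",
      v_call = v,
      d_call = NA_character_,
      j_call = rep(c("IGKJ2*01", "IGKJ2*02"), times = n),
      v_mutation_count = 0L,
      productive = TRUE
    )
  })
  dplyr::bind_rows(rec)
}

test_that("haplotype assignment follows the purity and coverage thresholds", {
  rec <- toy_individual(list(
    "IGKV1-5*01" = c(40L, 0L),   # pure on haplotype 1
    "IGKV1-6*01" = c(1L, 39L),   # near-pure on haplotype 2
    "IGKV1-7*01" = c(20L, 20L),  # 50/50: on both haplotypes
    "IGKV1-8*01" = c(3L, 2L)     # under-covered
  ))
  asg <- haplotype_individual(rec, "IGKJ2", cfg)
  got <- setNames(asg$assigned_haplotype, asg$v_allele)
  expect_equal(got[["IGKV1-5*01"]], "1")
  expect_equal(got[["IGKV1-6*01"]], "2")
  expect_equal(got[["IGKV1-7*01"]], "both")
  expect_equal(got[["IGKV1-8*01"]], "unassigned")
  expect_equal(unique(asg$anchor_allele_1), "IGKJ2*01")
})

test_that("anchor-homozygous individuals are skipped and mutated reads excluded", {
  rec <- toy_individual(list("IGKV1-5*01" = c(40L, 0L)))
  hom <- dplyr::mutate(rec, j_call = "IGKJ2*01")
  expect_message(out <- haplotype_individual(hom, "IGKJ2", cfg), "skipped")
  expect_null(out)
  # mutated reads do not inform haplotyping under the default cap of 0
  mut <- dplyr::mutate(rec, v_mutation_count = 5L)
  expect_message(haplotype_individual(mut, "IGKJ2", cfg), "skipped")
})

test_that("noiseless simulated haplotypes are recovered exactly", {
  locus <- generate_locus(seed = 31)
  rep <- simulate_repertoire(locus, n_individuals = 6,
                             reads_per_individual = 2000, seed = 32)
  asg <- haplotype_all(rep, locus$anchor_j_gene, cfg)
  haps <- attr(rep, "individuals")
  checked <- 0L
  for (i in seq_len(nrow(asg))) {
    row <- asg[i, ]
    if (row$assigned_haplotype == "unassigned") next
    h <- haps[haps$individual_id == row$individual_id, ]
    on1 <- row$v_allele %in% h$hap1
    on2 <- row$v_allele %in% h$hap2
    truth <- if (on1 && on2) "both" else if (on1) "1" else "2"
    expect_equal(row$assigned_haplotype, truth)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("co-location is inferred from consistent haplotype opposition", {
  mk_asg <- function(ind, novel_h, mapped_h) {
    tibble::tibble(
      individual_id = ind, anchor_gene = "IGKJ2",
      anchor_allele_1 = "IGKJ2*01", anchor_allele_2 = "IGKJ2*02",
      v_allele = c("IGKV3-15*01_A117G", "IGKV3-15*01"),
      count_on_anchor1 = c(0L, 0L), count_on_anchor2 = c(0L, 0L),
      assigned_haplotype = c(novel_h, mapped_h)
    )
  }
  mapped <- c("IGKV3-15*01" = "proximal")
  consistent <- dplyr::bind_rows(mk_asg("I1", "1", "2"), mk_asg("I2", "2", "1"))
  call <- infer_colocation(consistent, "IGKV3-15*01_A117G", mapped)
  expect_equal(call$inferred_locus, "proximal")
  expect_equal(call$method, "haplotype_cotrans")
  expect_setequal(call$supporting_individuals[[1]], c("I1", "I2"))

  # one contradictory individual among several vetoes the call
  contradicted <- dplyr::bind_rows(consistent, mk_asg("I3", "1", "1"))
  expect_message(out <- infer_colocation(contradicted, "IGKV3-15*01_A117G", mapped),
                 "contradicts")
  expect_null(out)

  # a call never contradicts an explicitly recorded locus
  expect_message(
    out2 <- infer_colocation(consistent, "IGKV3-15*01_A117G", mapped,
                             known_locus = "distal"),
    "conflicts"
  )
  expect_null(out2)
})

test_that("simulated co-location panels recover the simulated locus", {
  locus <- generate_locus(seed = 41)
  rep <- simulate_repertoire(locus, n_individuals = 20,
                             reads_per_individual = 1500, seed = 42)
  asg <- haplotype_all(rep, locus$anchor_j_gene, cfg)
  # treat one allele of a two-allele gene as "unmapped" and its sibling as
  # mapped; the inferred locus must equal the gene's simulated position
  two <- dplyr::filter(
    dplyr::count(dplyr::filter(locus$alleles, !is_pseudogene), gene),
    n == 2L
  )
  gene <- two$gene[[1]]
  pair <- locus$alleles[locus$alleles$gene == gene, ]
  mapped <- setNames(pair$locus_position[1], pair$name[1])
  call <- infer_colocation(asg, pair$name[2], mapped)
  expect_equal(call$inferred_locus, pair$locus_position[1])
  expect_gt(length(call$supporting_individuals[[1]]), 0L)
})

test_that("frequency bands classify proximal and distal expression", {
  expect_equal(classify_proximal_distal(c(4.5, 5.1, 4.2))$classification,
               "proximal")
  expect_equal(classify_proximal_distal(c(0.3, 0.5))$classification,
               "distal_consistent")
  expect_equal(classify_proximal_distal(2.0)$classification, "ambiguous")
  expect_equal(classify_proximal_distal(numeric(0))$classification[0],
               character(0))

  # monotonicity: raising every frequency never moves proximal -> distal
  set.seed(8)
  ranks <- c(distal_consistent = 1L, ambiguous = 2L, proximal = 3L)
  for (i in 1:25) {
    f <- runif(5, 0, 8)
    lo <- classify_proximal_distal(f)$classification
    hi <- classify_proximal_distal(f + runif(1, 0, 3))$classification
    expect_gte(ranks[[hi]], ranks[[lo]])
  }
})

test_that("locus exclusion assigns the unoccupied member of a duplicated pair", {
  pair <- c("IGKV3-15" = "proximal", "IGKV3D-15" = "distal")
  genotype <- tibble::tibble(
    individual_id = c("I1", "I1"),
    allele_name = c("IGKV3-15*i01", "IGKV3D-15*01"),
    copies = c(1L, 2L)
  )
  call <- locus_exclusion(genotype, "IGKV3-15*i01", pair)
  expect_equal(call$inferred_locus, "proximal")
  expect_equal(call$method, "locus_exclusion")

  het <- dplyr::mutate(genotype, copies = c(1L, 1L))
  expect_null(locus_exclusion(het, "IGKV3-15*i01", pair))
  expect_error(locus_exclusion(genotype, "x", c("a", "b")), "named")
})

test_that("per-individual gene frequencies use the productive VJ denominator", {
  rec <- tibble::tibble(
    sequence_id = as.character(1:10), individual_id = "I1",
    v_call = c(rep("IGKV1-5*01", 6), rep("IGKV2-8*01", 4)),
    d_call = NA_character_, j_call = "IGKJ2*01",
    v_mutation_count = 0L,
    productive = c(rep(TRUE, 6), rep(TRUE, 2), FALSE, FALSE)
  )
  freq <- gene_frequencies(rec)
  expect_equal(freq$frequency[freq$gene == "IGKV1-5"], 75)
  expect_equal(freq$frequency[freq$gene == "IGKV2-8"], 25)
})
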