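test_that("locus generation is deterministic and labels pseudogenes correctly", {
  a <- generate_locus(seed = 17)
  b <- generate_locus(seed = 17)
  expect_equal(a$alleles, b$alleles)
  expect_equal(a$anchor_j_alleles, b$anchor_j_alleles)
  expect_false(identical(a$alleles$sequence,
                         generate_locus(seed = 18)$alleles$sequence))

  # paralog pairs are identical by construction, and collapse removes
  # exactly one entry per pair
  locus <- generate_locus(n_paralog_pairs = 3, seed = 19)
  for (i in seq_len(nrow(locus$paralog_pairs))) {
    pa <- locus$alleles[locus$alleles$gene == locus$paralog_pairs$gene_a[i], ]
    pb <- locus$alleles[locus$alleles$gene == locus$paralog_pairs$gene_b[i], ]
    expect_setequal(pa$sequence, pb$sequence)
  }
  functional <- locus$alleles[!locus$alleles$is_pseudogene, ]
  entries <- toy_entries(functional$name, functional$sequence, chain = "IGK-V")
  n_dup <- sum(duplicated(functional$sequence))
  expect_equal(nrow(collapse_paralogs(entries)), nrow(entries) - n_dup)
})

test_that("error-free reports reproduce the truth with recall 1", {
  locus <- generate_locus(seed = 23)
  zero <- report_error_profile(substitution = 0, stop_codon = 0,
                               cys_knockout = 0, minor_truncation = 0,
                               major_truncation = 0)
  reports <- generate_reports(locus, zero, seed = 24)
  expect_true(all(reports$labels$truth %in% c("real", "pseudogene")))
  verdicts <- structural_filter(reports$candidates, locus$exemplars)
  src <- build_source_set(reports$candidates, verdicts)
  build <- build_reference_set(src$source_set, donors = reports$donors,
                               exemplars = locus$exemplars)
  expect_setequal(build$reference_set$sequence, locus_truth_sequences(locus))
})

test_that("single-source erroneous candidates never reach the Source Set", {
  heavy_errors <- report_error_profile(substitution = 0.5, stop_codon = 0.3,
                                       cys_knockout = 0.3,
                                       minor_truncation = 0.2,
                                       major_truncation = 0.3)
  locus <- generate_locus(seed = 29)
  reports <- generate_reports(locus, heavy_errors, seed = 30)
  erroneous <- reports$labels$name[grepl("^erroneous", reports$labels$truth)]
  expect_gt(length(erroneous), 10L)
  verdicts <- structural_filter(reports$candidates, locus$exemplars)
  src <- build_source_set(reports$candidates, verdicts)
  expect_length(intersect(src$source_set$name, erroneous), 0L)
})

test_that("repertoires show D trimming, V-J linkage and the kappa frequency structure", {
  locus <- generate_locus("IGH", seed = 35)
  rep <- simulate_repertoire(locus, n_individuals = 4,
                             reads_per_individual = 1000, seed = 36)
  # exonuclease trimming: full-length D observations are a minority
  full_length <- mean(rep$d_trim_5p == 0 & rep$d_trim_3p == 0)
  expect_lt(full_length, 0.5)
  expect_gt(mean(rep$d_trim_5p), 1)

  # perfect linkage: every record's J call matches its true haplotype
  anchors <- locus$anchor_j_alleles$name
  expect_true(all(rep$j_call == anchors[attr(rep, "true_haplotype")]))

  # kappa: simulated proximal pair genes classify proximal, distal distal
  kl <- generate_locus("IGK", seed = 37)
  krep <- simulate_repertoire(kl, n_individuals = 8,
                              reads_per_individual = 2000, seed = 38)
  freq <- gene_frequencies(krep)
  cls <- classify_proximal_distal(freq)
  got <- setNames(cls$classification, cls$gene)
  expect_true(all(got[kl$proximal_distal_pairs$proximal] == "proximal"))
  expect_true(all(got[kl$proximal_distal_pairs$distal] == "distal_consistent"))
})

test_that("naive annotation assigns everything to a single-allele reference", {
  set.seed(41)
  v <- igrefset:::rand_dna(100)
  reads <- vapply(1:20, function(i) paste0(v, igrefset:::rand_dna(10)), "")
  ann <- naive_annotate(reads, tibble::tibble(name = "IGHV1-1*01", sequence = v))
  expect_true(all(ann$best_call == "IGHV1-1*01"))
  expect_true(all(ann$mismatches == 0L))
  expect_error(naive_annotate(reads, tibble::tibble(name = character(0),
                                                    sequence = character(0))),
               "empty")
})

test_that("a truncated reference splits one allele's reads; extension repairs it", {
  demo <- truncation_artifact_demo(n_reads = 4000, seed = 43)
  truncated <- demo[demo$reference == "truncated", ]
  extended <- demo[demo$reference == "extended", ]
  # substantial minority misassigned, every misassignment carries a mismatch
  expect_gt(truncated$n_misassigned, 0L)
  expect_lt(truncated$fraction_misassigned, 0.5)
  expect_equal(truncated$n_misassigned_with_mismatch, truncated$n_misassigned)
  # extension eliminates misassignment (no exact ties in this geometry)
  expect_equal(extended$n_misassigned, 0L)
})
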