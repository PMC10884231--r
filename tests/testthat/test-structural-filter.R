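test_that("classify_orf agrees with a brute-force codon scan", {
  expect_true(classify_orf("TGTGCA")$is_orf)
  res <- classify_orf("ATGTAAGGG")
  expect_false(res$is_orf)
  expect_equal(res$stop_codons[[1]], 2L)

  # independent oracle: explicit loop over codon substrings
  brute_stops <- function(s, frame) {
    hits <- integer(0)
    i <- frame + 1L; k <- 0L
    while (i + 2L <= nchar(s)) {
      k <- k + 1L
      if (substr(s, i, i + 2L) %in% c("TAA", "TAG", "TGA")) hits <- c(hits, k)
      i <- i + 3L
    }
    hits
  }
  set.seed(42)
  for (rep in 1:20) {
    s <- igrefset:::rand_dna(300)
    for (frame in 0:2) {
      got <- classify_orf(s, frame)
      expect_equal(got$stop_codons[[1]], brute_stops(s, frame))
      expect_equal(got$is_orf, length(brute_stops(s, frame)) == 0L)
    }
  }
  expect_error(classify_orf("ACGT", reading_frame = 3), "reading_frame")
})

test_that("conserved-cysteine detection matches constructed ground truth", {
  ex <- toy_exemplar()
  pos <- c(ex$cys1_start, ex$cys2_start)

  expect_equal(
    check_conserved_cysteines(ex$sequence, ex$sequence, pos),
    tibble::tibble(first_present = TRUE, second_present = TRUE)
  )

  knocked <- ex$sequence
  substr(knocked, pos[2], pos[2] + 2) <- "TAT"
  expect_equal(
    check_conserved_cysteines(knocked, ex$sequence, pos),
    tibble::tibble(first_present = TRUE, second_present = FALSE)
  )

  # 20 simulated candidates with random single-codon knockouts
  set.seed(9)
  for (i in 1:20) {
    kill_first <- i %% 2L == 0L
    cand <- igrefset:::mutate_variant(ex$sequence, 3L,
                                      protect = igrefset:::cys_protect(ex))
    at <- if (kill_first) pos[1] else pos[2]
    substr(cand, at, at + 2) <- "GCT"
    got <- check_conserved_cysteines(cand, ex$sequence, pos)
    expect_equal(got$first_present, !kill_first)
    expect_equal(got$second_present, kill_first)
  }

  expect_error(check_conserved_cysteines("ACGT", "ACGTAA", c(1, 5)),
               "outside")
})

test_that("cysteine mapping survives end-truncation and indel alignment", {
  ex <- toy_exemplar()
  pos <- c(ex$cys1_start, ex$cys2_start)
  trunc5 <- substr(ex$sequence, 31, nchar(ex$sequence))
  expect_equal(
    check_conserved_cysteines(trunc5, ex$sequence, pos),
    tibble::tibble(first_present = TRUE, second_present = TRUE)
  )
  # internal deletion forces the pairwise-alignment fallback
  gapped <- paste0(substr(ex$sequence, 1, 150), substr(ex$sequence, 160, nchar(ex$sequence)))
  got <- check_conserved_cysteines(gapped, ex$sequence, pos)
  expect_true(got$first_present)
  expect_true(got$second_present)
})

test_that("truncation classification follows the threshold arithmetic", {
  cfg <- curation_config()
  comparison <- paste0(strrep("ACGT", 30), "TGCGAGAGA")  # 129 nt

  same <- classify_truncation(comparison, comparison, cfg)
  expect_equal(same$class, "none")
  expect_equal(same$missing_nt, 0L)

  minus2 <- classify_truncation(substr(comparison, 1, 127), comparison, cfg)
  expect_equal(minus2$class, "minor_3p")
  expect_equal(minus2$missing_nt, 2L)

  minus30 <- classify_truncation(substr(comparison, 31, 129), comparison, cfg)
  expect_equal(minus30$class, "major_5p")
  expect_equal(minus30$missing_nt, 30L)

  longer <- classify_truncation(paste0(comparison, "AA"), comparison, cfg)
  expect_equal(longer$class, "none")
  expect_equal(longer$missing_nt, 0L)
})

test_that("gene-level gate keeps genes with one sound allele and drops the rest", {
  ex <- toy_exemplar()
  sound <- igrefset:::mutate_variant(ex$sequence, 3L,
                                     protect = igrefset:::cys_protect(ex))
  stopper <- paste0(substr(sound, 1, 117), "TAA", substr(sound, 121, nchar(sound)))
  nocys <- sound
  substr(nocys, ex$cys2_start, ex$cys2_start + 2) <- "AGT"

  cand <- tibble::tibble(
    name = c("IGHV1-10*01", "IGHV1-10*02", "IGHV1-11*01"),
    sequence = c(sound, stopper, nocys),
    chain = "IGH-V"
  )
  gate <- gene_level_gate(cand, ex)
  expect_equal(gate$keep[gate$gene == "IGHV1-10"], TRUE)
  expect_equal(gate$keep[gate$gene == "IGHV1-11"], FALSE)

  verdicts <- structural_filter(cand, ex)
  # non-ORF allele of a kept gene is retained but flagged
  expect_true(verdicts$passed[2])
  expect_false(verdicts$is_orf[2])
  expect_length(verdicts$reasons[[2]], 0L)
  # only allele lacking the 2nd Cys: gene dropped, all reasons recorded
  expect_false(verdicts$passed[3])
  expect_setequal(verdicts$reasons[[3]],
                  c("no_orf_allele_in_gene", "missing_second_cysteine"))
})

test_that("simulated pseudogene-only genes are exactly the structural rejects", {
  locus <- generate_locus(n_functional = 10, n_pseudogenes = 5, seed = 21)
  cand <- tibble::tibble(
    name = locus$alleles$name,
    sequence = locus$alleles$sequence,
    chain = paste0(locus$chain, "-V")
  )
  verdicts <- structural_filter(cand, locus$exemplars)
  rejected_genes <- unique(verdicts$gene[!verdicts$passed])
  truth_genes <- unique(locus$alleles$gene[locus$alleles$is_pseudogene])
  expect_setequal(rejected_genes, truth_genes)
  expect_length(truth_genes, 5L)
})

test_that("verdict reasons match injected defect labels on fixture candidates", {
  fx <- candidate_fixture("IGHV", seed = 3)
  verdicts <- structural_filter(fx$candidates, fx$exemplars)
  joined <- dplyr::left_join(verdicts, fx$labels, by = "name")
  reject <- joined[grepl("^reject_", joined$category), ]
  expect_true(all(!reject$passed))
  expect_reason <- function(category, reason) {
    rows <- reject[reject$category == category, ]
    expect_true(all(purrr::map_lgl(rows$reasons, ~ reason %in% .x)),
                label = paste(category, "->", reason))
  }
  expect_reason("reject_stop", "stop_codon")
  expect_reason("reject_cys1", "missing_first_cysteine")
  expect_reason("reject_cys2", "missing_second_cysteine")
  expect_reason("reject_major_3p", "major_3p_truncation")
  expect_reason("reject_major_5p", "major_5p_truncation")
  # and every non-reject candidate passes
  expect_true(all(joined$passed[!grepl("^reject_", joined$category)]))
})
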