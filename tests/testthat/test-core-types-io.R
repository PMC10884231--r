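test_that("read_candidates joins FASTA records with their evidence rows", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "cand.fasta")
  writeLines(c(
    ">IGHV1-2*01", "ACGTACGT",
    ">IGHV1-3*01", "ACGTACGA",
    ">IGHV2-5*01", "TTGTACGA"
  ), fasta)
  ev <- tibble::tibble(
    sequence_name = c("IGHV1-2*01", "IGHV1-2*01", "IGHV1-3*01",
                      "IGHV1-3*01", "IGHV2-5*01"),
    kind = c("genomic_study", "genomic_study", "genomic_study",
             "iarc_affirmation", "genbank_unrearranged"),
    study_id = paste0("s", 1:5),
    laboratory = c("a", "b", "a", NA, NA),
    n_individuals = c(1L, 1L, 1L, 1L, 1L),
    mapped_locus = NA_character_,
    accession = c(NA, NA, NA, NA, "GB1")
  )
  evp <- file.path(dir, "evidence.tsv")
  readr::write_tsv(ev, evp)

  cand <- read_candidates(fasta, evp)
  expect_equal(cand$name, c("IGHV1-2*01", "IGHV1-3*01", "IGHV2-5*01"))
  expect_equal(purrr::map_int(cand$evidence, nrow), c(2L, 2L, 1L))
  expect_equal(cand$chain, c("IGH-V", "IGH-V", "IGH-V"))

  # no evidence table: empty evidence lists
  cand0 <- read_candidates(fasta, NULL)
  expect_true(all(purrr::map_int(cand0$evidence, nrow) == 0L))

  # evidence row naming an absent sequence is a hard error naming the row
  bad <- dplyr::bind_rows(ev, dplyr::mutate(ev[1, ], sequence_name = "IGHX9-9*01"))
  readr::write_tsv(bad, evp)
  expect_error(read_candidates(fasta, evp), "IGHX9-9\\*01")
})

test_that("reference set FASTA/JSON round-trips losslessly with annotated headers", {
  set.seed(5)
  entries <- toy_entries(
    sprintf("IGHV1-%d*01", 1:10),
    replicate(10, igrefset:::rand_dna(60))
  )
  entries$paralogs[[1]] <- "IGHV1-69D*01"
  entries$aliases[[2]] <- "IGHV1-old*01"
  entries$extended_3p[3] <- 2L
  entries$sequence[3] <- paste0(entries$sequence[3], "GA")
  entries$extension_donor[3] <- "genomic"
  entries$locus <- sprintf("locus%02d", 1:10)
  entries$representative_accession[4] <- "AC000123"

  dir <- withr::local_tempdir()
  fa <- file.path(dir, "set.fasta"); js <- file.path(dir, "set.json")
  nt <- file.path(dir, "notes.txt")
  summary <- write_reference_set(entries, "v9", fa, js, nt)
  expect_equal(summary$n_entries, 10L)

  headers <- grep("^>", readLines(fa), value = TRUE)
  expect_true(any(grepl("IGHV1-1\\*01\\|paralog=IGHV1-69D\\*01", headers)))
  expect_true(any(grepl("alias=IGHV1-old\\*01", headers)))

  back <- read_reference_set(js)
  expect_equal(back$version_label, "v9")
  expect_equal(back$entries, entries)

  notes <- readLines(nt)
  extended_block <- notes[(which(notes == "extended:") + 1):(which(notes == "") [2] - 1)]
  expect_length(grep("IGHV1-3\\*01", extended_block), 1L)
  expect_length(grep("\\+2 nt 3'", extended_block), 1L)
  group_block <- notes[(which(notes == "collapsed paralog groups:") + 1):length(notes)]
  expect_length(grep("IGHV1-1\\*01 = IGHV1-69D\\*01", group_block), 1L)
  # exactly the one extended entry and the one group are listed
  expect_length(extended_block, 1L)
  expect_length(group_block, 1L)

  expect_error(
    write_reference_set(dplyr::bind_rows(entries, entries[1, ]), "dup"),
    "duplicate"
  )
})

test_that("entry invariants are enforced", {
  e <- toy_entries("IGHV1-1*01", "ACGT")
  e$extended_3p <- 1L  # flag without donor
  expect_error(igrefset:::validate_entries(e), "extension_donor")
  e2 <- toy_entries(c("IGHV1-1*01", "IGHV1-2*01"), c("ACGT", "ACGG"))
  e2$paralogs[[1]] <- "IGHV1-2*01"  # paralog alias also standalone
  expect_error(igrefset:::validate_entries(e2), "standalone")
})

test_that("curation_config validates its invariants", {
  expect_error(curation_config(haplotype_purity = 0.4), "purity")
  expect_error(curation_config(proximal_freq_hi = 0.5, distal_freq_lo = 0.6),
               "frequency bands")
  expect_error(curation_config(major_truncation_nt = 2), "exceed")
  cfg <- curation_config(seed = 7)
  expect_s3_class(cfg, "curation_config")
  expect_identical(cfg$min_independent_reports, 2L)
})

test_that("rearrangement tables round-trip with defaults filled in", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rearr.tsv")
  readr::write_tsv(tibble::tibble(
    sequence_id = c("r1", "r2"), individual_id = "I1",
    v_call = c("IGKV1-11*01", "IGKV1-11*02"), j_call = "IGKJ2*01"
  ), p)
  rec <- read_rearrangements(p)
  expect_equal(rec$v_mutation_count, c(0L, 0L))
  expect_true(all(rec$productive))
  write_rearrangements(rec, p)
  expect_equal(read_rearrangements(p), rec)
  readr::write_tsv(tibble::tibble(sequence_id = "r1"), p)
  expect_error(read_rearrangements(p), "lacks column")
})
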