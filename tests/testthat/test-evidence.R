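cfg <- curation_config()

test_that("independence rules count reports as specified", {
  # two genomic studies, different laboratories -> confirmed, count 2
  two_labs <- count_independent_reports(
    make_evidence(genomic_item("labA"), genomic_item("labB")), cfg
  )
  expect_true(two_labs$confirmed)
  expect_equal(two_labs$independent_report_count, 2L)

  # same laboratory twice -> one report, not confirmed
  same_lab <- count_independent_reports(
    make_evidence(genomic_item("labA", study = "s1"),
                  genomic_item("labA", study = "s2")), cfg
  )
  expect_false(same_lab$confirmed)
  expect_equal(same_lab$independent_report_count, 1L)

  # single multi-individual genomic study confirms on its own
  multi <- count_independent_reports(
    make_evidence(genomic_item("labA", n = 5)), cfg
  )
  expect_true(multi$confirmed)
  expect_true(any(grepl("multi-individual", multi$rationale[[1]])))

  # AIRR inference without GenBank corroboration does not count
  airr_only <- count_independent_reports(make_evidence(airr_item(4)), cfg)
  expect_false(airr_only$confirmed)
  expect_equal(airr_only$independent_report_count, 0L)

  # AIRR inference with enough individuals plus GenBank counts as one report
  airr_gb <- count_independent_reports(
    make_evidence(genomic_item("labA"), airr_item(4), genbank_item()), cfg
  )
  expect_true(airr_gb$confirmed)
  expect_equal(airr_gb$independent_report_count, 2L)

  # a GenBank record alone is only a corroborator
  gb <- count_independent_reports(make_evidence(genbank_item()), cfg)
  expect_equal(gb$independent_report_count, 0L)

  # IARC affirmation counts as one report by default ...
  iarc <- count_independent_reports(make_evidence(iarc_item()), cfg)
  expect_false(iarc$confirmed)
  expect_equal(iarc$independent_report_count, 1L)
  # ... and confirms alone under the configurable alternative reading
  iarc2 <- count_independent_reports(
    make_evidence(iarc_item()), curation_config(iarc_auto_confirm = TRUE)
  )
  expect_true(iarc2$confirmed)
})

test_that("novel sequences need more individuals for single-study confirmation", {
  five <- make_evidence(genomic_item("labG", n = 5))
  six <- make_evidence(genomic_item("labG", n = 6))
  expect_true(count_independent_reports(five, cfg, novel = FALSE)$confirmed)
  expect_false(count_independent_reports(five, cfg, novel = TRUE)$confirmed)
  expect_true(count_independent_reports(six, cfg, novel = TRUE)$confirmed)
})

test_that("IGHD expression admissibility enforces the central-nucleotide rules", {
  expect_true(d_expression_admissible(17, 8))
  expect_false(d_expression_admissible(17, 16))          # terminal nucleotide
  expect_false(d_expression_admissible(17, c(8, 16)))    # every position must be central
  expect_false(d_expression_admissible(17, 8, identical_pair_member = TRUE))
  expect_false(d_expression_admissible(17, integer(0)))  # nothing confirmable
  expect_false(d_expression_admissible(7, 3))            # too short (IGHD7-27-like)
})

test_that("build_source_set splits confirmed entries from the audit list", {
  set.seed(1)
  seqs <- replicate(10, igrefset:::rand_dna(20))
  cand <- igrefset:::as_candidates(
    tibble::tibble(name = sprintf("IGHJ%d*01", 1:10), sequence = seqs),
    NULL
  )
  cand$evidence <- c(
    replicate(7, make_evidence(genomic_item("labA"), genomic_item("labB")),
              simplify = FALSE),
    replicate(3, make_evidence(genomic_item("labA")), simplify = FALSE)
  )
  verdicts <- structural_filter(cand)
  src <- build_source_set(cand, verdicts, cfg)
  expect_equal(nrow(src$source_set), 7L)
  expect_equal(nrow(src$unconfirmed), 3L)
  # audit list and Source Set partition the structurally passing candidates
  expect_setequal(c(src$source_set$name, src$unconfirmed$candidate_name),
                  cand$name)
  # determinism
  src2 <- build_source_set(cand, verdicts, cfg)
  expect_equal(src2$source_set, src$source_set)
})

test_that("confirmation is monotone under added evidence", {
  set.seed(33)
  pool <- list(
    function() genomic_item(sample(c("labA", "labB", "labC"), 1),
                            n = sample(1:8, 1)),
    function() airr_item(sample(1:6, 1)),
    function() iarc_item(),
    function() genbank_item()
  )
  for (i in 1:60) {
    base <- dplyr::bind_rows(lapply(
      sample(pool, sample(1:4, 1), replace = TRUE), function(f) f()
    ))
    extra <- pool[[sample(length(pool), 1)]]()
    before <- count_independent_reports(base, cfg)
    after <- count_independent_reports(dplyr::bind_rows(base, extra), cfg)
    expect_false(before$confirmed && !after$confirmed)
    expect_gte(after$independent_report_count,
               before$independent_report_count)
  }
})

test_that("the D fixture's terminal-only variant is inadmissible and unconfirmed", {
  fx <- candidate_fixture("IGHD", seed = 1)
  verdicts <- structural_filter(fx$candidates)
  src <- build_source_set(fx$candidates, verdicts, cfg)
  expect_equal(src$unconfirmed$candidate_name, "IGHD2-2*03")
  expect_true(any(grepl("inadmissible",
                        unlist(src$confirmation$rationale[
                          src$confirmation$candidate_name == "IGHD2-2*03"]))))
})
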