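fx <- gen_genome_fixture(seed = 42)

test_that("filtration cascade reproduces the planted audit exactly", {
  fl <- filter_candidates(fx$probes, fx$transcripts, fx$protein_exons,
                          coding_calls = fx$coding_calls)
  got <- fl$audits[match(fx$expected$probe_set_id, fl$audits$probe_set_id), ]
  expect_equal(got$outcome, fx$expected$outcome)
  # every planted reason is present as the first (primary) reason
  primary <- vapply(strsplit(got$reasons, ","), function(r)
    if (length(r)) r[1] else "", character(1))
  expect_equal(primary, fx$expected$reasons)
  # audit completeness: retained + excluded = input, excluded have reasons
  expect_equal(nrow(fl$audits), nrow(fx$probes))
  expect_true(all(nzchar(fl$audits$reasons[fl$audits$outcome ==
                                             "excluded"])))
  expect_true(all(fl$audits$reasons[fl$audits$outcome == "retained"] ==
                    ""))
})

test_that("antisense overlap of protein exons survives the cascade", {
  fl <- filter_candidates(fx$probes, fx$transcripts, fx$protein_exons,
                          coding_calls = fx$coding_calls)
  expect_true("ps_anti" %in% fl$candidates$probe_set_id)
  # flipping the antisense probe onto the protein strand must exclude it
  probes2 <- fx$probes
  i <- which(probes2$probe_set_id == "ps_anti")
  probes2$placements[[i]]$strand <- "+"
  fl2 <- filter_candidates(probes2, fx$transcripts, fx$protein_exons,
                           coding_calls = fx$coding_calls)
  expect_false("ps_anti" %in% fl2$candidates$probe_set_id)
})

test_that("re-filtering the retained set is a no-op and order does not matter", {
  fl <- filter_candidates(fx$probes, fx$transcripts, fx$protein_exons,
                          coding_calls = fx$coding_calls)
  keep <- fx$probes[fx$probes$probe_set_id %in%
                      fl$candidates$probe_set_id, ]
  class(keep) <- class(fx$probes)
  fl2 <- filter_candidates(keep, fx$transcripts, fx$protein_exons,
                           coding_calls = fx$coding_calls)
  expect_equal(fl2$candidates$probe_set_id, fl$candidates$probe_set_id)
  expect_true(all(fl2$audits$outcome == "retained"))

  perm <- fx$probes[rev(seq_len(nrow(fx$probes))), ]
  class(perm) <- class(fx$probes)
  fl3 <- filter_candidates(perm, fx$transcripts, fx$protein_exons,
                           coding_calls = fx$coding_calls)
  m <- match(fl$audits$probe_set_id, fl3$audits$probe_set_id)
  expect_equal(fl3$audits$outcome[m], fl$audits$outcome)
})

test_that("dangling transcript references are rejected", {
  probes <- probe_mapping("p1",
                          data.frame(chrom = "chr1", start = 0L,
                                     end = 100L, strand = "+"),
                          target_transcript_id = "ghost")
  expect_error(filter_candidates(probes, fx$transcripts, fx$protein_exons),
               "dangling.*ghost")
})

test_that("ORF heuristic calls coding potential sensibly", {
  # no ATG anywhere: noncoding
  expect_equal(coding_potential(sequence = strrep("C", 300)), "noncoding")
  # external evidence overrides the heuristic
  expect_equal(coding_potential(sequence = strrep("C", 300),
                                external_call = "coding"), "coding")
  # a long clean ORF: ATG + 120 leucine codons + stop covers 100% of seq
  orf_seq <- paste0("ATG", strrep("CTG", 120), "TAA")
  expect_equal(coding_potential(sequence = orf_seq), "coding")
  # same ORF diluted below 30% coverage of the transcript
  diluted <- paste0(orf_seq, strrep("C", 3 * nchar(orf_seq)))
  expect_equal(coding_potential(sequence = diluted), "noncoding")
  # ORF below 100 codons
  short_orf <- paste0("ATG", strrep("CTG", 50), "TAA")
  expect_equal(coding_potential(sequence = short_orf), "noncoding")
  expect_error(coding_potential(sequence = "ACGTXX"), "non-IUPAC")
})

test_that("random sequences are rarely called coding", {
  # Null rate measured by simulation: with uniform base composition a
  # 1,000 nt sequence carries an ORF of >= 100 codons (each non-stop codon
  # has probability 61/64) often enough that ~5-10% of random sequences
  # pass the default thresholds; the bound below reflects that measured
  # null distribution.
  set.seed(99)
  calls <- replicate(1000, {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    coding_potential(sequence = s)
  })
  expect_gte(mean(calls == "noncoding"), 0.9)
  # stricter thresholds push the null rate below 1%
  calls2 <- replicate(300, {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    coding_potential(sequence = s, min_codons = 150, min_coverage = 0.45)
  })
  expect_gte(mean(calls2 == "noncoding"), 0.99)
})

test_that("reference matching requires a unique hit", {
  fl <- filter_candidates(fx$probes, fx$transcripts, fx$protein_exons,
                          coding_calls = fx$coding_calls)
  # geometric path: only ps_clean sits inside a reference transcript
  cand <- match_reference(fl$candidates, fx$reference, probes = fx$probes)
  expect_equal(cand$high_confidence,
               cand$probe_set_id == "ps_clean")

  # alignment-table path: two hits mean not unique, one hit means unique
  ref2 <- transcript_table(c("refA", "refB"), chrom = "chr1",
                           start = c(0L, 5000L), end = c(1000L, 6000L),
                           strand = "+", biotype = "annotated_ncRNA")
  at <- data.frame(probe_set_id = c("ps_clean", "ps_clean", "ps_anti"),
                   reference_id = c("refA", "refB", "refA"))
  cand2 <- match_reference(fl$candidates, ref2, alignment_table = at)
  expect_false(cand2$high_confidence[cand2$probe_set_id == "ps_clean"])
  expect_true(cand2$high_confidence[cand2$probe_set_id == "ps_anti"])

  # empty reference: all false
  cand3 <- match_reference(fl$candidates, ref2[0, ], probes = fx$probes)
  expect_true(all(!cand3$high_confidence))

  expect_error(
    match_reference(fl$candidates, ref2,
                    alignment_table = data.frame(probe_set_id = "ps_clean",
                                                 reference_id = "nope")),
    "unknown ids")
})
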