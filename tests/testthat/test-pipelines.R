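test_that("annotation pipeline reproduces the planted tables end to end", {
  fx <- gen_genome_fixture(seed = 71)
  out <- suppressMessages(run_annotation_pipeline(
    probes = fx$probes, transcripts = fx$transcripts,
    protein_exons = fx$protein_exons, coding_calls = fx$coding_calls,
    reference = fx$reference))
  m <- match(fx$expected$probe_set_id, out$audits$probe_set_id)
  expect_equal(out$audits$outcome[m], fx$expected$outcome)
  retained <- fx$expected$probe_set_id[fx$expected$outcome == "retained"]
  expect_setequal(out$candidates$probe_set_id, retained)
  hc <- fx$expected$high_confidence[match(out$candidates$probe_set_id,
                                          fx$expected$probe_set_id)]
  expect_equal(out$candidates$high_confidence, hc)
  # too few candidates for a length fit: skipped, not an error
  expect_null(out$fit)
})

test_that("annotation pipeline wires neighbors and enrichment", {
  fx <- gen_genome_fixture(seed = 72)
  # place a protein gene right next to the retained antisense lncRNA
  tm <- term_mapping(list(go_near = c("g_prot", "g_sense"),
                          go_far = c("g_far1", "g_far2")),
                     universe = c("g_prot", "g_sense", "g_far1", "g_far2",
                                  "g_anti_nb"))
  out <- suppressMessages(run_annotation_pipeline(
    probes = fx$probes, transcripts = fx$transcripts,
    protein_exons = fx$protein_exons, coding_calls = fx$coding_calls,
    mapping = tm))
  # the only protein_coding transcript is tx_prot (g_prot); neighbors are
  # those candidates within 10 kb of it (none in this sparse layout)
  expect_true(is.data.frame(out$neighbors))
})

test_that("empty probe input yields empty outputs with a warning", {
  fx <- gen_genome_fixture(seed = 73)
  empty <- fx$probes[0, ]
  expect_warning(
    out <- suppressMessages(run_annotation_pipeline(
      probes = empty, transcripts = fx$transcripts,
      protein_exons = fx$protein_exons)),
    "empty")
  expect_equal(nrow(out$candidates), 0L)
})

test_that("pipeline reruns with the same config are byte-identical", {
  fx <- gen_genome_fixture(seed = 74)
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- default_config()
  for (d in c(d1, d2))
    suppressMessages(run_annotation_pipeline(
      config = cfg, probes = fx$probes, transcripts = fx$transcripts,
      protein_exons = fx$protein_exons, coding_calls = fx$coding_calls,
      reference = fx$reference, outdir = d))
  for (f in c("candidates.tsv", "audits.tsv", "neighbors.tsv",
              "manifest.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("biomarker pipeline trains a signature on a planted cohort", {
  g <- gen_cohort(cohort_gen_spec(n_patients = 60, n_probes = 200,
                                  n_informative = 20,
                                  effect_per_stage = 2, noise_sd = 1),
                  seed = 75)
  ev <- gen_cohort(cohort_gen_spec(n_patients = 40, n_probes = 200,
                                   n_informative = 20,
                                   effect_per_stage = 2, noise_sd = 1),
                   seed = 76)
  outdir <- tempfile()
  out <- suppressMessages(run_biomarker_pipeline(
    cohort = g$cohort, eval_cohort = ev$cohort, outdir = outdir))
  expect_gt(sum(out$screen$selected), 10)
  expect_gt(out$fit$cv_accuracy, 0.7)   # well above the 50% chance level
  expect_true(!is.null(out$clusters))
  expect_true(is.numeric(out$evaluation$accuracy))
  expect_true(file.exists(file.path(outdir, "screen.tsv")))
  expect_true(file.exists(file.path(outdir, "manifest.yaml")))

  # evaluation cohort absent: step skipped, with a log notice
  msgs <- capture.output(
    out2 <- run_biomarker_pipeline(cohort = g$cohort), type = "message")
  expect_true(any(grepl("skipped", msgs)))
  expect_null(out2$evaluation)
})

test_that("non-MNA restriction reaches the trained signature", {
  g <- gen_cohort(cohort_gen_spec(n_patients = 80, n_probes = 150,
                                  n_informative = 15,
                                  effect_per_stage = 2, noise_sd = 1),
                  seed = 77)
  cfg <- default_config()
  cfg$restrict <- "non_mna"
  out <- suppressMessages(run_biomarker_pipeline(cfg, cohort = g$cohort))
  n_nonmna <- sum(!g$cohort$metadata$mycn_amplified)
  expect_equal(attr(out$screen, "n_early") + attr(out$screen, "n_late"),
               n_nonmna)
})
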