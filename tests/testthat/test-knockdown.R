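test_that("triple-criterion caller recovers planted sets exactly", {
  kd <- gen_knockdown(n_probes = 400, de_up = 20, de_down = 25,
                      effect_log2 = 1, seed = 51)
  for (fc in c(1.3, 1.4)) {
    de <- call_de(kd$cohort, fc_min = fc)
    expect_setequal(de$consensus$probe_id, c(kd$up, kd$down))
    cons_dir <- de$consensus$direction[match(c(kd$up, kd$down),
                                             de$consensus$probe_id)]
    expect_equal(cons_dir, c(rep("up", 20), rep("down", 25)))
  }
  # consensus is contained in both per-condition pass lists
  de <- call_de(kd$cohort)
  for (cd in c("siRNA_1", "siRNA_2")) {
    pc <- de$per_condition[de$per_condition$condition == cd, ]
    expect_true(all(de$consensus$probe_id %in% pc$probe_id[pc$passes]))
  }
})

test_that("each criterion is enforced individually", {
  kd <- gen_knockdown(n_probes = 50, de_up = 0, de_down = 0,
                      noise_sd = 0.05, seed = 52)
  v <- kd$cohort$values
  cond <- kd$cohort$metadata$condition
  # a probe at fold change ~1.35 in both conditions: passes at 1.3, not 1.4
  v["probe_0001", cond != "control"] <-
    v["probe_0001", cond != "control"] + log2(1.35)
  # a probe shifted strongly in siRNA_1 only
  v["probe_0002", cond == "siRNA_1"] <-
    v["probe_0002", cond == "siRNA_1"] + 2
  ch <- cohort_matrix(v, kd$cohort$metadata)
  de13 <- call_de(ch, fc_min = 1.3)
  de14 <- call_de(ch, fc_min = 1.4)
  expect_true("probe_0001" %in% de13$consensus$probe_id)
  expect_false("probe_0001" %in% de14$consensus$probe_id)
  p1 <- de14$per_condition[de14$per_condition$probe_id == "probe_0001", ]
  expect_true(all(!p1$passes))          # fails criterion 2 only
  expect_true(all(p1$p_t < 0.05))
  expect_true(all(p1$reps_beyond_control >= 3))
  expect_false("probe_0002" %in% de13$consensus$probe_id)

  expect_error(call_de(subset_cohort(ch,
    samples = ch$metadata$sample_id[cond != "siRNA_2"])),
    "siRNA_2")
})

test_that("raising the thresholds never enlarges the consensus", {
  kd <- gen_knockdown(n_probes = 300, de_up = 15, de_down = 15,
                      effect_log2 = 0.6, noise_sd = 0.3, seed = 53)
  base <- call_de(kd$cohort, fc_min = 1.3, min_reps = 3)
  tighter_fc <- call_de(kd$cohort, fc_min = 1.4, min_reps = 3)
  tighter_reps <- call_de(kd$cohort, fc_min = 1.3, min_reps = 4)
  expect_true(all(tighter_fc$consensus$probe_id %in%
                    base$consensus$probe_id))
  expect_true(all(tighter_reps$consensus$probe_id %in%
                    base$consensus$probe_id))
})

test_that("null knock-down fixtures yield (almost) no consensus calls", {
  sizes <- sapply(54:58, function(s)
    nrow(call_de(gen_knockdown(n_probes = 500, de_up = 0, de_down = 0,
                               seed = s)$cohort)$consensus))
  # expectation is bounded by n * p_de^2 under cross-condition independence
  expect_true(all(sizes <= 3))
  expect_lte(mean(sizes), 500 * 0.05^2)
})

test_that("target correlation flags monotone dependence with correct sign", {
  g <- gen_cohort(cohort_gen_spec(n_patients = 50, n_probes = 40,
                                  n_informative = 0), seed = 61)
  v <- g$cohort$values
  anchor <- v["probe_0001", ]
  v["probe_0002", ] <- anchor + rnorm(50, sd = 0.3)   # positive target
  v["probe_0003", ] <- -2 * anchor + rnorm(50, sd = 0.3) # negative target
  ch <- cohort_matrix(v, g$cohort$metadata)
  res <- correlate_targets(ch, "probe_0001",
                           c("probe_0001", "probe_0002", "probe_0003",
                             "probe_0004"))
  expect_equal(res$tau[1], 1)
  expect_true(res$significant[1])
  expect_true(res$significant[2] && res$sign[2] == 1)
  expect_true(res$significant[3] && res$sign[3] == -1)

  # independent targets are significant at about the nominal rate
  set.seed(62)
  hits <- replicate(200, {
    y <- rnorm(50)
    kt <- suppressWarnings(cor.test(anchor, y, method = "kendall",
                                    exact = FALSE))
    kt$p.value < 0.05
  })
  expect_lt(mean(hits), 0.1)
  expect_error(correlate_targets(
    cohort_matrix(rbind(v, const = rep(1, 50)), g$cohort$metadata),
    "const", "probe_0002"), "constant")
})

test_that("binary outcome markers are detected and nulls behave", {
  g <- gen_cohort(cohort_gen_spec(n_patients = 100, n_probes = 30,
                                  n_informative = 0, noise_sd = 1),
                  seed = 63)
  v <- g$cohort$values
  outcome <- rep(c(TRUE, FALSE), each = 50)
  v["probe_0001", outcome] <- v["probe_0001", outcome] + 3  # 3 x noise
  ch <- cohort_matrix(v, g$cohort$metadata)
  res <- binary_marker_test(ch, outcome)
  expect_true(res$significant[res$probe_id == "probe_0001"])
  expect_true(all(res$q >= res$p))
  # null probes: roughly the nominal false-positive rate
  expect_lte(sum(res$significant[-1]), 5)
  expect_error(binary_marker_test(ch, rep(TRUE, 100)), "non-empty")
})
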