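test_that("Mann-Whitney exact path matches full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2 extreme of the 20 arrangements
  # identical multisets: p = 1 on the approximate path
  expect_equal(mann_whitney(c(1, 2, 2), c(2, 1, 2))$p, 1)
  # random untied inputs across all small size splits
  set.seed(2)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      x <- sample(seq(1, 100), n1)
      y <- sample(setdiff(seq(1, 100), x), n2)
      expect_equal(mann_whitney(x, y)$p, oracle_mw_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("pooled t-test matches hand computation and conventions", {
  tt <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4L)
  expect_equal(students_t(c(0, 0), c(0, 0))$p, 1)
  expect_equal(students_t(c(1, 2), c(1, 2))$p, 1)
  expect_equal(students_t(c(1, 1), c(2, 2))$p, 0)
  expect_error(students_t(1, c(1, 2)), ">= 2")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.07), 0.07)    # m = 1: q = p
  set.seed(3)
  p <- runif(40)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kendall tau-b matches pair counting with ties", {
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3)
  set.seed(4)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    y <- sample(1:4, n, replace = TRUE)   # heavy ties, like stages
    expect_equal(kendall_tau(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(-x, y), -kendall_tau(x, y))
  }
  expect_true(is.na(kendall_tau(rnorm(5), rep(2, 5))))
})

test_that("stage screen recovers planted markers and controls nulls", {
  g <- gen_cohort(cohort_gen_spec(n_patients = 60, n_probes = 300,
                                  n_informative = 30,
                                  effect_per_stage = 2, noise_sd = 1),
                  seed = 11)
  s <- screen_stage_markers(g$cohort)
  expect_s3_class(s, "ScreenResult")
  expect_true(all(s$q_mw >= s$p_mw))
  expect_true(all(s$selected == (s$pass_discrimination & s$pass_tau)))
  recovered <- mean(g$markers$probe_id %in% s$probe_id[s$selected])
  expect_gte(recovered, 0.9)
  # planted signs agree with the tau signs of the recovered markers
  m <- match(g$markers$probe_id, s$probe_id)
  expect_true(all(sign(s$tau[m]) == sign(g$markers$slope)))

  g0 <- gen_cohort(cohort_gen_spec(n_patients = 60, n_probes = 300,
                                   n_informative = 0), seed = 12)
  s0 <- screen_stage_markers(g0$cohort)
  expect_lte(sum(s0$selected), 2)

  # non-MNA restriction drops the amplified samples
  s_nm <- screen_stage_markers(g$cohort, restrict = "non_mna")
  n_nonmna <- sum(!g$cohort$metadata$mycn_amplified)
  expect_equal(attr(s_nm, "n_early") + attr(s_nm, "n_late"), n_nonmna)

  only_early <- g$cohort$metadata$sample_id[g$cohort$metadata$stage == 1]
  few <- subset_cohort(g$cohort, samples = only_early)
  expect_error(screen_stage_markers(few), "3 samples")
})

test_that("NSC with delta = 0 equals the unshrunken nearest-centroid rule", {
  set.seed(21)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:n)))
  x[1, y == "b"] <- x[1, y == "b"] + 4
  fit <- nsc_train(cohort_matrix(x), y, delta_grid = 0, folds = 5,
                   seed = 1)
  pred <- nsc_predict(fit$model, cohort_matrix(x))
  expect_equal(pred$class, oracle_nearest_centroid(x, y, x))
  expect_setequal(fit$model$surviving_features, rownames(x))
})

test_that("NSC shrinkage selects the informative feature and is monotone", {
  set.seed(22)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:n)))
  x[1, y == "b"] <- x[1, y == "b"] + 4   # 4 x noise separation
  fit <- nsc_train(cohort_matrix(x), y,
                   delta_grid = seq(0, 6, length.out = 80), folds = 5,
                   seed = 2)
  expect_true("f01" %in% fit$model$surviving_features)
  expect_gte(fit$cv_accuracy, 0.9)
  # surviving-feature count is non-increasing across the grid
  expect_true(all(diff(fit$report$n_features) <= 0))
  # total shrinkage: every prediction is the prior-maximizing class
  dmax <- max(abs(fit$model$d))
  full <- nsc_train(cohort_matrix(x), y, delta_grid = dmax + 1, folds = 5,
                    seed = 3)
  expect_length(full$model$surviving_features, 0)
  pred <- nsc_predict(full$model, cohort_matrix(x))
  expect_true(all(pred$class ==
                    full$model$classes[which.max(full$model$priors)]))
})

test_that("NSC predicts a class centroid as that class and checks features", {
  set.seed(23)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:30)))
  y <- rep(c("a", "b"), each = 15)
  x[1:5, y == "b"] <- x[1:5, y == "b"] + 3
  fit <- nsc_train(cohort_matrix(x), y, delta_grid = c(0, 0.5), folds = 5,
                   seed = 4)
  cent <- matrix(fit$model$shrunken_centroids[, "b"], ncol = 1,
                 dimnames = list(fit$model$feature_ids, "c1"))
  expect_equal(nsc_predict(fit$model, cohort_matrix(cent))$class, "b")
  expect_error(nsc_predict(fit$model,
                           cohort_matrix(cent[-1, , drop = FALSE])),
               "f1")
})

test_that("training-set resubstitution beats held-out accuracy on average", {
  accs <- sapply(31:34, function(s) {
    set.seed(s)
    n <- 30
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(40 * n), 40, n,
                dimnames = list(sprintf("f%d", 1:40), sprintf("s%d",
                                                              1:n)))
    x[1:3, y == "b"] <- x[1:3, y == "b"] + 1.5
    fit <- nsc_train(cohort_matrix(x), y, delta_grid = c(0, 1, 2),
                     folds = 5, seed = s)
    resub <- mean(nsc_predict(fit$model, cohort_matrix(x))$class == y)
    c(resub = resub, cv = fit$cv_accuracy)
  })
  expect_gte(mean(accs["resub", ] - accs["cv", ]), 0)
})

test_that("signature clustering recovers anti-correlated probe blocks", {
  set.seed(41)
  n <- 30
  base <- rnorm(n)
  up <- t(sapply(1:6, function(i) base + rnorm(n, sd = 0.2)))
  dn <- t(sapply(1:5, function(i) -base + rnorm(n, sd = 0.2)))
  v <- rbind(up, dn)
  dimnames(v) <- list(c(sprintf("up%d", 1:6), sprintf("dn%d", 1:5)),
                      sprintf("s%d", 1:n))
  cl <- cluster_signature(cohort_matrix(v))
  expect_equal(length(unique(cl$clusters[1:6])), 1L)
  expect_equal(length(unique(cl$clusters[7:11])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[7])
  # tau matrix is symmetric with unit diagonal
  expect_equal(cl$tau, t(cl$tau))
  expect_equal(unname(diag(cl$tau)), rep(1, 11))
  # constant probe: distances maxed out, still returns a 2-cut
  v2 <- rbind(v, const = rep(5, n))
  cl2 <- suppressMessages(cluster_signature(cohort_matrix(v2)))
  expect_equal(sort(unique(cl2$clusters)), c(1L, 2L))
  expect_error(cluster_signature(cohort_matrix(v[1:2, ])), "3 probes")
})
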