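# The clinical screening cascade: per-probe two-test stage discrimination
# with BH FDR reported alongside, a Kendall tau-b stage-correlation filter,
# a nearest-shrunken-centroid (NSC/PAM) signature with stratified
# cross-validation, and correlation-structure clustering of the signature.

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration p-value when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Thin wrapper over [stats::wilcox.test()]
#' selecting the path per that rule.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `U` (statistic for `x`) and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pooled-variance two-sample t-test (two-sided)
#'
#' Student's t with `n1 + n2 - 2` degrees of freedom. Degenerate inputs
#' follow a documented convention: zero pooled variance with equal means
#' gives `t = 0, p = 1`; zero pooled variance with unequal means gives
#' `p = 0`.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return list with `t`, `p`, `df`.
#' @export
students_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  df <- length(x) + length(y) - 2L
  sp2 <- ((length(x) - 1) * stats::var(x) +
          (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = df)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (wraps
#'   [stats::p.adjust()]`(method = "BH")` after a domain check).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Kendall tau-b rank correlation
#'
#' Tie-corrected on both variables. Undefined (returns `NA`) when either
#' variable is constant.
#'
#' @param values,stages numeric vectors of equal length (>= 2).
#' @return tau-b, or `NA` if undefined.
#' @export
kendall_tau <- function(values, stages) {
  if (length(values) != length(stages) || length(values) < 2L)
    stop("need two equal-length vectors with >= 2 samples")
  if (length(unique(values)) < 2L || length(unique(stages)) < 2L)
    return(NA_real_)
  stats::cor(values, stages, method = "kendall")
}

# tau-b plus its normal-approximation p-value.
kendall_tau_test <- function(x, y) {
  tau <- kendall_tau(x, y)
  if (is.na(tau)) return(list(tau = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE)
  )
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Screen a cohort for stage-associated probes
#'
#' The primary marker screen: for every probe, a two-sided Mann-Whitney U
#' test and a pooled-variance t-test of early-stage (1-2) vs late-stage
#' (3-4) samples, BH q-values over all tested probes, and Kendall tau-b of
#' expression against ordinal stage over all restricted samples. A probe is
#' selected when both test p-values pass `p_screen` (raw by default; set
#' `cut_on = "q"` to cut on the BH-adjusted values) and `|tau| > tau_min`.
#'
#' Stage-4s samples are excluded by default (prognostically anomalous and
#' not ordinally comparable); `restrict = "non_mna"` additionally keeps only
#' samples with `mycn_amplified == FALSE`.
#'
#' @param cohort a [cohort_matrix()] with stage metadata.
#' @param early,late stage sets defining the two groups.
#' @param p_screen per-test p cutoff (default 0.001).
#' @param tau_min Kendall |tau| floor (default 0.25, strict inequality).
#' @param restrict `"all"` or `"non_mna"`.
#' @param cut_on `"raw"` or `"q"`: which p enters the `p_screen` cut.
#' @param include_4s include stage-4s samples as stage 4.
#' @return data.frame of class `"ScreenResult"`: per probe `p_mw`, `p_t`,
#'   `q_mw`, `q_t`, `tau`, `pass_discrimination`, `pass_tau`, `selected`;
#'   sample counts in attributes `n_early`/`n_late`.
#' @export
screen_stage_markers <- function(cohort, early = c(1, 2), late = c(3, 4),
                                 p_screen = 0.001, tau_min = 0.25,
                                 restrict = c("all", "non_mna"),
                                 cut_on = c("raw", "q"),
                                 include_4s = FALSE) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  restrict <- match.arg(restrict)
  cut_on <- match.arg(cut_on)
  md <- cohort$metadata
  keep <- !is.na(md$stage)
  if (!include_4s) keep <- keep & !(md$stage_4s %in% TRUE)
  if (restrict == "non_mna") keep <- keep & (md$mycn_amplified %in% FALSE)
  md <- md[keep, , drop = FALSE]
  v <- cohort$values[, md$sample_id, drop = FALSE]
  is_early <- md$stage %in% early
  is_late <- md$stage %in% late
  if (sum(is_early) < 3L || sum(is_late) < 3L)
    stop("need at least 3 samples per stage group after restriction")

  np <- nrow(v)
  p_mw <- p_t <- tau <- numeric(np)
  for (i in seq_len(np)) {
    p_mw[i] <- mann_whitney(v[i, is_early], v[i, is_late])$p
    p_t[i] <- students_t(v[i, is_early], v[i, is_late])$p
    tau[i] <- kendall_tau(v[i, is_early | is_late],
                          md$stage[is_early | is_late])
  }
  q_mw <- bh_fdr(p_mw)
  q_t <- bh_fdr(p_t)
  cut_mw <- if (cut_on == "raw") p_mw else q_mw
  cut_t <- if (cut_on == "raw") p_t else q_t
  res <- data.frame(
    probe_id = rownames(v),
    p_mw = p_mw, p_t = p_t, q_mw = q_mw, q_t = q_t, tau = tau,
    pass_discrimination = cut_mw < p_screen & cut_t < p_screen,
    pass_tau = !is.na(tau) & abs(tau) > tau_min,
    stringsAsFactors = FALSE
  )
  res$selected <- res$pass_discrimination & res$pass_tau
  attr(res, "n_early") <- sum(is_early)
  attr(res, "n_late") <- sum(is_late)
  class(res) <- c("ScreenResult", "data.frame")
  res
}

# ---- nearest shrunken centroids (PAM) ------------------------------------

# Unshrunken statistics from a features x samples matrix and a class factor.
nsc_stats <- function(values, y) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes")
  n <- ncol(values)
  nk <- table(y)
  overall <- rowMeans(values)
  centroids <- vapply(classes, function(k)
    rowMeans(values[, y == k, drop = FALSE]), numeric(nrow(values)))
  ss <- 0
  for (k in classes) {
    vk <- values[, y == k, drop = FALSE]
    ss <- ss + rowSums((vk - centroids[, k])^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(mk) <- classes
  d <- sweep(centroids - overall, 2, mk, "/") / (s + s0)
  list(classes = classes, priors = as.numeric(nk) / n, overall = overall,
       centroids = centroids, s = s, s0 = s0, mk = mk, d = d)
}

# Soft-threshold the standardized differences and rebuild centroids.
nsc_shrink <- function(st, delta) {
  dshr <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  shrunken <- st$overall +
    sweep(dshr, 2, st$mk, "*") * (st$s + st$s0)
  list(dshr = dshr, shrunken = shrunken,
       surviving = rowSums(dshr != 0) > 0)
}

nsc_discriminant <- function(st, shrunken, priors, x) {
  # x: features x samples; returns samples x classes score matrix
  vapply(seq_along(st$classes), function(k)
    colSums((x - shrunken[, k])^2 / (st$s + st$s0)^2) - 2 * log(priors[k]),
    numeric(ncol(x)))
}

nsc_classify <- function(st, shrunken, priors, x) {
  scores <- nsc_discriminant(st, shrunken, priors, x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  # argmin; ties broken by first class in label order
  st$classes[apply(scores, 1, which.min)]
}

#' Train a nearest-shrunken-centroid signature
#'
#' Implements the PAM classifier: per-feature standardized centroid
#' differences `d_ik = (centroid_ik - overall_i) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)` and fudge constant `s0 = median(s_i)`, soft-
#' thresholded by each `delta` in the grid. Stratified k-fold cross-
#' validation scores every delta; the chosen delta is the largest one whose
#' CV error count is within 1 of the minimum (parsimony rule). Deterministic
#' given `seed`.
#'
#' @param cohort a [cohort_matrix()] restricted to the screened probes.
#' @param labels class labels (factor/character), aligned with the cohort's
#'   samples or named by sample id.
#' @param delta_grid shrinkage thresholds; default 30 values from 0 to the
#'   largest `|d_ik|`.
#' @param folds number of CV folds (default 10, capped at the smallest
#'   class size).
#' @param seed integer seed for fold assignment.
#' @return list of class `"NSCFit"`: `model` (an `"NSCModel"`: statistics,
#'   chosen `delta`, shrunken centroids, `surviving_features`), `report`
#'   (per-delta data.frame `delta`, `n_features`, `cv_errors`,
#'   `cv_accuracy`), `chosen_delta`, `cv_accuracy`, `confusion` (held-out
#'   predictions at the chosen delta), and per-class `sensitivity` /
#'   `specificity`.
#' @export
nsc_train <- function(cohort, labels, delta_grid = NULL, folds = 10,
                      seed = 1) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  values <- cohort$values
  if (!is.null(names(labels)))
    labels <- labels[colnames(values)]
  y <- droplevels(as.factor(labels))
  if (length(y) != ncol(values)) stop("labels must match cohort samples")
  if (anyNA(y)) stop("missing class label")
  st <- nsc_stats(values, y)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30)
  if (length(delta_grid) == 0L) stop("delta_grid must be non-empty")
  delta_grid <- sort(delta_grid)

  folds <- min(folds, min(table(y)))
  if (folds < 2L) stop("need at least 2 samples in the smallest class")
  withr::local_seed(seed)
  fold_of <- integer(length(y))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }

  cv_pred <- vector("list", length(delta_grid))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    st_f <- nsc_stats(values[, !test, drop = FALSE], y[!test])
    for (di in seq_along(delta_grid)) {
      sh <- nsc_shrink(st_f, delta_grid[di])
      pred <- nsc_classify(st_f, sh$shrunken, st_f$priors,
                           values[, test, drop = FALSE])
      if (is.null(cv_pred[[di]])) cv_pred[[di]] <- character(length(y))
      cv_pred[[di]][test] <- pred
    }
  }
  errors <- vapply(cv_pred, function(p) sum(p != as.character(y)),
                   integer(1))
  n_features <- vapply(delta_grid, function(d)
    sum(nsc_shrink(st, d)$surviving), integer(1))
  report <- data.frame(delta = delta_grid, n_features = n_features,
                       cv_errors = errors,
                       cv_accuracy = 1 - errors / length(y))
  chosen <- max(delta_grid[errors <= min(errors) + 1L])
  sh <- nsc_shrink(st, chosen)
  model <- structure(
    list(feature_ids = rownames(values), classes = st$classes,
         priors = st$priors, overall_centroid = st$overall,
         class_centroids = st$centroids, pooled_sd = st$s, s0 = st$s0,
         mk = st$mk, d = st$d, delta = chosen,
         shrunken_centroids = sh$shrunken,
         surviving_features = rownames(values)[sh$surviving]),
    class = "NSCModel")

  chosen_pred <- cv_pred[[which(delta_grid == chosen)[1]]]
  confusion <- table(truth = y, predicted = factor(chosen_pred,
                                                   levels = st$classes))
  sens <- diag(confusion) / rowSums(confusion)
  spec <- vapply(seq_along(st$classes), function(k)
    sum(confusion[-k, -k]) / sum(confusion[-k, ]), numeric(1))
  names(spec) <- st$classes
  structure(list(model = model, report = report, chosen_delta = chosen,
                 cv_accuracy = 1 - sum(chosen_pred != as.character(y)) /
                   length(y),
                 confusion = confusion, sensitivity = sens,
                 specificity = spec),
            class = "NSCFit")
}

#' Predict classes with a trained NSC model
#'
#' Discriminant score per class:
#' `sum_i (x_i - shrunken centroid_ik)^2 / (s_i + s0)^2 - 2 log(prior_k)`;
#' the smallest score wins, ties going to the first class in label order.
#'
#' @param model an `"NSCModel"` from [nsc_train()].
#' @param cohort a [cohort_matrix()] containing all model features (a
#'   missing feature is an error naming it).
#' @return data.frame with `sample_id`, `class`, and one score column per
#'   class.
#' @export
nsc_predict <- function(model, cohort) {
  stopifnot(inherits(model, "NSCModel"), inherits(cohort, "CohortMatrix"))
  missing <- setdiff(model$feature_ids, rownames(cohort$values))
  if (length(missing))
    stop("cohort lacks model feature: ", paste(missing, collapse = ", "))
  x <- cohort$values[model$feature_ids, , drop = FALSE]
  st <- list(classes = model$classes, s = model$pooled_sd, s0 = model$s0)
  scores <- nsc_discriminant(st, model$shrunken_centroids, model$priors, x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  cls <- model$classes[apply(scores, 1, which.min)]
  out <- data.frame(sample_id = colnames(x), class = cls,
                    stringsAsFactors = FALSE)
  colnames(scores) <- paste0("score_", model$classes)
  cbind(out, as.data.frame(scores))
}

#' Cluster signature probes by their Kendall correlation structure
#'
#' Pairwise Kendall tau-b between probe expression vectors, average-linkage
#' hierarchical clustering on distance `1 - tau`, tree cut into two
#' clusters. A constant probe has undefined correlations; its distances are
#' set to the maximum (2) and the event is logged.
#'
#' @param cohort a [cohort_matrix()] restricted to the signature probes
#'   (>= 3 probes).
#' @return list with `clusters` (named integer vector in 1:2), `tau`
#'   (probe x probe tau-b matrix, unit diagonal), and `hclust` (the tree).
#' @export
cluster_signature <- function(cohort) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  v <- cohort$values
  if (nrow(v) < 3L) stop("need at least 3 probes")
  tau <- suppressWarnings(stats::cor(t(v), method = "kendall"))
  diag(tau) <- 1
  if (anyNA(tau)) {
    const <- rownames(v)[apply(v, 1, function(r) length(unique(r)) < 2L)]
    log_kv("cluster_signature", constant_probes = length(const))
    tau[is.na(tau)] <- -1   # distance 1 - tau = 2, the maximum
  }
  d <- stats::as.dist(1 - tau)
  hc <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(hc, k = 2)
  list(clusters = clusters, tau = tau, hclust = hc)
}
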