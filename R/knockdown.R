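# The triple-criterion differential-expression caller for siRNA knock-down
# replicate arrays, plus downstream target screening: Kendall correlation of
# targets with the knocked-down transcript in clinical cohorts, and binary
# outcome (relapse / 5-year survival) marker tests.

#' Call differentially expressed probes in a knock-down experiment
#'
#' Per siRNA condition, a probe passes when all three criteria hold:
#' (1) pooled-variance t-test of treated vs control replicates, `p < p_de`;
#' (2) fold-change ratio of median treated to median control beyond
#' `fc_min` (in either direction);
#' (3) at least `min_reps` treated replicates beyond the control median in
#' the fold-change direction (above it for up-regulation, below for down —
#' the replicate criterion is direction-aware).
#' The consensus list contains probes passing all three in BOTH siRNA
#' conditions with the same direction.
#'
#' @param cohort a [cohort_matrix()] whose metadata `condition` column
#'   labels samples as `control` and the names in `conditions`.
#' @param p_de t-test p cutoff (default 0.05).
#' @param fc_min linear-scale fold-change floor, strict (default 1.3; the
#'   alternative conventional setting is 1.4).
#' @param min_reps replicate-concordance floor (default 3).
#' @param scale `"log2"` (fold change computed after exponentiation) or
#'   `"linear"`.
#' @param conditions treated condition labels (default `siRNA_1`,
#'   `siRNA_2`).
#' @return list with `per_condition` (data.frame per probe x condition:
#'   `fold_change`, `p_t`, `reps_beyond_control`, `direction`, `passes`)
#'   and `consensus` (data.frame `probe_id`, `direction`).
#' @export
call_de <- function(cohort, p_de = 0.05, fc_min = 1.3, min_reps = 3,
                    scale = c("log2", "linear"),
                    conditions = c("siRNA_1", "siRNA_2")) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  scale <- match.arg(scale)
  cond <- cohort$metadata$condition
  missing <- setdiff(c("control", conditions), unique(cond))
  if (length(missing))
    stop("condition missing from cohort: ", paste(missing, collapse = ", "))
  v <- cohort$values
  if (scale == "log2") v <- 2^v
  ctrl <- v[, cond == "control", drop = FALSE]
  if (ncol(ctrl) < min_reps)
    stop("fewer control replicates than min_reps")
  ctrl_med <- apply(ctrl, 1, stats::median)

  per_cond <- lapply(conditions, function(cd) {
    trt <- v[, cond == cd, drop = FALSE]
    if (ncol(trt) < min_reps)
      stop("fewer ", cd, " replicates than min_reps")
    trt_med <- apply(trt, 1, stats::median)
    fc <- trt_med / ctrl_med
    direction <- ifelse(fc >= 1, "up", "down")
    # t-test on the analysis scale the data came in on
    lt <- if (scale == "log2") log2(trt) else trt
    lc <- if (scale == "log2") log2(ctrl) else ctrl
    p_t <- vapply(seq_len(nrow(v)), function(i)
      students_t(lt[i, ], lc[i, ])$p, numeric(1))
    beyond <- vapply(seq_len(nrow(v)), function(i) {
      if (direction[i] == "up") sum(trt[i, ] > ctrl_med[i])
      else sum(trt[i, ] < ctrl_med[i])
    }, integer(1))
    data.frame(
      probe_id = rownames(v), condition = cd, fold_change = fc,
      p_t = p_t, reps_beyond_control = beyond, direction = direction,
      passes = p_t < p_de & pmax(fc, 1 / fc) > fc_min & beyond >= min_reps,
      stringsAsFactors = FALSE
    )
  })
  per_condition <- do.call(rbind, per_cond)
  rownames(per_condition) <- NULL

  pass_tabs <- lapply(per_cond, function(d) d[d$passes, c("probe_id",
                                                          "direction")])
  consensus <- Reduce(function(a, b) merge(a, b, by = c("probe_id",
                                                        "direction")),
                      pass_tabs)
  consensus <- consensus[order(consensus$probe_id), , drop = FALSE]
  rownames(consensus) <- NULL
  list(per_condition = per_condition, consensus = consensus)
}

#' Correlate candidate targets with an anchor transcript
#'
#' Kendall tau-b between the anchor probe's expression and each target
#' probe across the cohort samples, with the tau normal-approximation
#' p-value; a target is flagged significant at `p < p_max`.
#'
#' @param cohort a clinical [cohort_matrix()].
#' @param anchor_probe probe id of the anchor (e.g. the knocked-down
#'   lncRNA); a constant anchor is an error.
#' @param target_probes probe ids to test.
#' @param p_max significance cutoff (default 0.05, uncorrected).
#' @return data.frame per target: `probe_id`, `tau`, `p`, `significant`,
#'   `sign`.
#' @export
correlate_targets <- function(cohort, anchor_probe, target_probes,
                              p_max = 0.05) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  v <- cohort$values
  ids <- c(anchor_probe, target_probes)
  missing <- setdiff(ids, rownames(v))
  if (length(missing))
    stop("probe not in cohort: ", paste(missing, collapse = ", "))
  anchor <- v[anchor_probe, ]
  if (length(unique(anchor)) < 2L) stop("anchor probe is constant")
  out <- do.call(rbind, lapply(target_probes, function(p) {
    kt <- kendall_tau_test(anchor, v[p, ])
    data.frame(probe_id = p, tau = kt$tau, p = kt$p,
               significant = !is.na(kt$p) & kt$p < p_max,
               sign = ifelse(is.na(kt$tau), NA_integer_,
                             as.integer(sign(kt$tau))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test probes against a binary clinical outcome
#'
#' Mann-Whitney U per probe between the two outcome groups (relapse vs no
#' relapse, survived vs not). Raw p-values are cut at `p_max` (matching the
#' uncorrected usage of such marker tests) with BH q-values reported
#' alongside.
#'
#' @param cohort a [cohort_matrix()].
#' @param outcome name of the metadata flag (`"relapse"` or
#'   `"survived_5y"`) or a logical vector aligned with the samples.
#' @param probes probe ids to test (default all).
#' @param p_max significance cutoff (default 0.05).
#' @return data.frame per probe: `probe_id`, `U`, `p`, `q`, `significant`.
#' @export
binary_marker_test <- function(cohort, outcome, probes = NULL,
                               p_max = 0.05) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% names(cohort$metadata))
      stop("unknown outcome column: ", outcome)
    outcome <- cohort$metadata[[outcome]]
  }
  keep <- !is.na(outcome)
  grp <- as.logical(outcome[keep])
  if (!any(grp) || all(grp)) stop("both outcome groups must be non-empty")
  v <- cohort$values[, keep, drop = FALSE]
  if (is.null(probes)) probes <- rownames(v)
  missing <- setdiff(probes, rownames(v))
  if (length(missing))
    stop("probe not in cohort: ", paste(missing, collapse = ", "))
  res <- do.call(rbind, lapply(probes, function(p) {
    mw <- mann_whitney(v[p, grp], v[p, !grp])
    data.frame(probe_id = p, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  res$significant <- res$p < p_max
  rownames(res) <- NULL
  res
}

#' Collapse probe-level calls to genes
#'
#' Optional post-step: keeps, for every gene, its maximum-variance probe.
#'
#' @param cohort a [cohort_matrix()].
#' @param probe_to_gene data.frame with `probe_id`, `gene_id`.
#' @return character vector of retained probe ids, named by gene.
#' @export
collapse_probes <- function(cohort, probe_to_gene) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  pv <- apply(cohort$values, 1, stats::var)
  keep <- vapply(split(probe_to_gene$probe_id, probe_to_gene$gene_id),
                 function(ps) {
                   ps <- intersect(ps, names(pv))
                   if (!length(ps)) return(NA_character_)
                   ps[which.max(pv[ps])]
                 }, character(1))
  keep[!is.na(keep)]
}
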