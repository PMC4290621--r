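# End-to-end pipelines: annotation (filtration cascade -> length classes ->
# neighbors -> enrichment) and biomarker discovery (stage screen -> NSC
# signature -> correlation clustering), with run manifests for
# reproducibility.

#' Run the annotation pipeline
#'
#' Executes [filter_candidates()], then fits the length mixture and
#' classifies candidate lengths (when at least 30 distinct lengths are
#' available), marks the high-confidence subset against a reference
#' catalogue when given, finds protein-coding neighbors and tests term
#' enrichment of the neighbor set when a term mapping is given. Stage
#' record counts are logged; empty input yields empty outputs with a
#' warning log, not an error.
#'
#' Inputs may be passed as objects or read from `config$paths`
#' (`probes_bed`, `transcripts` + `transcripts_format`,
#' `protein_exons_bed`, `coding_calls_tsv`, `reference` +
#' `reference_format`, `term_mapping_gmt`, `outdir`).
#'
#' @param config list from [default_config()] / [read_run_config()].
#' @param probes a [probe_mapping()].
#' @param transcripts,reference [transcript_table()] objects.
#' @param protein_exons data.frame chrom/start/end/strand.
#' @param coding_calls optional evidence table.
#' @param mapping optional [term_mapping()].
#' @param outdir optional output directory for TSVs + manifest.
#' @return list with `candidates`, `audits`, `fit`, `classes`, `neighbors`,
#'   `enrichment`.
#' @export
run_annotation_pipeline <- function(config = default_config(),
                                    probes = NULL, transcripts = NULL,
                                    protein_exons = NULL,
                                    coding_calls = NULL, reference = NULL,
                                    mapping = NULL, outdir = NULL) {
  p <- config$paths
  if (is.null(probes) && !is.null(p$probes_bed)) {
    bed <- read_intervals(p$probes_bed, "BED")
    probes <- probe_mapping(
      probe_set_id = bed$transcript_id,
      placements = bed[, c("chrom", "start", "end", "strand")],
      target_transcript_id = if (!is.null(p$probe_targets_tsv)) {
        tgt <- utils::read.delim(p$probe_targets_tsv,
                                 stringsAsFactors = FALSE)
        tgt$transcript_id[match(bed$transcript_id, tgt$probe_set_id)]
      } else NA_character_
    )
  }
  if (is.null(transcripts) && !is.null(p$transcripts))
    transcripts <- read_intervals(p$transcripts,
                                  p$transcripts_format %||% "GFF3")
  if (is.null(protein_exons) && !is.null(p$protein_exons_bed)) {
    bed <- read_intervals(p$protein_exons_bed, "BED")
    protein_exons <- bed[, c("chrom", "start", "end", "strand")]
  }
  if (is.null(coding_calls) && !is.null(p$coding_calls_tsv))
    coding_calls <- utils::read.delim(p$coding_calls_tsv,
                                      stringsAsFactors = FALSE)
  if (is.null(reference) && !is.null(p$reference))
    reference <- read_intervals(p$reference, p$reference_format %||% "GFF3")
  if (is.null(mapping) && !is.null(p$term_mapping_gmt))
    mapping <- read_term_mapping(p$term_mapping_gmt)
  if (is.null(outdir)) outdir <- p$outdir

  if (is.null(probes) || nrow(probes) == 0L) {
    warning("no probe mappings supplied; emitting empty outputs")
    log_kv("annotate", probes = 0)
    out <- list(candidates = data.frame(), audits = data.frame(),
                fit = NULL, classes = NULL, neighbors = data.frame(),
                enrichment = NULL)
    if (!is.null(outdir)) write_annotation_outputs(out, config, outdir)
    return(invisible(out))
  }

  flt <- filter_candidates(probes, transcripts, protein_exons,
                           coding_calls = coding_calls,
                           min_length = config$min_length)
  log_kv("filter", input = nrow(probes), retained = nrow(flt$candidates),
         excluded = sum(flt$audits$outcome == "excluded"))
  if (!is.null(reference) && nrow(flt$candidates))
    flt$candidates <- match_reference(flt$candidates, reference,
                                      probes = probes)

  fit <- NULL
  classes <- NULL
  lens <- flt$candidates$length_nt
  if (length(unique(lens)) >= 30L) {
    fit <- fit_mixture(lens, n_components = config$n_components)
    classes <- data.frame(probe_set_id = flt$candidates$probe_set_id,
                          length_nt = lens,
                          class = classify_lengths(lens, fit$cutoffs_nt,
                                                   config$min_length),
                          stringsAsFactors = FALSE)
    log_kv("classify", cutoff1 = round(fit$cutoffs_nt[1]),
           cutoff2 = round(fit$cutoffs_nt[2]))
  } else {
    log_kv("classify", skipped = "too few distinct lengths")
  }

  neighbors <- data.frame()
  enrichment <- NULL
  if (!is.null(transcripts) && nrow(flt$candidates)) {
    lnc <- transcripts[transcripts$transcript_id %in%
                         flt$candidates$transcript_id, , drop = FALSE]
    coding <- transcripts[transcripts$biotype == "protein_coding", ,
                          drop = FALSE]
    if (nrow(coding))
      neighbors <- find_neighbors(lnc, coding, window = config$window)
    log_kv("neighbors", pairs = nrow(neighbors))
    if (!is.null(mapping) && nrow(neighbors)) {
      sel <- intersect(unique(neighbors$gene_id), mapping$universe)
      enrichment <- enrich(sel, mapping, p_max = config$p_go,
                           min_enrichment = config$min_enrichment)
      log_kv("enrich", significant = nrow(enrichment$significant))
    }
  }

  out <- list(candidates = flt$candidates, audits = flt$audits, fit = fit,
              classes = classes, neighbors = neighbors,
              enrichment = enrichment)
  if (!is.null(outdir)) write_annotation_outputs(out, config, outdir)
  invisible(out)
}

write_annotation_outputs <- function(out, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(out$candidates, "candidates.tsv")
  wtsv(out$audits, "audits.tsv")
  if (!is.null(out$classes)) wtsv(out$classes, "length_classes.tsv")
  if (!is.null(out$fit)) {
    co <- t(vapply(out$fit$components, function(c)
      c(a0 = c$a0, a1 = c$a1, a2 = c$a2), numeric(3)))
    rep <- data.frame(component = seq_len(nrow(co)), co,
                      check.names = FALSE)
    wtsv(rep, "mixture_fit.tsv")
  }
  wtsv(out$neighbors, "neighbors.tsv")
  if (!is.null(out$enrichment)) wtsv(out$enrichment$table, "enrichment.tsv")
  write_manifest(config, outdir,
                 counts = list(candidates = nrow(out$candidates),
                               neighbors = nrow(out$neighbors)))
}

#' Run the biomarker-discovery pipeline
#'
#' Executes [screen_stage_markers()], trains the NSC signature on the
#' selected probes with early/late stage labels, applies the trained model
#' unchanged to an optional evaluation cohort (e.g. a relapse-annotated
#' series; skipped with a log notice when absent), and clusters the
#' signature probes by their Kendall correlation structure.
#'
#' @param config list from [default_config()] / [read_run_config()];
#'   `restrict`, `p_screen`, `tau_min`, `cut_on`, `folds`, `seed` are used.
#' @param cohort a [cohort_matrix()] with stage metadata, or read from
#'   `config$paths$expr_tsv` / `meta_tsv`.
#' @param eval_cohort optional evaluation [cohort_matrix()] (or
#'   `eval_expr_tsv` / `eval_meta_tsv`); its `relapse` flag, when present,
#'   is compared against the late-stage class.
#' @param outdir optional output directory.
#' @return list with `screen`, `fit` (an `"NSCFit"`), `clusters`,
#'   `evaluation` (predictions + accuracy or `NULL`).
#' @export
run_biomarker_pipeline <- function(config = default_config(),
                                   cohort = NULL, eval_cohort = NULL,
                                   outdir = NULL) {
  p <- config$paths
  if (is.null(cohort) && !is.null(p$expr_tsv))
    cohort <- read_cohort(p$expr_tsv, p$meta_tsv)
  if (is.null(eval_cohort) && !is.null(p$eval_expr_tsv))
    eval_cohort <- read_cohort(p$eval_expr_tsv, p$eval_meta_tsv)
  if (is.null(outdir)) outdir <- p$outdir
  if (is.null(cohort)) stop("no cohort supplied")

  screen <- screen_stage_markers(cohort, p_screen = config$p_screen,
                                 tau_min = config$tau_min,
                                 restrict = config$restrict,
                                 cut_on = config$cut_on)
  log_kv("screen", tested = nrow(screen), selected = sum(screen$selected))
  sel <- screen$probe_id[screen$selected]

  fit <- NULL
  clusters <- NULL
  evaluation <- NULL
  if (length(sel) >= 2L) {
    md <- cohort$metadata
    keep <- !is.na(md$stage) & !(md$stage_4s %in% TRUE)
    if (config$restrict == "non_mna")
      keep <- keep & (md$mycn_amplified %in% FALSE)
    sub <- subset_cohort(cohort, probes = sel,
                         samples = md$sample_id[keep])
    labels <- ifelse(sub$metadata$stage <= 2, "early", "late")
    fit <- nsc_train(sub, labels, folds = config$folds,
                     seed = config$seed)
    log_kv("signature", features = length(fit$model$surviving_features),
           cv_accuracy = round(fit$cv_accuracy, 3))
    if (length(fit$model$surviving_features) >= 3L)
      clusters <- cluster_signature(
        subset_cohort(sub, probes = fit$model$surviving_features))
    if (!is.null(eval_cohort)) {
      pred <- nsc_predict(fit$model, eval_cohort)
      truth <- eval_cohort$metadata$relapse
      acc <- if (any(!is.na(truth)))
        mean((pred$class == "late")[!is.na(truth)] ==
               truth[!is.na(truth)])
      else NA_real_
      evaluation <- list(predictions = pred, accuracy = acc)
      log_kv("evaluate", samples = nrow(pred),
             accuracy = round(acc, 3))
    } else {
      log_kv("evaluate", skipped = "no evaluation cohort")
    }
  } else {
    log_kv("signature", skipped = "fewer than 2 selected probes")
  }

  out <- list(screen = screen, fit = fit, clusters = clusters,
              evaluation = evaluation)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(screen, file.path(outdir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(fit))
      utils::write.table(fit$report, file.path(outdir, "signature.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(clusters))
      utils::write.table(
        data.frame(probe_id = names(clusters$clusters),
                   cluster = clusters$clusters),
        file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    write_manifest(config, outdir,
                   counts = list(tested = nrow(screen),
                                 selected = length(sel)))
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Manifest: config hash + seed + stage counts, enough to reproduce the run.
write_manifest <- function(config, outdir, counts = list()) {
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, counts = counts)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
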