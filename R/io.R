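# Readers/writers for interval tables, expression cohorts and gene-set
# mappings. All coordinates are converted to 0-based half-open on the way in
# and back to the source dialect on the way out; nothing downstream ever sees
# a 1-based coordinate.

#' Read transcript intervals from BED, GFF3 or TSV
#'
#' BED (6-column) and GFF3 are parsed with `rtracklayer::import`; GFF3's
#' 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention. The TSV dialect is the one [write_intervals()]
#' emits (already 0-based half-open, exons encoded `start-end;start-end`).
#'
#' For GFF3, features of type `transcript` or `mRNA` become records and
#' `exon` features are attached via their `Parent` attribute; `gene_id` and
#' `biotype` attributes are honoured when present.
#'
#' @param path file path.
#' @param format one of `"BED"`, `"GFF3"`, `"TSV"`.
#' @return a [transcript_table()].
#' @export
read_intervals <- function(path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  tx <- switch(format,
    BED  = read_intervals_bed(path),
    GFF3 = read_intervals_gff3(path),
    TSV  = read_intervals_tsv(path)
  )
  validate_transcripts(tx)
}

read_intervals_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("malformed BED in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (length(gr) == 0L) return(empty_transcript_table())
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else sprintf("interval_%d", seq_along(gr))
  transcript_table(
    transcript_id = ids,
    chrom  = as.character(GenomeInfoDb::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,
    end    = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
}

read_intervals_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  type <- as.character(gr$type)
  is_tx <- type %in% c("transcript", "mRNA")
  if (!any(is_tx)) return(empty_transcript_table())
  txg <- gr[is_tx]
  ids <- as.character(txg$ID)
  exg <- gr[type == "exon"]
  parents <- vapply(as.list(exg$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  exons <- lapply(seq_along(txg), function(i) {
    e <- exg[!is.na(parents) & parents == ids[i]]
    if (length(e) == 0L)
      cbind(start = BiocGenerics::start(txg[i]) - 1L,
            end   = BiocGenerics::end(txg[i]))
    else
      cbind(start = BiocGenerics::start(e) - 1L,
            end   = BiocGenerics::end(e))
  })
  gene_id <- if (!is.null(txg$gene_id)) as.character(txg$gene_id) else ids
  biotype <- if (!is.null(txg$biotype)) as.character(txg$biotype)
             else "unannotated"
  transcript_table(
    transcript_id = ids,
    gene_id = ifelse(is.na(gene_id), ids, gene_id),
    chrom   = as.character(GenomeInfoDb::seqnames(txg)),
    start   = BiocGenerics::start(txg) - 1L,
    end     = BiocGenerics::end(txg),
    strand  = as.character(BiocGenerics::strand(txg)),
    biotype = ifelse(is.na(biotype), "unannotated", biotype),
    exons   = exons
  )
}

read_intervals_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("interval TSV missing columns: ", paste(missing, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      stop("malformed ", col, " at line ", bad[1] + 1L, " of ", path)
    df[[col]] <- v
  }
  exons <- if ("exons" %in% names(df)) lapply(df$exons, parse_exon_field)
           else NULL
  transcript_table(
    transcript_id = df$transcript_id,
    gene_id = if ("gene_id" %in% names(df)) df$gene_id else df$transcript_id,
    chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
    biotype = if ("biotype" %in% names(df)) df$biotype else "unannotated",
    exons = exons
  )
}

parse_exon_field <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p)
    cbind(start = as.integer(p[1]), end = as.integer(p[2]))))
}

empty_transcript_table <- function() {
  transcript_table(character(0), character(0), character(0),
                   integer(0), integer(0), character(0), character(0),
                   exons = list())
}

#' Write transcript intervals as TSV
#'
#' Emits the package's 0-based half-open TSV dialect, which
#' [read_intervals()] round-trips exactly.
#'
#' @param tx a [transcript_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(tx, path) {
  out <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = tx$chrom, start = tx$start, end = tx$end, strand = tx$strand,
    biotype = tx$biotype,
    exons = vapply(tx$exons, function(e)
      paste(sprintf("%d-%d", e[, 1], e[, 2]), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse INSS stage labels
#'
#' Sub-stages `2a`/`2b` collapse to 2; `4s` is stored as stage 4 with a
#' distinguishing flag (and is excluded by default from stage-ordered
#' analyses, see [screen_stage_markers()]). Anything outside 1-4 errors.
#'
#' @param x character or numeric vector of stage labels; `NA`/empty allowed.
#' @return list with integer `stage` and logical `stage_4s`.
#' @export
parse_stage <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  stage <- rep(NA_integer_, length(x))
  s4 <- rep(NA, length(x))
  known <- !is.na(x)
  core <- sub("^([1-4])[abs]?$", "\\1", x[known])
  bad <- !grepl("^[1-4]([ab]|s)?$", x[known]) |
    (grepl("[ab]$", x[known]) & core != "2") |
    (grepl("s$", x[known]) & core != "4")
  if (any(bad))
    stop("invalid stage label: ", paste(unique(x[known][bad]), collapse = ", "))
  stage[known] <- as.integer(core)
  s4[known] <- grepl("s$", x[known])
  list(stage = stage, stage_4s = s4)
}

#' Read an expression cohort from TSV
#'
#' @param expr_path TSV with probe ids in the first column and one numeric
#'   column per sample. Any non-numeric cell is an error naming its row and
#'   column; missing values are not allowed.
#' @param meta_path optional TSV keyed by `sample_id` with any of the columns
#'   `stage` (labels parsed by [parse_stage()]), `mycn_amplified`, `relapse`,
#'   `survived_5y`, `condition`. Samples without metadata get empty records;
#'   metadata for an unknown sample is an error.
#' @return a [cohort_matrix()].
#' @export
read_cohort <- function(expr_path, meta_path = NULL) {
  raw <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression TSV needs probe id + sample columns")
  probe_ids <- raw[[1]]
  values <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                   dimnames = list(probe_ids, names(raw)[-1]))
  for (j in seq_len(ncol(values))) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric expression value at probe '%s', sample '%s'",
                   probe_ids[bad[1]], colnames(values)[j]))
    values[, j] <- v
  }
  metadata <- NULL
  if (!is.null(meta_path)) {
    md <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (is.null(md$sample_id)) stop("metadata TSV needs a sample_id column")
    metadata <- data.frame(sample_id = md$sample_id,
                           stringsAsFactors = FALSE)
    if (!is.null(md$stage)) {
      st <- parse_stage(md$stage)
      metadata$stage <- st$stage
      metadata$stage_4s <- st$stage_4s
    }
    for (col in c("mycn_amplified", "relapse", "survived_5y"))
      if (!is.null(md[[col]])) metadata[[col]] <- parse_flag(md[[col]], col)
    if (!is.null(md$condition)) metadata$condition <- md$condition
  }
  cohort_matrix(values, metadata)
}

parse_flag <- function(x, what) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "no", "n")] <- FALSE
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad))
    stop("invalid ", what, " flag: ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Write an expression cohort as TSV
#'
#' Inverse of [read_cohort()]: values round-trip exactly (full double
#' precision), metadata in the same dialect.
#'
#' @param cohort a [cohort_matrix()].
#' @param expr_path,meta_path output files (`meta_path` optional).
#' @return `expr_path`, invisibly.
#' @export
write_cohort <- function(cohort, expr_path, meta_path = NULL) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  df <- data.frame(probe_id = rownames(cohort$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in colnames(cohort$values))
    df[[s]] <- sprintf("%.17g", cohort$values[, s])
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path)) {
    md <- cohort$metadata
    md$stage <- ifelse(!is.na(md$stage) & !is.na(md$stage_4s) & md$stage_4s,
                       "4s", as.character(md$stage))
    md$stage_4s <- NULL
    utils::write.table(md, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(expr_path)
}

#' Read a GMT-like term-to-gene mapping
#'
#' Tab-separated lines `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @param universe optional explicit universe; defaults to the union of all
#'   mapped genes.
#' @return a [term_mapping()].
#' @export
read_term_mapping <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1], " in ", path)
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- vapply(fields, `[[`, character(1), 1L)
  if (is.null(universe)) universe <- unique(unlist(terms))
  term_mapping(terms, universe)
}

#' Default run configuration
#'
#' All pipeline thresholds with their standard defaults: minimum lncRNA
#' length 200 nt, screen p cutoff 0.001, Kendall |tau| floor 0.25, DE p
#' cutoff 0.05, fold-change floor 1.3, minimum concordant replicates 3,
#' neighbor window 10 kb, enrichment p cutoff 0.01 and enrichment floor 2.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    min_length = 200, p_screen = 0.001, tau_min = 0.25,
    cut_on = "raw", p_de = 0.05, fc_min = 1.3, min_reps = 3,
    window = 10000, p_go = 0.01, min_enrichment = 2.0,
    restrict = "all", n_components = 3, folds = 10, seed = 1,
    paths = list()
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys are kept (they may name input/output paths); known threshold
#' keys override [default_config()] after domain checks.
#'
#' @param path YAML file.
#' @return named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  validate_config(out)
}

validate_config <- function(cfg) {
  chk <- function(name, lo, hi) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop("config ", name, " must be a number in [", lo, ", ", hi, "]")
  }
  chk("min_length", 1, Inf); chk("p_screen", 0, 1); chk("tau_min", 0, 1)
  chk("p_de", 0, 1); chk("fc_min", 1, Inf); chk("min_reps", 1, Inf)
  chk("window", 0, Inf); chk("p_go", 0, 1); chk("min_enrichment", 0, Inf)
  if (!cfg$restrict %in% c("all", "non_mna"))
    stop("config restrict must be 'all' or 'non_mna'")
  if (!cfg$cut_on %in% c("raw", "q"))
    stop("config cut_on must be 'raw' or 'q'")
  cfg
}
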