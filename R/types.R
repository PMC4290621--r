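#' @keywords internal
"_PACKAGE"

STRANDS <- c("+", "-", "*")

#' Construct a table of transcript records
#'
#' The central annotation container: one row per transcript with its genomic
#' interval (0-based half-open coordinates throughout the package), an exon
#' structure, a biotype and the summed exon length in nucleotides.
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param gene_id character vector of gene identifiers (recycled if length 1).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open transcript interval.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param biotype one of `"protein_coding"`, `"annotated_ncRNA"`,
#'   `"unannotated"`.
#' @param exons optional list of two-column matrices (`start`, `end`, 0-based
#'   half-open) giving the exon structure; defaults to a single exon spanning
#'   the whole interval.
#' @return a `data.frame` with class `"transcript_table"` and a list-column
#'   `exons`; column `length_nt` holds the summed exon span.
#' @export
transcript_table <- function(transcript_id, gene_id = transcript_id,
                             chrom, start, end, strand = "*",
                             biotype = "unannotated", exons = NULL) {
  n <- length(transcript_id)
  tx <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id       = rep_len(as.character(gene_id), n),
    chrom         = rep_len(as.character(chrom), n),
    start         = rep_len(as.integer(start), n),
    end           = rep_len(as.integer(end), n),
    strand        = rep_len(as.character(strand), n),
    biotype       = rep_len(as.character(biotype), n),
    stringsAsFactors = FALSE
  )
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i)
      cbind(start = tx$start[i], end = tx$end[i]))
  }
  tx$exons <- I(lapply(exons, function(e) {
    e <- cbind(start = as.integer(e[, 1]), end = as.integer(e[, 2]))
    e[order(e[, 1]), , drop = FALSE]
  }))
  tx$length_nt <- vapply(tx$exons, function(e)
    sum(e[, 2] - e[, 1]), integer(1))
  class(tx) <- c("transcript_table", "data.frame")
  validate_transcripts(tx)
}

#' Validate transcript-table invariants
#'
#' Checks identifier uniqueness, strand symbols, interval sanity, and that
#' exons are sorted, non-overlapping and contained in the transcript interval
#' with spans summing to `length_nt`.
#'
#' @param tx a [transcript_table()].
#' @return `tx`, invisibly unchanged, or an error.
#' @export
validate_transcripts <- function(tx) {
  dup <- unique(tx$transcript_id[duplicated(tx$transcript_id)])
  if (length(dup))
    stop("duplicated transcript_id: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(tx$strand), STRANDS)
  if (length(bad))
    stop("unknown strand symbol: ", paste(bad, collapse = ", "))
  if (any(tx$start < 0L)) stop("negative interval start")
  if (any(tx$end <= tx$start)) stop("interval end must exceed start")
  ok_bt <- c("protein_coding", "annotated_ncRNA", "unannotated")
  if (!all(tx$biotype %in% ok_bt))
    stop("biotype must be one of: ", paste(ok_bt, collapse = ", "))
  for (i in seq_len(nrow(tx))) {
    e <- tx$exons[[i]]
    if (any(e[, 2] <= e[, 1]))
      stop("empty exon in ", tx$transcript_id[i])
    if (is.unsorted(e[, 1]) ||
        (nrow(e) > 1 && any(e[-1, 1] < e[-nrow(e), 2])))
      stop("overlapping or unsorted exons in ", tx$transcript_id[i])
    if (e[1, 1] < tx$start[i] || e[nrow(e), 2] > tx$end[i])
      stop("exon outside transcript interval in ", tx$transcript_id[i])
    if (sum(e[, 2] - e[, 1]) != tx$length_nt[i])
      stop("length_nt does not equal summed exon span in ",
           tx$transcript_id[i])
  }
  invisible(tx)
}

#' Construct an expression cohort
#'
#' Couples a normalized log-scale expression matrix (probes x samples) with
#' per-sample clinical metadata. Metadata fields the clinical analyses use:
#' INSS `stage` (integer 1-4; sub-stages 2a/2b collapse to 2, 4s is stored as
#' 4 with `stage_4s = TRUE`), `mycn_amplified`, `relapse`, `survived_5y`, and
#' a `condition` label for designed experiments.
#'
#' @param values numeric matrix with probe rownames and sample colnames; no
#'   missing values are allowed.
#' @param metadata optional `data.frame` with a `sample_id` column; samples in
#'   `values` without a metadata row get all-`NA` records. A metadata sample
#'   absent from the matrix is an error.
#' @return an object of class `"CohortMatrix"`.
#' @export
cohort_matrix <- function(values, metadata = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing expression values are not allowed")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  md <- empty_metadata(colnames(values))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (is.null(metadata$sample_id)) stop("metadata needs a sample_id column")
    unknown <- setdiff(metadata$sample_id, colnames(values))
    if (length(unknown))
      stop("metadata sample absent from matrix: ",
           paste(unknown, collapse = ", "))
    i <- match(metadata$sample_id, md$sample_id)
    for (col in setdiff(intersect(names(metadata), names(md)), "sample_id"))
      md[[col]][i] <- metadata[[col]]
  }
  structure(list(values = values, metadata = md), class = "CohortMatrix")
}

empty_metadata <- function(sample_ids) {
  data.frame(
    sample_id      = sample_ids,
    stage          = NA_integer_,
    stage_4s       = NA,
    mycn_amplified = NA,
    relapse        = NA,
    survived_5y    = NA,
    condition      = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.CohortMatrix <- function(x, ...) {
  cat(sprintf("CohortMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  filled <- vapply(x$metadata[-1], function(v) sum(!is.na(v)), integer(1))
  filled <- filled[filled > 0]
  if (length(filled))
    cat("metadata:", paste(sprintf("%s (%d)", names(filled), filled),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Subset a cohort by probes and/or samples
#'
#' @param cohort a [cohort_matrix()].
#' @param probes,samples character vectors of ids to keep (default all).
#' @return a `CohortMatrix`.
#' @export
subset_cohort <- function(cohort, probes = NULL, samples = NULL) {
  stopifnot(inherits(cohort, "CohortMatrix"))
  v <- cohort$values
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(v))
    if (length(missing))
      stop("probe not in cohort: ", paste(missing, collapse = ", "))
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("sample not in cohort: ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  md <- cohort$metadata[match(colnames(v), cohort$metadata$sample_id), ,
                        drop = FALSE]
  rownames(md) <- NULL
  structure(list(values = v, metadata = md), class = "CohortMatrix")
}

#' Construct a term-to-gene mapping
#'
#' A gene-set collection for over-representation testing: each term maps to a
#' non-empty set of gene ids, all drawn from a stated universe.
#'
#' @param terms named list of character vectors (term id -> gene ids).
#' @param universe character vector of all eligible gene ids.
#' @return an object of class `"TermMapping"`.
#' @export
term_mapping <- function(terms, universe) {
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("every term needs a name")
  if (any(lengths(terms) == 0L)) stop("terms must be non-empty")
  stray <- setdiff(unique(unlist(terms)), universe)
  if (length(stray))
    stop("mapped gene outside universe: ", paste(stray, collapse = ", "))
  structure(list(terms = terms, universe = universe), class = "TermMapping")
}

# Minimal gap between two half-open intervals on a shared chromosome;
# 0 when they overlap or abut.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1 - end2, start2 - end1))
}

# TRUE when half-open [s1,e1) and [s2,e2) share at least one base.
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

#' Timestamped key=value log line
#'
#' @param stage short stage label.
#' @param ... named scalar fields.
#' @return the formatted line, invisibly; emitted via [message()].
#' @export
log_kv <- function(stage, ...) {
  fields <- list(...)
  kv <- if (length(fields))
    paste(names(fields), vapply(fields, format, character(1)),
          sep = "=", collapse = " ")
  else ""
  line <- trimws(sprintf("%s stage=%s %s",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, kv))
  message(line)
  invisible(line)
}
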