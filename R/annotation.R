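# The probe-set filtration cascade: from all probe mappings down to lncRNA
# candidates with a complete audit trail, an ORF-based coding-potential
# stand-in for external classifiers, and reference-catalogue matching that
# marks the high-confidence subset.

FILTER_RULES <- c("non_unique", "protein_annotated",
                  "same_strand_protein_exon_overlap", "coding_potential",
                  "below_min_length", "no_reference_match")

#' Construct a probe-mapping table
#'
#' One row per probe set, with all genomic placements attached. A probe set
#' is a `unique_match` exactly when it has a single placement.
#'
#' @param probe_set_id character vector, one entry per placement (repeated
#'   ids denote multi-locus probes).
#' @param placements data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), aligned with `probe_set_id`.
#' @param target_transcript_id transcript targeted by each placement's probe
#'   set (`NA` when unknown); must be constant within a probe set.
#' @return a data.frame of class `"probe_mapping"` with list-column
#'   `placements`.
#' @export
probe_mapping <- function(probe_set_id, placements,
                          target_transcript_id = NA_character_) {
  stopifnot(nrow(placements) == length(probe_set_id))
  if (any(placements$end <= placements$start))
    stop("placement end must exceed start")
  if (!all(placements$strand %in% STRANDS))
    stop("unknown strand symbol in placements")
  target_transcript_id <- rep_len(as.character(target_transcript_id),
                                  length(probe_set_id))
  ids <- unique(probe_set_id)
  rows <- lapply(ids, function(id) {
    sel <- probe_set_id == id
    tgt <- unique(target_transcript_id[sel])
    if (length(tgt) > 1L)
      stop("probe set ", id, " maps to multiple target transcripts")
    list(pl = placements[sel, c("chrom", "start", "end", "strand"),
                         drop = FALSE],
         target = tgt)
  })
  out <- data.frame(
    probe_set_id = ids,
    target_transcript_id = vapply(rows, `[[`, character(1), "target"),
    n_placements = vapply(rows, function(r) nrow(r$pl), integer(1)),
    stringsAsFactors = FALSE
  )
  out$unique_match <- out$n_placements == 1L
  out$placements <- I(lapply(rows, `[[`, "pl"))
  class(out) <- c("probe_mapping", "data.frame")
  out
}

#' Filtration cascade from probe mappings to lncRNA candidates
#'
#' A probe set is retained iff it (in this fixed rule order) has a unique
#' genomic placement, targets a transcript not annotated as protein-coding,
#' overlaps no protein exon on the same strand (antisense overlap is
#' explicitly allowed), shows no protein-coding potential, and its
#' transcript is at least `min_length` nt. Every input probe gets an audit
#' record; excluded probes carry all failing rule ids in cascade order.
#'
#' @param probes a [probe_mapping()] table.
#' @param transcripts a [transcript_table()]; every named target transcript
#'   must be present (a dangling reference is an error).
#' @param protein_exons data.frame of protein-coding exons with columns
#'   `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @param coding_calls optional evidence table (`probe_set_id`, `call` in
#'   coding/noncoding) from an external classifier; it takes precedence over
#'   the built-in ORF heuristic.
#' @param sequences optional named character vector of transcript sequences
#'   for the ORF heuristic; transcripts with neither external call nor
#'   sequence are treated as noncoding (no evidence of coding).
#' @param min_length minimum candidate length in nt (default 200, the
#'   conventional lncRNA floor).
#' @return list with `candidates` (probe_set_id, transcript_id, length_nt,
#'   high_confidence = `NA` until [match_reference()]) and `audits`
#'   (probe_set_id, outcome, reasons).
#' @export
filter_candidates <- function(probes, transcripts, protein_exons,
                              coding_calls = NULL, sequences = NULL,
                              min_length = 200) {
  stopifnot(inherits(probes, "probe_mapping"))
  named <- probes$target_transcript_id
  dangling <- setdiff(named[!is.na(named)], transcripts$transcript_id)
  if (length(dangling))
    stop("dangling transcript reference: ", paste(dangling, collapse = ", "))
  txi <- match(named, transcripts$transcript_id)

  reasons <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    r <- character(0)
    if (!probes$unique_match[i]) r <- c(r, "non_unique")
    tx <- if (!is.na(txi[i])) transcripts[txi[i], , drop = FALSE] else NULL
    if (!is.null(tx) && tx$biotype == "protein_coding")
      r <- c(r, "protein_annotated")
    pl <- probes$placements[[i]]
    hit <- FALSE
    if (!is.null(protein_exons) && nrow(protein_exons)) {
      for (j in seq_len(nrow(pl))) {
        same <- protein_exons$chrom == pl$chrom[j] &
          protein_exons$strand == pl$strand[j]
        if (any(same & intervals_overlap(protein_exons$start,
                                         protein_exons$end,
                                         pl$start[j], pl$end[j]))) {
          hit <- TRUE
          break
        }
      }
    }
    if (hit) r <- c(r, "same_strand_protein_exon_overlap")
    verdict <- coding_potential(
      transcript = tx,
      sequence = if (!is.null(tx)) sequences[[tx$transcript_id]],
      external_call = lookup_coding_call(coding_calls, probes$probe_set_id[i])
    )
    if (verdict == "coding") r <- c(r, "coding_potential")
    if (!is.null(tx) && tx$length_nt < min_length)
      r <- c(r, "below_min_length")
    reasons[[i]] <- r
  }

  excluded <- lengths(reasons) > 0L
  audits <- data.frame(
    probe_set_id = probes$probe_set_id,
    outcome = ifelse(excluded, "excluded", "retained"),
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  keep <- which(!excluded)
  candidates <- data.frame(
    probe_set_id = probes$probe_set_id[keep],
    transcript_id = named[keep],
    length_nt = transcripts$length_nt[txi[keep]],
    high_confidence = NA,
    stringsAsFactors = FALSE
  )
  list(candidates = candidates, audits = audits)
}

lookup_coding_call <- function(coding_calls, probe_set_id) {
  if (is.null(coding_calls)) return(NULL)
  hit <- match(probe_set_id, coding_calls$probe_set_id)
  if (is.na(hit)) NULL else coding_calls$call[hit]
}

#' Coding-potential verdict for a transcript
#'
#' External evidence (e.g. from a dedicated coding/noncoding classifier)
#' takes precedence when supplied. Otherwise the built-in heuristic is
#' applied to the sequence: the transcript is called coding iff its longest
#' open reading frame (ATG to stop, three forward frames) is at least
#' `min_codons` codons long AND covers at least `min_coverage` of the
#' transcript length. With neither evidence nor sequence the verdict is
#' noncoding.
#'
#' @param transcript optional single-row [transcript_table()]; when both it
#'   and `sequence` are given their lengths must agree.
#' @param sequence optional nucleotide string (IUPAC alphabet; U allowed).
#' @param external_call optional `"coding"`/`"noncoding"` verdict.
#' @param min_codons ORF length floor in codons (start codon included, stop
#'   excluded).
#' @param min_coverage minimum fraction of the transcript covered by the ORF
#'   (stop codon included).
#' @return `"coding"` or `"noncoding"`.
#' @export
coding_potential <- function(transcript = NULL, sequence = NULL,
                             external_call = NULL, min_codons = 100,
                             min_coverage = 0.3) {
  if (!is.null(external_call)) {
    if (!external_call %in% c("coding", "noncoding"))
      stop("external coding call must be 'coding' or 'noncoding'")
    return(external_call)
  }
  if (is.null(sequence) || is.na(sequence) || !nzchar(sequence))
    return("noncoding")
  seq <- toupper(gsub("U", "T", toupper(sequence)))
  if (grepl("[^ACGTRYSWKMBDHVN]", seq))
    stop("sequence contains non-IUPAC characters")
  if (!is.null(transcript) && nchar(seq) != transcript$length_nt)
    stop("sequence length does not match transcript length_nt")
  orf <- longest_orf(seq)
  if (orf$codons >= min_codons &&
      orf$span_nt / nchar(seq) >= min_coverage) "coding" else "noncoding"
}

# Longest forward-strand ORF over the three reading frames.
# codons counts ATG..(stop-1); span_nt includes the stop codon.
longest_orf <- function(seq) {
  best <- list(codons = 0L, span_nt = 0L)
  n <- nchar(seq)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    open <- NA_integer_
    for (k in seq_len(n_codons)) {
      if (is.na(open) && codons[k] == "ATG") open <- k
      if (!is.na(open) && codons[k] %in% c("TAA", "TAG", "TGA")) {
        len <- k - open
        if (len > best$codons)
          best <- list(codons = len, span_nt = 3L * (len + 1L))
        open <- NA_integer_
      }
    }
  }
  best
}

#' Mark high-confidence candidates by reference-catalogue matching
#'
#' A candidate is high-confidence iff its probe set matches exactly one
#' transcript of an external lncRNA reference catalogue — via a supplied
#' alignment table when available, otherwise geometrically: every placement
#' of the probe must fall within the exons of the reference transcript, on
#' the same strand.
#'
#' @param candidates the `candidates` table from [filter_candidates()].
#' @param reference a [transcript_table()] of reference lncRNAs (unique
#'   ids required).
#' @param alignment_table optional data.frame (`probe_set_id`,
#'   `reference_id`) of precomputed alignment hits; ids not present among
#'   candidates/reference are an error.
#' @param probes the [probe_mapping()] table (needed for the geometric
#'   fallback).
#' @return `candidates` with `high_confidence` set.
#' @export
match_reference <- function(candidates, reference, alignment_table = NULL,
                            probes = NULL) {
  if (anyDuplicated(reference$transcript_id))
    stop("reference transcript ids must be unique")
  if (!is.null(alignment_table)) {
    bad_ref <- setdiff(alignment_table$reference_id,
                       reference$transcript_id)
    bad_probe <- setdiff(alignment_table$probe_set_id,
                         candidates$probe_set_id)
    if (length(bad_ref) || length(bad_probe))
      stop("alignment table names unknown ids: ",
           paste(c(bad_ref, bad_probe), collapse = ", "))
    hits <- table(alignment_table$probe_set_id)
    n_hit <- as.integer(hits[candidates$probe_set_id])
    n_hit[is.na(n_hit)] <- 0L
    candidates$high_confidence <- n_hit == 1L
    return(candidates)
  }
  if (is.null(probes))
    stop("geometric matching needs the probe mapping table")
  pi <- match(candidates$probe_set_id, probes$probe_set_id)
  candidates$high_confidence <- vapply(pi, function(i) {
    pl <- probes$placements[[i]]
    n_match <- 0L
    for (r in seq_len(nrow(reference))) {
      ex <- reference$exons[[r]]
      ok <- all(vapply(seq_len(nrow(pl)), function(j) {
        pl$chrom[j] == reference$chrom[r] &&
          pl$strand[j] == reference$strand[r] &&
          any(ex[, 1] <= pl$start[j] & pl$end[j] <= ex[, 2])
      }, logical(1)))
      if (ok) n_match <- n_match + 1L
    }
    n_match == 1L
  }, logical(1))
  candidates
}
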