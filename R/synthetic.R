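# Seeded generators for every fixture the pipeline consumes: transcript
# length populations with known mixture structure, staged expression cohorts
# with planted stage-monotone probes, siRNA knock-down replicate designs with
# planted up/down genes, and a toy annotated genome exercising every
# filtration path. All generators are pure functions of (spec, seed).

#' Specification for the 3-component length generator
#'
#' The generative twin of the length-mixture model: a log-normal "body" of
#' short lncRNAs plus two power-law tails, split at known breakpoints. The
#' defaults mirror the study conditions used throughout the package's
#' recovery experiments: class proportions 4% / 87% / 9% and breakpoints at
#' 400 and 2,300 nt, with transcripts truncated below 200 nt (the
#' conventional lncRNA length floor).
#'
#' @param n number of lengths to draw.
#' @param proportions three non-negative class weights summing to 1
#'   (short body, middle tail, long tail).
#' @param break1_nt,break2_nt generative breakpoints in nucleotides.
#' @param body_mu,body_sigma natural-log parameters of the truncated
#'   log-normal body on `[min_nt, break1_nt]`.
#' @param tail_exponents two negative reals: iCDF log-log slopes of the
#'   middle (truncated) and long (unbounded) Pareto tails.
#' @param min_nt lower truncation in nt.
#' @return a list of class `"LengthGenSpec"`.
#' @export
length_gen_spec <- function(n = 5000,
                            proportions = c(0.04, 0.87, 0.09),
                            break1_nt = 400, break2_nt = 2300,
                            body_mu = log(300), body_sigma = 0.35,
                            tail_exponents = c(-1.2, -2.5),
                            min_nt = 200) {
  if (length(proportions) != 3L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be 3 non-negative reals summing to 1")
  if (!(min_nt < break1_nt && break1_nt < break2_nt))
    stop("need min_nt < break1_nt < break2_nt")
  if (length(tail_exponents) != 2L || any(tail_exponents >= 0))
    stop("tail_exponents must be 2 negative reals")
  structure(list(n = n, proportions = proportions,
                 break1_nt = break1_nt, break2_nt = break2_nt,
                 body_mu = body_mu, body_sigma = body_sigma,
                 tail_exponents = tail_exponents, min_nt = min_nt),
            class = "LengthGenSpec")
}

# Inverse-transform draw from a Pareto with survival exponent alpha > 0,
# truncated to [a, b] (b = Inf for the unbounded tail).
rpareto_trunc <- function(n, alpha, a, b = Inf) {
  u <- stats::runif(n)
  if (is.finite(b)) {
    sa <- a^(-alpha); sb <- b^(-alpha)
    (sa - u * (sa - sb))^(-1 / alpha)
  } else {
    a * u^(-1 / alpha)
  }
}

#' Draw transcript lengths from the 3-component mixture
#'
#' Component 1 is a log-normal truncated to `[min_nt, break1_nt]`; components
#' 2 and 3 are Pareto laws (inverse-transform sampled) on
#' `[break1_nt, break2_nt]` and `[break2_nt, Inf)` whose iCDFs are linear in
#' double-log coordinates with slopes `tail_exponents`.
#'
#' @param spec a [length_gen_spec()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `lengths` (numeric, nt) and `component` (integer 1-3
#'   class-of-origin labels, for recovery testing).
#' @export
gen_lengths <- function(spec = length_gen_spec(), seed = 1) {
  stopifnot(inherits(spec, "LengthGenSpec"))
  withr::local_seed(seed)
  comp <- sample.int(3L, spec$n, replace = TRUE, prob = spec$proportions)
  lengths <- numeric(spec$n)
  n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
  if (n1) {
    plo <- stats::plnorm(spec$min_nt, spec$body_mu, spec$body_sigma)
    phi <- stats::plnorm(spec$break1_nt, spec$body_mu, spec$body_sigma)
    u <- stats::runif(n1, plo, phi)
    lengths[comp == 1L] <- stats::qlnorm(u, spec$body_mu, spec$body_sigma)
  }
  if (n2)
    lengths[comp == 2L] <- rpareto_trunc(n2, -spec$tail_exponents[1],
                                         spec$break1_nt, spec$break2_nt)
  if (n3)
    lengths[comp == 3L] <- rpareto_trunc(n3, -spec$tail_exponents[2],
                                         spec$break2_nt)
  list(lengths = lengths, component = comp)
}

#' Specification for a staged synthetic cohort
#'
#' Emulates the structure of a staged tumor microarray cohort: `n_patients`
#' samples over INSS stages 1-4, a fraction MYCN-amplified, and
#' `n_informative` probes whose expectation moves monotonically with stage.
#' Defaults mirror a 64-sample cohort with 14/64 MYCN-amplified tumors.
#'
#' @param n_patients,n_probes cohort dimensions.
#' @param n_informative number of stage-monotone probes (planted markers).
#' @param effect_per_stage mean log-expression shift per stage step.
#' @param noise_sd residual standard deviation (log scale).
#' @param frac_mna fraction of MYCN-amplified samples.
#' @param frac_positive fraction of planted markers with a positive stage
#'   slope (the remainder get a negative slope).
#' @return a list of class `"CohortGenSpec"`.
#' @export
cohort_gen_spec <- function(n_patients = 64, n_probes = 1581,
                            n_informative = 50, effect_per_stage = 1,
                            noise_sd = 1, frac_mna = 14 / 64,
                            frac_positive = 0.8) {
  if (n_informative > n_probes)
    stop("n_informative must not exceed n_probes")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_patients = n_patients, n_probes = n_probes,
                 n_informative = n_informative,
                 effect_per_stage = effect_per_stage, noise_sd = noise_sd,
                 frac_mna = frac_mna, frac_positive = frac_positive),
            class = "CohortGenSpec")
}

#' Generate a staged expression cohort with planted markers
#'
#' Informative probes have expectation `baseline + slope * (stage - 1)` with
#' `slope = +/- effect_per_stage` (sign positive for `frac_positive` of the
#' markers); all other probes are pure noise around their baseline. Relapse
#' is drawn from a logistic model increasing in stage
#' (`plogis(-2 + 0.8 * (stage - 1))`); MYCN amplification is assigned
#' independently of the planted effects.
#'
#' @param spec a [cohort_gen_spec()].
#' @param seed integer seed.
#' @return list with `cohort` (a [cohort_matrix()] with stage, MYCN and
#'   relapse metadata) and `markers` (data.frame of planted probe ids and
#'   slopes).
#' @export
gen_cohort <- function(spec = cohort_gen_spec(), seed = 1) {
  stopifnot(inherits(spec, "CohortGenSpec"))
  withr::local_seed(seed)
  np <- spec$n_probes; ns <- spec$n_patients
  probe_ids <- sprintf("probe_%04d", seq_len(np))
  sample_ids <- sprintf("tumor_%03d", seq_len(ns))
  stage <- sample(rep_len(1:4, ns))
  mna <- stats::runif(ns) < spec$frac_mna
  relapse <- stats::runif(ns) < stats::plogis(-2 + 0.8 * (stage - 1))
  baseline <- stats::rnorm(np, mean = 7, sd = 1)
  values <- matrix(stats::rnorm(np * ns, sd = spec$noise_sd), np, ns,
                   dimnames = list(probe_ids, sample_ids))
  values <- values + baseline
  n_inf <- spec$n_informative
  slope <- numeric(0)
  if (n_inf > 0) {
    n_pos <- round(spec$frac_positive * n_inf)
    slope <- spec$effect_per_stage *
      sample(c(rep(1, n_pos), rep(-1, n_inf - n_pos)))
    values[seq_len(n_inf), ] <- values[seq_len(n_inf), ] +
      outer(slope, stage - 1)
  }
  md <- data.frame(sample_id = sample_ids, stage = stage, stage_4s = FALSE,
                   mycn_amplified = mna, relapse = relapse,
                   stringsAsFactors = FALSE)
  list(cohort = cohort_matrix(values, md),
       markers = data.frame(probe_id = probe_ids[seq_len(n_inf)],
                            slope = slope, stringsAsFactors = FALSE))
}

#' Generate a siRNA knock-down replicate experiment
#'
#' Three conditions — `control`, `siRNA_1`, `siRNA_2` — with `reps`
#' exchangeable replicates each, log2-scale values with i.i.d. replicate
#' noise. Planted genes are shifted by `+effect_log2` (up) or `-effect_log2`
#' (down) in BOTH siRNA conditions, as expected for true targets of the
#' knocked-down transcript.
#'
#' @param n_probes total probes.
#' @param de_up,de_down numbers of planted up-/down-regulated probes.
#' @param effect_log2 planted log2 shift.
#' @param reps replicates per condition (at least 3, the consensus caller's
#'   replicate criterion).
#' @param noise_sd replicate noise standard deviation (log2 scale);
#'   the default 0.1 reflects technical-replicate reproducibility.
#' @param seed integer seed.
#' @return list with `cohort` (condition labels in metadata), `up`, `down`
#'   (planted probe id vectors).
#' @export
gen_knockdown <- function(n_probes = 1000, de_up = 43, de_down = 53,
                          effect_log2 = 1, reps = 4, noise_sd = 0.1,
                          seed = 1) {
  if (de_up + de_down > n_probes)
    stop("de_up + de_down must not exceed n_probes")
  if (reps < 3) stop("need at least 3 replicates per condition")
  withr::local_seed(seed)
  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
  conditions <- rep(c("control", "siRNA_1", "siRNA_2"), each = reps)
  sample_ids <- paste0(conditions, "_r", rep(seq_len(reps), 3))
  baseline <- stats::rnorm(n_probes, mean = 8, sd = 1)
  values <- matrix(stats::rnorm(n_probes * length(sample_ids),
                                sd = noise_sd),
                   n_probes, length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
  values <- values + baseline
  shift <- numeric(n_probes)
  up <- probe_ids[seq_len(de_up)]
  down <- probe_ids[de_up + seq_len(de_down)]
  shift[seq_len(de_up)] <- effect_log2
  shift[de_up + seq_len(de_down)] <- -effect_log2
  treated <- conditions != "control"
  values[, treated] <- values[, treated] + shift
  md <- data.frame(sample_id = sample_ids, condition = conditions,
                   stringsAsFactors = FALSE)
  list(cohort = cohort_matrix(values, md), up = up, down = down)
}

#' Generate the toy annotated genome fixture
#'
#' A deterministic (seed-jittered) toy genome containing one instance of
#' every filtration path the probe-annotation cascade distinguishes:
#' a clean unique noncoding probe (retained, and uniquely matched in the
#' bundled lncRNA reference), a multi-locus probe, a probe on a
#' protein-annotated transcript, a same-strand protein-exon overlap, an
#' antisense overlap of protein exons (which must survive — the geometry of
#' an antisense lncRNA inside a coding cluster), a transcript with protein-
#' coding potential (flagged via the coding-evidence table), and a short
#' (<200 nt) transcript. The expected audit outcome of every probe is
#' enumerated in the returned `expected` table.
#'
#' @param seed integer seed (jitters coordinates only; topology is fixed).
#' @return list with `transcripts` (a [transcript_table()]), `protein_exons`
#'   (data.frame chrom/start/end/strand), `probes` (a [probe_mapping()]
#'   table), `coding_calls` (probe -> coding/noncoding evidence),
#'   `reference` (lncRNA reference transcript_table), and `expected`
#'   (probe_set_id, outcome, reasons, high_confidence).
#' @export
gen_genome_fixture <- function(seed = 1) {
  withr::local_seed(seed)
  off <- function() sample.int(500L, 1L)  # coordinate jitter

  b <- 10000L + off()                      # base of the toy locus layout
  tx <- list()
  protein_exons <- NULL
  add_pe <- function(chrom, start, end, strand)
    rbind(protein_exons,
          data.frame(chrom = chrom, start = start, end = end,
                     strand = strand, stringsAsFactors = FALSE))

  # 1. clean unique noncoding transcript, 1,500 nt, present in reference
  tx$tx_clean <- list(id = "tx_clean", gene = "g_clean", chrom = "chr1",
                      start = b, end = b + 1500L, strand = "+",
                      biotype = "unannotated")
  # 2. transcript targeted by a multi-locus probe
  tx$tx_multi <- list(id = "tx_multi", gene = "g_multi", chrom = "chr1",
                      start = b + 20000L, end = b + 21000L, strand = "+",
                      biotype = "unannotated")
  # 3. protein-annotated transcript
  tx$tx_prot <- list(id = "tx_prot", gene = "g_prot", chrom = "chr1",
                     start = b + 40000L, end = b + 42000L, strand = "+",
                     biotype = "protein_coding")
  protein_exons <- add_pe("chr1", b + 40000L, b + 42000L, "+")
  # 4. noncoding transcript whose probe overlaps a protein exon, same strand
  pe2 <- b + 60000L
  protein_exons <- add_pe("chr1", pe2, pe2 + 800L, "+")
  tx$tx_sense <- list(id = "tx_sense", gene = "g_sense", chrom = "chr1",
                      start = pe2 + 400L, end = pe2 + 1600L, strand = "+",
                      biotype = "unannotated")
  # 5. antisense transcript spanning two protein exons on the other strand
  pe3 <- b + 80000L
  protein_exons <- add_pe("chr1", pe3, pe3 + 600L, "+")
  protein_exons <- add_pe("chr1", pe3 + 2000L, pe3 + 2600L, "+")
  tx$tx_anti <- list(id = "tx_anti", gene = "g_anti", chrom = "chr1",
                     start = pe3 + 100L, end = pe3 + 2500L, strand = "-",
                     biotype = "unannotated")
  # 6. transcript with coding potential (external evidence says coding)
  tx$tx_orf <- list(id = "tx_orf", gene = "g_orf", chrom = "chr1",
                    start = b + 100000L, end = b + 101000L, strand = "+",
                    biotype = "unannotated")
  # 7. short transcript, below the 200 nt lncRNA floor
  tx$tx_short <- list(id = "tx_short", gene = "g_short", chrom = "chr1",
                      start = b + 120000L, end = b + 120150L, strand = "+",
                      biotype = "unannotated")

  transcripts <- transcript_table(
    transcript_id = vapply(tx, `[[`, character(1), "id"),
    gene_id = vapply(tx, `[[`, character(1), "gene"),
    chrom = vapply(tx, `[[`, character(1), "chrom"),
    start = vapply(tx, function(t) t$start, integer(1)),
    end = vapply(tx, function(t) t$end, integer(1)),
    strand = vapply(tx, `[[`, character(1), "strand"),
    biotype = vapply(tx, `[[`, character(1), "biotype")
  )

  probe_at <- function(t, shift = 200L, len = 300L)
    data.frame(chrom = t$chrom, start = t$start + shift,
               end = t$start + shift + len, strand = t$strand,
               stringsAsFactors = FALSE)
  probes <- probe_mapping(
    probe_set_id = c("ps_clean", "ps_multi", "ps_multi", "ps_prot",
                     "ps_sense", "ps_anti", "ps_orf", "ps_short"),
    placements = rbind(
      probe_at(tx$tx_clean),
      probe_at(tx$tx_multi),
      data.frame(chrom = "chr2", start = 5000L, end = 5300L, strand = "+",
                 stringsAsFactors = FALSE),   # second locus of ps_multi
      probe_at(tx$tx_prot),
      probe_at(tx$tx_sense, shift = 100L),    # overlaps protein exon pe2
      probe_at(tx$tx_anti, shift = 300L),     # antisense to protein exons
      probe_at(tx$tx_orf),
      data.frame(chrom = "chr1", start = tx$tx_short$start,
                 end = tx$tx_short$end, strand = "+",
                 stringsAsFactors = FALSE)
    ),
    target_transcript_id = c("tx_clean", "tx_multi", "tx_multi", "tx_prot",
                             "tx_sense", "tx_anti", "tx_orf", "tx_short")
  )

  coding_calls <- data.frame(
    probe_set_id = c("ps_clean", "ps_sense", "ps_anti", "ps_orf", "ps_short"),
    call = c("noncoding", "noncoding", "noncoding", "coding", "noncoding"),
    stringsAsFactors = FALSE
  )

  # lncRNA reference catalogue: contains tx_clean's locus only, so ps_clean
  # is the unique high-confidence match.
  reference <- transcript_table(
    transcript_id = "ref_clean", gene_id = "ref_clean", chrom = "chr1",
    start = tx$tx_clean$start, end = tx$tx_clean$end, strand = "+",
    biotype = "annotated_ncRNA"
  )

  expected <- data.frame(
    probe_set_id = c("ps_clean", "ps_multi", "ps_prot", "ps_sense",
                     "ps_anti", "ps_orf", "ps_short"),
    outcome = c("retained", "excluded", "excluded", "excluded",
                "retained", "excluded", "excluded"),
    reasons = c("", "non_unique", "protein_annotated",
                "same_strand_protein_exon_overlap", "",
                "coding_potential", "below_min_length"),
    high_confidence = c(TRUE, NA, NA, NA, FALSE, NA, NA),
    stringsAsFactors = FALSE
  )

  list(transcripts = transcripts, protein_exons = protein_exons,
       probes = probes, coding_calls = coding_calls, reference = reference,
       expected = expected)
}
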