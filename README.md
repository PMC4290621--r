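# lncscreen

Annotation, length classification and clinical screening of
lncRNA-measuring microarray probe sets.

## The problem

Affymetrix U133-generation microarrays carry thousands of probe sets
designed against ESTs and unannotated transcripts. A substantial fraction
of those measure long noncoding RNAs (lncRNAs, noncoding transcripts
≥ 200 nt), which makes two decades of archived clinical microarray data a
free resource for lncRNA biomarker discovery — *if* one can (a) decide
which probe sets genuinely and uniquely measure lncRNAs, and (b) mine
staged patient cohorts for lncRNA expression signatures with defensible
statistics. `lncscreen` implements that computational pipeline for
bioinformaticians working with tumor expression cohorts (the package's
vocabulary follows neuroblastoma: INSS stages 1–4, MYCN amplification,
relapse and 5-year survival annotations), plus the knock-down analysis
used to identify the target genes of an individual lncRNA.

## What it computes

- **Probe-set filtration cascade** (`filter_candidates()`,
  `coding_potential()`, `match_reference()`): retains a probe set iff it
  has a unique genomic placement, does not target an annotated
  protein-coding transcript, overlaps no protein exon *on the same strand*
  (antisense overlap survives — the geometry of antisense lncRNAs in
  coding clusters), shows no coding potential, and is ≥ 200 nt. Every
  exclusion carries its rule ids in a full audit table.
- **Length-class model** (`fit_mixture()`, `classify_lengths()`): the
  empirical inverse CDF of transcript lengths, in coordinates
  x = log₁₀ L, y = log₁₀ P(length ≥ L), is fitted as three quadratic
  ("extended power-law") components by exhaustive least-squares
  segmentation; the intersections of adjacent components give the nt
  cutoffs that partition lncRNAs into three length classes.
- **Stage-marker screen** (`screen_stage_markers()`): per probe,
  Mann–Whitney U *and* pooled-variance t of early (stage 1–2) vs late
  (3–4) tumors at p < 0.001 with BH q-values reported, plus a Kendall
  τ-b filter |τ| > 0.25 against ordinal stage.
- **NSC/PAM signature** (`nsc_train()`, `nsc_predict()`,
  `cluster_signature()`): nearest-shrunken-centroid classifier
  d_ik = (x̄_ik − x̄_i)/(m_k(s_i + s₀)), soft-thresholded by Δ chosen via
  stratified cross-validation, applied unchanged to evaluation cohorts;
  signature probes clustered on 1 − τ distance.
- **Knock-down DE caller** (`call_de()`): a probe is a consensus target
  iff, in *both* independent siRNA conditions: t-test p < 0.05, median
  fold change beyond 1.3 (or 1.4), and ≥ 3 replicates beyond the control
  median in the fold-change direction.
- **Synthetic-data generators** (`gen_lengths()`, `gen_cohort()`,
  `gen_knockdown()`, `gen_genome_fixture()`): seeded fixtures with planted
  ground truth for every stage of the pipeline.

See `vignettes/lncscreen-methods.Rmd` for the full model descriptions,
parameter rationale and numerical safeguards.

## Worked example

Simulate a staged 64-patient cohort (14/64 MYCN-amplified, 1,581 probes,
50 planted stage-monotone markers at twice the noise sd), screen the
non-amplified subgroup, and train a signature:

```r
library(lncscreen)

g <- gen_cohort(cohort_gen_spec(n_patients = 64, n_probes = 1581,
                                n_informative = 50, effect_per_stage = 2),
                seed = 7)
screen <- screen_stage_markers(g$cohort, restrict = "non_mna")
sum(screen$selected)
#> [1] 51
sum(g$markers$probe_id %in% screen$probe_id[screen$selected])
#> [1] 50
head(screen[screen$selected, c("probe_id", "p_mw", "p_t", "tau")], 3)
#>     probe_id         p_mw          p_t        tau
#> 1 probe_0001 7.335659e-09 1.215336e-12 -0.8142009
#> 2 probe_0002 3.307435e-09 5.276408e-16 -0.8177996
#> 3 probe_0003 2.947564e-09 5.369360e-14  0.8267963
```

All 50 planted markers are recovered (plus one chance hit among the 1,531
null probes); the τ column carries the stage-correlation sign of each
marker. The selected probes then feed the classifier:

```r
md  <- g$cohort$metadata
sub <- subset_cohort(g$cohort, probes = screen$probe_id[screen$selected],
                     samples = md$sample_id[!md$mycn_amplified])
fit <- nsc_train(sub, ifelse(sub$metadata$stage <= 2, "early", "late"),
                 seed = 1)
c(delta = fit$chosen_delta, features = length(fit$model$surviving_features),
  cv_accuracy = fit$cv_accuracy)
#>       delta    features cv_accuracy
#>    4.778097   34.000000    1.000000
```

The parsimony rule shrinks the 51-probe screen hit list to a 34-feature
signature that separates early from late tumors with cross-validated
accuracy 1.00 on this (deliberately strong-effect) synthetic cohort.

The length model works the same way from a length vector:

```r
f <- fit_mixture(gen_lengths(length_gen_spec(), seed = 7)$lengths)
f
#> MixtureFit: 3 component(s), n = 5000, SSE = 0.2356
#> cutoffs (nt): 402, 2163
#> class proportions: 0.048, 0.853, 0.098
```

The fitted cutoffs recover the generative breakpoints (400 / 2,300 nt)
within a few percent, and `classify_lengths()` then bins any length vector
into `below_min` / `class1` / `class2` / `class3`.

A thin command-line wrapper over the same functions lives at
`inst/cli/lncscreen.R` (subcommands `simulate`, `run-annotation`,
`run-biomarker`, `knockdown-de`, each taking a YAML config).

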