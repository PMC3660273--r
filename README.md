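# ffpetconcord

Concordance analysis of gene-expression profiling workflows for
formalin-fixed, paraffin-embedded tissue (FFPET) against matched
fresh-frozen (FF) samples on short-oligonucleotide microarrays.

Most archival tumor material exists only as FFPET, in which RNA is
fragmented, chemically modified and 3'-biased. Before FFPET profiles can be
trusted for biomarker work, a workflow has to be scored against the FF gold
standard: how many of the FF findings does it recover (sensitivity), and
how many findings does it invent (specificity)? This package implements
that evaluation end to end for people developing or assessing FFPET
expression workflows — including the in-silico array re-annotation and the
synthetic matched-cohort generator needed to test every step against known
truth.

## What it computes

For matched ER+/ER- breast-tumor cohorts (the default design: 8 + 8 pairs,
each tumor split into mirrored FF and FFPET sections):

* **Probe-set revision.** Every 25-mer probe is re-mapped against the
  reference transcriptome (both orientations, Hamming matching); probe sets
  are split into *unique* (kept, with only uniquely matching probes
  retained), *nonunique* and *mismatched*, and the *complete-mismatch*
  blank sets (no hit anywhere at up to 3 mismatches) are identified.
* **Expression indices** via the RMA triplet: normal + exponential
  convolution background correction, quantile normalization, and
  median-polish summarization `log2 I_ps ≈ μ + α_p + e_s` (probe affinity
  `α_p`, expression index `e_s`), run per preparation/kit cohort.
* **QC metrics.** Limit of blank `LOB = Q95(blank expression)` per sample;
  percent present calls (`expression > LOB`); percent genes with
  inconsistent probe sets (median pairwise Pearson r ≤ 0.5); matched-pair
  correlations; and the in-silico 3'/5' intensity ratio of a tiled control
  transcript (≈ 1 for intact RNA, rising with degradation).
* **Concordance.** Per probe set, effect sizes
  `Δ = mean log2 expr(ER+) − mean log2 expr(ER−)` in FF and FFPET are
  classified at the 2-fold threshold into TP / TN / FN / FP / WP
  (wrong-positive: relevant both, direction flipped), giving

      sensitivity = 100·TP/(TP+FN+WP),   specificity = 100·TN/(TN+FP)

  globally and within |Δ_FF| bins, plus pooled-variance probe-set t-tests
  and a Monte-Carlo power estimate for the two-group design.
* **PCA** of samples ("super genes") for cluster comparison between
  preparations.
* A **synthetic-data generator** producing the whole study — reference
  transcriptome, flawed array design (nonmatching, cross-hybridizing and
  blank probe sets), and matched FF/FFPET intensity cohorts under a
  per-kit degradation model (log2-additive attenuation, linear 3' decay,
  extra noise, dropout) — with complete ground truth and byte-identical
  reproducibility under a fixed seed.

See `vignettes/methods.Rmd` for the models, parameter meanings, defaults
and design decisions.

## Worked example

```r
library(ffpetconcord)

cfg <- sim_config(seed = 7, n_genes = 60, n_complete_mismatch_sets = 25)
cfg
#> Matched FF/FFPET cohort simulation config
#>   60 genes, 8+8 matched pairs (ER+/ER-), 3 kits (nugen, affy2c, wta)
#>   DE fraction 0.20, |effect| in [1.20, 3.00] log2; seed 7

study <- simulate_study(cfg)
revised <- revise_design(study$design, study$reference)
revised <- with_complete_mismatch_sets(revised, study$design, study$reference)
revised
#> revised_design: 117 probe sets (92 unique / 0 nonunique / 25 mismatched),
#> 940 of 1287 probes retained, 25 blank control sets

expr_ff    <- expression_index(study$cohort$ff, revised)$expression
expr_nugen <- expression_index(study$cohort$ffpet$nugen, revised)$expression

rec <- concordance_records(expr_ff, expr_nugen, study$cohort$sheet,
                           exclude = revised$complete_mismatch_set_ids)
sensitivity_specificity(rec)
#> FFPET vs FF concordance over 92 probe sets
#>   sensitivity 100.0%, specificity 100.0%
#>   counts: TP=17 TN=75 FN=0 FP=0 WP=0
```

The mildly degraded `nugen`-style cohort recovers all 17 FF-relevant probe
sets with no false positives. The heavily degraded `wta`-style kit on the
same tumors collapses:

```r
expr_wta <- expression_index(study$cohort$ffpet$wta, revised)$expression
rec_wta <- concordance_records(expr_ff, expr_wta, study$cohort$sheet,
                               exclude = revised$complete_mismatch_set_ids)
sensitivity_specificity(rec_wta)
#> FFPET vs FF concordance over 92 probe sets
#>   sensitivity 5.9%, specificity 100.0%
#>   counts: TP=1 TN=75 FN=16 FP=0 WP=0
```

Quality metrics tell the same story. Matched-pair correlations of log2
expression: median r = 0.98 (nugen) versus 0.70 (wta). The in-silico 3'/5'
ratio of the control transcript is 0.98 in FF (intact RNA ≈ 1) and 3.15 in
the nugen-style FFPET cohort:

```r
ctrl <- study$truth$control
mean(three_prime_ratio(study$cohort$ff, study$design,
                       ctrl$transcript_id, ctrl$length))
#> [1] 0.98
mean(three_prime_ratio(study$cohort$ffpet$nugen, study$design,
                       ctrl$transcript_id, ctrl$length))
#> [1] 3.15
```

`run_pipeline("config.yaml", "outdir")` chains all stages (simulate →
revise → preprocess per cohort → qc → concordance → pca) and writes every
stage artifact plus a machine-readable `report.json`; a default
configuration ships at `inst/extdata/default_config.yaml` and a thin CLI
wrapper at `inst/scripts/ffpetconcord.R`.

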