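---
title: "Models and methods behind ffpetconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ffpetconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Archival tumor material is almost always preserved as formalin-fixed,
paraffin-embedded tissue (FFPET). Formalin fixation fragments and chemically
modifies RNA, so expression profiles measured from FFPET on
short-oligonucleotide arrays are noisier, globally attenuated and biased
toward the transcript 3' end relative to matched fresh-frozen (FF) tissue,
the gold-standard RNA source. Whether an FFPET workflow is usable for
biomarker discovery is therefore an empirical question: how much of what the
FF arrays find does the FFPET arm recover, and how much does it invent?

`ffpetconcord` implements the full evaluation pipeline for that question:

1. a **synthetic cohort generator** producing matched FF/FFPET breast-tumor
   pairs (8 ER+ and 8 ER- by default) with known ground truth;
2. **in-silico probe re-annotation** of an Affymetrix-style array design
   against a reference transcriptome, and probe-set revision;
3. **RMA-style expression indices** (convolution background correction,
   quantile normalization, median-polish summarization);
4. **quality metrics**: limit of blank (LOB) and present calls, probe-set
   consistency, matched-pair correlation, and an in-silico 3'/5' ratio;
5. **concordance scoring** of each FFPET workflow against FF
   (sensitivity/specificity over relevance quadrants), plus a probe-set
   t-test and a Monte-Carlo power estimate;
6. **PCA** of samples; and
7. a one-call **pipeline** (`run_pipeline()`) that chains all stages from a
   single YAML configuration.

Because no public per-probe data accompany the study design this package
addresses, the generator is a first-class, tested component: every
downstream claim is validated against planted truth.

# The generative model

## Latent expression and the FF arm

Each tumor `s` contributes one latent log2 expression value per gene `g`,
shared by its mirrored FF and FFPET sections:

```
e_gs = baseline_g + delta_g * [s is ER+] + tissue_gs
```

with `baseline_g ~ N(baseline_mean, baseline_sd)` and
`tissue_gs ~ N(0, tissue_sd)`. A fraction `frac_de_genes` of genes carries a
signed ER effect with `|delta_g|` uniform on `effect_range` (default
[1.2, 3] log2); all other genes have `delta_g = 0`. A fraction
`frac_silent_genes` of the non-DE genes is not expressed in the tissue at
all and emits pure background — this matters more than it may appear (see
*Numerical behavior* below).

The FF probe-level log2 signal adds a fixed per-probe affinity
`a_p ~ N(0, probe_affinity_sd)` and measurement noise
`N(0, measurement_sd_ff)`. Intensities are emitted on the linear scale as
`2^signal + background`, with `background ~ N(background_mean,
background_sd)` truncated at zero, and floored at 1 so downstream logs are
always defined.

## Planted design flaws

The probe-set revision needs known truth, so the generator plants the flaws
the re-annotation is meant to find:

* **nonmatching probes** — a fraction of probes replaced by random 25-mers
  verified absent from the reference at Hamming distance <= 3 on both
  orientations; they emit background only;
* **cross-hybridizing probes** — a fraction of probes whose target 25-mer
  is copied into a second gene's transcript (the reference is mutated
  accordingly); they emit the sum of both genes' linear signals;
* **complete-mismatch control sets** — whole probe sets of verified-absent
  probes, the blank distribution behind the limit of blank.

One transcript per gene keeps the unique/nonunique truth unambiguous;
multi-gene matching arises only from the planted cross-hybridization.
Cross-hybridization planting sites are chosen so no other probe's window is
touched, keeping every probe's truth class exact.

## The degradation model

FFPET degradation per kit is additive in log2 space and linear in the
probe's distance `d` from the transcript 3' end:

```
signal_FFPET = signal_FF - global_attenuation - three_prime_decay * d
               + N(0, extra_noise_sd)
```

with probes additionally dropped to background with probability
`dropout_prob`. This is the simplest model that reproduces the 3' bias of
oligo-dT-primed amplification from fragmented RNA, and it has a closed-form
3'/5' ratio. The FFPET arm reuses the FF draws (latent expression, probe
affinities, measurement noise, background), so an all-zero profile gives a
byte-identical FFPET matrix — the identity limit the acceptance checks rely
on. The three bundled presets (`nugen` < `affy2c` < `wta` in severity) are
free parameters chosen to produce clearly separated cohort quality, not
measured kit properties.

All randomness derives from one master seed by fixed offsets (reference:
`seed`, design: `seed + 1`, cohort: `seed + 2`, kit `i`: `seed + 100 + i`),
using the Mersenne-Twister generator with inversion sampling for normal
deviates, so every artifact is byte-identical across runs and platforms.

## What the generator does and does not emulate

It emulates the statistical structure the analysis assumes: matched pairs
sharing biology, probe-level affinity structure, additive optical
background, design flaws with exact truth, and kit-graded degradation. It
does **not** emulate image-level artifacts beyond what the spatial-masking
QC needs, sequence-thermodynamic cross-hybridization, fragment-length
distributions, or batch/chemistry effects. Passing tests therefore show the
*pipeline* behaves correctly under the stated model; they do not certify
any particular real kit.

# Probe re-annotation and probe-set revision

Every probe is matched against the reference transcriptome on both
orientations with `Biostrings`-based Hamming matching (0-based, half-open
windows). Probes are classified at zero mismatches: `MATCH_UNIQUE` (all
perfect hits in one gene), `MATCH_MULTI`, or `NO_MATCH`. A probe set stays
**unique** if at least `min_retained` (default 3) probes are
`MATCH_UNIQUE` — only those probes are retained; otherwise it is
**nonunique** if any probe is multi-gene, else **mismatched**. The floor of
3 is our choice (median polish needs at least two probes; three adds
robustness); the alternative reading — any multi-gene probe demotes the
whole set — discards sets that are rescuable by dropping bad probes, which
is precisely the phenomenon the revision exists to exploit.

`build_complete_mismatch_set()` returns the sets whose probes have no hit
anywhere at up to 3 mismatches; these blanks are summarized like ordinary
sets and feed the LOB. The matcher itself is checked exhaustively against
an independent brute-force Hamming scan in the test suite (all tolerances
0-3, both orientations).

# Expression indices

The cited expression-index method for this workflow is not fully specified
anywhere recoverable, so this package implements the classic RMA triplet as
its documented interpretation, behind the single `expression_index()` entry
point so variants can be swapped:

1. **Spatial masking** (`mask_spatial_outliers()`): the chip is cut into a
   `zone_grid^2` grid; per zone and sample, probes further than `k_mad`
   MADs from the zone median (log2) are masked. Per-sample optical noise
   (SD of the lowest 2% of log2 values) and the zone-median surface are
   reported.
2. **Convolution background correction** (`background_correct()`): per
   sample, observed intensity is modeled as signal + background with
   `signal ~ Exp(alpha)` and `background ~ N(mu, sigma)`; each value is
   replaced by the closed-form posterior mean (`rma_posterior_mean()`,
   validated against numerical integration). Parameters are estimated from
   the intensity density: mode as `mu`, left-tail spread as `sigma`,
   right-tail mean as `1/alpha`. A constant column falls back to
   `(min - 1)` subtraction with a warning.
3. **Quantile normalization** (`quantile_normalize()`): each column's
   sorted values are replaced by the across-column mean of order
   statistics; ties receive the mean of their assigned quantile values
   (average ranks, linearly interpolated), so `[1,2,3]` and `[4,5,6]` both
   become `[2.5, 3.5, 4.5]`. Masked entries are excluded and placed back by
   rank interpolation.
4. **Median polish** (`median_polish()`, `summarize_probe_sets()`): per
   retained probe set, the log2 probe x sample submatrix is decomposed into
   overall + probe + sample effects (tolerance 1e-6, at most 100 sweeps,
   the classic stopping rule on the absolute-residual sum). Expression is
   overall + sample effect; the probe affinities are the row effects
   re-centered to sum to zero.

Summarization runs per preparation/kit cohort separately, matching how
amplification methods are processed independently in practice;
`run_pipeline()` enforces this.

# QC metrics

* **LOB**: per sample, the 95th percentile of the blank sets' expression,
  using linear interpolation between order statistics (R's quantile type
  7) — fixed so that blanks `1..20` give exactly 19.05.
* **Present calls**: percentage of non-blank sets whose expression exceeds
  the sample's LOB. The pooled "sets above LOB" number needs a rule the
  original column headings leave open; we compare each set's median
  expression across samples with the median LOB.
* **Consistency**: for genes with two or more retained sets, the median
  pairwise Pearson correlation across samples; a gene is inconsistent when
  it does not exceed 0.5. The median reduces to the single pairwise r for
  the common two-set case and is robust for three.
* **Matched-pair correlation**: Pearson r over shared probe sets per
  FF/FFPET pair, summarized by median and quartiles.
* **3'/5' ratio**: mean linear intensity of the control transcript's
  probes in its 3'-most third over the 5'-most third. The generator ships a
  dedicated, densely tiled control transcript (1998 nt, one probe every 18
  nt by default) because the ratio of two tercile means inherits the
  sampling noise of the fixed probe affinities — precision scales with the
  number of control probes, not with the number of samples.

# Concordance scoring

Effects are differences of mean log2 expression, ER+ minus ER-. With FF as
the gold standard (100% sensitivity and specificity by definition), each
probe set falls into a quadrant at the 2-fold threshold (`|effect| > 1`
log2): TP (relevant in both, same direction), WP (relevant in both,
flipped direction), FN (FF only), FP (FFPET only), TN (neither).

```
sensitivity = 100 * TP / (TP + FN + WP)
specificity = 100 * TN / (TN + FP)
```

Two conventions are ours and exposed as options: WP counts against
sensitivity (a sign-flipped finding is not a recovery; the case did not
occur in the motivating data, so the literature does not constrain it), and
specificity is the standard TN/(TN+FP) — the only reading under which a
perfect workflow scores 100%. Binned estimates recompute both within
`|effect_FF|` bins (default edges 1, 1.5, 2.5) to show that larger FF
effects survive degradation more often. The probe-set t-test is the
pooled-variance two-sample t (Welch behind a flag), and
`power_simulation()` estimates its power by Monte Carlo; the within-group
SD must be supplied by the user, because power claims are meaningless
without a variance assumption. The estimate is validated against the
noncentral-t closed form.

## Predicting the false negatives

A purely global log2 attenuation *cancels* in a group difference, so it
cannot by itself shrink an effect. What shrinks effects is the background
floor: once the attenuated signal approaches the optical background, the
measured log2 expression flattens and the group difference compresses.
`predicted_ffpet_effect()` turns this into a closed-form prediction: the
noise-free degraded signal of every retained probe is pushed through the
convolution-model posterior mean with the generative background parameters,
and — because the compression curve is convex near the floor — averaged
over the generative spread of probe-level signals by Gauss-Hermite
quadrature. Predicted false negatives are the FF-relevant sets whose
predicted FFPET effect magnitude falls below the threshold; the test suite
shows they overlap the observed FN set (overlap coefficient
`|A∩B| / min(|A|,|B|)` above 0.8) at low noise, and that sensitivity is
non-increasing along a five-point attenuation grid in which only the
attenuation varies (one kit per simulation call, so all noise draws are
shared across grid points).

# Numerical behavior worth knowing

* **Quantile normalization compresses desk-scale effects.** With a few
  hundred probe sets of which ~20% carry strong DE, the ER+ and ER- columns
  genuinely differ in distribution, and forcing a common distribution
  shrinks individual effects beyond the background compression. On real
  54k-set arrays the DE mass is relatively far smaller and the artifact is
  mild. Tests therefore check global calibration (regression slope near 1,
  high correlation with truth) on the full pipeline and per-gene recovery
  on the normalization-free summarization route.
* **The background estimator needs background.** The density-mode estimate
  of `mu` assumes a visible population of background-level probes. A
  simulated chip where every gene is expressed breaks that assumption and
  over-subtracts; the default configuration keeps 30% of genes silent,
  which is also biologically sensible for any one tissue.
* **The 3'/5' ratio saturates.** Under heavy attenuation or decay both
  terminal terciles approach the background floor and the ratio bends back
  toward `(signal_3' + bg)/bg` and ultimately toward 1. Monotonicity in the
  decay rate holds in the unsaturated regime; QC interpretation of very
  large ratios should treat them as "beyond quantification".
* **Floors and degenerate inputs.** Linear intensities are floored at 1
  before any log; zero-variance t-tests and empty blank sets are hard
  errors rather than silent zeros; empty concordance denominators report
  `NA`, never 0; masked-out probe sets yield `NA` expression with a count.

# Problem sizes

The default configuration simulates 200 genes (~270 probe sets plus 60
blank controls and a tiled QC transcript) across 16 tumors and three kits;
unit tests run reduced cohorts of 30-100 genes. The acceptance script uses
60 genes with 25 blanks and a zero-degradation kit for the identity and
intact-RNA checks (with the QC transcript tiled every 9 nt for a precise
ratio), and 40 genes with 200 blank sets for the LOB check. These sizes are
the package's choices for a complete desk-scale exercise of every code
path; all of them are configuration fields, and nothing in the method
depends on scale.

# Known limitations

* The expression index is the classic RMA triplet; the modified variant the
  motivating workflow used could differ in its normalization details.
* The degradation model is phenomenological plumbing: additive, linear in
  3' distance, with independent dropout. Real FFPET degradation depends on
  fragment-length distributions, fixation chemistry and storage history.
* Probe matching is transcriptome-only Hamming matching (a genomic FASTA
  can be folded in as pseudo-transcripts); there is no spliced alignment
  and no thermodynamic cross-hybridization model.
* Quadrant scoring compares point estimates of effects; it inherits their
  compression and makes no attempt at shrinkage or moderated variance.
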