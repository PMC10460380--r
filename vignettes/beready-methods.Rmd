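---
title: "Methods: receptivity dating with a targeted UMI panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptivity dating with a targeted UMI panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beready)
```

## The problem

The endometrium is receptive to embryo implantation only during a limited
window (the window of implantation, WOI), nominally around seven days after
the LH peak. In some women the window is displaced in time, which is one
proposed cause of recurrent implantation failure (RIF) after IVF.
Transcriptomic dating estimates a biopsy's position in the cycle from the
expression of receptivity-associated genes, so that embryo transfer can be
timed to the individual WOI.

`beready` implements a complete dating pipeline for targeted ligation-probe
sequencing panels (TAC-seq-style assays): single-molecule counting through
unique molecular identifiers (UMIs), housekeeper normalisation, and a
hierarchical centroid classifier over the menstrual-cycle phase groups of a
development cohort, with five ordered output classes — pre-receptive,
early-receptive, receptive, late-receptive, post-receptive. Early- and
late-receptive are *transitionary* classes: they are never training labels
and arise only when a test sample sits between two adjacent reference
centroids. Calls in the early/receptive/late range are read as normal WOI
variability; pre- or post-receptive calls at an expected mid-secretory
sample indicate a displaced WOI.

## From reads to molecule counts

Each probe complex carries the ligated target sequence flanked by a
2 × 4 bp UMI. The counter assigns a read to the panel target with the
minimal Hamming distance over the fixed-length target region, accepting up
to 5 mismatches (inclusive); ties at the minimal distance are discarded as
ambiguous rather than broken arbitrarily, and `N` bases count as
mismatches. Hamming distance (no indels) is appropriate because ligation
probes produce fixed-length inserts. Reads sharing a (target, UMI) pair are
PCR copies of one molecule: the molecule count of a target is the number of
distinct UMIs with at least `umi_read_threshold` supporting reads
(default 1). Raising the threshold can only lower counts, which the test
suite asserts as a monotonicity property. No 1-edit UMI merging is applied:
exact UMI identity defines a molecule, and the threshold is exposed because
deeper applications of the same chemistry use stricter values.

The default read layout is `[UMI-4][target][UMI-4]` with the molecule key
being the 8-mer concatenation; the layout object is configurable for other
probe designs.

## Normalisation

Per sample, every gene count is divided by the geometric mean of the four
housekeeper counts (SDHA, CYC1, TBP, HMBS in the default panel), computed
in log space. This removes library-size effects exactly: multiplying a
sample's whole row by any positive constant leaves its normalised profile
unchanged. A zero housekeeper count signals assay failure; the sample is
excluded (QC fail) rather than pseudocounted. For statistical testing the
shifted logarithm `ln(x + 1)` is applied to normalised values; the shift
constant is configurable. On the model path, values are normalised and then
z-scored per gene with development-set parameters — without a log transform
by default, matching the literal model description; `log_before_scale`
enables the alternative ordering, and the transform-state flag on the
matrix container enforces that the two paths cannot be mixed accidentally.

## The classifier

Training maps cycle phases onto three reference classes (proliferative and
early-secretory → pre-receptive; mid-secretory → receptive;
late-secretory → post-receptive) and then:

1. normalises and scales the development matrix (test samples always reuse
   the development centre/scale);
2. computes a PCA and retains `k` components by Horn's parallel analysis
   (100 iterations, 0.05 quantile): the null eigenvalues come from
   independently permuting each column of the observed matrix, and `k` is
   the number of leading observed eigenvalues above the per-component null
   95th percentile, floored at 1. Column permutation is preferred over
   Gaussian resampling because it preserves each gene's marginal
   distribution;
3. forms per-class centroids of the projected training samples and a pooled
   within-class covariance in PC space with a ridge
   `1e-6 · trace/k` on the diagonal. The pooled form is used because
   per-class covariances are unstable at the 10–18 samples per class
   typical of development cohorts.

A test sample is projected with the stored eigenvectors and its squared
Mahalanobis distance `d² = (x − c)ᵀ Σ⁻¹ (x − c)` to each centroid is
computed. Under the Gaussian model `d²` is χ²(k) distributed, which gives
an outlier gate: by default a sample whose *upper*-tail probability falls
below 0.025 for every class is flagged as distant from all references (the
distance-based outlier notion); the literal lower-tail rule, which flags
samples unusually *close* to a centroid, is preserved via
`outlier_tail = "lower"`. Outliers are still classified but flagged for
cautious interpretation.

The decision is hierarchical and exclusive. Stage 1 finds the closest
reference class; stage 2 selects, among the temporally adjacent pairs
containing it (pre/receptive and receptive/post), the pair with the smaller
summed `d²`, and computes the relative probability
`p = exp(−d²_a/2) / (exp(−d²_a/2) + exp(−d²_b/2))` — the Gaussian-kernel
likelihood ratio, the canonical choice under the model's own Gaussian
assumption, evaluated through `plogis((d²_b − d²_a)/2)` for numerical
stability. If the leading class's probability reaches the upper boundary
(default 0.75) the call is that reference class; otherwise the call is the
transitionary class between the pair. The boundaries `(0.25, 0.75)` are
configurable and recorded in every report; a sample exactly equidistant
between pre-receptive and receptive is by construction early-receptive.
When pre- and post-receptive are jointly closest (a pathological tie), the
pair containing receptive is preferred — the clinically conservative
in-range reading.

## Evaluation machinery

*Cross-validation.* Stratified fivefold cross-validation repeated 100
times: partitions are redrawn (rejection sampling) until every test fold
contains at least one sample of each reference class; the entire model —
scaling, Horn's `k`, centroids, covariance — is refitted on each training
split so nothing leaks from the full data; held-out samples receive the
most probable reference class. Macro accuracy is the unweighted mean of
per-class recall averaged over repeats (micro accuracy is reported
alongside). The permutation control redraws the label permutation in every
repeat; a single fixed permutation can correlate by chance with real
cluster structure and systematically bias the null away from 1/3.

*Concordance accounting.* Predictions are tabulated against the expected
collection phase: early-secretory expects pre-receptive, late-secretory
expects post-receptive, and mid-secretory accepts anything in the
early/receptive/late range (transitionary calls at the expected receptive
window count as normal variability, not displacement). Displacement is any
call outside the expected set; percentages are exact integer ratios.

*Proportion and expression tests.* The displaced-WOI proportions of two
cohorts are compared with a lower-tailed Fisher's exact test (exact
hypergeometric tail, validated against exhaustive enumeration for all
tables with `N ≤ 30`). Per-gene differential expression uses Welch's
t-test by default (the pooled-variance form is a flag) with Bonferroni
correction by default and Benjamini–Hochberg as an option — both are
offered because methods sections and results sections in this field
commonly mix the two conventions. Two-factor designs (phase × condition)
are tested per gene with a two-way ANOVA; the interaction F-test uses type
II sums of squares, which is invariant to cell imbalance for the
highest-order term and is recorded in the output metadata.

## The synthetic-data generator

No patient-level data ships with the package, so every statistical claim is
exercised on synthetic cohorts with known ground truth. The default
configuration (`default_md_like_config()`) emulates a development cohort of
63 samples (18 proliferative, 18 early-, 17 mid-, 10 late-secretory) over a
72-gene panel: 4 housekeepers with phase-constant means (150/300/80/120),
11 named WOI genes and 57 placeholder biomarkers. Biomarker means follow a
3-latent-factor structure on the log scale — a dominant temporal factor
(phase scores −1.2, −0.9, 0.3, 1.4, keeping proliferative and
early-secretory adjacent as they jointly form the pre-receptive class) and
two weaker shape factors — so the phases separate in a few principal
components (well beyond four pooled standard deviations along the dominant
factor) and Horn's analysis has genuine low-rank structure to find.
Counts are negative binomial (size 20, a moderate overdispersion typical of
targeted expression panels; `Inf` gives the Poisson limit) around
`library factor × phase mean`, with a log-normal library factor
(σ = 0.35). Because housekeeper means are phase-constant, geometric-mean
normalisation is exactly the right de-noising for the library factor.

The read simulator emits `[UMI][target][UMI]` reads per true molecule with
a uniform UMI, a geometric PCR-duplicate count (mean 5) and per-base
substitution errors (default 0.002) confined to the target region. UMI
bases are emitted error-free: a substituted UMI base would mint a phantom
molecule and silently break the ground-truth accounting, whereas
target-region errors exercise the mismatch-tolerant assignment exactly the
way sequencing noise does. A warning cites the birthday bound when any
gene's molecule count makes UMI collisions non-negligible (> 1%).

What passing on these data does *not* show: the generator has independent
genes given the latent factors, no batch effects, no RNA-degradation
gradient, no probe-efficiency differences, and cluster separations chosen
to represent a clean development cohort. Accuracy numbers on it demonstrate
correctness of the machinery (no leakage, calibrated nulls, exact
recovery), not expected clinical performance.

## Reproduced versus substituted results

The concordance and displacement percentages of the published validation
and RIF tables (98.2%, 1.8%, 23.1%, 15.9%) and the Fisher p-value
comparing the displaced proportions (0.012) are recomputed exactly from
the printed prediction counts, which are inputs the package can consume.
The published 98.8% cross-validation accuracy cannot be reproduced without
the original cohort (available only on request); the acceptance suite
substitutes properties on the synthetic cohort — CV macro accuracy ≥ 0.95,
a permutation null consistent with 1/3, and ≥ 95% held-out recovery to the
generating class or its adjacent transitionary class. Problem sizes
(63-sample development set, 100 CV repeats, 100 held-out draws, 100 Horn
seeds) are chosen as the smallest sizes at which these properties are
statistically meaningful.

## Numerical choices and limitations

- Geometric means in log space; doubles in model files are serialised as
  17-significant-digit strings so a reloaded model classifies
  bit-identically.
- The scaling step drops genes whose development-set standard deviation is
  below `1e-10 · max(|mean|, 1)` — exact zeros plus floating-point-level
  constants (e.g. a lone housekeeper after normalisation).
- Horn's permutations are seeded; fitting is otherwise deterministic, and
  identical inputs plus seed give bit-identical classifications.
- The relative-probability functional form, the transitionary boundaries
  and the outlier tail direction are modelling choices exposed as
  parameters and recorded in every report; the defaults are stated above.
- The pipeline assumes demultiplexed per-sample FASTQ input, single-end
  fixed-length inserts, and no indel errors; paired-end merging and
  quality-aware matching are out of scope.
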