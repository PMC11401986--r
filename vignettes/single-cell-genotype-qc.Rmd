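---
title: "Methods: quality control and confidence rescoring of single-cell SNP-array genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and confidence rescoring of single-cell SNP-array genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`scgeno` operates on batches of Illumina genotype-call (GTC) files plus
three metadata artifacts: a SNP manifest (marker names, chromosome tokens,
positions, intensity-only flags), a genotype-cluster file (per-SNP AA/AB/BB
cluster statistics in the MA plane), and a user sample sheet mapping sample
ids to GTC paths with `individual` and `family` metadata. `assemble_table()`
joins them into one long data frame with a row per (sample, SNP) — the
single container every later stage consumes and extends. IDAT parsing and
the vendor's IDAT-to-GTC conversion are out of scope; GTC is the entry
format.

The GTC codec implements the publicly documented little-endian
table-of-contents layout, restricted to the entries this pipeline needs
(genotypes, GenCall scores, raw X/Y, normalization transforms, sample
name) plus a per-record transform-index table. Manifest and cluster files
are supported in a tabular TSV dialect and a small length-prefixed binary
dialect carrying identical fields; the full vendor BPM/EGT layouts hold far
more than this pipeline consumes and are not reproduced. Unknown GTC
table-of-contents entries are skipped with a warning so files from newer
writers still load; truncated or malformed sections are format errors
naming the byte offset.

## Intensity normalization

Raw two-channel intensities are normalized by the six-parameter affine
transform in the vendor reference order: subtract the channel offsets,
rotate by `theta`, remove the shear from the first coordinate, divide by
the per-axis scales. Negative results are clamped to zero. The clamp is a
deliberate numerical choice: the MA transform takes logarithms, and a
pseudo-count only protects against zeros, not negatives. The algebraic
inverse (`invert_normalization()`) omits the clamp and is exact on interior
points to ~1e-9 relative error, which the test suite asserts; it is also
how the simulator manufactures raw intensities that normalize onto a
target point.

## MA features

For intensities `(x, y)` the features are `m = log2(x + eps) - log2(y + eps)`
and `a = (log2(x + eps) + log2(y + eps)) / 2`, computed on both the raw and
the normalized channels (four appended columns: `m_raw`, `a_raw`, `m`,
`a`). Two conventions are explicit configuration because the field uses
several:

* **Log base 2.** It is the microarray convention and makes the observed
  homozygous ridges at `m = +/-4` correspond to a 16:1 channel ratio.
* **Pseudo-count `eps = 1`** raw-intensity unit, added before every log so
  zero intensities stay finite. One unit is negligible against typical
  signal (hundreds to thousands of units) and only matters near zero,
  which is where protection is needed.

No-call records keep their MA features: the scorer needs them for
diagnostics, and dropping rows here would silently change every
denominator downstream.

## QC summaries

`callrate()` reports, per group, the proportion of each genotype class
over *all* records including no-calls, so proportions sum to one.
`heterozygosity()` reports the AB fraction among *called* genotypes only.
The two denominators are deliberately different contracts: the first
describes assay yield, the second genotype composition; mixing them makes
haploid ADI rates uninterpretable. Groups with zero called genotypes
report `NA` rather than 0 — absence of evidence, not evidence of absence.

`genotype_pca()` uses only SNPs called in every sample (complete cases, no
imputation), codes genotypes as allele-B dosage (AA = 0, AB = 1, BB = 2),
centres columns and does not variance-scale them (dosage units are already
commensurate). Dosage coding rather than one-hot indicators is the
standard genetics convention and was chosen here as the default; it keeps
one column per SNP and makes PC loadings interpretable as allele effects.
Run per chromosome the same decomposition can flag aneuploid chromosomes;
run on the whole table it validates kinship, which is how the two-family
silhouette check uses it.

`filter_informative()` implements the informative-SNP rule: keep records
with chromosome token not `"0"`, SNP name not containing `"cnv"`
(case-sensitive, matching the probe naming convention), and manifest
`intensity_only` flag false. The loader never filters — filtering is a
visible, idempotent pipeline stage.

## The two-layer confidence model

The scorer (`rfgda()`) is a classed fitting function in the classic R
modelling idiom, with `print`, `summary`, `coef` and `predict` methods.

**First layer.** A probability random forest (via `ranger`, 100 trees,
unlimited depth, single-threaded for determinism) over the feature list
`(m, a, m_raw, a_raw)`, trained on calls whose correctness is known. In
this package the labelled corpus is synthetic (the simulator's truth
table); the layer is a plug-in, and a forest trained on any labelled batch
can be reused via `rfgda(data, rf = )`.

**Second layer.** Per individual, a two-class Gaussian discriminant
model. The forest's confident calls seed the classes: probability
`>= p_hi` (default 0.9) defines the "correct" set, `<= p_lo` (default
0.15) the "error" set. Each class gets a maximum-likelihood mean and full
covariance, regularized as `Sigma + ridge I` (`ridge = 1e-6`), with priors
from the counts. The final score is the two-class posterior probability
the call is correct.

Design choices worth recording, because the design was genuinely open:

* **Two classes, not per-genotype Gaussians.** A correct/error mixture is
  the minimal model consistent with an unlabelled second layer seeded by
  first-layer confidence; per-genotype variants (3–6 Gaussians) would need
  genotype-conditional seeding rules the data do not obviously support.
  The choice is documented, configurable in its thresholds, and isolated
  behind `fit_gda()`.
* **Seeding thresholds `p_hi = 0.9`, `p_lo = 0.15`.** Asymmetric because
  errors are the minority class: a low `p_lo` keeps the error class pure
  at the cost of size, while `p_hi = 0.9` keeps the correct class large.
* **Per-individual fitting** is the point of the layer: one individual's
  outlying amplification behaviour must not bias another's scoring
  function. The test suite pins this as an independence property
  (corrupting one individual's features changes only that individual's
  layer).
* **Pooled fallback.** Individuals with fewer than `min_count = 200`
  seeded calls in either class are fitted on the pooled batch instead and
  flagged in the model's provenance. The fallback layer exists only when
  some individual needed it; scoring an individual the model has never
  seen uses it (with a warning) or fails loudly.
* **No-calls** are scored for diagnostics but never converted back into
  called genotypes.

Numerically, posteriors are computed from log-densities via Cholesky
factors with the max-subtraction trick, so the complement identity
`P(correct) + P(error) = 1` holds to 1e-12 and scores at the class means
do not overflow. The tests compare the posterior against an independent
direct evaluation of the two densities (`mclust::dmvnorm`) to 1e-10.

Model serialization (`save_model()` / `load_model()`) is a versioned
container; a reloaded model reproduces scores bit-for-bit, and corrupted
or version-mismatched files are explicit errors.

## Thresholding and sweeps

`set_threshold()` no-calls records whose score is *strictly* below the
threshold, keeping the original genotype in a `gtype_orig` shadow column.
Strict inequality makes threshold 0.0 a no-op, so the sweep's first grid
point reproduces the unthresholded call-rate report exactly — a property
the tests assert. Records that were already NC stay NC and keep
contributing to call-rate denominators. `threshold_sweep()` applies every
(algorithm, threshold) pair to the original table and emits long-format
rows `(individual, thr, alg, AA, AB, BB, NC, callrate)`;
`summarize_sweep()` collapses across individuals to means with standard
errors (sample SD / sqrt(n); `NA` for a single individual).

## What the simulator emulates — and what it does not

`simulate_batch()` generates the study conditions the package is
benchmarked under. The defaults, chosen once as a realistic sperm-typing
design, are: 23 haploid samples from two families (12 + 11), 20,000 SNPs
of which 1% are intensity-only probes, ADI rate 0.10, ADO rate 0.20
(within the reported up-to-30% prevalence; inert in haploid mode, where no
true heterozygote exists), and a 5% baseline no-call rate.

The generative chain: population B-allele frequencies from Beta(2, 2);
per family a diploid donor whose two alleles each sample inherits from at
random per SNP (this is what creates kinship structure — siblings share
the donor's homozygous genotypes); noise applied as no-call, then ADO
(true AB observed AA/BB), then ADI (true AA/BB observed AB); MA features
drawn from per-genotype Gaussian clusters — homozygotes at
`(m, a) = (+/-4, 10)`, true AB at `(0, 10)`, the ADI artifact at `(0, 7)`
with inflated variance, no-calls in the same low-intensity region;
intensities back-transformed from (m, a) and pushed through the *inverse*
of a randomly drawn per-sample affine transform, so the pipeline's
normalization path is exercised non-trivially; GenCall-like scores from
Beta distributions (correct calls mode ~0.8, errors ~0.45, no-calls
~0.12), quantized through float32 so written fixtures round-trip exactly.
Scores for errors overlap scores for correct calls by design: the
baseline must have genuine but imperfect discrimination for a comparison
against it to mean anything.

What it does **not** emulate, and what passing tests therefore do not
show: genome-positional correlation of ADO (real drop-out is regionally
correlated along amplicons, not i.i.d. per SNP), copy-number and
aneuploidy signal, between-SNP cluster heterogeneity (real cluster files
differ per SNP; the simulator uses shared geometry), any realistic joint
distribution of GenCall score and error class (the Beta model is a
documented stand-in), and batch effects between samples beyond the random
affine transforms. Results on real arrays will be worse than on this
simulator wherever those features matter; the simulator's role is to make
the machinery testable and the comparisons directional, not to predict
absolute error rates.

## Problem sizes and evaluation choices

The test suite and the acceptance script run the full study preset
(23 x 20,000 calls) for the end-to-end checks, a 10-sample independent
batch for first-layer training — deployment-shaped: the forest never sees
the batch it is evaluated on — and smaller batches (4–6 samples, 800–5,000
SNPs) for module-level properties; these sizes give binomial error bands
well inside the tested tolerances while keeping a full run in minutes on
one CPU.

One evaluation convention needs stating. The sweep comparison quotes
"matched call rates" (e.g. 0.99, 0.95, 0.90). With a 5% baseline no-call
rate the absolute call rate cannot exceed ~0.95, so matched call rates are
interpreted as the retained fraction of *originally called* genotypes —
the quantity a score threshold actually moves, and the axis on which two
scores can be compared at equal yield. At every such matched rate the
two-layer score retains fewer AB (error) calls than the simulated GenCall
score, and at threshold 0.5 it removes essentially all drop-in calls
while keeping >99.9% of correct ones; the acceptance script recomputes
these numbers from scratch on every run.

## Known limitations

* The first layer must be trained on labelled data; with no public
  ground-truth corpus the package trains on simulation, and a forest
  carried to real data inherits the simulator's idealizations.
* The GDA layer assumes each class is one Gaussian in feature space; real
  error clouds are heavier-tailed, and the posterior is correspondingly
  overconfident far from both means.
* Per-individual fitting needs enough seeded calls per class
  (`min_count`); small targeted panels will land on the pooled fallback,
  where the per-individual robustness argument no longer applies.
* The cluster file is carried as metadata but not yet used by the scorer;
  per-SNP cluster-aware scoring is a natural extension.
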