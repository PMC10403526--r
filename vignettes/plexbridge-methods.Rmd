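---
title: "plexbridge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plexbridge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `plexbridge`, the
assumptions it rests on, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely
open. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The processing model

### Identification filtering

PSMs from a concatenated target–decoy database search carry three
quality scores: the cross correlation `xcorr`, the gap to the runner-up
match `delta_cn`, and the precursor mass error in ppm. `fit_discriminant()`
combines them into one score by classical two-class linear discriminant
analysis with pooled within-class covariance,
`w = S_pooled^-1 (μ_target − μ_decoy)`, oriented so higher is more
target-like. Mass error enters as `|ppm|`: error of either sign indicates
a mismatch, and folding it keeps the discriminant linear while using that
information. When the pooled covariance is numerically singular (e.g. a
constant feature), a small ridge proportional to the mean diagonal is
added and a warning emitted rather than failing — a deliberate choice, as
degenerate score columns occur in small calibration runs.

`fdr_curve()` uses the concatenated-search convention: at each distinct
score threshold, FDR = `2 · decoys / (targets + decoys)` at or above it.
The factor 2 reflects that incorrect matches fall into the target and
decoy halves of the database with equal probability, so the decoy count
estimates an equal number of incorrect targets. Because the raw curve is
not monotone, a q-value (running minimum over all more permissive
thresholds) makes the retained set at any level well defined;
`filter_peptides()` keeps targets at or above the most permissive
threshold whose q-value is strictly below `alpha`, removes decoys, and
keeps the best-scoring PSM per peptide. Note that this estimator counts
decoys in its denominator while the reported list contains only targets;
at the PSM level the realized target false-discovery proportion is
therefore roughly half the nominal level, while at the collapsed peptide
level (where correct identifications are consolidated across repeated
PSMs but incorrect ones rarely repeat) the two move back toward
agreement. The calibration tests measure the realized proportion on the
peptide list, which is what the filter actually returns.

Protein inference follows parsimony: each peptide is assigned to the
longest of its candidate proteins ("largest protein" read as residue
count), with ties broken by the lexicographically smallest accession so
the output is deterministic. Protein-level FDR uses the same estimator on
protein scores; the protein score is the best peptide discriminant score
of the protein. That statistic is a documented simplification — richer
protein-level scores exist, but the best-peptide score is the simplest
defensible choice and is exposed at a single point
(`filter_protein_fdr()`) for replacement. The discriminant is fit on the
table it is given; studies that want per-set fits simply call the filter
per set.

Quantification filters are strict inequalities — summed reporter signal
`> 200` counts, isolation specificity `> 0.7` — so boundary values are
removed; the removal counts per criterion are attached to the result.

### Bench QC

*Missed cleavage*: an internal K or R not immediately followed by P is a
missed site; a C-terminal K/R is a realized cleavage. The rate is
`Σ missed / Σ (missed + realized)` over identified peptides — an
operationalization of "potential cleavage sites left uncleaved" from
observable data using the standard trypsin/Lys-C rule (K-P/R-P bonds are
not cleavable). Whether peptide N-terminal context should enter the
denominator is not observable from the peptide list alone; it is
deliberately excluded. Default ceiling 0.15.

*Labeling efficiency*: labeled / labelable sites summed over PSMs,
default floor 0.95.

*Ratio check*: channel totals of a set are compared to the median
channel total; the correction factor `median/total` exactly equalizes
totals when applied. The median was chosen as reference because the
check's purpose is robust detection of one or two discrepant channels;
the pass tolerance (default ±10% relative) is a package parameter, as
"compared for equivalence" admits no universal numeric rule.

### Bridge normalization

With `ẋ_ijk` the raw intensity of peptide `i` in sample `j` of set `k`:

1. **Within-set** — multiply each sample by (bridge total / sample
   total), totals over all peptides present in the set. The bridge is a
   fixed point; afterwards all sample totals in a set equal the bridge
   total. This exactly removes multiplicative per-sample loading
   factors, and *assumes equal underlying protein amounts per channel* —
   which the bench protocol enforces by labelling equal protein masses
   and pooling equal amounts as judged by the ratio check.
2. **Across-set** — multiply each set by (reference-set bridge raw total
   / set bridge raw total). Both totals are computed from *raw*
   intensities, as the equations' symbols indicate; for the bridge
   itself the within-set step is the identity, so the two readings
   coincide. The reference set is a fixed point, and afterwards all
   bridge totals equal the reference's. This exactly removes per-set
   (batch) intensity factors.
3. **Rollup** — protein quantity is the mean of its peptides' normalized
   intensities in that set (`Σ/n_lk`). Surrounding descriptions of this
   step sometimes say "summing": the division by the per-set peptide
   count makes it a mean, and the mean is what corrects for the per-set
   differences in peptides quantified per protein.
4. **0–100 scaling** — each feature is expressed as its percentage of
   the feature's total over the samples of its set. The denominator
   includes bridge channels by default (the formula sums over all
   samples of the set); `scale_include_bridge = FALSE` excludes them for
   downstream biology where bridge channels are not samples of interest.

Sums run over peptides present after filtering; missing peptides are
absent rows, never imputed, mirroring between-set under-sampling.
Division-by-zero policy: a zero sample or bridge total is a hard error
(it indicates corrupt input), while a zero per-feature set total in the
scaling step passes the feature through as all-zero with a warning
(legitimately possible after aggressive filtering).

When a set carries several bridge channels, the first-flagged one is the
anchor by default (the equations index a single bridge channel `j^b`);
`bridge_policy = "average"` instead averages the bridge totals. The two
options agree when bridges are true technical replicates.

### Diagnostics

PCA operates on `log2(x + 1)` of a feature-by-sample matrix restricted
to features observed in every set (the complete-case roster on which
cross-set comparisons are meaningful), with per-feature centering, via
`prcomp`. The transform default reflects the multiplicative nature of MS
intensities and can be disabled; the pseudocount of 1 is negligible
against raw intensities (hundreds) and merely guards zeros after
scaling. Component signs are fixed by making each component's
largest-magnitude loading positive, so embeddings are deterministic.
Separation is the mean silhouette width on the top 10 components
(Euclidean distance) — enough components to capture batch and subtype
axes without re-introducing noise dimensions; singleton label classes
contribute 0, with a warning. Replicate fidelity is the mean pairwise
Pearson correlation among a line's placements versus the mean
correlation of each placement with a contrast line, on the same
complete-case roster.

### Association

For each protein quantified in all included lines,
`lm(gr_aoc ~ z + receptor_status)` where `z` is the protein's
standardized `log2(x + 1)` abundance across lines. Standardization makes
effect sizes comparable across proteins (response units per SD of
abundance); the covariate absorbs subtype-level response differences so
that subtype-marker proteins do not masquerade as response predictors.
Proteins with zero variance or collinear with the covariate are flagged
`untestable` rather than dropped, so row accounting is stable. Raw
p-values are the primary column; Benjamini–Hochberg adjusted values are
added. Replicate placements of a line are averaged before fitting;
bridge channels are excluded. Whether non-malignant lines enter the fit
is left to the caller's response table — the generator's default
response covers malignant lines only.

## The synthetic-data generator

`simulate_study()` emulates a 60-line, 8-set, 2-batch, bridge-anchored
panel:

* **Latent proteome** — per-protein baseline `log2` abundance
  `N(7, 1)`; 200 of 2000 proteins are subtype markers with per-subtype
  effects `N(0, 1)` (log2); per-line effects `N(0, 0.5)`. Profiles are
  then scaled per line to a common expected total MS signal (abundances
  weighted by each protein's summed peptide efficiencies) — the in-model
  counterpart of labelling equal protein amounts and pooling equal
  peptide amounts per channel. Only relative abundances are meaningful.
* **Design** — 8 sets, sets 1–4 in batch 1 and 5–8 in batch 2; one
  bridge channel per set, mixed as the arithmetic mean (equal parts on
  the linear scale) of six designated lines; one non-malignant line
  (`MCF10A`) placed in five sets spanning both batches; nine further
  lines duplicated once, giving 81 channels in sets of 10–11.
* **Peptide layer** — each protein has a pool of ~10 peptides with
  log-normal ionization efficiencies (SD 1 in log2). A peptide enters a
  set's roster with probability 0.4 (batch 1) or 0.7 (batch 2), giving
  ~4 versus ~7 detected peptides per protein — the deeper second batch.
  Rostered peptides are reported for *every* channel of the set (TMT
  completeness); under-sampling acts only between sets.
* **Observed intensity** — `abundance × efficiency × batch factor ×
  loading factor × 2^N(0, 0.25)`: batch 2 carries a 3× intensity factor
  (the batch-to-batch signal gain is not a published number; 3 is a
  clearly visible yet realistic default, exposed in the config), loading
  factors are log-normal with SD 0.15 (natural log), and measurement
  noise is log-normal with SD 0.25 in log2 units.
* **PSM tables** — targets are a mixture of correct matches
  (`xcorr ~ N(3.2, 0.6)`, `delta_cn ~ N(0.45, 0.12)`, mass error
  `N(0, 1.2)` ppm) and incorrect matches (`N(1.7, 0.45)`,
  `N(0.12, 0.08)`, `N(0, 5)`); each incorrect match falls in the target
  or decoy half with probability ½. Correct matches share peptides
  (~2 PSMs per peptide, as repeated fragmentation produces); incorrect
  matches scatter to unique peptides. Hidden `correct` labels are kept
  for calibration tests only. Reporter totals are log-normal and
  isolation specificity Beta(12, 3), so a realistic minority of rows
  fails the quantification filters.
* **Response** — `gr_aoc = subtype offset + β · z(causal protein) +
  N(0, 0.5)` with β = 0.5 and the causal protein chosen among
  non-markers by default, so the causal signal is not partially absorbed
  by the receptor-status covariate.

What the generator does **not** emulate: spectra and co-isolation
physics, retention time, isotopic impurity, real protein sequences
(sequences are synthetic tryptic-like strings), correlated peptide
efficiencies within a protein, non-multiplicative batch distortions, and
missingness that depends on abundance. Passing tests therefore show that
the algebra and statistics behave as designed under a faithful
multiplicative model — not that every artefact of real acquisitions is
corrected.

## Problem sizes and determinism

All randomness flows through explicit seeds; identical config + seed
give identical outputs. The test suite runs the full default study
(2000 proteins, 81 channels, ~900k peptide rows) once for the
batch-effect and replicate checks, 20 PSM simulations of 20,000 rows for
FDR calibration, and 50 association studies of 1000 proteins × 56 lines
— sizes chosen to make every property measurable with comfortable
Monte-Carlo margins while keeping a desk-scale run. Oracle-equivalence
checks compare every normalization stage to an independent scalar-loop
implementation at 1e-9 relative tolerance (1e-12 on small fixtures);
fixed-point and sum-to-100 invariants are asserted at 1e-9 relative.

## Known limitations

* The protein-level FDR score (best peptide) ignores peptide counts;
  single-hit wonders are not penalized beyond their one score.
* Parsimony by maximal length is greedy per peptide; it does not compute
  a minimal protein set cover.
* The pipeline assumes equal protein loading per channel was achieved at
  the bench (as the ratio check verifies); gross loading failures should
  be fixed upstream, not by Eq. 1.
* Association fits are univariate per protein; correlated proteins will
  share signal, and no multivariate or regularized model is provided.
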