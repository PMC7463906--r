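---
title: "Correlating marker-locus distances with metabolomic fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating marker-locus distances with metabolomic fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genophen)
```

## The question and the method

DNA barcode loci (ITS, LSU, and newer single-copy markers) order closely
related yeast strains by sequence divergence. Metabolomic fingerprints —
whole-cell FTIR spectra and annotated LC-MS metabolite tables — order the
same strains by phenotype. `genophen` quantifies how well the first
ordering predicts the second, per locus, at rest and under short-term
ethanol stress.

Everything reduces to comparisons between labeled strain-by-strain
distance matrices:

1. **Genetic side.** Per locus, pairwise distances from the aligned
   sequences under a closed-form model (`p`, JC69, K80, TN93), expressed
   in substitutions per site. K80 is the default: the cited distance tool
   defaults to it and the marker panels involved show
   transition/transversion asymmetry; the model is a flag everywhere.
   Sites containing gaps or `N` are dropped alignment-wide by default
   (complete deletion), pairwise on request. A saturated pair (logarithm
   argument non-positive) is an explicit error naming the pair, never a
   silent `NaN`.
2. **Phenotype side.** Euclidean distances between replicate-averaged
   strain profiles — whole spectra, spectral regions, or metabolite
   vectors.
3. **Comparison.** Pearson correlation of the two lower triangles
   (`matrix_correlation()`), aligned by strain label. Significance uses
   Mantel-style row/column permutations; with `n ≤ 7` strains all `n!`
   relabelings are enumerated, so for the canonical four-strain panel the
   p-value granularity is 1/24 and the attainable minimum is 0.042. The
   parametric `t` transform of `r` (what a naive `cor.test` on distance
   vectors reports) is available for comparability but is documented as
   anti-conservative: the 6 pairwise distances among 4 strains are not
   independent observations.

The per-descriptor scan (`descriptor_scan()`) repeats comparison (3) for
every single wavenumber or metabolite, using `|xᵢ − xⱼ|` as the 1-D
distance. The **PSW** statistic (`psw()`) is the percentage of descriptors
whose scan correlation exceeds 0.75 (strictly). Constant descriptors are
recorded as `r = 0` and kept in the denominator, so PSW denominators are
comparable across conditions; this choice is logged in the scan output
(`constant` column).

### Small-sample inflation, and why PSW needs its threshold

With only 6 strain pairs, a pure-noise descriptor produces `|r| > 0.75` in
roughly 10–30% of draws depending on the genetic matrix's shape. This is
why (a) the scan's permutation p-values are exhaustive rather than
parametric, (b) PSW uses a strict, high threshold, and (c) any *recovery*
statement about a planted signal under noise must be read against the
scan's own background: the PSW observed at conditions where nothing was
planted. The test suite measures planted recovery as the planted-condition
PSW minus that background.

### PSW trends over ethanol dose

`classify_trend()` reduces a marker's PSW-versus-dose curve to three
archetypes: *non-monotonous* if the maximum PSW occurs at an interior
condition (a rise-then-fall response), otherwise *high* or *low* according
to whether the maximum reaches the `split` parameter. The default split of
5 PSW points sits midway between the empirically observed low-response
maxima (2–4%) and high-response maxima (6–32%); it is configurable.

### Region analysis

The W1–W4 fingerprint windows follow the whole-cell FTIR literature:
fatty acids [3200, 2800), amides [1800, 1500), mixed [1500, 1200),
carbohydrates [1200, 900) cm⁻¹ (half-open on the low-wavenumber side).
`region_max_correlation()` reports, per marker × region, the maximum scan
correlation separately for control spectra (lowest condition) and the
pooled stressed spectra — replicates, and for the stressed group all
stressed conditions, are averaged per strain before scanning. Averaging is
the arithmetic mean by default with median as a flag; the choice is
recorded in the outputs.

## FTIR preprocessing

The chain is quality check → rubberband baseline correction → vector
normalization, applied to whole spectra before any region extraction
(whether the original workflow normalized before or after extraction is
not documented; whole-spectrum-first is this package's fixed choice).

* **Quality.** SNR = full-spectrum amplitude (max − min) divided by the
  RMS residual of a linear fit in the featureless 2100–1900 cm⁻¹ window;
  pass means SNR > 4000. This is a documented surrogate for the
  instrument's proprietary test: on real 256-scan spectra it reproduces
  the accept/reject behavior; on synthetic data with visible noise it
  flags everything, so the pipeline reports QC without enforcing it unless
  asked (`enforce_quality`).
* **Rubberband.** The baseline is the lower convex hull of the spectrum,
  anchored on 64 equally spaced support abscissae (the instrument
  convention for "64 points") and linearly interpolated back to the full
  axis. A pure line corrects to zero exactly; peaks survive outside their
  hull-bridged interval. The 64-anchor interpolation makes repeated
  application idempotent only up to the anchor interpolation error —
  machine-exact for smooth spectra, bounded by a few times the noise
  scale otherwise.
* **Vector normalization.** Mean-subtract, then scale to unit sum of
  squares; scale-invariant and idempotent.
* Atmospheric CO₂/water-vapor compensation is instrument-specific and out
  of scope; `mask_intervals()` can zero the affected bands when real
  spectra need it.

## Metabolomics processing

`iqr_filter()` (rank by IQR, drop the lowest fraction, zero-IQR always
dropped) → `median_normalize()` (per-sample median to 1) →
`pareto_scale()` (center, divide by √SD). The IQR filter takes an explicit
`drop_fraction` (default 0.1) rather than any tool-version-dependent size
schedule. An optional `log_transform()` sits between normalization and
scaling; the whole-profile LC-MS distances in `run_resting()` use it,
matching the log2 scale on which differential-metabolite heatmaps are
conventionally drawn. A state flag on the table enforces the order
raw → filtered → normalized → scaled.

PLS-DA (`plsda_vip()`) is PLS2 by NIPALS on the centered one-hot class
matrix. VIP for metabolite *j* is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a \mathrm{SSY}_a\, (w_{aj}/\lVert w_a \rVert)^2}{\sum_a \mathrm{SSY}_a}}$$

with *p* metabolites and SSYₐ the Y-variance explained by component *a*.
Unit-norm weights make the mean squared VIP exactly 1 — the analytic fact
behind the "greater than one" selection rule (`select_discriminant()`,
strict inequality). Two components is the default (the class structures
here are small); deflation stops early, with a message, if a weight vector
degenerates. The implementation agrees with mixOmics' VIP to ~1e-10 on
random tables (cross-checked in the tests, never substituted for it).

`hca()` performs Ward clustering (`ward.D2`, Ward on unsquared distances)
on Euclidean or Spearman (`1 − ρ`) distances. Ward formally assumes
Euclidean geometry; offering it over Spearman distances follows common
chemometrics practice and is a documented caveat, not an error.

## The synthetic-data generators

The generators produce inputs with the statistical structure the analysis
assumes, so every stage is testable without any external download. They
emulate a four-strain, four-condition (0/8/12/16 % v/v ethanol) design
with three FTIR readings and five LC-MS replicates per condition — the
replicate counts of the emulated assay types — on a strain tree shaped
like the *sensu stricto* panel with barcode-scale branch lengths.

* **Marker alignments** evolve site-independently under JC69 along the
  tree (per-branch substitution probability `3/4(1 − e^{−4bm/3})`).
  Distance estimators are validated against this model's closed-form
  expectations and against additive matrices.
* **Gene-tree heterogeneity.** Each locus gets its own copy of the strain
  tree with log-normally jittered branch lengths (`jitter_sd`, default
  1.6), rescaled to keep the total tree length fixed; the locus rate
  multiplier alone controls overall divergence. Rationale: real marker
  panels mix mitochondrial, ribosomal and single-copy nuclear loci whose
  relative distances disagree strongly, and a scale-invariant correlation
  cannot distinguish loci whose matrices are exactly proportional — with
  `jitter_sd = 0` no locus could ever "rank top". Fixing the total length
  keeps fast loci away from distance-correction saturation however heavy
  the jitter.
* **Spectra** are smooth random cubic baselines plus i.i.d. Gaussian noise
  plus *planted signals*: at condition *c*, `n_wavelengths` positions
  inside a target region gain `amplitude[c] × score(strain)`, where the
  scores are the 1-D classical-scaling embedding of the source locus'
  tree distances. Pairwise |score| differences then track the locus'
  distances, exactly so when those distances form a line metric — which
  is how the tests construct exact PSW recoveries
  (100·50/901 = 5.549% for 50 planted wavelengths on the 901-point axis).
* **Feature tables** are log-normal intensities (baseline spread 0.5 on
  the log scale, replicate CV 5%) in which 40% of metabolites carry
  strain effects spanning the *full* principal-coordinate embedding of
  the source locus' distances, with block-orthonormal effect directions
  so the planted between-strain log-profile distances reproduce the
  embedded distances exactly rather than only on average, and a dose
  amplification toward the highest ethanol condition. By default the
  driving distances are *realized* — estimated from the locus' simulated
  alignment — because a metabolome responds to the strains' actual
  genotypes, not to the latent expected divergence; `basis = "expected"`
  switches to tree distances for analytic constructions. These choices
  were calibrated once, jointly, so that the generating locus wins the
  whole-profile ranking in at least 95% of seeds — the planted-recovery
  property the test suite measures over 100 seeds; weaker variants (a
  1-D score embedding, unwhitened effect directions, or linear-scale
  distance computation) each lose enough distance structure to break
  that property.
* **Viability** counts are Poisson around `Ct(1 − M/100)` with a default
  mortality profile shaped like the published dose response (one
  sensitive strain saturating by 12% ethanol, one tolerant, two
  intermediate).

All four generators are deterministic functions of the scenario seed
(per-stream child seeds keep the outputs independent of evaluation
order).

### What passing on synthetic data does not show

The generators emulate the *statistical* structure — distance-driven
strain separation, condition-dependent amplitudes, replicate noise,
smooth baselines — not the chemistry: no real band shapes or vibrational
assignments within W1–W4, no atmospheric interference, no isotope
patterns or annotation errors in the feature table, no batch effects.
Passing tests demonstrate that the statistics recover what was planted
under the stated noise; they cannot certify instrument-specific
preprocessing against real spectra.

## Pipelines, determinism, problem sizes

`run_resting()` reproduces the resting-state analysis structure: marker
distance matrices (plus the ITS+LSU concatenation), an NJ tree with
column-bootstrap support for ITS_LSU, whole-profile FTIR clustering on
the informative windows (3200–2800 and 1800–1200 cm⁻¹), Spearman/Ward
clustering of the processed metabolite table, and the ranked
marker-versus-phenotype correlation table. `run_stress()` produces the
mortality table, per-marker PSW trends with classes, and the
control-versus-stressed region table. Both accept a scenario (in-memory
generation) or a directory of files, write CSV/Newick reports plus a run
log (seed, thresholds, timings), and are deterministic under a fixed
seed; every PSW value in the trend summary equals recomputation from the
persisted scan. NJ itself is delegated to `ape::nj` behind
`neighbor_joining()`; negative branch lengths are kept by default so that
additive matrices are reproduced exactly, with clamping available for
display.

Default problem sizes keep the full test suite and pipelines in the
minutes range on one core: 12 loci of 0.6–1.7 kb, 48 spectra of 901
points, 80 × 89 feature tables, 100–1000 bootstrap replicates; the
planted-recovery property is measured over 100 seeds. These are the
package's chosen study conditions, stated here so results are read at the
scale they were computed.

## Known limitations

* Four strains give 6 distance pairs: permutation p-values cannot go
  below 1/24, and every correlation carries the small-n inflation
  discussed above. The machinery generalizes to more strains unchanged.
* TN93 estimates base frequencies per sequence pair; tools that use
  alignment-wide frequencies differ in the 4th decimal (the cross-check
  tolerance acknowledges this).
* "Maximum Composite Likelihood" distances require a joint optimizer
  specific to one desktop application; TN93 is the closest closed-form
  pairwise analogue (same unequal-transition-rate assumptions) and is the
  supported substitute, with the model selectable throughout.
* Pathway enrichment/topology analyses need external pathway graphs and
  are out of scope, as are raw-spectrum (OPUS/mzML) ingestion, alignment
  computation, and genome-scale marker extraction.
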