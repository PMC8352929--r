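---
title: "Methods: re-quantification of label-free DDA proteomics by identity propagation and direct ion current extraction"
author: "requant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: re-quantification of label-free DDA proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Data-dependent acquisition (DDA) selects precursors for MS2 fragmentation
stochastically, so a peptide is *identified* in only a subset of samples
even when its ions are present in every MS1 map. The resulting missing
values grow with cohort size and disproportionately affect low-abundance
peptides. `requant` closes these gaps by re-quantifying every consensus
peptide feature in every sample directly from the centroided MS1 ion
cloud (direct ion current extraction, DICE), inside a narrow
feature-specific retention-time (RT) x m/z window, after per-sample
drift and mass-error correction. Decoy windows — copies of every feature
window shifted well away from all real features — provide an empirical
background model against which the reliability of every recovered
quantification is scored.

## Model and procedure

**Alignment windows.** For every peptide identity key (sequence,
normalized modifications, charge) observed in at least two samples, RT
and calibrated-m/z deviations from the key's cross-sample median are
pooled as absolute values. The RT window is 1.5 x IQR of the pooled
absolute RT deviations; the m/z window is 1.0 x IQR of the m/z
deviations (type-7 quantiles, so the numbers are reproducible). User
floors (defaults 0.2 min, 0.001 Th) guard against degenerate windows;
user-fixed values bypass estimation.

**Consensus features.** Features sharing an identity key are aggregated;
contributors deviating from the key medians by more than the windows are
excluded and the medians recomputed once. If that exclusion would empty a
key (two contributors straddling their median), the contributor nearest
the median is kept — a consensus must retain at least one contributor.
Sequence-less detected features falling inside a consensus window attach
to the nearest consensus (feature-based identity propagation). Features
of equal charge closer than 0.002 Th with overlapping RT extents merge
transitively; conflicting sequences never merge. Every feature gets a
decoy companion (+5 windows in RT and m/z, shifted further in m/z until
collision-free) and a +1-isotope companion (+1.002/charge Th).

**Correction models.** For samples that observed a feature, the
*individual* correction is used: the expected window center is the
sample's own observed position (median contributor RT; median
uncalibrated m/z — uncalibrated m/z is where the ions actually sit).
For samples without an observation the correction is estimated: a
random-forest regressor (bagged variance-reduction trees, 100 trees, 4
candidate predictors per split, minimum terminal node 100, 80/20
train/holdout split) predicts the mass error
`uncalibrated - calibrated m/z` from (RT, m/z, charge, resolution), and
a generalized additive model (thin-plate spline, `mgcv`, automatic
smoothness selection) predicts the RT deviation from the consensus
reference RT. RT predictions outside the training range clamp to the
boundary; fewer than 200 usable rows (m/z) or 10 pairs (RT) fall back to
the global median with a warning. The RT pairs come from all of a
sample's sequenced features matched by identity key, not only retained
contributors, so large smooth drifts are not truncated at the window.

**Noise model.** Decoy windows (RT extent = feature peak width, m/z
extent = alignment window) are extracted in every sample; a GAM of decoy
intensity against RT gives the expected background intensity, its
residual dispersion (1.4826 x MAD by default, configurable to plain SD)
the noise standard deviation, and the empirical decoy ion-count
distribution both the KDE minimum-ion threshold (its median) and the
significance score.

**Peak detection and selection.** Around each expected center, ions from
an extended search region (±3 alignment windows; at least the window
half-width in RT) are standardized by the alignment windows and smoothed
with an intensity-*unweighted* bivariate normal KDE (`MASS::kde2d`,
50 x 50 grid). Local maxima (strict 8-neighbour) become candidates; each
is kept when its supporting ion count reaches the median decoy count or
it lies inside the expected window, and the 5 closest to the expected
center are stored. Samples with an observed feature take the nearest
valid candidate ("known"). Other samples take the candidate closest to
the known peaks' consensus location — computed in the *model frame*
(deviations from the model-predicted centers), which cancels the shared
feature-level alignment error — within one RT window and three m/z
windows of that location, not overlapping a distinct rejected peak seen
in a known sample ("transferred"); otherwise the expected window itself
is used ("fallback"). Extraction counts all ions in the selected window
and sums their intensities; ions above the noise mean at that RT plus
two noise SDs count as signal.

**Significance, filters, FDR, imputation.** Each quantification's ion
count is scored against the sample's decoy counts with an add-one
empirical p-value, `p = (1 + #{decoy >= obs}) / (1 + #decoys)`; p < 0.05
marks accumulation unlikely under background. Selection outliers are
removed on alignment residuals (peak minus model-predicted center):
whole features whose cross-sample residual IQR is a robust-z > 3 outlier
of the feature population *and* exceeds half an alignment window;
individual cells whose residual deviates from the feature median by
robust z > 3 *and* more than the window half-size; and cells where the
monoisotopic and +1-isotope peaks disagree (RT by more than the RT
window, or spacing off by more than the m/z window). Peak-selection FDR
is estimated by masking: up to 500 sequenced features per sample are
re-selected as if unobserved; a re-selection is wrong when its center
leaves the original window or its intensity deviates by more than 20%.
True-missing cells (no ion in the window) are imputed from the noise
model (RT-local mean plus a resampled residual), flagged, given p = 1,
and reported alongside an untouched non-imputed table.

**Rollup.** Contaminant/reverse rows and proteins with fewer than 2
peptides are removed; per-sample protein values need at least 2
quantified peptides. Tables are median-normalized (factors anchored so
the median sample keeps factor 1; spike-in designs should pass the
constant background rows as the reference). Protein aggregation is Top3
(mean of the up-to-3 most intense peptides), total sum, or MaxLFQ
(median pairwise peptide log-ratios, least-squares reconstruction with
minimum ratio count 2, anchored to the mean log of the per-sample
peptide sums).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `windows$min_rt` / `min_mz` | 0.2 min / 0.001 Th | floors for the data-driven alignment windows |
| `kde$resolution` | 50 | KDE grid points per dimension |
| `merge$delta_mass` | 0.002 Th | consensus merge threshold |
| `decoy$offset_multiplier` | 5 | decoy displacement in alignment windows |
| `isotope$delta` | 1.002 Th | isotope spacing per charge |
| `transfer$max_mz_multiple` | 3 | m/z transfer limit in windows |
| `signal$sd_multiple` | 2 | noise SDs above background defining signal |
| `significance$alpha` | 0.05 | accumulation significance threshold |
| `fdr$n_mask` | 500 | masked features per sample |
| `fdr$tolerance` | 0.2 | relative intensity deviation counted wrong |
| `impute$enabled` | TRUE | background-noise imputation |
| `rollup$method` / `min_peptides` | top3 / 2 | protein aggregation |

## The synthetic world

The generator emulates the statistical structure the workflow assumes,
with known ground truth. Defaults describe one fixed world, chosen once:

* 6 samples in two groups of 3; 500 peptide species, 5 per protein, on a
  30-min gradient (RT 10–40 min).
* The m/z axis is a **24-Th slice** (400–424 Th) at realistic *local* ion
  density: 2000 uniform background ions per (min x Th) plus 2000
  unsequenced "extra" molecular species. A full-width m/z axis at that
  density would need ~10^8 ions per run; the narrow slice preserves the
  local statistics (decoy windows catch a few ions, so the
  median-decoy-count threshold is meaningful) at desk scale. The extra
  species emulate MaxQuant-style `allPeptides` tables, which are
  dominated by unidentified features — they are what gives the
  per-sample m/z forest realistic training mass (~2000 rows rather than
  ~350).
* Gaussian elution peaks (sd 0.08 min) sampled on a regular 0.01-min MS1
  scan grid; centroid m/z jitter sd 5e-4 Th; per-scan log-normal
  intensity jitter (sd 0.1 log-units).
* Smooth per-sample RT drift, linear + sinusoid, amplitude 0.5 min; m/z
  error, constant + slow RT-dependent term, amplitude 3 ppm. Calibrated
  m/z carries a 0.2-ppm residual (MaxQuant-like calibration);
  uncalibrated m/z is the observed, error-laden coordinate.
* 30% MS2-identification dropout per species and sample; 30% of dropped
  cells still yield a sequence-less detected feature; +1-isotope
  envelopes at half intensity; species abundances log-normal
  (meanlog log 1e6, sdlog 1) with 5% between-sample measurement noise.
* Optional interference: a fraction of species receives a companion
  cluster offset by 0.1–0.3 min and 1–2.5 m/z windows at equal
  intensity, in every sample — a worst-case co-eluting near-isobar.

What the generator does **not** emulate: MS2 spectra and chimeric
identifications, detector saturation, intensity-dependent centroiding
dropout, correlated (structured) chemical noise, charge-state envelopes
beyond the +1 isotope, and ion mobility (the extraction supports an
optional mobility filter, but the generator never produces the
dimension). A green acceptance suite therefore establishes that the
algorithmic machinery — windows, models, propagation, selection,
scoring, rollup — behaves as designed under the stated statistical
assumptions; it does not certify performance on any particular
instrument's raw data.

## Numerical choices

* Quantiles are type-7 everywhere (windows reproducible to the digit).
* KDE coordinates are standardized by the alignment windows (the raw
  scales differ by ~1e5); bandwidths follow the normal-reference rule
  per dimension, floored at kernel sd 0.5 window units. The floor is a
  deliberate design choice: sub-window structure is centroid jitter by
  construction, the ion density along a flat elution ridge is
  approximately uniform (the KDE is unweighted), and without the floor
  the ridge maximum wanders and isolated background ions each become
  local maxima.
* Local maxima are strict 8-neighbour maxima; exact-tie plateaus keep
  the cell nearest the expected center.
* Cross-sample outlier filters operate on alignment residuals, not raw
  positions — raw peak positions legitimately differ between samples by
  the injected drift. The robust-z > 3 rules carry physical floors
  (half a window for feature dispersion, the window half-size for
  per-cell deviations) so localization jitter is not excised;
  "significantly" has no printed test in the source procedure, and this
  combination is the package's declared interpretation.
* The transfer limits (1 RT window, 3 m/z windows) bound the deviation
  from the known peaks' consensus location, measured in the model frame;
  when no known peak exists they bound the deviation from the expected
  center.
* The empirical p-value carries an add-one pseudocount so p = 0 never
  occurs; imputed cells always report p = 1.
* Ties on window boundaries are included (closed intervals on all four
  edges); extraction is exactly reproducible against a brute-force scan.
* RT is minutes everywhere; mzXML second-based retention times convert
  at parse time.
* Degenerate inputs: empty ion regions give all-zero KDE maps and no
  candidates; samples with too few features fall back to median
  corrections; MaxLFQ components disconnected at the minimum ratio count
  fall back to per-sample log sums.

## Design decisions where the procedure was open

* The m/z-correction forest is implemented in-package (Rcpp bagged
  variance-reduction trees) because no random-forest package is
  available in the target environment; hyper-parameters follow the
  printed values. With 4 predictors and 4 candidates per split this is
  bagging of CART trees.
* Whether unknown features attach before or after median-outlier
  exclusion is ambiguous; attachment here uses the final medians.
* Median recomputation after exclusion happens exactly once.
* Decoy collisions with target windows are resolved by further +1 m/z
  window shifts (up to 10, else the decoy is dropped with a warning).
* The masking FDR re-expresses a masked sample's cached candidates in
  the model frame rather than recomputing the KDE map at the model
  center: the two regions overlap by construction (centers differ by
  less than a window, regions span ±3), and the approximation keeps the
  estimator inside the runtime budget.
* p-values compare counts against the sample's global decoy
  distribution; the RT dependence of the background is carried by the
  intensity model only.
* Protein groups are taken from the input tables; no protein inference
  is performed.

## Known limitations

* Recovery accuracy for samples without an observed feature is bounded
  by the correction models; with few identified features per sample the
  forest falls back to a median and transfers lean entirely on the known
  peaks' consensus location.
* The consensus reference (cross-sample median of identified runs) is
  itself noisy at small cohort sizes and high dropout; this noise is
  shared across samples and cancelled in the transfer matching, but it
  bounds how tightly "expected" windows can be placed.
* Quantification sums centroid intensities inside a rectangular window;
  no chromatographic peak-shape fitting or area integration is
  attempted, matching the source procedure.
* The mzXML reader handles centroided MS1 scans only; profile-mode files
  are rejected rather than centroided.
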