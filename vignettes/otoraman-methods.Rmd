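---
title: "Methods: the otoraman decision pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the otoraman decision pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(otoraman)
```

# Scope and model

`otoraman` classifies middle-ear lesion sites from fingerprint-region
(600–1800 cm⁻¹) Raman spectra into three classes: cholesteatoma,
mineralized myringosclerosis and non-mineralized myringosclerosis. The
working assumptions are those of point-scanned tissue Raman spectroscopy:

* each site yields one spectrum on a shared, calibrated wavenumber axis;
* intensities are detector counts, shot-noise limited, riding on a broad
  autofluorescence background that is **not** removed — baseline
  correction can introduce artifacts, so the multivariate stages must
  tolerate a background-dominated signal;
* cosmic-ray hits appear as 1–2 channel transients and are the only
  artifact corrected before analysis;
* specimens differ from one another (tissue heterogeneity between
  individuals) far more than replicate sites within a specimen differ.

The chemical contrast rests on marker bands: the phosphate ν₁ mode of
apatite at 960 cm⁻¹ and the ν₃ mode near 1044 cm⁻¹ that gains intensity
with carbonate/silicate substitution of the lattice (with a 948 cm⁻¹ ν₁
component resolved only in the unsubstituted limit, and substitution
broadening 960); and the protein bands of keratin/collagen at 1005, 1032,
1128, 1447, 1654 and ~1680 cm⁻¹.

# Despiking

Cosmic rays are removed by a Hampel filter (`despike()`): a channel whose
robust z-score `|x − median| / (1.4826 · MAD)` against a sliding window
exceeds `threshold` (default 8) is replaced by the window median. Flags are
computed on the unmodified spectrum, then applied at once, which makes the
operation idempotent in practice.

The window default is 21 channels. This was calibrated against the
filter's own false-positive behaviour: with a 7-channel window the MAD of
so few samples is unstable and spike-free Gaussian spectra lose roughly
0.4% of their channels even at threshold 8 (the same rate is obtained from
`pracma::hampel`, an independent implementation), whereas at 21 channels
the false-positive rate drops to ~2.5 × 10⁻⁵ per channel while 1–2 channel
spikes of realistic amplitude are still recovered essentially completely
(161/163 planted spike channels on the default synthetic dataset). A
data-quality cap (`max_fraction`, default 2% of channels) turns pathological
inputs into errors instead of silently rewriting them.

No other preprocessing exists in the package, by design: no baseline
removal, smoothing or normalization.

# Mineralization screen

`screen_dataset()` converts the two gross labels into the three analysis
classes. Sites labelled cholesteatoma pass through; each myringosclerosis
spectrum is searched for a phosphate ν₁ peak in a 20 cm⁻¹ band centred at
960 cm⁻¹ (`find_band_peak()`).

The detection statistic is chord-baseline prominence divided by a robust
noise estimate, with threshold 5:

* a straight chord across the band removes the slowly varying background
  to first order; its endpoints are averaged over the three outermost band
  channels so that two noisy samples do not define the local baseline;
* the chord residual is smoothed with a 3-channel running mean before the
  in-band maximum is taken — without this, the maximum of ~9 independent
  noisy channels has a null tail far heavier than its nominal robust-z
  label, and the faint 960 cm⁻¹ traces of uninvolved tissue produce false
  mineral calls at the percent level;
* channel noise is estimated as `1.4826 · MAD(diff(y)) / √2` in a
  signal-free flank, 1700–1800 cm⁻¹ by default. The first-difference
  estimator is insensitive to the smooth amide-I tail entering that
  window, and the long flank (51 channels) keeps the estimate itself from
  flipping borderline decisions; the estimate is scaled by √(2/3) to the
  variance of the averaged statistic.

Prominence and noise both scale linearly with intensity, so the decision
is invariant to positive rescaling of a spectrum, and raising the
threshold can only reduce the number of mineral calls. Ties between equal
in-band maxima resolve to the channel nearest the band centre. The screen
is a detector, not a quantifier: no fitting or 948/960 deconvolution is
attempted.

A degenerate corner worth knowing: on strictly noise-free input any
nonzero in-band feature is infinitely significant for a scale-free
detector, so exact-recovery checks of the screen use phenotypes without
sub-threshold in-band bands.

# PCA and RadViz

`pca_fit()` performs centred, unscaled PCA (`stats::prcomp`); whether to
variance-scale channels was an open choice, and unscaled was selected
because Raman channels share physical units and scaling would inflate
noise-only channels. Since the background is left in the data, the leading
components are background-dominated and marker bands surface in later
loadings — marker searches (`loading_has_band()`) therefore scan all
retained loadings (7 per class by default) and require a local maximum of
|loading| to reach 80% of that loading's peak magnitude, a floor at which
noise-dominated loadings stop producing spurious hits (verified against
phenotypes generated without the queried band). Loading signs follow the
largest-element-positive convention so results are reproducible across
platforms.

`radviz_embed()` implements radial visualization: anchors for the K score
dimensions sit equally spaced on the unit circle (first anchor at 90°),
each dimension is min-max standardized to [0, 1], and a site maps to the
standardized-score-weighted mean of the anchor positions, hence always
into the anchors' convex hull. Conventions for degenerate input: an
all-zero standardized row (a 0/0 weighted mean) maps to the origin; a
zero-range dimension maps to constant 0 with a warning. Which PCs to
anchor was an open choice; `select_anchor_pcs()` ranks PCs by the one-way
variance ratio (between-class over within-class mean squares) of their
scores and keeps the top `k_select` (default 7) in PC order, ties to the
lower index — an objective, reproducible stand-in for manual selection.

# PLS-DA and its evaluation

`plsda_fit()` implements PLS2 discriminant analysis from the NIPALS
recursion directly (one-hot responses, column-centred X and Y, iterative
extraction of weights/scores/loadings with deflation after each latent
variable; coefficients `B = W (PᵀW)⁻¹ Qᵀ`). Convergence is declared when
the weight vector changes by less than 1e-10 (at most 500 iterations per
component); an exhausted X residual raises an error naming the component,
since that means the requested number of latent variables exceeds the
effective rank. Hard labels are the argmax of the continuous responses,
ties resolved by class order. On small problems the predictions agree with
`mixOmics` to 1e-6 and the first weight vector aligns with the dominant
left singular vector of the X–Y cross-covariance, which are the package's
correctness oracles, not its implementation.

The number of latent variables is not fixed a priori; when unspecified,
`choose_n_latent()` picks it by stratified 5-fold cross-validated accuracy
over 1–10, smallest count on ties. The resampled evaluations take an
explicit `n_latent`, and `run_pipeline()` chooses it once on the screened
dataset rather than inside every resampling iteration — with 100
iterations the inner selection would dominate runtime while changing the
choice rarely; this is a deliberate simplification.

`balanced_resample_evaluate()` mirrors standard practice for small
spectroscopy cohorts. Per iteration: every class is downsampled at site
granularity to the smallest class's site count (re-drawn each iteration,
which gives unbiased rate estimates, a mild departure from balancing
once); each class's sites are split 60/40 into train and test, so no site
contributes to both; PLS-DA is fitted on the training spectra and the test
spectra predicted; the confusion matrix is accumulated. Rates are computed
per iteration and averaged (pooling predictions first is the alternative;
averaging was chosen and documented). Splitting at site granularity is the
default and only mode used by the pipeline — spectrum-level splitting
would leak replicate structure whenever sites carry several spectra.

`negative_control()` re-runs the identical machinery with class labels
permuted uniformly at random over sites each iteration (class sizes
preserved). Any genuine signal is destroyed, so the mean overall correct
rate must collapse to 1/c for c balanced classes; on the default synthetic
dataset the three-class control sits within a point of 33%. A debug hook
can force the identity permutation, which reproduces the unpermuted
evaluation exactly and pins the two code paths together.

For two-class tasks the positive-class continuous scores of all test
predictions are pooled across iterations into one ROC curve
(`roc_curve()`: thresholds swept over unique scores, equal scores grouped,
endpoints (0,0) and (1,1), trapezoid AUC — identical to Mann–Whitney pair
counting), and PPV/NPV/sensitivity/specificity/accuracy are computed from
the summed confusion matrix; zero-denominator metrics are reported as
undefined (`NA`), never 0.

# The synthetic forward model

`generate_dataset()` exists so the entire chain can be exercised and
validated without clinical spectra. Per phenotype it renders a clean
spectrum from a versioned band table (`inst/extdata/phenotype_bands.yaml`):
Lorentzian bands of 10–20 cm⁻¹ FWHM for sharp mineral/protein modes,
broader Gaussians for the amide-I envelope, over a cubic polynomial
background (coefficients `(1.0, 1.2, −1.4, 0.4)` on the normalized axis,
scaled to 350–450 counts) validated nonnegative. Band positions follow the
assignments above; amplitudes and widths are not tabulated anywhere and
were chosen once as plausible for NIR tissue spectra, all overridable. The
mineral class's substitution degree defaults to 0.7, in the
strongly-substituted regime that motivates the 1044 cm⁻¹ marker; the
non-mineralized class carries faint 960/1048 cm⁻¹ traces at 5% of the
mineralized amplitudes, emulating biochemical change at lesion margins,
plus a protein table that differs from cholesteatoma only in the keratin
markers (weaker 1005/1032, no 1680 shoulder) so the two non-mineral
classes are the subtle pair.

Sampling design: 4 specimens per class × 10 sites per specimen (the
clinical study this emulates had six patients in total; the default is
chosen for statistical power of the validation, not fidelity to that n),
one log-normal amplitude multiplier per specimen (σ = 0.25 on the log
scale) so between-specimen variation dominates, Poisson shot noise on
total counts, and cosmic-ray spikes at Poisson rate 1 per spectrum, 1–2
channels wide, 500–3000 counts. Equal seeds give bit-identical datasets.

What the model does **not** emulate — and therefore what passing tests do
not show about real data: biological within-class diversity beyond a
common-mode amplitude (each class has one fixed band pattern), instrument
drift and wavenumber miscalibration, detector etaloning/read noise,
spatial heterogeneity within a site, and histology-registration error. On
synthetic data the classes are close to perfectly separable and the
three-class rates saturate near 100%; clinical rates are substantially
lower. The transferable validations are structural: chance-level negative
control, leave-sites-out disjointness, oracle equivalence of the
numerical engines, scale-free screening, and marker-band recovery in the
loadings.

# Reproducibility and problem sizes

All stochastic stages consume explicit integer seeds; `run_pipeline()`
derives per-stage seeds deterministically from the single run seed
(`(seed · 48271 + hash(stage) · 7919) mod (2³¹ − 1)`), so any stage can be
replayed in isolation and a rerun is byte-identical, including the
`summary.json` it writes. The test suite validates on the default
120-spectrum dataset with 100-iteration resampling (seconds per
evaluation); oracle comparisons use toy matrices up to 10 × 10 where
brute-force eigensolves and reference implementations are exact.

# Known limitations

* The despiking and screening defaults were calibrated on the synthetic
  noise model (Poisson counts); very different detectors may need the
  window, threshold or flank re-examined.
* JCAMP-DX support covers plain-number XYPOINTS and X++(Y..Y) tables only,
  not SQZ/DIF compression.
* The screen decides per spectrum; it does not borrow strength across
  sites of a specimen, and it cannot distinguish a genuine weak mineral
  trace from any other in-band feature of comparable prominence.
* PLS-DA is linear; strongly nonlinear class structure is out of scope, as
  are sparse/kernel variants and probability calibration.
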