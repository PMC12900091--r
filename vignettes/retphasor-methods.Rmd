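---
title: "Phasor-based classification of multispectral retinal images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based classification of multispectral retinal images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retphasor)
```

retphasor classifies retinal health from multispectral fundus image cubes.
Each case is an H x W x n stack of narrow-band images (by default n = 12
LED bands peaking at 416-955 nm). The pipeline compresses every pixel's
spectrum to a two-dimensional *spectral phasor*, summarizes a retina (or an
anatomical region of it) into a two- or three-number feature vector,
classifies healthy versus diseased cases with classical machine-learning
models, and tests group separation with a two-group MANOVA. This vignette
explains each model, the tunable parameters, and the design choices made
where the procedure was genuinely open.

## Reflectance calibration

Raw sensor output is a digital level (DL), not a tissue property: it folds
in LED power, sensor sensitivity and dark current, all wavelength-dependent.
`compute_reflectance()` converts DLs to spectral reflectance per pixel
$(i, j)$ and band $\lambda_n$:

$$
R_{\lambda_n}(i,j) =
\frac{DL_{\lambda_n}(i,j) - DL^{dark}_{\lambda_n}(i,j)}
     {DL^{white}_{\lambda_n}(i,j) - DL^{dark}_{\lambda_n}(i,j)}
\cdot R^{ref}_{\lambda_n},
$$

where the white and dark cubes are images of a calibrated reference target
and of the sensor without illumination, and $R^{ref}$ is the target's
certified per-band reflectance (default 0.95, accepted as a vector because
certified targets are rarely spectrally flat). Two choices matter:

* **No clipping.** Noise can push $R$ slightly below 0 or above $R^{ref}$;
  values are preserved because the downstream Z-score makes clipping both
  unnecessary and distorting.
* **Denominator guard** `eps` (default 1 DL): where white minus dark falls
  below the sensor noise floor the ratio is meaningless, so the pixel is
  marked invalid rather than given an arbitrary value.

## Band-wise Z-score normalization and trimming

Absolute reflectance varies with acquisition (pupil size, media clarity,
illumination geometry) more than with pathology. `zscore_bands()`
standardizes each band independently over the entire-retina mask,
$Z = (X - \mu)/\sigma$, with the *population* standard deviation — the
statistic describes the full pixel population of the scope, not a sample
from it. After normalization every band has mean 0 and variance 1 inside
the scope, so only relative, wavelength-specific contrast survives.

Z-scored distributions have heavy tails (specular reflexes, mask edges),
so `trim_percentiles()` removes, per band, pixels strictly below the 20th
or strictly above the 80th percentile of the analysis scope (linear-
interpolation percentiles; strict inequality so ties at the boundary
survive). A pixel trimmed in *any* band is dropped entirely, because the
phasor transform needs the full spectrum; surviving spectra are never
altered, only the validity mask changes.

Two scope decisions were open and are fixed as follows:

* **Z-score statistics are always global** (entire retina), even for
  region-of-interest analyses. Normalizing inside a small ROI would erase
  exactly the inter-region contrast the features rely on and make
  $\sigma$ unstable for ROIs of a few hundred pixels.
* **Trimming is local to the analysis ROI.** Anatomically distinctive
  regions (vessels, optic disk, macula) are, by construction, tails of the
  *global* per-band distributions; trimming against global percentiles can
  therefore remove a small ROI wholesale. Trimming against the ROI's own
  percentiles removes that ROI's outliers, which is the operation's intent.

## The spectral phasor transform

`phasor_transform()` maps a pixel's spectrum $I(m)$, $m = 0, \dots, n-1$ in
ascending wavelength, to one Fourier harmonic $k \in \{1, \dots, n-1\}$,
normalized by total intensity:

$$
g = \frac{\sum_m I(m)\cos(2\pi k m/n)}{\sum_m I(m)}, \qquad
s = \frac{\sum_m I(m)\sin(2\pi k m/n)}{\sum_m I(m)}.
$$

Properties the test suite verifies exactly: a flat spectrum maps to the
origin; a single-band spectrum maps onto the unit circle at its band's
phase; any nonnegative spectrum stays inside the unit disk (the phasor is a
convex combination of unit-circle points); the transform is invariant to
intensity scaling; and spectral mixtures map to intensity-weighted linear
combinations of their components' phasors — the property that makes phasor
coordinates a faithful low-dimensional summary of spectral shape.

Design choices:

* **Phase axis.** The default phase is uniform per channel,
  $\varphi_m = 2\pi k m / n$ — the standard spectral-phasor convention, under
  which a single camera's constant channel bandwidth cancels in the ratio.
  A wavelength-proportional axis
  ($\varphi = 2\pi k (\lambda - \lambda_0)/(\lambda_n - \lambda_0)$, sums
  weighted by per-band bandwidth) is available via
  `phase_axis = "wavelength"` for spectrometer-style data with uneven band
  spacing.
* **k = 0 is never a feature** — after normalization it is identically
  $(1, 0)$.
* **Denominator guard.** Z-scored spectra sum to approximately zero for
  unremarkable pixels. Dividing by a near-zero sum makes the per-pixel
  phasor heavy-tailed (the ratio of two near-zero quantities carries no
  phase information, only noise), and a plain average over such pixels is
  noise-dominated. The feature pipeline therefore applies an adaptive
  guard, `min_denom_quantile = 0.5`: only pixels whose $|\sum_m I(m)|$ lies
  above the median of the analysis scope enter the phasor average. This is
  the spectral analogue of the intensity threshold routinely applied before
  lifetime-phasor analysis, where dim pixels are excluded for the same
  reason. For unnormalized reflectance the sums are bounded away from zero
  and only the absolute guard (`eps`, default 1e-6) applies.

`summarize_phasor()` averages the per-pixel coordinates over the scope into
$(g_{avg}, s_{avg})$ and reports a scalar dispersion
$STD = \sqrt{\mathrm{var}(g) + \mathrm{var}(s)}$ (population variances).
A single rotation-invariant scalar was chosen over separate per-component
deviations so that the three-feature set is exactly
$(g_{avg}, s_{avg}, STD)$.

The averaging baselines `band_average_features()` produce the per-band mean
reflectance over the scope: 12 features for the full cube ("Avg-MSI"),
3 for the RGB-like sub-cube ("Avg-RGB"). `extract_rgb_like()` builds that
sub-cube from the bands at 471, 595 and 732 nm, emulating a conventional
color fundus camera's blue, green and red channels.

## Classification protocol

`evaluate()` applies a repeated random hold-out: `round(0.7 n)` cases train,
the rest test, 10 repetitions, unstratified, all driven by one seed; the
same split list is shared by every feature set, classifier, harmonic and
ROI within an experiment so that rows of a comparison table differ only in
the quantity being compared. Four classifiers are supported: Nearest
Centroid and Gaussian Naive Bayes consume raw features; the SVM and nu-SVC
(RBF kernel; cost 1 and nu 0.5 — conventional defaults, exposed as
hyperparameters) receive features standardized with the training split's
mean and standard deviation, fitted on the training data only, with
`gamma = 1/(d Var(X_train))`. Six metrics are reported per repetition and
averaged: overall accuracy, balanced accuracy, specificity, sensitivity,
precision and F1. The *diseased* class is the positive class throughout —
sensitivity measures disease detection — and any 0/0 metric is 0 by
convention, with a warning.

## Group statistics

`manova_wilks()` compares the multivariate feature means of the two groups
with Wilks' Lambda, $\Lambda = \det(W)/\det(W+B)$, computed from
sums-of-squares-and-cross-products scatter matrices ($\Lambda$ is invariant
to degrees-of-freedom scaling). Only the two-group case is implemented: the
F transform $F = \frac{1-\Lambda}{\Lambda}\cdot\frac{n-d-1}{d}$ on
$(d, n-d-1)$ degrees of freedom is then *exact* via the Hotelling $T^2$
identity, so no general multi-group approximation is needed. Phasor
representations enter with exactly $d = 2$ dependent variables
$(g_{avg}, s_{avg})$; the averaging baselines with $d$ equal to their band
count (3 or 12). No covariates are modeled.

## The synthetic data generator

No clinical multispectral fundus dataset is publicly deposited, so
`generate_dataset()` fabricates one with the statistical structure the
analysis assumes, making every downstream stage testable. Defaults are the
study conditions used across the test suite: 73 healthy and 60 diseased
cases, 12 bands, 64 x 64 pixels (a computational downscale that preserves
the anatomy/lesion geometry; the native sensor's 1757 x 1757 field adds
pixels, not structure, to the per-case averages).

**Anatomy.** A circular retina field contains a bright optic-disk ellipse,
a darker macular disk on the opposite side, a branching random-walk vessel
network rooted at the disk, and background; the four regions partition the
retina, and masks for each are emitted alongside every cube. Tissue
reflectance curves are smooth parametric forms — a melanin-like sigmoid
rise toward the red/NIR times Gaussian absorption dips (hemoglobin near
555 nm for vessels, macular pigment near 460 nm) — with contracts the tests
assert: vessels darker than background in the 500-600 nm window, optic disk
brightest everywhere, all values in (0, 1].

**Inter-subject variability.** Each case draws its own vessel density
(5-7 roots, widths scaled to the field), per-tissue brightness and
melanin-slope factors (lognormal, sd 0.03) and absorption-dip depths
(Gaussian, sd 0.05). These nuisances apply identically to both classes.

**Disease model.** Diseased cases receive focal drusen-like lesions:
Gaussian blobs (about 20 per case, radii 2-5 px) scattered inside the
configured extent (whole retina by default; optionally confined to the
macula, disk or vessels), plus a smooth low-amplitude widespread component
(relative amplitude 0.5) standing for the diffuse changes of advanced
disease. Lesions add reflectance with a band-limited Gaussian spectral
profile peaked at 560 nm (width 60 nm), so the contrast lives mainly in the
494-624 nm bands. The focal/diffuse structure matters: a spatially
*uniform* additive shift would be removed exactly by per-case band-wise
Z-scoring, leaving nothing to detect. The default peak contrast of 0.3 was
chosen, together with the nuisance levels below, to represent advanced,
clearly expressed disease — the regime in which the pipeline's
classification claims are meaningful; it is a synthetic setting, not a
biologically calibrated one.

**Noise.** Three acquisition nuisances: a per-pixel lognormal illumination
field shared across bands (sd 0.05), a *per-band* smooth illumination
nonuniformity field (amplitude 0.10; each band is lit by its own LED, so
each acquisition carries band-independent smooth structure that a flat
reference cannot remove) and additive Gaussian sensor noise on digital
levels (sd 30 DL). The forward model
`DL = dark + (white - dark) * R / refl_ref`, clipped to the 16-bit range,
is exactly the model calibration inverts, which the tests verify to 1e-10
with noise disabled.

**What the generator does not emulate** — and hence what passing tests do
not show about clinical data: real lesion morphology (drusen shapes,
hemorrhages, exudates), disease-specific spectral signatures, eye-motion
artifacts and inter-band misregistration, optical blur, and the diversity
of real pathologies. Results on this generator validate the *pipeline
mechanics* (calibration exactness, transform correctness, estimator and
test calibration, and the internal ordering of representations under a
narrow-band disease signature), not clinical performance.

## Experiment orchestration

`run_experiment()` reproduces the full comparison structure on one dataset:
classifier comparison on unnormalized first-harmonic phasors, harmonic
comparison (k = 1..4 by default) with the nu-SVC, MANOVA per harmonic, the
normalization/STD ablation, the four-representation comparison and its
MANOVA counterpart, and the per-ROI comparison. For region analyses,
`roi_case_filter()` drops diseased cases whose configured extent does not
intersect the region (a macula-confined disease is uninformative about the
optic disk) while keeping every healthy case. ROI rows with reduced case
sets regenerate splits from the same protocol seed.

## Numerical and testing notes

* Cubes are stored as multi-page TIFF (one page per band, ascending
  wavelength) with a JSON sidecar carrying band metadata, stage and the
  scale/offset mapping into the TIFF sample range. Raw digital levels use
  16-bit pages and round-trip integer DLs bit-exactly; floating-point
  stages use 32-bit pages, which quantize to about `range * 2^-32` — ample
  for values that feed Z-scoring, but not arbitrary-precision storage.
* Percentiles are type-7 (linear interpolation); exclusion is strict, so
  constant bands trim nothing.
* The test suite sizes simulations to its purpose: the MANOVA type-I
  calibration runs 500 zero-effect datasets of 10+10 cases at 32 x 32
  pixels; the effect-size monotonicity check uses 16 seeds of 16+16 cases
  at 40 x 40; classification-level acceptance checks use the full default
  133-case, 64 x 64 configuration.
* Known limitations: the two-group MANOVA does not extend to more groups
  or covariates; no stratified splitting (the default dataset is close to
  balanced); SVM hyperparameters are fixed conventions, not tuned; and the
  adaptive phasor denominator guard discards half of each scope's pixels by
  design, which is appropriate for scope-averaged features but would be
  wasteful for dense per-pixel phasor maps.
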