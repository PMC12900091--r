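# retphasor

Spectral phasor analysis of multispectral retinal images, for researchers
evaluating whether narrow-band fundus imaging separates healthy from
diseased retinas better than conventional color photography.

Multispectral fundus cameras record one image per narrow illumination band
(here: 12 bands peaking at 416–955 nm), giving every pixel a reflectance
spectrum. That richness is also a burden: 12 correlated values per pixel
for datasets of at most a few hundred eyes. retphasor compresses each
pixel's spectrum to one Fourier harmonic, normalized by total intensity —
the **spectral phasor**

```
g = Σₘ I(m) cos(2πkm/n) / Σₘ I(m),   s = Σₘ I(m) sin(2πkm/n) / Σₘ I(m)
```

so a retina (or one anatomical region of it) becomes a single point
(g_avg, s_avg), optionally with a dispersion scalar STD. Phasor coordinates
are scale-invariant, confined to the unit disk for nonnegative spectra, and
linear under spectral mixing, which makes them a faithful two-dimensional
summary of spectral *shape*.

The package implements the full analysis pipeline:

* **Calibration** — digital levels to reflectance via white-reference and
  dark-current images: `compute_reflectance()`.
* **Normalization** — band-wise Z-score over the retina plus percentile
  trimming of outlier pixels: `zscore_bands()`, `trim_percentiles()`.
* **Features** — per-pixel phasor transform at any harmonic, whole-retina
  or per-ROI summaries, and per-band averaging baselines (Avg-MSI /
  Avg-RGB, with an RGB-like 3-band sub-cube emulating a color camera):
  `phasor_transform()`, `summarize_phasor()`, `band_average_features()`,
  `extract_rgb_like()`.
* **Classification** — Nearest Centroid, Gaussian Naive Bayes, SVM and
  nu-SVC under a seeded, repeated 70/30 hold-out with six metrics:
  `evaluate()`.
* **Statistics** — two-group MANOVA with Wilks' Lambda (exact F via the
  Hotelling T² identity): `manova_wilks()`.
* **Synthetic data** — a generator of full datasets (cubes, reference
  images, ROI masks, labels) with realistic anatomy, acquisition noise and
  a configurable focal+diffuse disease model, so the entire pipeline is
  testable without clinical data: `synthetic_config()`, `generate_dataset()`.
* **Orchestration** — `run_experiment()` produces the complete set of
  comparison tables (classifiers, harmonics, normalization ablation,
  representations, MANOVA, ROIs) from one configuration.

File formats: cubes are multi-page TIFF with a JSON sidecar, masks are
single-channel PNG, feature tables are CSV, manifests are JSON.

## Worked example

```r
library(retphasor)

# 30-case synthetic dataset: 16 healthy, 14 diseased retinas, 12 bands
cfg <- synthetic_config(n_healthy = 16, n_diseased = 14,
                        image_size = c(64, 64), seed = 11)
ds <- generate_dataset(cfg)

# Z-scored first-harmonic phasor features, whole retina
tab <- build_feature_table(ds, "phasor_msi", harmonic = 1,
                           normalize = "zscore")
head(tab, 3)
#>   case_id   label       g_avg       s_avg
#> 1    H001 healthy  0.12044894 -0.02490418
#> 2    H002 healthy -0.06545279 -0.29669211
#> 3    H003 healthy  0.15347153 -0.15148914

# repeated 70/30 hold-out with the nu-SVC
evaluate(tab, split_protocol(0.7, 10, seed = 42), "nusvc")
#> classification_report (nusvc, 10 reps): OA 99% BA 99% spec 1.00 sens 0.99 prec 1.00 F1 0.99

# two-group MANOVA on (g_avg, s_avg)
manova_wilks(tab[c("g_avg", "s_avg")], tab$label)
#> Wilks' Lambda = 0.186 [F(2, 27) = 59.09], p = 1.37e-10
```

Each feature-table row is one eye: (g_avg, s_avg) is the average phasor of
its retina's Z-scored spectra at the first harmonic. The report's balanced
accuracy (99%) says the two synthetic classes are almost perfectly
separable in that plane under this dataset's large disease effect; Wilks'
Lambda = 0.186 means within-group scatter is a small fraction of total
scatter, with the group difference far beyond chance (p ≈ 1e-10).

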