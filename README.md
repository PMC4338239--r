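# adiposim

Whole-body MR quantification of adipose tissue in young infants is attractive
— no ionizing radiation, full 3D coverage — but validating it is hard: the
subjects must sleep through the scan, breathing cannot be suspended, and the
segmentation step dominates the error budget. `adiposim` is an in-silico
laboratory for exactly this validation problem. It simulates water-suppressed
turbo-spin-echo (wsTSE) scans of ground-truthed objects — lard-wrapped tube
phantoms and parametric infant torsos with an analytically known fat volume —
and pushes them through the two segmentation procedures used in practice, so
that accuracy and reproducibility can be measured against a known truth.

The package implements, end to end:

* **Synthetic data** — seeded 3D renders on realistic acquisition grids
  (0.9×0.9×5 mm or 1.1×1.1×5 mm voxels, 1 mm slice gap), with linear
  partial-volume mixing, a multiplicative bias field, suppressed
  connective-tissue streak texture, magnitude-folded Gaussian noise, and
  breathing-artifact surrogates (coherent phase-encode ghosting for cartesian
  scans, residual rotational blur for PROPELLER scans).
* **Segmentation** — (1) threshold-based: voxels above a fixed threshold
  (candidates 150/250/350 between the background mode ≈15 and fat mode ≈420),
  with regions smaller than 25 mm³ excluded; (2) a k-means pipeline:
  bias-field correction, histogram-derived deterministic cluster
  initialization, k-means intensity clustering, and region-based
  active-contour refinement; plus the subcutaneous / intra-abdominal
  separation.
* **Volumetry** — label masks to ml (each slice represents its slab of one
  pitch = thickness + gap) and to grams at an adipose density of
  0.925 g/cm³.
* **Statistics** — accuracy as the root mean square of per-phantom relative
  differences against the analytic truth (the in-silico stand-in for water
  displacement), Pearson r², reproducibility as the RMS of per-subject
  coefficients of variation `cv = sd/mean` with `df = Σ (n_scans − 1)`,
  Fisher-z comparison of correlations, paired t tests and a KS normality
  screen.
* **Study drivers** — `run_phantom_accuracy()` (10 phantoms, 54–300 ml,
  method × sequence × motion grid) and `run_infant_reproducibility()`
  (3 repeats in 7 subjects cartesian, 4+3+3+3 repeats in 4 subjects
  PROPELLER).

## Worked example

```r
library(adiposim)

spec <- build_phantom_spec(target_volume = 172, rng_seed = 7)
spec
#> <phantom_spec> 6 lard layers, true fat volume 172.0 ml (target 172 ml), seed 7

img <- render(spec, phantom_geometry("cartesian"), rng_seed = 1)
find_histogram_peaks(img)
#> background_peak        fat_peak
#>              15             435

vol_km  <- mask_volume(kmeans_segment(img))
vol_150 <- mask_volume(threshold_segment(img, threshold_config(150)))
c(kmeans = vol_km, thr150 = vol_150, truth = analytic_fat_volume(spec))
#>   kmeans   thr150    truth
#> 182.3909 167.2229 172.0000
```

The clustering pipeline lands a few percent *above* the analytic truth (it
keeps the partial-volume rim and re-fills suppressed septa), the
threshold-based mask a few percent *below* it (partial-volume and
low-intensity fat voxels fall under the cutoff) — the over/under pattern that
makes the choice of segmentation the dominant accuracy factor. Raising the
threshold to 250 or 350 loses a large share of the fat volume outright.

A full study, with reports written as CSV/JSON:

```r
study <- run_phantom_accuracy(
  experiment_config(study = "phantom_accuracy", seed = 1,
                    out_dir = "results/phantom")
)
tidy(study)      # RMS error, r2, mean signed error per method x condition
autoplot(study)
```

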