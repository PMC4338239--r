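---
title: "Simulating and segmenting water-suppressed MR scans of infant adipose tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and segmenting water-suppressed MR scans of infant adipose tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(adiposim)
```

## The problem

Measuring body fat in young infants by whole-body MR requires two things the
scanner cannot give you directly: a *reference truth* to quantify accuracy,
and *repeat scans* to quantify reproducibility. Physical phantoms with a
known fat volume provide the first; scanning a sleeping infant three or four
times provides the second. `adiposim` reproduces both study designs fully in
silico, replacing the physical truth (volume by water displacement) with the
analytic volume of parametric specs, so every stage — contrast, artifacts,
segmentation, volumetry, statistics — can be exercised, stressed and tested
against a known answer.

## Image model

Water-suppressed TSE contrast is modelled at image level, not at pulse-
sequence level. Water and air are suppressed to a background-noise mode at
15 scanner units; adipose tissue sits at a mode of 420. In between, a voxel
containing a fat fraction $f$ takes the linearly mixed intensity

$$ I = I_{bg} + f\,(I_{fat} - I_{bg}), $$

with $f$ computed by sub-voxel supersampling (default $5\times5$ in-plane
sample points per voxel; through-slice coverage is closed-form for extruded
solids and sampled at 5 positions across the slice thickness otherwise).
Slices integrate over the 5 mm slice thickness only and are placed at a
pitch of thickness + gap (6 mm): the gap is never imaged, exactly as in
gapped 2D multi-slice acquisitions.

On top of the two-point contrast the renderer applies, in order:

* **Bias field** — a multiplicative order-2 polynomial, centre-bright
  (coil-sensitivity shape) plus a small seeded random polynomial, bounded at
  ±12% by default. It is anatomy/session-locked (seeded by the spec), so
  back-to-back repeats share it.
* **Streak texture** — 15% of the fat volume is occupied by voxel-scale
  speckle at 25% of the local fat intensity, standing in for thin
  connective-tissue septa and water content that the water suppression
  nulls. It is the reason a fixed threshold loses fat volume even well below
  the fat mode, and it is anatomy-locked.
* **Noise** — additive Gaussian with sd 12, folded to magnitude
  (absolute value). Both tissue modes are far from zero, so the Rician tail
  would change nothing measurable; the fold only prevents negative
  intensities near the background mode.

Intensities are arbitrary "scanner units" anchored to the histogram modes
15/420; nothing is normalized across subjects.

### Phantoms

`build_phantom_spec(target_volume, rng_seed)` wraps 2–4 mm-thick, ~5 cm-wide
layers of lard around two 6 cm water tubes (an empty breathing tube sits
between them). Wraps are separated radially by a 2.2 mm signal void — the
sealed bags the lard is kept in — which multiplies the exposed surface, the
design feature that makes partial-volume errors visible. Wrap arcs placed on
the outer slots avoid the sector facing the other tube, which guarantees the
wraps never interpenetrate; the union volume is then an exact sum of annular
sector volumes, and the final wrap's arc is solved so the spec lands on the
requested target. The brute-force counting oracle (`raster_fat_volume()`)
verifies both the volume and the disjointness.

### Infants

`build_infant_spec(rng_seed)` builds a desk-scale torso: a cylinder of
suppressed tissue carrying a subcutaneous fat shell whose thickness varies
around the circumference (first and second circular harmonics of a 5–7 mm
base), tapering to zero over the last 15 mm of the torso — subcutaneous fat
thins out; a flat-faced shell would make entire end-slice rings flip across
segmentation cutoffs when repositioning jitter moves the slab coverage.
Inside sit a few small ellipsoidal depots (about a tenth of the shell
volume; young infants carry little internal fat). Two arms flank the torso
and, by default, carry regions of *imperfect water suppression* at ~40% of
the fat-background contrast — the confounder that defeats fully automatic
intensity segmentation of the extremities in practice. Shell (quadrature)
and depot (closed-form) volumes give the exact compartment truths.

Reproducibility statistics are scale-invariant (they are built from
per-subject coefficients of variation), so the smaller-than-life torso does
not distort them; what matters is that the per-repeat perturbations are
realistic.

### Breathing artifacts

Both surrogates act in image space; reconstruction physics is out of scope.

* `cartesian_ghost`: periodic motion modulates cartesian k-space line to
  line, so the surrogate superimposes attenuated replicas of the image
  displaced along the phase-encode axis (weights summing to
  $\rho = A/(A+12)$ at amplitude $A$ mm, randomized spacing), plus a small
  Gaussian smear (sd $A/8$ mm). Circular shifts conserve total intensity
  exactly.
* `propeller_blur`: rotating-blade acquisitions scatter the same motion
  incoherently and correct most of it; the residual is modelled as the
  average of the image under small in-plane rotations. The rotation spread
  is fixed (normal quantiles scaled to an edge displacement of about
  $A/20$), with only a small seeded phase jitter: breathing at 50/min is
  periodic, so the blade-to-blade pattern is reproducible between repeats
  while its phase is not.

The default amplitude of 2.5 mm corresponds to the chest excursion of
roughly a 20 ml tidal breath in a young infant. Repeat series add
independent noise, independent artifact realizations and a rigid
repositioning jitter (sd 0.4 mm) per repeat.

## Segmentation

Two procedures, deliberately asymmetric:

**Threshold pipeline.** All voxels strictly above the threshold (150, 250 or
350) are adipose; connected regions smaller than 25 mm³ are excluded.
Components are 2D 8-connected within each slice, with volume = area × slice
thickness: a ≥1 mm slice gap makes through-plane connectivity of thin
structures physically dubious. Thresholding operates on *raw* intensities —
the bias-field correction belongs to the clustering pipeline only.

**k-means pipeline** (four stages): (i) bias-field correction — an order-2
polynomial fit to the log-intensities of nearly-pure fat voxels (above 75%
of the fat mode, with one residual-trimming refit pass), divided out;
(ii) deterministic parameter estimation — initial cluster centers from the
histogram modes (background, fat, and the midpoint for the default
3-cluster background / partial-volume / fat model), never random, so the
reproducibility study is not confounded by algorithmic randomness;
(iii) Lloyd k-means on the corrected intensities; (iv) adipose detection by
a region-based active contour: starting from the highest-center cluster,
voxels are reassigned to minimize the two-phase piecewise-constant energy
with Chan–Vese weights $\lambda_{out}/\lambda_{in} = 1.6$, alternating with
a 3×3 binary-median curvature pass (replicated image edges), 12 iterations,
ending on a smoothing pass. The corrected image is denoised beforehand with
an in-plane Gaussian of 1.1 voxel FWHM — the standard preprocessing for
intensity clustering; without it, voxel-scale suppressed septa inside thin
fat layers defeat the curvature regularizer (a boundary-row streak voxel has
too few fat neighbours to be re-filled) and the clustering inherits the
thresholds' deficit.

The asymmetry produces the characteristic error structure: the clustering
pipeline keeps the partial-volume rim and re-fills the septa, landing a few
percent *over* the truth; thresholds lose septa and rim and land *under*,
increasingly so at 250 and 350 where genuinely darkened fat (bias-field
periphery, partial slabs) falls below the cutoff.

The unequal Chan–Vese weighting is the textbook response to unequal class
variances — the adipose class, spread by partial volume and texture, is far
broader than the suppressed background — and its default (1.6) was fixed
together with the generator calibration below.

**Compartment separation.** The body outline is built per slice by
morphological closing of the adipose mask and hole filling; adipose
components touching the outline's surface band are subcutaneous, the rest
intra-abdominal, so the two labels always partition the adipose voxels.
When the ring fails to enclose an interior on more than 30% of the
fat-bearing slices (an open outline — e.g. a shell gap wider than the
closing radius), the result is flagged low-confidence with a warning rather
than silently returned. In the manual workflow this is where an operator
would intervene; the automated exclusion of non-body components replaces
that interaction here.

## Volumetry and statistics

`mask_volume()` reports voxel count × in-plane area × pitch: each slice
stands for its full 6 mm slab, which is how whole-body volumes are
extrapolated across unimaged gaps (a `slab = "thickness"` mode supports
sensitivity analyses of that choice; on smooth objects halving the pitch
moves volumes by under 2%). Mass uses 0.925 g/cm³.

Accuracy is the RMS of per-phantom relative differences versus the analytic
truth, with Pearson r² alongside; reproducibility is the RMS of per-subject
CVs (sample sd over mean; the n−1 convention is the standard one for
repeated measurements), with df = Σ(n_scans − 1). Both are scale-invariant.
Fisher-z comparison of correlations, two-sided paired t tests (zero-variance
differences are flagged, not silently given a p of 1) and a KS screen
against a fitted normal complete the statistics module. The p < 0.05 level
is a report annotation; no multiple-testing correction is applied, matching
the validation-study practice the module mirrors.

## Study drivers and design sizes

`run_phantom_accuracy()` builds 10 phantoms spanning 54–300 ml, renders each
motionless with both sequence geometries (cartesian 0.9 mm /
PROPELLER 1.1 mm — the sequence difference is represented by resolution +
artifact mode), applies the breathing surrogate for the breathing condition,
segments with k-means and thresholds 150/250/350, and reports the RMS error,
r² and mean signed error per cell. `run_infant_reproducibility()` renders
3 repeats in each of 7 cartesian-arm subjects (df = 14) and 4+3+3+3 repeats
in 4 PROPELLER-arm subjects (df = 9; the first PROPELLER subject is the
first cartesian subject re-scanned, as one infant took part in both arms),
segments every repeat with k-means, thr150 and thr250, separates
compartments for k-means only, and reports RMS-CV per
sequence × method × compartment. Everything derives from one master seed;
rerunning a config reproduces the outputs bit for bit. A full phantom study
takes on the order of two minutes on one CPU; the infant study a few
minutes more — sizes chosen so the complete validation suite stays
interactive.

## Calibration and what the defaults mean

The generator's free parameters (noise sd, bias amplitude, streak fraction /
depth / scale, artifact weights, jitter) have no published values to copy;
they were calibrated once, before the acceptance tests were frozen, to make
the in-silico studies *meaningful* — error levels comparable to the physical
validation rather than trivially clean — and have not been revisited since.
The structural findings (over/under sign pattern, error growth with
threshold, artifact-mode ranking, compartment-separation penalty) are
properties of the mechanisms, not of a particular seed: they hold across the
seed-swept probes used during calibration.

## Numerical choices and degenerate inputs

* Supersampled fractions make renders deterministic given (spec, geometry,
  model, seed); raster volume converges to the analytic volume as the
  supersampling factor grows (tested over doublings).
* The counting oracle needs a grid a few times finer than the thinnest
  structure: tapering infant shells fall below 0.5 mm near their ends, so
  oracle comparisons there use finer grids or slightly wider tolerances
  than the 0.5% used for phantoms.
* Ties at a threshold go to background (strict `>`).
* A constant image has no separable classes: peak finding (and everything
  downstream of it) fails with a typed error instead of guessing.
* `remove_small_regions()` is idempotent and never adds voxels;
  `min_volume = 0` is the identity.
* With zero noise, zero bias, no texture and no partial volume, the k-means
  pipeline reduces exactly to midpoint thresholding. With curvature
  smoothing enabled the identity holds for boundaries without curvature
  (straight edges); any curvature regularizer moves corners, which is its
  purpose.
* Breathing operators at amplitude 0 return the input unchanged; both
  conserve total image intensity to well under 1%.

## Limitations

The simulator reproduces the *statistical structure* of the validation
problem, not infant anatomy: organs, bowel gas and milk (unsuppressed fatty
signal in the gut), long-term scanner drift, and operator interaction are
absent, and k-space physics (echo trains, GRAPPA, blade regridding) is
represented only through image-level surrogates. Passing the in-silico
studies therefore demonstrates that the pipeline's algorithms behave
correctly under controlled contrast, partial volume, inhomogeneity, noise
and motion surrogates — not that any particular accuracy figure transfers
to a given scanner and protocol. Real histogram anchors, thresholds and
artifact levels must be re-derived per protocol, exactly as the
histogram-derived thresholds here were derived from the rendered data.
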