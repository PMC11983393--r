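---
title: "Validating expansion microscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating expansion microscopy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmqc)
options(exmqc.verbose = FALSE)
```

`exmqc` quantifies three things about an expansion-microscopy experiment:
the expansion factor, the nonrigid distortion left after rigid scaling,
and the apparent size and spatial grouping of sub-diffraction puncta.
This vignette explains the underlying models, the parameters a user may
need to touch, the numerical decisions taken where several defensible
options existed, and what the synthetic-data tests do and do not
demonstrate about real data.

## Conventions

Volumes are arrays in `(z, y, x)` order (planes `(y, x)`), with per-axis
voxel sizes in nanometres at the *expanded-sample* scale. All public
coordinate tables (landmarks, punctum centers, point clouds) are 0-based,
one convention across every module and file format so no transpose or
off-by-one ambiguity can creep in between stages. Distances at native
tissue scale are expanded distances divided by the expansion factor.
Physical image metadata travels in a JSON sidecar next to each TIFF; the
sidecar is authoritative because TIFF resolution tags cannot portably
carry z spacing.

## Expansion factor from paired landmarks

The model is a similarity transform: `post = s·R·pre + t` with isotropic
scale `s > 0`, proper rotation `R` (reflections excluded) and translation
`t`. `estimate_similarity()` solves the least-squares problem in closed
form (Procrustes/Umeyama). A closed form was preferred over iterative
optimization because it returns the global optimum of the stated
objective deterministically; the test suite cross-checks it against a
coarse-to-fine grid search over `(s, θ)` with the translation solved
analytically per node.

Landmarks are converted to physical units with each image's voxel sizes
*before* fitting. With equal pixel sizes this is equivalent to fitting in
pixels, but when pre- and post-expansion images were acquired at
different magnifications (e.g. 100 nm pre vs 90 nm post pixels), or with
anisotropic voxels, fitting in pixel units would bias the scale; whether
the original workflow minimized pixel or physical residuals is not
decidable from the outside, and physical units are the choice that keeps
the estimate acquisition-independent. 2D landmark tables (no `*_z`
columns) are supported because post-expansion data is sometimes a single
optical slice.

Degenerate configurations (coincident or collinear landmarks) raise an
error rather than returning an arbitrary rotation. Both per-specimen and
pooled expansion factors are supported (`summarize_expansion_factors()`);
per-specimen is the default since expansion varies between gels.

## Distortion as measurement error versus measurement length

The pipeline (`distortion_pipeline()`) chains:

1. **Alignment.** The pre-expansion image is resampled onto the post grid
   through the fitted similarity transform (linear interpolation,
   out-of-support voxels zero, 3D inputs maximum-projected after
   alignment).
2. **Appearance matching.** Both images are smoothed (defaults σ = 1 px
   for the resampled pre image, σ = 6 px for the post image — the
   resampled pre image is already magnified ~4× and therefore smooth;
   the assignment can be swapped by argument if an acquisition inverts
   the relation) and background-subtracted with a σ = 80 px Gaussian
   blur of themselves; negatives clip to zero.
3. **Foreground masking.** Each preprocessed image is thresholded and the
   masks combined by logical OR (single-image masks available), then a
   morphological closing (disc radius 2 px) removes small spurious
   holes. The default threshold is Otsu's method: a visually chosen
   threshold is not reproducible, Otsu is deterministic, and a manual
   `threshold` override exists for cases where Otsu fails. Pairs are
   sampled from the OR mask so that features present in either image
   contribute.
4. **Nonrigid registration.** A demons-type algorithm estimates the
   residual displacement field: per-iteration updates from intensity
   differences and symmetric image gradients, step magnitude capped at
   2 px, Gaussian regularization of the accumulated field after every
   iteration, on a 3-level multi-resolution pyramid with 100 iterations
   per level. The inner loop is compiled (Rcpp). Both inputs are
   rescaled to a common brightness before registration since the update
   is intensity-driven. The field-smoothing default is σ = 3 px, chosen
   by the planted-warp recovery experiment below (σ between 2 and 4
   trades noise suppression against fidelity to short-wavelength
   distortion; 3 px minimized the median endpoint error on textured
   scenes with 30 px correlation length and ~3 px amplitude). If the
   mean absolute intensity mismatch fails to decrease over a level the
   field is still returned, flagged `converged = FALSE`, with a warning.
5. **Statistic.** 200,000 feature-point pairs are drawn uniformly with
   replacement from the mask (degenerate pairs resampled; sampling is
   seeded and reproducible). For each pair the measurement length
   `L = ‖p − q‖` and error `e = ‖d(p) − d(q)‖` are converted to
   pre-expansion micrometres and binned (default 1 µm bins). Each bin
   reports mean, SD, RMS, the mean length and the pair count. Because
   `e` depends only on displacement *differences*, any constant offset of
   the field cancels exactly — which is also why the synthetic residual
   field is calibrated on differential rather than absolute displacement.

Binning choices the statistic itself does not dictate: bins are kept up
to the 95th percentile of sampled pair lengths and bins with fewer than
50 pairs are dropped — outermost bins sample only the extreme corners of
the mask and are unstable (their apparent drops are a sampling artifact,
so monotonicity of the curve is deliberately not asserted anywhere).
`rms_across_samples()` pools curves across specimens by pair-count-
weighted RMS of the squared errors: pooling squared errors equals the
RMS over all pairs of all specimens, which keeps the estimator unbiased
when specimens contribute different pair counts per bin.

## Punctum detection, FWHM and clustering

Raw photon counts are normalized by the image's 99.9th percentile
(linear-interpolation quantile), which makes all brightness thresholds
relative and the whole pipeline invariant to multiplying the raw image
by a constant — asserted as a property test. Detection smooths with an
isotropic Gaussian and takes local maxima under full 8/26-connectivity;
a maximum must be ≥ every neighbor and > at least one, so flat regions
and plateau interiors yield nothing while twin equal peaks survive until
the minimum-separation rule keeps the brighter (greedy in descending
brightness, index-stable for exact ties). The brightness cutoff is
relative to the *smoothed* image maximum, because that is the scale on
which the maxima were found (a raw-image option exists).

Standard parameterizations, expressed in pixels with their physical
meaning at the standard acquisition settings:

| mode | smoothing | brightness cutoff | isolation | fit window |
|------|-----------|-------------------|-----------|------------|
| 2D (30 nm px) | σ 3.3 px (~100 nm) | 25% of max | 30 px (900 nm) | 41 px |
| 3D (100 nm voxel) | σ 1 voxel (100 nm) | 25% | 18 voxels (1.8 µm) | 21 voxels |
| 3D cluster detection | σ 0.7 px (70 nm) | 10% | 2 voxels (200 nm) | — |

All of these may equivalently be given in expanded-sample nanometres
(`sigma_smooth_nm`, `isolation_nm`), converted through the voxel size.
Isolation is symmetric — *both* members of a too-close pair are excluded
— reading "separated from other detections" literally; the alternative
(keep one) would feed the fitter spots with a known bright neighbor.
Fits use single planes in 2D mode, matching plane-wise acquisition of
STED images.

Gaussian fits run on the normalized *raw* data (not the smoothed copy)
in a window centered on the candidate: models `iso2d` (4 dof), `aniso2d`
(5), `iso3d` (5), `aniso3d` (7) — amplitude, σ per axis or shared,
subpixel center, *no constant offset term* (these dof counts define the
model; an offset would trade against σ in low-count windows).
Levenberg–Marquardt (minpack.lm) starts from amplitude = window maximum,
σ = detection smoothing σ, center = candidate; σ is bounded to
[0.1, window] and non-convergence is recorded in the output row, never
thrown. Candidates whose window crosses the image edge are skipped and
counted rather than padded — padding with any value biases σ̂.
`FWHM = 2√(2 ln 2)·σ·voxel`, divided by the expansion factor for the
native scale; anisotropic fits report per-axis FWHM and their geometric
mean. Summaries are median and quartiles with the linear-interpolation
convention (alternatives shift quartiles by less than one sample
spacing).

Manual rejection of failed fits is replaced by a deterministic rule set
(`qc_filter()`): converged; all σ in [0.5 px, window/4]; center within
the central third of the window; relative residual < 0.5; amplitude > 0.
On clean synthetic fields these rules reject essentially no good fits
while catching constructed failure cases (overlapping pairs, runaway σ);
each rejection carries its reason.

Clustering uses OPTICS (reachability ordering with unbounded maximum
radius) with xi-steep cluster extraction (ξ = 0.05) including
predecessor correction; unassigned points are noise (−1). The single
exposed tunable is the minimum cluster size (default 10), used both as
the density parameter (`min_samples`) and the size floor — pinning the
extraction variant and coupling the two parameters makes the procedure a
self-contained specification rather than a reference to one library
version's defaults; `min_samples` can still be overridden separately.
Clustering operates in pixel coordinates; anisotropic voxels are
rescaled to physical units first. Interactive 3D rendering is replaced
by `export_point_cloud()` (CSV with pixel and physical coordinates plus
labels).

## The synthetic-data generator

`make_expansion_pair()` emulates the distortion study's inputs:
filaments drawn as cubic splines through random control points
(microtubule-like texture), rendered by point splatting plus Gaussian
PSF blur, Poisson noise on signal + background (photon-counting
detection; Gaussian read noise available, default off). The post image
renders the same filaments through a planted similarity transform
composed with a smooth residual field; landmarks are exact corresponding
spline control points. Defaults — 128×128 pre image at 300 nm pixels,
scale 4 (512×512 post), 12 filaments, peak 150 counts over background 5
— give a ~38 µm pre-expansion field of view of confocal-like overview
data. The residual field is low-pass-filtered white noise (generated on
a padded grid and cropped, so its statistics are stationary rather than
edge-inflated), zero-mean, rescaled so the RMS *pairwise differential*
displacement at a calibration length (default 20 µm) over the structure
support matches the requested amplitude: absolute offsets are invisible
to the measurement-error statistic, and calibrating over the support
makes the planted amplitude the quantity the downstream pipeline
actually measures.

`make_puncta_volume()` plants Gaussian spots (peak = amplitude) with
minimum-separation rejection sampling (bounded retries, explicit packing
error), optional cluster structure (k cluster centers, Gaussian spread,
unclustered fraction), Poisson noise applied last. Truth tables carry
exact subpixel centers, σ, amplitudes and cluster labels.

Everything is bit-reproducible under a fixed seed, and generation is
split into independently seeded stages (geometry / field / noise) so
changing one knob does not silently reshuffle another stage's draws.

What the generator does *not* emulate: real root anatomy and its
spatially varying labeling density, optical aberrations and depth-
dependent PSF broadening, STED depletion physics, vesicle substructure
and antibody linkage error, sample drift. Passing the synthetic tests
therefore demonstrates the *algorithms* recover planted truth under
realistic noise — not that a particular biological dataset is free of
the systematic effects above.

## Validation experiments and problem sizes

The acceptance checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run at sizes chosen to exercise the full
pipelines while staying desk-scale: expansion-factor recovery over 100
landmark sets (planted scale 3.9, 20 landmarks, 0.5 px jitter; median
relative error is required under 2%, observed ~0.05%); the analytic
linear-field identity `mean error = 3% of mean length` to 1e-9; sampled
versus exhaustive pair statistics on a 12×12 mask (10⁶ samples against
all 10,296 pairs, within 1%); end-to-end recovery of a planted 0.5 µm
differential RMS at 20 µm through the complete distortion pipeline on a
512×512 post grid (within 25%; the residual deviation combines the
demons error floor with the realization-to-realization variability of a
smooth random field over a finite mask); FWHM recovery on 200 planted
spots (noiseless median error < 1%, ~100-count Poisson peaks < 5%) with
a dense grid-search cross-check of single fits; OPTICS recovery of
planted two-cluster fields at adjusted Rand index 1; and byte-identical
reruns of every file-writing stage under a fixed seed.

## Known limitations

- Distortion analysis is 2D (projections); axial distortion is only
  captured insofar as it displaces projected structure laterally.
- The demons field is reliable where the mask has texture; between
  structures it is an extrapolation of the regularizer. Bins beyond the
  95th-percentile pair length are suppressed for this reason.
- Distortion claims are meaningful only above the resolution of the
  *pre*-expansion image (~diffraction limit): the field is estimated from
  intensity structure both images share.
- xi-based cluster extraction can trim boundary members of a cluster
  whose reachability profile has internal texture, occasionally labeling
  a few true members noise; in small point sets (n close to the minimum
  cluster size) isolated points can conversely be absorbed, since their
  core distances span the whole set. The planted-cluster tests use
  configurations where the expected partition is unambiguous.
- The automated QC filter is a surrogate for expert visual rejection; on
  data with structured background (out-of-focus planes) its residual
  threshold may need tightening.
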