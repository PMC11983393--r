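# exmqc — quantitative validation of expansion microscopy

Expansion microscopy (ExM) embeds a specimen in a swellable hydrogel and
physically expands it ~4-fold per dimension, so a conventional microscope
resolves structure at an effectively 4× finer scale. Whether the numbers a
lab reports from expanded samples can be trusted hinges on three
quantitative questions:

1. **How much did the sample expand?** The expansion factor `exF` is
   estimated as the isotropic scale `s` of the similarity transform
   (scale + rotation + translation, no shear or reflection) that minimizes
   the squared residuals of ~20 manually paired landmarks between the pre-
   and post-expansion images:
   `argmin_{s,R,t} Σᵢ ‖postᵢ − (s·R·preᵢ + t)‖²`, solved in closed form
   (Procrustes/Umeyama). All native-tissue-scale distances are expanded
   distances divided by `exF`.
2. **How uniform was the expansion?** After rigid scaling, a demons-type
   nonrigid registration yields a dense residual displacement field
   `d(p)`. For feature-point pairs `(p, q)` sampled from the signal
   foreground, the *measurement error* at measurement length
   `L = ‖p − q‖` is `e = ‖d(p) − d(q)‖`; binned over `L` (mean, SD, RMS,
   pre-expansion scale) it tells you how much a distance measurement of a
   given length may be distorted.
3. **How small an object can you measure?** Sub-diffraction puncta
   (e.g. ~45 nm COPI-coated vesicles in plant root tissue, imaged with
   ExM + STED) are detected as smoothed local maxima, isolated, and fitted
   with offset-free 2D/3D Gaussians (Levenberg–Marquardt); the apparent
   size is `FWHM = 2√(2 ln 2)·σ ≈ 2.355·σ`, reported at expanded and
   native scale, summarized as median with quartiles, and grouped with
   OPTICS density clustering (minimum cluster size 10).

`exmqc` implements all three analyses as composable, tibble-first R
functions, plus a synthetic-data generator that plants known transforms,
distortion fields and punctum parameters so every stage can be validated
against ground truth. Audience: microscopy labs running ExM/ExM-STED
experiments and methods developers who need a reproducible, scriptable
validation pipeline instead of one-off notebook code.

## Test suite

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "exmqc", load_package = "installed")'
```

## Worked example

Simulate a pre/post pair of filamentous structures with a planted
expansion factor of 3.9 and a planted nonlinear distortion of 0.3 µm
(differential RMS at 20 µm, pre-expansion scale), then recover both:

```r
library(exmqc)

sim <- make_expansion_pair(seed = 42, scale = 3.9, residual_rms_um = 0.3,
                           calibration_length_um = 20)
fit <- estimate_similarity(sim$landmarks,
                           voxel_size_pre_nm = 300, voxel_size_post_nm = 300)
fit
#> <similarity_transform> 2D, n = 20 landmarks
#>   scale (expansion factor): 3.89497
#>   rotation angle (deg): 2.81343
#>   translation (px, post grid): 4.93061, -1.87493
#>   landmark RMSE (px): 2.242
```

The fitted scale is the expansion factor (planted: 3.9; the ~2 px landmark
RMSE comes from the planted nonlinear distortion, which no similarity
transform can absorb). The full distortion pipeline — resampling,
preprocessing, foreground masking, demons registration, 200,000 sampled
feature pairs — returns the measurement-error curve:

```r
res <- distortion_pipeline(sim$pre, sim$post, sim$landmarks,
                           n_pairs = 200000, seed = 1)
tidy(res)[18:22, ]
#> # A tibble: 5 × 6
#>   bin_center_um mean_err_um sd_err_um rms_err_um mean_len_um n_pairs
#>           <dbl>       <dbl>     <dbl>      <dbl>       <dbl>   <int>
#> 1          17.5       0.262     0.150      0.302        17.5    8447
#> 2          18.5       0.262     0.158      0.306        18.5    8125
#> 3          19.5       0.263     0.152      0.303        19.5    7803
#> 4          20.5       0.260     0.138      0.295        20.5    7481
#> 5          21.5       0.258     0.135      0.291        21.5    7540
```

At the 20 µm calibration length the recovered RMS error is ~0.30 µm — the
planted 0.3 µm, i.e. ~1.5% of the measurement length. `autoplot(res$curve)`
draws the curve, `autoplot(res$field)` the distortion vector field.

Punctum sizing on a synthetic STED-like plane (30 nm pixels, spots of
σ = 1.5–2.5 px, i.e. 27–45 nm native FWHM at exF 3.9):

```r
pv <- make_puncta_volume(shape = c(512, 512), n_puncta = 40,
                         sigma_range = c(1.5, 2.5), amplitude_range = c(80, 150),
                         min_separation_px = 35, background = 1,
                         voxel_size_nm = 30, expansion_factor = 3.9, seed = 7)
fw <- puncta_pipeline(pv$vol, mode = "2d")
glance(fw)
#> # A tibble: 1 × 6
#>   n_detected n_isolated n_qc_pass median_nm q25_nm q75_nm
#>        <int>      <int>     <int>     <dbl>  <dbl>  <dbl>
#> 1         40         40        34     38.8    32.9   42.7
```

All 40 planted spots are detected; 34 survive the automated fit-quality
filter (the rest sit too close to the image edge for a full 41-px fit
window) and their median native-scale FWHM of 38.8 nm matches the planted
size distribution. `cluster_pipeline()` adds OPTICS clustering with noise
labeling, and `export_point_cloud()` writes the labeled point cloud as CSV.

A command-line interface wrapping these pipelines
(`simulate`, `expansion-factor`, `distortion`, `puncta2d`, `puncta3d`,
`cluster`, `profile`) ships at `inst/cli/exmqc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/exmqc.R", package = "exmqc"))')" \
    simulate --out-dir demo --seed 5
```

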