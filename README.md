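# microreflect

Optical thickness metrology for thin protein and other transparent
biomaterial films on oxidized silicon (Si/SiO2) wafers, for the lab that
characterises such films with a reflected-light microscope rather than an
ellipsometer: drop-cast and spin-coated films are often too small or too
nonuniform for area-averaging techniques, while a microreflectance spectrum
from a micrometre-scale spot pins the local thickness to a couple of
nanometres without touching the sample.

## What it computes

The measurement normalises the reflected spectrum on the film against the
bare substrate next to it,

    C(λ) = (I_film − I_subst) / (I_film + I_subst),

which cancels the lamp spectrum and leaves a pure interference signature.
The package:

* simulates `C(λ)` for an air / film / SiO2 / Si stack with the
  transfer-matrix method — per-layer characteristic matrices with phase
  thickness `δ = 2π n t / λ`, complex indices throughout (absorbing Si
  substrate), `R = |r|²` from the matrix product;
* inverts a measured contrast spectrum to film thickness by least squares,
  scanning all interference orders on a coarse grid, refining each local
  minimum, and reporting the global solution with its alternatives and a
  curvature-based uncertainty;
* renders the model reflectance to apparent sRGB colour (CIE 1931 2°
  observer, CIE A halogen illuminant) and builds a thickness–colour lookup
  guide with nearest-colour (CIE Lab) thickness estimation;
* segments bright-field film micrographs into apparent-colour regions with
  k-means (k-means++ seeding, Lloyd iterations), turns pixel counts into
  areas via an explicit mm/px scale and region thicknesses into film
  volumes (1 mm² × 1 nm = 10³ μm³);
* fits linear thickness–concentration calibrations (OLS, 95% t-intervals),
  predicts thickness at a concentration and plans the concentration needed
  for a target thickness;
* ships synthetic-data generators (noisy contrast spectra, multi-region
  film images, noisy calibration tables) with ground-truth sidecars so the
  whole pipeline is testable without laboratory data.

A thin command-line front end over the same functions lives at
`inst/cli/microreflect.R` (subcommands `simulate`, `fit`, `guide`,
`segment`, `calibrate`, `synth`).

## Worked example

```r
library(microreflect)

# simulate a noisy measurement of a 115 nm film and invert it
spec <- synth_contrast(t_true = 115, sigma = 0.01, seed = 1)
fit  <- fit_thickness(spec, fit_config(t_bounds = c(0, 300)))
fit
#> Film thickness: 114.99 nm (+/- 0.07 nm), RMS residual 0.00962 (n = 301)
```

The fit recovers the generating thickness to 0.01 nm; the ±0.07 nm is the
curvature-based uncertainty from the residual variance, and the RMS
residual ≈ 0.0096 matches the injected contrast noise of 0.01.

```r
# thickness-colour guide on the standard 295 nm oxide
guide <- build_color_guide()          # 10-200 nm at 1 nm, CIE A
subset(guide, thickness_nm %in% c(50, 100, 150))[, 1:4]
#>     thickness_nm      R      G      B
#> 41            50 0.2360 0.6111 0.6054
#> 91           100 0.6771 0.6157 0.4429
#> 141          150 0.6441 0.4539 0.6386
```

A 50 nm film looks teal, 100 nm straw-yellow, 150 nm violet — the
interference colour sequence used for quick visual thickness estimates.

```r
# segment a three-region synthetic micrograph and estimate its volume
img <- synth_film_image(c(17, 96, 151), guide, dim = c(60, 90),
                        scale_mm_per_px = 0.01, sigma = 0.02, seed = 1)
seg <- segment_kmeans(img, k = 3, seed = 1)
estimate_film_volume(region_areas(seg), c(17, 96, 151))
#> $per_region
#> [1]  3.06 17.28 27.18
#> $total
#> [1] 47.52        # x 10^3 um^3

# calibrate thickness against concentration from the built-in table
t1 <- load_fixture("table1")
fit_linear(data.frame(concentration_uM = t1$concentration_uM,
                      thickness_nm = t1$microreflectance_nm))
#> Calibration: thickness = -0.5 (+/- 2.6) + 0.05333 (+/- 0.0052) x conc, R2 = 0.9906, n = 8
```

The fitted spin-coating slope, 0.0533 nm/μM, says: to spin-coat a ~30 nm
film of the 4-repeat protein, use `plan_concentration()` → ≈ 572 ± 25 μM.

See `vignettes/thickness-metrology.Rmd` for the model, its assumptions and
the numerical choices.

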