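---
title: "Optical thickness metrology for thin biomaterial films: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical thickness metrology for thin biomaterial films: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microreflect)
```

## The measurement problem

Thin films of self-assembling repeat proteins (and other transparent
biomaterials) deposited on oxidized silicon wafers are a few nanometres to a
few hundred nanometres thick. Ellipsometry averages over millimetres and
fails on small, nonuniform drop-cast films; AFM step measurements require
scratching the film. Microreflectance spectroscopy measures the reflected
white-light spectrum from a micrometre-scale spot through a microscope, on
the film and on the bare substrate next to it, and the normalised **optical
contrast**

$$C(\lambda) \;=\; \frac{I_\mathrm{film}(\lambda) - I_\mathrm{subst}(\lambda)}
                      {I_\mathrm{film}(\lambda) + I_\mathrm{subst}(\lambda)}$$

cancels the lamp's spectral shape. Because the film sits on a thick
(295 nm) thermal oxide, thin-film interference makes $C(\lambda)$ strongly
thickness-dependent, so the film thickness can be recovered by fitting
$C(\lambda)$ to an optical model. This package implements that workflow end
to end: forward simulation, spectrum I/O, inversion, an apparent-colour
guide, micrograph segmentation with volume estimation, and
thickness-concentration calibration, plus synthetic-data generators that
make every stage testable without laboratory data.

## Forward model: transfer-matrix reflectance

Reflectance at normal incidence is computed with the characteristic-matrix
(transfer-matrix) method. Each layer $j$ with complex index $n_j(\lambda)$
and thickness $t_j$ contributes a phase thickness
$\delta_j = 2\pi n_j t_j / \lambda$ and a matrix

$$M_j = \begin{pmatrix} \cos\delta_j & -\tfrac{i}{n_j}\sin\delta_j \\
-\,i\,n_j \sin\delta_j & \cos\delta_j \end{pmatrix},$$

and with $(B, C)^\top = \big(\prod_j M_j\big) (1, n_s)^\top$ the amplitude
reflection coefficient against the ambient index $n_0$ is
$r = (n_0 B - C)/(n_0 B + C)$ and $R = |r|^2$. Sign conventions follow the
absorbing convention $n + ik$, $k \ge 0$ (forward waves $e^{+ikz}$); the
off-diagonal $-i$ terms are fixed by that choice, and the implementation is
verified against an independently coded single-film Airy closed form to
$10^{-10}$, including the absorbing silicon substrate. For all-lossless
stacks the transmitted fraction from the same matrices satisfies
$R + T = 1$ to machine precision, which the test suite checks.

Assumptions and limitations:

* **Normal incidence only.** The angular spread of the microscope objective
  is ignored; for the modest numerical apertures of metallurgical
  objectives the induced phase-thickness error is small compared with the
  fit uncertainty, but this is a documented approximation, not a fitted
  correction.
* **Fixed, real film index.** The film is modelled as a Cauchy layer
  $n(\lambda) = A + B/\lambda^2 + C/\lambda^4$ with defaults $A = 1.5$,
  $B = C = 0$ — the accepted visible-band index of dried repeat-protein
  films. The coefficients are user-overridable
  (`ctpr_index(A, B, C)`); index dispersion is *not* fitted jointly with
  thickness (the two are strongly degenerate over a single visible
  spectrum).
* **Shipped substrate optical constants.** The SiO2 table is computed from
  the Malitson Sellmeier equation for fused silica; the Si table is a
  smoothed transcription of standard crystalline-silicon literature values
  (see `data-raw/`). Both are plain-CSV, linearly interpolated, and
  swappable via `read_dispersion_csv()`. Evaluation outside a table's
  380–1000 nm support is an error, never an extrapolation.

## Inversion: thickness fitting

The objective is the sum of squared differences between measured and
simulated contrast over the fit window (default 450–750 nm). Interference
makes it multimodal in thickness — films whose optical thickness differs by
about half a wavelength produce similar spectra — so `fit_thickness()`:

1. scans a coarse grid (default 0–500 nm at 1 nm) and collects **all**
   local minima;
2. refines each by bounded scalar minimisation plus a Newton polish with
   central differences (the polish drives the noiseless round-trip SSE
   down to ~1e-21, i.e. the recovered thickness is exact to well below
   0.001 nm);
3. returns the global minimum with the ranked alternatives
   (`$alternatives`), so the interference-order ambiguity is always
   visible; `residual_profile()` exposes the full objective curve.

Numerical choices: two refined minima are treated as *tied* when their SSEs
differ by less than 1% relatively **or** their RMS residuals differ by less
than $10^{-3}$ contrast units — an instrument-noise floor that makes the
tie test meaningful even for noiseless synthetic data, where the best SSE
is ~1e-21 and any relative comparison degenerates. Among tied orders the
smallest thickness is reported and the fit is flagged `ambiguous`; a global
minimum on a search boundary is flagged `boundary` (an all-zero spectrum
correctly fits to 0 nm, which is such a boundary). The reported
uncertainty is a curvature estimate, $\sigma_t = \sqrt{2 s^2 / H}$ with $H$
the numerical second derivative of the SSE at the minimum and
$s^2 = \mathrm{SSE}/(n-1)$; with the default 301-point window and contrast
noise of 0.01 this is of order 0.1 nm, comfortably inside the ~2 nm
spot-to-spot repeatability a real instrument achieves (alignment, focus and
spot placement dominate over photon noise).

## Apparent colour: the thickness–colour guide

Films of different thickness show distinct interference colours under the
microscope, so a colour lookup table gives a
no-instrument thickness estimate. `build_color_guide()` simulates the stack
reflectance for each thickness (default 10–200 nm at 1 nm on 295 nm oxide)
over 380–780 nm and renders it to sRGB:

* **Observer**: CIE 1931 2° colour-matching functions, shipped at 1 nm.
  The table is generated from the Wyman–Sloan–Shirley multi-lobe Gaussian
  analytic fit (accurate to ~1e-3, ample for interference-colour work);
  the generator is in `data-raw/make_cmf.R`.
* **Illuminant**: CIE A by default — the Planckian 2856 K spectrum is the
  right model for a halogen microscope lamp — with equal-energy E as the
  neutral alternative. Daylight illuminants are not shipped: they require
  the CIE daylight-component tables, and a daylight-lit reflected-light
  microscope is not a realistic use case.
* **Rendering**: trapezoidal XYZ integration at 1 nm (checked against an
  independent trapezoidal oracle to 1e-8), von Kries white normalisation in
  XYZ so a perfect mirror renders as exact white, the standard sRGB matrix
  (rows balanced to the D65 white point) and gamma. Out-of-gamut values are
  clipped to [0, 1] and the clipping recorded per entry — simple and
  testable, at the cost of slight chroma distortion for the most saturated
  interference colours.

`thickness_from_color()` does nearest-neighbour lookup in CIE Lab and also
reports the nearest *competing* entry more than 10 nm away, so colour
degeneracy between interference branches is visible to the user. The guide
is model-based, **not** camera-calibrated: real micrographs pass through
camera spectral response, white balance and exposure, so matching a real
photograph against the model guide can be systematically off; matching
synthetic or model-rendered colours (as the tests do) is exact at zero
noise and degrades gracefully with noise (MAE a few nm at per-channel noise
0.02, versus the ~20 nm error expected of visual inspection).

## Micrograph segmentation and film volume

`segment_kmeans()` clusters per-pixel colours with Lloyd's algorithm seeded
by k-means++ (hand-written seeding; the Lloyd iterations are
`stats::kmeans`). Clustering runs in CIE Lab by default so distances are
perceptual; sRGB is available for simpler workflows. `k` defaults to 3, the
typical centre/annulus/rim structure of a drop-cast film; the substrate, if
visible, is treated as its own cluster unless masked out. Runs are
deterministic given the seed, clusters are renumbered by decreasing area,
and asking for more clusters than distinct colours is a reported error.
The pixel scale (mm/px) must always be supplied explicitly.

Areas are pixel counts times the squared pixel scale, so per-cluster areas
sum to the unmasked image area *exactly*. Volumes use
$1\,\mathrm{mm^2} \times 1\,\mathrm{nm} = 10^3\,\mathrm{\mu m^3}$:
`estimate_film_volume()` reports exact products of its area and thickness
arguments. For the built-in three-region reference scenario (areas 2.0,
0.9, 0.5 mm² at 17, 96, 151 nm) the exact products are 34, 86.4 and
75.5 ×10³ μm³; published summaries of the same scenario print 34, 84 and
72 because they were computed from unrounded areas before tabulation — the
package reports the exact arithmetic and leaves reconciliation to the user.

## Calibration: thickness versus concentration

Film thickness grows linearly with the concentration of the protein
solution, with a slope that increases with protein length and is roughly an
order of magnitude larger for drop-casting than for spin-coating.
`fit_linear()` is ordinary least squares `thickness ~ concentration` with
95% intervals from the $t$ distribution on $n-2$ degrees of freedom. The
intercept is free by default (`through_origin = TRUE` to constrain it);
nominal concentrations are used as given and their stated uncertainties are
not propagated (errors-in-variables fitting is out of scope); each
measurement technique is fitted separately, never pooled. `predict()` gives
the confidence band of the fitted mean; `plan_concentration()` inverts the
calibration with a first-order delta-method interval — the practical
"what concentration do I need for a 30 nm film?" tool. The built-in
reference tables (`load_fixture("table1")` … `"table3"`) carry the
spin-coating calibration data, the slope summary for three protein lengths
and two deposition methods, and the segmentation reference scenario.

## Synthetic data: what it does and does not emulate

The generators make the study conditions explicit and reproducible; each is
a pure function of its parameters and seed (the caller's RNG state is
untouched) and attaches its ground truth to the output (JSON sidecar via
`write_synth()`).

* `synth_contrast()`: model contrast plus additive Gaussian noise in
  contrast units, default $\sigma = 0.01$ — the scale consistent with the
  ~2 nm thickness repeatability of a well-aligned instrument. Noise is
  clipped to keep $|C| \le 1$; at the default sigma the clip never
  engages.
* `synth_film_image()`: regions painted with their guide colours plus
  per-channel Gaussian colour noise, default $\sigma = 0.02$, clipped to
  [0, 1]. Default geometry is equal vertical bands; any integer label map
  can be supplied.
* `synth_calibration()`: a line plus Gaussian thickness noise, default
  $\sigma = 2$ nm, matching the single-spot precision.

What the synthetic data deliberately *omits*: wavelength-correlated noise
and etaloning, illumination gradients and vignetting across micrographs,
camera spectral response and white balance, film roughness and index
dispersion mismatch. Passing tests therefore demonstrate that the
*inversion machinery* is correct and precise under the stated noise model —
they do not certify accuracy on real instruments, where the systematic
terms above dominate.

## Problem sizes used in the checks

The repeatability check fits 100 independently generated noisy spectra
(301 wavelength points each, thickness grid 0–300 nm at 1 nm); the colour
check draws 200 thicknesses against the 191-entry guide; segmentation runs
on 60×90-pixel three-region images; calibration coverage uses 400
replicates of an 8-point design. These sizes give stable estimates of the
quantities being checked (a standard deviation over 100 fits, an MAE over
200 draws) while keeping the whole suite fast on a laptop.

## A worked example

```{r example, eval = FALSE}
# forward-simulate, add noise, invert
spec <- synth_contrast(t_true = 115, sigma = 0.01, seed = 1)
fit <- fit_thickness(spec, fit_config(t_bounds = c(0, 300)))
fit

# colour guide and lookup
guide <- build_color_guide()
thickness_from_color(as.numeric(guide[guide$thickness_nm == 150,
                                      c("R", "G", "B")]), guide)

# segmentation and volume
img <- synth_film_image(c(17, 96, 151), guide, dim = c(60, 90),
                        scale_mm_per_px = 0.01, sigma = 0.02, seed = 1)
seg <- segment_kmeans(img, k = 3, seed = 1)
estimate_film_volume(region_areas(seg), c(17, 96, 151))

# calibration
t1 <- load_fixture("table1")
fit_linear(data.frame(concentration_uM = t1$concentration_uM,
                      thickness_nm = t1$microreflectance_nm))
```
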