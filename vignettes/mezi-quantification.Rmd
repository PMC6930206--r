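---
title: "Quantifying macular ellipsoid-zone intensity from SD-OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular ellipsoid-zone intensity from SD-OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meziq)
library(ggplot2)
```

## The measurement

On a spectral-domain OCT B-scan the outer retina shows a stack of
hyperreflective bands: the external limiting membrane (ELM), the ellipsoid
zone (EZ, the mitochondria-dense photoreceptor inner-segment band), and the
retinal pigment epithelium (RPE). EZ reflectivity is a severity marker in
several retinal diseases, and relative EZ attenuation has been reported in
glaucoma. Because absolute OCT brightness varies between acquisitions, the
quantity of interest is a *ratio*: the macular EZ intensity (mEZi), defined
as the EZ band's peak intensity divided by the ELM band's peak intensity,
sampled across the central macula and averaged per eye. The ELM serves as
the within-scan reference, so a global gain change of the image cancels.

The package implements an automated quantifier for this ratio:

1. **Working scale.** Quantification happens on logarithmically scaled
   intensities, the scale on which OCT devices export B-scans for reading.
   `log_transform()` maps linear intensities by `v -> log(1 + v)` and
   rescales so the image maximum is preserved; it is strictly monotone
   (never reorders intensities within an A-scan), defined at zero, and
   never applied twice. Inputs that are already device-exported log-scale
   rasters skip this step (`cmd_quantify(log_transformed = TRUE)`, the
   default — applying the map twice would distort the ratio).
2. **Central crop.** The EZ becomes less distinct with eccentricity, so
   analysis is restricted to the central 4000 µm
   (`crop_central_region()`), centred on the foveal column (metadata, or
   the image centre by default; automatic foveal detection is out of
   scope).
3. **Inner-retina elimination.** `eliminate_inner_retina()` thresholds the
   cropped image with a global Otsu histogram split, finds per A-scan the
   contiguous suprathreshold runs, merges runs separated by less than
   50 µm, and keeps the *deepest* merged run — the outer retinal complex
   (ELM + EZ + RPE). Everything above it, which includes the bright
   inner-retina complex, is zeroed.
4. **Peak extraction.** Within the retained region of each A-scan,
   `extract_bands()` finds local maxima; the shallowest qualifying peak is
   the ELM and the next deeper peak within a plausible axial separation
   (10–80 µm) is the EZ. The separation window stops the RPE, typically
   ~90 µm below the ELM, from being mistaken for the EZ. Columns that
   cannot produce an ordered ELM/EZ pair are invalid.
5. **Vessel-shadow exclusion.** Retinal vessels attenuate everything below
   them. Crucially, attenuation cancels in the EZ/ELM ratio, so a shadowed
   column can produce a plausible-looking number from unreliable signal;
   exclusion must therefore use *absolute* signal. `detect_vessel_shadows()`
   flags columns whose summed outer-band energy falls below
   `median − 3·MAD` and dilates each flagged run by one column.
6. **Sectors and eyes.** `am_quantify_scan()` tiles the 4000-µm extent into
   220 evenly spaced sectors and computes, per sector, the highest EZ peak
   over its valid columns divided by the highest ELM peak — the same
   per-window rule the manual protocol uses. `mm_quantify_scan()` instead
   reproduces the manual sampling geometry: 21 windows of 150 µm at 200-µm
   intervals, fovea to ±2000 µm. `quantify_eye()` pools all valid sectors
   across the acquisition design (11 horizontal + 11 vertical line scans)
   with equal weight.

```{r pipeline}
ph <- generate_bscan(phantom_spec(seed = 1))
ex <- quantify_bscan(ph$image)
sectors <- am_quantify_scan(ex)
quantify_eye(sectors)
ph$truth$true_mezi
```

## Design choices in the band pipeline

The published description of the automated method is a flowchart; several
details are necessarily this implementation's own choices.

* **Threshold.** The Otsu split on a mostly-dark B-scan separates
  background from the *bright* band mass and can land above the ELM — the
  dimmest structure the method must keep. Runs are therefore taken at a
  configurable fraction (default 0.5) of the Otsu split: far above
  background, safely below the ELM. When the between-class variance has a
  plateau (empty histogram gap between background and tissue) the plateau
  midpoint is used.
* **Run merging.** The ELM/EZ/RPE Gaussian-like bands are separated by
  troughs that can dip under the threshold; runs closer than 50 µm are
  merged so the outer complex is one unit, while the inner-retina complex
  (≥100 µm shallower than the ELM) stays separate and is discarded. Taking
  the literally deepest *contiguous* run would keep only the RPE.
* **Sub-pixel peaks.** Peak intensities are read with 3-point parabolic
  refinement. At a 3.87 µm axial pitch, a σ = 8 µm band whose centre falls
  between pixel rows would otherwise be under-read by up to ~3%, more than
  the accuracy budget of the whole pipeline.
* **Idempotence.** The eliminated image carries the threshold it was cut
  with, so re-running the elimination changes nothing; a recomputed
  data-dependent threshold could not guarantee that.
* **Failure flagging.** A scan yields no numbers when fewer than half of
  its A-scans produce a valid peak pair, or when the fitted EZ depth spans
  more than 40% of the frame height — the signature of the strongly curved
  (typically myopic) posterior pole on which automated cropping is known
  to fail. Both thresholds are configurable; the published work reports a
  6.28% failure *rate* but not its criterion.
* **Windows and indexing.** All windows are 1-based and inclusive, the R
  convention. Sector bins are equal half-open lateral intervals; a column
  centred exactly on a boundary joins the lower-index sector.

## The synthetic phantom

`phantom_spec()` + `generate_bscan()` render a four-band A-scan model:
axially Gaussian profiles for the inner-retina complex, ELM, EZ and RPE,
each with a configurable peak amplitude, width, and depth that may vary
laterally (constant, tilt, or quadratic curvature), over a dark background.
Noise is a unit-mean log-normal multiplicative speckle plus additive
Gaussian noise; vessel shadows multiply everything below a start depth by
`1 − attenuation` in their columns. Ground truth is computed from the
analytic amplitudes — per sector, max EZ amplitude over max ELM amplitude,
matching the quantifier's own statistic — so recovery can be asserted
exactly.

Defaults emulate the acquisition the method targets: a 9-mm
high-resolution line scan (768 A-scans, 11.7 µm/px; 496 rows, 3.87 µm/px),
ELM/EZ/RPE at 250/290/340 µm with amplitudes 60/240/255 on the working
scale (mEZi 4.0, the healthy-macula regime of the published group means),
and a broad inner-retina complex at 120 µm. Amplitudes are specified on the
*post-log* working scale so truth is exact where the quantifier operates;
`scale = "linear"` inverts the transform for end-to-end tests through
`log_transform()` (the rescaled map preserves the image maximum, so the
round trip is exact).

What the phantom does **not** model: realistic speckle statistics and the
axial point-spread function, pathology (drusen, hyperreflective foci,
outer-retinal disruption), motion/registration artefacts, and depth-
dependent signal roll-off. Passing recovery tests on phantoms demonstrates
that the *algorithm* is correct under its stated model, not that it is
robust to all clinical image quality; the published method itself was
restricted to artefact-free scans of good signal quality.

## Agreement statistics

Calibrating an automated method against a manual one is a method-comparison
problem; both measurements carry error, so ordinary least squares is biased
and **Deming regression** (`deming_fit()`) is used, with the error-variance
ratio λ defaulting to 1 (orthogonal regression — λ is not identifiable from
the paired data themselves and 1 is the conventional default). The slope is
the closed form
$$b = \frac{s_{yy} - \lambda s_{xx} + \sqrt{(s_{yy} - \lambda s_{xx})^2 +
4 \lambda s_{xy}^2}}{2 s_{xy}},$$
the intercept passes the line through the centroid, the reported R² is the
squared Pearson correlation (Deming regression has no canonical R²), and
standard errors are leave-one-out jackknife estimates, the standard choice
when no error model is assumed. The test suite checks the closed form
against a brute-force minimiser of the perpendicular-distance objective
(slope grid with the intercept profiled out analytically).

**Bland-Altman** (`bland_altman()`) summarises agreement as the mean and
sample SD of the per-pair differences (AM − MM), with 95% limits of
agreement `mean ± 1.96·SD`, and fits the difference on the pair average by
OLS to expose proportional bias. That same difference-versus-average line
is the **compensation model** (`fit_compensation()`): automated values are
corrected by subtracting the modelled disagreement. Two application forms
exist, isolated in `apply_compensation()`:

* with the pair average available, `AMc = AM − (a + b·avg)`; compensating
  the calibration set is then an exact fixed point (OLS residuals are
  orthogonal to any affine transform of the regressor, so the refitted
  coefficients are identically zero);
* for a lone automated value, the AM value substitutes for the average,
  `AMc = AM − (a + b·AM)` — the validation-study situation, where no
  trusted average exists. With `b = 0` both reduce to subtracting the mean
  bias.

Validation asks whether the compensated automated value lies inside the
95% t-interval (df = 4) of five repeated manual quantifications per image
(`replicate_ci()`, `ci_coverage()`; closed intervals). Group distributions
are compared with a Mann-Whitney rank-sum test (`rank_sum_compare()`):
exact enumeration with midranks below 8 per group, tie-corrected normal
approximation with continuity correction above.

`generate_paired_measurements()` emulates the three-group calibration
design: latent mEZi per eye drawn from the group distributions (defaults:
normal 4.08 ± 0.42, mild-to-moderate 3.14 ± 0.43, severe 2.36 ± 0.52; 40,
60 and 60 eyes), manual = latent + noise, automated =
slope·latent + bias + noise. With slope 1.047, bias −0.058 and per-method
noise SD 0.242 — chosen analytically so the between-method difference SD is
≈0.344 — the emulation reproduces the published agreement geometry: mean
difference ≈ 0.09 and limits of agreement ≈ (−0.59, +0.76). Under this
latent-Gaussian model that difference SD implies a Pearson R² of ≈0.85;
the published R² (0.914) and limits of agreement cannot both hold under
such a model, and the emulation follows the difference SD. The residual
validation bias the original study reports after compensation (+0.15)
likewise does not follow from the stated mechanics and is not emulated;
the 32/33 coverage outcome is instead reproduced on a constructed design
with exactly one value outside its replicate interval.

```{r agreement}
cal <- generate_paired_measurements(c(40, 60, 60), method_slope = 1.047,
                                    method_bias = -0.058,
                                    noise_sd_each = 0.242, seed = 42)
fit <- deming_fit(cal)
tidy(fit)
glance(fit)
bland_altman(cal)
```

```{r ba-plot, fig.width = 5, fig.height = 4}
autoplot(bland_altman(cal))
```

## En-face maps

`build_mezi_map()` assembles sector values from the horizontal and
vertical line scans into a lattice over the central 4000 × 4000 µm square:
values are linearly interpolated along each measured line, then across
lines, and the two meridian fields are averaged where both exist. Linear
interpolation is convex, so no interpolated cell leaves the measured value
range, and cells not backed by a measurement are flagged in
`interpolation_mask`. Because horizontal and vertical lines cross, two
measurements can share a lattice cell; such cells store their mean, and
the measured-cell summary (`map_measured_mean()`) is defined over the
per-measurement records so it equals the pooled per-eye mEZi exactly.
Rendering (`render_mezi_map()`, `autoplot()`) uses a monotone blue-to-
yellow ramp — greater mEZi yellower, smaller bluer — with the colour scale
defaulting to the 1st–99th percentile of the lattice; the PNG writer is a
deterministic function of the map.

```{r map, fig.width = 5, fig.height = 4.5}
scans <- lapply(seq(-2000, 2000, length.out = 11), function(p) {
  s <- am_quantify_scan(quantify_bscan(generate_bscan(
    phantom_spec(band_peak_values = list(
      inner_retina_complex = 180, elm = 60,
      ez = function(u) if (p > 0) 190 else 240, rpe = 255),
    seed = 1))$image))
  s$scan_pos_um <- p
  s
})
autoplot(build_mezi_map(scans, n_grid = 64))
```

## Numerical and degenerate-input behaviour

* All-zero or signal-free scans take the failure path (no numbers, flag
  set) rather than producing ratios from noise.
* A sector or window with no valid column is reported as excluded with a
  reason (`vessel_shadow` or `no_valid_peak`), never dropped — a line scan
  always yields exactly its configured number of sector records.
* Peak refinement falls back to the raw sample when the three-point
  neighbourhood is not concave.
* The shadow threshold `median − 3·MAD` marks nothing on a noise-free
  shadow-free phantom (MAD = 0, strict inequality).
* Deming fitting refuses degenerate inputs by name: fewer than three
  pairs, zero x-variance, or zero covariance.

## Problem sizes

The bundled tests exercise full-size 768 × 496 phantoms for the end-to-end
checks (a single scan quantifies in well under a second; a 22-scan eye in
a few seconds) and 256 × 128 phantoms for unit tests. The acceptance
script (`scripts/acceptance.R`) uses 22-scan eyes, a 160-pair emulated
calibration set, a 33-unit validation design, and 20 random datasets for
the Deming oracle comparison — the study's own problem sizes throughout.

## Limitations

* Foveal centring relies on metadata; no foveal-bulge detection.
* No multi-layer segmentation: scans whose outer complex cannot be
  isolated by thresholding (severe pathology, heavy artefact) fail rather
  than degrade gracefully.
* The phantom's speckle is a convenience model; robustness claims are
  limited accordingly.
* The agreement emulation reproduces the published study's *geometry*, not
  its data: the original per-image measurements are not redistributed with
  the text, so printed coefficients are recovered as distributional
  properties, not row-for-row.
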