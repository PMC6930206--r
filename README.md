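# meziq

Automated quantification of macular ellipsoid-zone intensity (mEZi) from
spectral-domain OCT B-scans, with the statistics needed to calibrate and
validate it against a manual grading protocol.

## What it measures, and for whom

The ellipsoid zone (EZ) is the outer retina's second hyperreflective band
on SD-OCT — the mitochondria-dense inner segment of the photoreceptors —
and its reflectivity is a severity marker in several retinal diseases;
relative EZ attenuation has also been reported in glaucoma. Absolute OCT
brightness varies between acquisitions, so the useful quantity is the
ratio of the EZ peak intensity to that of the external limiting membrane
(ELM), the first outer-retinal band:

```
mEZi = max intensity of EZ band / max intensity of ELM band
```

sampled across the central 4000 µm of the macula and averaged per eye
(220 evenly spaced sectors per line scan, 11 horizontal + 11 vertical
lines). The package is aimed at reading-centre and vision-science work:
it runs the full image pipeline (log working scale → central crop →
inner-retina removal by thresholding → per-A-scan ELM/EZ peak extraction
→ vessel-shadow exclusion → sector/eye aggregation), renders en-face mEZi
colour maps, and supplies the method-comparison toolkit used to tie an
automated quantifier to a manual one: Deming errors-in-variables
regression, Bland-Altman limits of agreement, a difference-versus-average
compensation model, replicate confidence intervals and their coverage,
and the Mann-Whitney test. A synthetic phantom generator with exact
ground truth makes the whole pipeline testable without clinical data.

The Deming slope is the closed-form errors-in-variables estimate

```
b = [ s_yy − λ·s_xx + sqrt((s_yy − λ·s_xx)² + 4λ·s_xy²) ] / (2·s_xy)
a = ȳ − b·x̄,        λ = error-variance ratio (default 1)
```

with jackknife standard errors; limits of agreement are
`mean(d) ± 1.96·sd(d)` for `d = AM − MM`.

## Worked example

Quantify a synthetic eye and fit the calibration statistics:

```r
library(meziq)

ph <- generate_bscan(phantom_spec(seed = 1))   # ground-truth mEZi = 4.0
ex <- quantify_bscan(ph$image)
ex
#> <band_extraction 'phantom'> 341 columns, 100.0% valid

sectors <- am_quantify_scan(ex)                # 220 sectors, one line scan
quantify_eye(sectors, eye_id = "phantom_eye")
#> # A tibble: 1 × 6
#>   eye_id      group    mezi n_sectors_used n_scans_used failed
#>   <chr>       <chr>   <dbl>          <int>        <int> <lgl>
#> 1 phantom_eye unknown  3.99            220            1 FALSE
```

The eye-level mEZi of 3.99 recovers the phantom's configured EZ/ELM ratio
of 4.0 to 0.24%. Agreement statistics on an emulated three-group
calibration design (normal / mild-to-moderate / severe, 40/60/60 eyes,
generating line `AM = 1.047·MM − 0.058`, per-method noise SD 0.242):

```r
cal <- generate_paired_measurements(c(40, 60, 60), method_slope = 1.047,
                                    method_bias = -0.058,
                                    noise_sd_each = 0.242, seed = 42)
deming_fit(cal)
#> Deming regression (lambda = 1, n = 160)
#>   am = 1.0652(mm) -0.1141,  R^2 = 0.8734
bland_altman(cal)
#> Bland-Altman (n = 160): mean diff 0.0851, SD 0.3242, LoA [-0.5502, 0.7205]
fit_compensation(cal)
#> Compensation model (n = 160): diff = -0.1039 +0.0610 * average
```

The Deming fit recovers the generating line within its jackknife standard
errors, and the limits of agreement come out near (−0.59, +0.76), the
geometry this emulation is built to reproduce. Fitted objects have
`tidy()`, `glance()` and `autoplot()` methods; `build_mezi_map()` /
`render_mezi_map()` turn per-sector tables into en-face colour maps
(yellow = high mEZi, blue = low).

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/meziq.R phantom  --out-dir scans --n-scans 22 --seed 1
Rscript inst/cli/meziq.R quantify --inputs 'scans/*.tiff' --out-dir out \
        --lateral-um-per-px 11.72 --axial-um-per-px 3.87
Rscript inst/cli/meziq.R calibrate --calibration cal.csv --out-dir out
Rscript inst/cli/meziq.R validate  --validation val.csv \
        --calibration cal.csv --out-dir out
Rscript inst/cli/meziq.R map --sectors out/sectors.csv --out map.png
```

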