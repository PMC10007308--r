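# thzleaf

Terahertz radiation is absorbed extremely strongly by liquid water and
barely at all by dry plant matter, so a THz image of a leaf mounted on a
metal backing is essentially a hydration map: wherever the tissue holds
water, the beam that would otherwise bounce off the metal and return is
attenuated on its double pass. `thzleaf` is an R package for scientists
working with (or planning) such measurements. It implements the two
complementary imaging chains end to end — broadband **time-domain
spectroscopy (TDS)**, slow but frequency-resolved in amplitude and phase,
and fast **quantum-cascade-laser laser-feedback interferometry (LFI)** at
2.71 THz, which images in ~25 s and can watch a plucked leaf dehydrate in
stages — together with a synthetic drying-leaf phantom so the whole
analysis can be validated against known ground truth.

The physics core:

- **Water optics** — double-Debye permittivity
  `eps(w) = eps_inf + (eps_s − eps_i)/(1 − iw·tau1) + (eps_i − eps_inf)/(1 − iw·tau2)`,
  with the extinction calibrated by least squares through measured
  absorption anchors (default: alpha = 500 cm⁻¹ at 2.71 THz, hence a
  1/alpha penetration depth of 20 µm in pure water).
- **Effective medium** — leaf tissue as a volume-weighted mix of water,
  dry matter (n = 1.5, low loss) and air.
- **Stack reflectivity** — transfer-matrix reflection of the
  leaf-on-metal stack at arbitrary incidence/polarisation, with a
  metal-echo component (`component = "echo"`) that carries the hydration
  contrast.
- **Self-mixing interferometry** — the excess-phase equation
  `phi_s = phi_fb + C·sin(phi_fb + atan(alpha_H))`, swept-frequency
  interferograms (~4.8 fringes for a 1.2 m cavity and 600 MHz sweep) and
  dominant-FFT-peak amplitude recovery with scalloping correction.
- **Dehydration staging** — blue-pixel fractions (leaf pixels ≤ −60 dB
  below the frame peak) versus time, fitted with a continuous
  piecewise-linear changepoint model.

## Worked example

```r
library(thzleaf)

# calibrated water optics
wp <- calibrated_water_params()
absorption_coefficient(water_permittivity(c(1.0, 2.0, 2.71), wp))
#> # A tibble: 3 × 2
#>   freq_THz alpha_cm
#>      <dbl>    <dbl>
#> 1     1        379.
#> 2     2        474.
#> 3     2.71     500
```

The calibrated model passes exactly through the 500 cm⁻¹ anchor at the
LFI operating frequency; 379 cm⁻¹ at 1 THz sits inside the published
120-740 cm⁻¹ band for liquid water in the TDS range.

```r
# a drying leaf phantom, and a TDS scan of it (row-major raster, so the
# leaf dries while the scan proceeds top to bottom)
ph  <- generate_phantom("parallel_venation", shape = c(40, 45), seed = 3)
cfg <- tds_config(grid = c(40, 45), extent_mm = c(8, 9))
cube <- raster_scan_tds(ph, drying_curve(), cfg)
img  <- spectral_images(cube, freqs = c(1.0, 2.0, 2.75))
tds_drying_gradient(img, freq_THz = 1.0, n_rows = 10)
#> # A tibble: 1 × 4
#>   freq_THz top_mean bottom_mean gradient
#>      <dbl>    <dbl>       <dbl>    <dbl>
#> 1        1    0.239       0.299   0.0599
```

Rows scanned later (bottom) are drier and reflect ~0.06 more of the
normalised amplitude at 1 THz — the drying-during-scan gradient a slow
raster imprints. Reducing the pixel dwell shrinks it.

```r
# fast LFI imaging: blue-pixel fraction every 2.5 min, then staging
lcfg <- lfi_config(grid = c(40, 45), extent_mm = c(8, 9))
ser  <- simulate_hydration_series(ph, drying_curve(),
                                  times_min = seq(0, 300, by = 2.5),
                                  cfg = lcfg)
fit  <- fit_breakpoints(ser, n_breaks = 2)
fit
#> <stage_fit> 2 breakpoint(s) at 17.50, 207.50 min (significant); SSE 0.003065 (line 0.04814)
autoplot(fit)   # series, piecewise fit, breakpoints
```

The first fitted kink lands at the fast-to-plateau transition of the
generative drying curve (20 min, to within the 2.5 min sampling); the
second tracks where the last wet veins cross the −60 dB threshold. On
noise-free piecewise-linear series at the full 25 s frame cadence the
search recovers both generator breakpoints (20 and 120 min) exactly —
that case is in the test suite.

```r
# system metrics of the two modalities
dplyr::select(compute_metrics(tds_config()),
              modality, pixel_pitch_um, frame_time_s, freq_THz, resolvable_um)
#> # A tibble: 3 × 5
#>   modality pixel_pitch_um frame_time_s freq_THz resolvable_um
#>   <chr>             <dbl>        <dbl>    <dbl>         <dbl>
#> 1 TDS                 200         4536     1            1464
#> 2 TDS                 200         4536     2             732
#> 3 TDS                 200         4536     2.75          532.
```

A Markdown comparison report combining both modalities is produced by
`comparison_report()`; a thin command-line wrapper around the same
pipeline lives in `inst/scripts/thzleaf-report.R`.

## Package layout

- `R/water-optics.R`, `R/layer-stack.R` — dielectric models, calibration,
  transfer-matrix reflectivity
- `R/leaf-phantom.R` — phantom generator and drying dynamics
- `R/tds-pipeline.R` — pulse synthesis, raster simulation, spectral
  images, penetration maps, absorbance recovery
- `R/lfi-pipeline.R`, `R/stages.R` — self-mixing simulation, amplitude
  recovery, hydration series, changepoint staging
- `R/report.R` — system metrics, comparison report, TIFF/YAML interchange
- `vignettes/thz-leaf-hydration.Rmd` — the methods vignette (model
  assumptions, parameter choices, numerical decisions, limitations)
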