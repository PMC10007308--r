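---
title: "Modelling dual-modality terahertz hydration imaging of leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual-modality terahertz hydration imaging of leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzleaf)
```

## The problem

Liquid water absorbs terahertz radiation very strongly while dry plant
matter (mostly cellulose) is comparatively transparent, so a THz image of a
leaf on a metal backing is, to first order, a map of its water content:
wherever the leaf holds water, the beam that would otherwise bounce off the
metal and come back is eaten up on its double pass through the tissue.
Two very different instruments exploit this. A broadband time-domain
spectrometer (TDS) records, pixel by pixel, the reflected electric field
versus time, giving amplitude *and* phase at every frequency in a 0.2-4 THz
band, but needs on the order of an hour per image. A terahertz
quantum-cascade laser used as a laser-feedback interferometer (LFI) is a
single-frequency device (2.71 THz here) that acquires a full image in tens
of seconds, fast enough to watch a plucked leaf dehydrate in stages.

No raw image data from such instruments are bundled here. Instead the
package pairs each processing chain with a forward simulator and a
procedural drying-leaf phantom, so every statistic the analysis produces
can be exercised, end to end, on data whose ground truth is known.

## Optical model

**Water.** The complex permittivity of liquid water is modelled with a
double-Debye relaxation,
$$\varepsilon(\omega) = \varepsilon_\infty +
\frac{\varepsilon_s - \varepsilon_i}{1 - i\omega\tau_1} +
\frac{\varepsilon_i - \varepsilon_\infty}{1 - i\omega\tau_2},$$
with defaults $\varepsilon_s = 78.36$, $\varepsilon_i = 4.93$,
$\varepsilon_\infty = 3.48$, $\tau_1 = 8.24$ ps, $\tau_2 = 0.18$ ps —
literature-style room-temperature values. The sign convention is
$e^{-i\omega t}$ throughout, so passivity means non-negative imaginary
parts. A bare double-Debye curve underestimates absorption above about
2 THz, so the extinction coefficient carries a scalar calibration factor:
`calibrate_absorption()` fits it by least squares through measured
anchors of the power absorption coefficient $\alpha = 4\pi f k / c$. The
default anchor is the published value $\alpha(2.71\,\mathrm{THz}) =
500\ \mathrm{cm^{-1}}$, which the calibrated model reproduces exactly
(`calibrated_water_params()`), giving a $1/\alpha$ penetration depth of
20 µm in pure water at that frequency. Note the Debye static limit is only
approached as $f \to 0$ like $1 - (\omega\tau_1)^2$; at 1 GHz the real part
still sits about 0.25 % below $\varepsilon_s$.

**Dry matter.** No cellulose dielectric data are assumed beyond "low-loss,
index about 1.5": constant $n = 1.5$ with a constant extinction chosen so
that $\alpha$ is 10 cm⁻¹ at 1 THz and rises linearly with frequency.

**Mixing.** Leaf tissue is treated as a three-component effective medium —
water, dry matter, air — whose complex refractive index is the volume-
fraction-weighted sum of the component indices. This is the simplest
defensible rule; `effective_leaf_index()` exposes a `mixing` argument so a
Landau-Lifshitz-Looyenga or similar rule can be added without touching
callers.

**The stack.** The sample is a single effective-medium layer on an ideal
metal backing (perfect electric conductor, reflection $-1$), illuminated at
8° (TDS, s-polarisation) or normally (LFI). `stack_reflectivity()`
implements the standard transfer-matrix method for arbitrary 1-D stacks
and is validated in the test suite against an independent truncated
multiple-reflection (bounce-series) oracle to better than $10^{-6}$ over
random stacks, and against the front-surface Fresnel coefficient in the
opaque limit. Internally the matrices are evaluated in the conjugate
(engineering) convention and conjugated back, which keeps decaying waves
decaying; a clamp on the imaginary phase thickness prevents overflow for
extremely opaque layers.

**Total versus echo reflectivity.** The full coherent reflection of a
leaf-on-metal stack is the sum of the front-surface Fresnel term and
everything that travelled through the tissue. For a well-hydrated leaf the
front term dominates (|r| ≈ 0.3 at 2.71 THz), which means the *total*
reflectivity is neither small for wet tissue nor monotone in water
content — single-frequency thin-film interference even makes it oscillate.
What carries the hydration contrast in this geometry is the metal echo:
the doubly transmitted, doubly attenuated return whose amplitude falls
like $e^{-\alpha_\mathrm{eff} d}$. `stack_reflectivity(component =
"echo")` isolates it by subtracting the front Fresnel term. The TDS
simulator uses the total response (a time-domain trace genuinely contains
both pulses); the LFI hydration map uses the echo component, reflecting
that the measured image contrast tracks the substrate return — a focused,
confocal interferometer rejects much of the off-axis specular glint from a
curved leaf surface, and the package makes that idealisation explicit
rather than burying it. With the default composition (80 % water on
veins, 200 µm thickness) the vein echo sits near −70 dB relative to bare
metal, the fresh lamina (40 % water) near −36 dB, so a −60 dB threshold
separates veins from lamina exactly as intended.

## The drying-leaf phantom

`generate_phantom()` draws a leaf blade (superellipse with a bare-metal
margin), a vein network — parallel longitudinal veins for a grass-like
leaf, or a midrib with branching secondaries for a pinnate one — and
smooth spatially correlated fields for water fraction (0.8 on veins, 0.4
on lamina, ±10 % noise), dry-matter fraction (≤ 0.2, remainder air) and
thickness (200 µm ± 10 %). Everything is a pure function of the seed. An
optional Gaussian ridge on the thickness map emulates a crease in the
blade; it is off by default. The vein fraction of leaf pixels lands in the
0.05-0.30 band by construction of the vein spacing.

Dehydration follows a continuous piecewise-exponential multiplier with
three stages: a fast stage until 20 min (rate 0.04 min⁻¹), a near-plateau
until 120 min (0.001 min⁻¹), then a slow decay (0.008 min⁻¹), floored at a
15 % residual, with vein rates divided by a retention factor of 3 so veins
stay wet longest. The 20/120-minute breakpoints mirror the staging
reported for fast THz imaging of plucked leaves; the functional form, the
rates, the floor and the retention factor are this package's generative
choices (no fitted biophysical model exists to copy) and are all exposed
as `drying_curve()` parameters. The generator emulates vein/lamina
contrast, staged drying and within-scan evolution; it does not emulate
species-accurate morphometry, stomatal physiology, 3-D structure,
scattering from surface roughness, or instrument drift — so green tests
demonstrate the processing chain is correct, not that real leaves behave
this simply.

## TDS pipeline

The emitter pulse is a first-derivative-of-Gaussian (typical of
photoconductive antennas) with the envelope FWHM set to the configured
0.6 ps; its spectrum peaks near 1 THz. Additive white time-domain noise is
scaled so the mean noise-floor bin magnitude sits the configured 90 dB
below the reference spectrum at 0.9 THz. The raster visits pixels row-major
from the top (serpentine optional); pixel $k$ sees the phantom dried to
$t = \mathrm{start} + k\,\mathrm{dwell}$ and its completion time is
stamped, so a 630 ms dwell on 80×90 pixels spans 75.6 minutes and imprints
the drying dynamics as a top-to-bottom brightness gradient. Because the
single-frequency reflectivity of a uniform layer is interference-prone,
the gradient statistic (`tds_drying_gradient()`) is meaningful on the
heterogeneous phantom, where the ±10 % thickness spread averages the
fringes out and the echo trend dominates; the suite checks that the
gradient is positive, grows with dwell and vanishes for a frozen phantom.

`spectral_images()` applies a Tukey window ($\alpha = 0.25$, no echo
time-gating, since the recorded response is deliberately the full
convolved one), FFTs every pixel, samples requested lines at the nearest
FFT bin (recording the bin), normalises each amplitude image to its own
maximum, and reports phase relative to a bare-metal reference pixel after
unwrapping along frequency from the low band edge. Phase images are left
unnormalised. `recover_echo_absorbance()` inverts the forward model on a
uniform leaf: it gates the trace past the front-surface pulse and takes
the negative log spectral ratio against a bare-metal pixel, recovering the
round-trip absorbance $\alpha_\mathrm{eff} d / \cos\theta_\mathrm{int}$
within a few percent (the neglected interface transmission factor
contributes under 1 %). `penetration_map()` tabulates
$\delta(f, t) = 1/\alpha$ for the drying composition, capped at 5 mm for
near-lossless states.

## LFI pipeline

During each 500 ns drive pulse the laser frequency ramps linearly by
600 MHz, winding the round-trip phase of the 1.2 m external cavity through
$2L\Delta f/c \approx 4.8$ fringes. Feedback is modelled with the
steady-state excess-phase relation
$\varphi_s = \varphi_{fb} + C\sin(\varphi_{fb} + \arctan\alpha_H)$,
solved by a safeguarded Newton iteration (unique solution for $C < 1$)
with a bracket-bisection fallback and warm-started continuation for
stronger feedback, to a residual below $10^{-10}$; solutions carry a
`multistable` flag for $C \ge 4.6$. The terminal-voltage model is
$v = C_\mathrm{eff}\cos\varphi_{fb}$ with $C_\mathrm{eff} = C\,|r|$, so a
vanishing return gives a DC-only trace and weak feedback is linear in
target amplitude. The experiment's feedback level is not published; the
default $C = 0.3$, $\alpha_H = 3$ are conventional values and both are
config fields.

`recover_amplitude()` follows the dominant-FFT-peak recipe — mean removal,
Hann window, largest non-DC bin — but corrects the peak with two-bin
(Grandke) interpolation and, by default, a least-squares single-tone
refinement. The raw Hann peak alone scallops by up to ~15 % between bins,
which would be unusable at the 4.8-fringe operating point; with the
refinement a pure cosine is recovered to machine precision at any
fractional frequency, phase or DC offset. That is what makes the scheme
"amplitude-only": the post-objective field curvature adds a quadratic
phase across the image, and the estimator is exactly invariant to a
per-pixel phase offset in the linear regime (and within ~1 % at
$C = 0.3$, where harmonic distortion couples phase in weakly — no
dominant-peak estimator can do better there, which is why the stronger
invariance is asserted only for the linear regime).

`scan_frame()` maps the phantom through the echo reflectivity at the
carrier and either simulates and demodulates a full interferogram per
pixel or uses the weak-feedback linearisation directly (`method =
"amplitude"`, the default; the two agree within 0.5 dB and the
linearisation makes 720-frame series cheap). Within-frame drying is
neglected — a 25 s frame is short against the drying timescales, unlike
the 75-minute TDS scan, where it is modelled. The dB map is referenced to
each frame's peak (the bare-metal region); `blue_fraction()` counts leaf
pixels at or below −60 dB. A global-reference variant would only differ
if the metal calibration drifted, which is not simulated.

`fit_breakpoints()` stages the dehydration series with a continuous
piecewise-linear least-squares fit, searching breakpoint pairs on the
observed time grid (coarse grid then full-resolution refinement around the
optimum, with an `exhaustive` override; ties break toward earlier times;
strict SSE improvement is required so the earliest minimiser wins). Fits
report the improvement over a single line and flag breaks that gain less
than 1 % of total SS as non-significant. The staging is descriptive — the
underlying drying is piecewise-exponential, and a blue-pixel count is a
threshold-crossing statistic of it — so on pipeline-generated series the
fitted kinks track where the crossing *rate* changes, which lands at the
20-minute transition exactly and near the end of the vein dry-out for the
second; exact recovery of both generator breakpoints is asserted on
noise-free piecewise-linear series sampled at the 25 s frame cadence
(720 frames), where localisation is within one frame interval.

## System metrics and reporting

`compute_metrics()` derives pixel pitch (extent/grid: 200 µm TDS, 50 µm
LFI), frame time (pixels × dwell: 4536 s and 25 s) and the Rayleigh
resolvable feature $1.22\,\lambda N$ with a default f-number of 4 — the
unique value consistent with the published 1464/732 µm pair at 1 and
2 THz. Those round numbers presuppose the nominal $c = 3\times10^8$ m/s
($\lambda = 300$ µm at 1 THz), so that is the default constant in this one
formula, with the exact value available via `c_nominal`; the published
2.75 THz and LFI entries are not reproduced by $1.22\lambda N$ with any
single f-number and are simply reported as computed, not forced.
`comparison_report()` writes a deterministic Markdown report with the
metrics table, the TDS gradient statistic, the staged hydration series and
the penetration-depth surface.

## Numerical choices and test problem sizes

FFTs use base R's kernel; reflectivities computed in the $e^{-i\omega t}$
convention are conjugated before synthesis so that delays arrive later in
the trace. Degenerate inputs are handled explicitly: empty stacks are bare
mirrors, zero traces recover zero amplitude, frozen curves are a
degenerate `drying_curve` (`static_curve()`), all-zero extinction gives
the capped penetration depth. Simulated scans in the test suite use
reduced grids chosen to keep the full suite under a minute while leaving
every mechanism intact: 40×45-pixel images for gradient and hydration
properties, a 64×64 cube for absorbance recovery, 16-24 pixel grids for
exactness checks, and 720-point series at the true 25 s cadence for the
staging search. Serialisation sticks to plain text (CSV spectra and
series, YAML configs) plus 16-bit TIFF for maps; waveform cubes live in
memory as R objects.

## Known limitations

Linear volume mixing ignores microstructure resonances; the metal backing
is a perfect conductor; there is no rough-surface scattering, no
atmospheric water-vapour lines, no frequency-shaped detector noise, no
transient laser dynamics (the excess-phase relation is the steady state),
and the LFI field curvature enters only as the phase map it defeats. The
blue-pixel threshold is applied per frame; the staging fit is a
descriptive changepoint model, not a transpiration model. These bounds are
deliberate: each one marks where the synthetic study conditions end and
claims about real instruments would begin.
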