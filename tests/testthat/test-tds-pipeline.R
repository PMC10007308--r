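# Broadband TDS simulation and spectral image processing.

test_that("reference pulse has the configured width, zero area and dynamic range", {
  cfg <- tds_config(noise = TRUE)
  ref <- reference_pulse(cfg)
  # envelope FWHM = pulse width within one sample step
  env <- thzleaf:::analytic_envelope(ref$trace)
  half <- max(env) / 2
  idx <- range(which(env >= half))
  dt <- cfg$sample_step_ps
  # sub-sample edge interpolation
  lo <- ref$time_ps[idx[1] - 1] +
    (half - env[idx[1] - 1]) / (env[idx[1]] - env[idx[1] - 1]) * dt
  hi <- ref$time_ps[idx[2]] +
    (half - env[idx[2]]) / (env[idx[2] + 1] - env[idx[2]]) * dt
  expect_lt(abs((hi - lo) - cfg$pulse_width_ps), dt)
  # derivative pulse integrates to ~zero
  area <- abs(sum(ref$trace) * cfg$sample_step_ps)
  expect_lt(area, 1e-10 * max(abs(ref$trace)) * cfg$time_window_ps)
  # unit peak
  expect_equal(max(abs(ref$trace)), 1)
  # noise floor realises the configured dynamic range at 0.9 THz (+/- 1 dB):
  # measure mean |FFT| of noise-only traces against the reference spectrum
  S <- Mod(thzleaf:::rfft_bins(ref$trace))
  b09 <- which.min(abs(ref$freq_THz - 0.9))
  set.seed(4)
  nothing <- rep(0 + 0i, length(ref$freq_THz))
  noise_mags <- replicate(40, {
    tr <- pixel_waveform(nothing, cfg, ref = ref)
    mean(Mod(thzleaf:::rfft_bins(tr)))
  })
  dr_db <- 20 * log10(S[b09] / mean(noise_mags))
  expect_lt(abs(dr_db - cfg$dynamic_range_db), 1)
})

test_that("pixel waveforms reproduce identity, mirror and delay oracles", {
  cfg <- tds_config(noise = FALSE)
  ref <- reference_pulse(cfg)
  nf <- length(ref$freq_THz)
  # identity reflector returns the reference pulse
  expect_lt(max(abs(pixel_waveform(rep(1 + 0i, nf), cfg, ref = ref) -
                      ref$trace)), 1e-10)
  # mirror sign
  expect_lt(max(abs(pixel_waveform(rep(-1 + 0i, nf), cfg, ref = ref) +
                      ref$trace)), 1e-10)
  # wrong grid is rejected
  expect_error(pixel_waveform(rep(1 + 0i, nf - 1), cfg), "FFT grid")
  # metal-echo delay of a lossless 200 um n = 1.5 layer at 8 deg:
  # 2 n d cos(theta_int) / c (geometry oracle)
  st <- stack_from_n(ref$freq_THz[-1], list(1.5 + 0i), 200,
                     incidence_deg = 8)
  r <- stack_reflectivity(st)$r
  tr <- pixel_waveform(c(-1 + 0i, r), cfg, ref = ref) # f = 0 bin: mirror
  env <- thzleaf:::analytic_envelope(tr)
  pk <- which(diff(sign(diff(env))) < 0) + 1
  pk <- pk[env[pk] > 0.05 * max(env)]
  expect_gte(length(pk), 2)
  measured_ps <- ref$time_ps[pk[2]] - ref$time_ps[pk[1]]
  theta_int <- asin(sin(8 * pi / 180) / 1.5)
  oracle_ps <- 2 * 1.5 * 200e-6 * cos(theta_int) / 299792458 * 1e12
  expect_lt(abs(measured_ps - oracle_ps), cfg$sample_step_ps)
})

test_that("raster scan orders pixels, stamps times and imprints drying", {
  ph <- uniform_phantom(16, 18)
  cfg <- small_tds_cfg(grid = c(16, 18))
  cube <- raster_scan_tds(ph, static_curve(), cfg)
  # timestamps strictly increasing in raster order, last = npx * dwell
  stv <- as.vector(t(cube$timestamps_min))
  expect_true(all(diff(stv) > 0))
  expect_equal(max(cube$timestamps_min), 16 * 18 * cfg$pixel_dwell_ms / 60000)
  # static phantom, noise-free: all leaf pixels bit-identical, zero gradient
  img <- spectral_images(cube, freqs = c(1.0))
  g0 <- tds_drying_gradient(img, 1.0, n_rows = 4)
  expect_equal(g0$gradient, 0, tolerance = 1e-12)
  # default drying: the leaf dries during the scan, so later (bottom) rows
  # reflect more at 1 THz (heterogeneous leaf; thickness spread averages the
  # thin-film interference so the echo trend dominates)
  ph2 <- generate_phantom("parallel_venation", shape = c(40, 45), seed = 3)
  cfg2 <- tds_config(grid = c(40, 45), extent_mm = c(8, 9), noise = FALSE)
  cube_dry <- raster_scan_tds(ph2, drying_curve(), cfg2)
  gd <- tds_drying_gradient(spectral_images(cube_dry, freqs = 1.0),
                            1.0, n_rows = 10)
  expect_gt(gd$gradient, 0)
})

test_that("drying gradient grows with pixel dwell", {
  ph <- generate_phantom("parallel_venation", shape = c(40, 45), seed = 3)
  grads <- sapply(c(630, 63), function(dw) {
    cfg <- tds_config(grid = c(40, 45), extent_mm = c(8, 9),
                      pixel_dwell_ms = dw, noise = FALSE)
    cube <- raster_scan_tds(ph, drying_curve(), cfg)
    tds_drying_gradient(spectral_images(cube, freqs = 1.0), 1.0,
                        n_rows = 10)$gradient
  })
  expect_gt(grads[1], grads[2])
  expect_gt(grads[2], 0)
})

test_that("spectral images honour normalisation, reference phase and band", {
  ph <- uniform_phantom(16, 18)
  cfg <- small_tds_cfg(grid = c(16, 18))
  cube <- raster_scan_tds(ph, static_curve(), cfg)
  img <- spectral_images(cube)
  for (q in seq_along(img$freq_requested)) {
    expect_equal(max(img$amplitude[[q]]), 1)
    mr <- img$metal_ref
    expect_equal(img$phase[[q]][mr[1], mr[2]], 0, tolerance = 1e-12)
  }
  expect_error(spectral_images(cube, freqs = 9), "band")
  # phase accumulation grows with frequency for a lossless dielectric leaf
  ph_lossless <- uniform_phantom(16, 18, f_water = 0, f_dry = 1)
  cube_l <- raster_scan_tds(ph_lossless, static_curve(), cfg,
                            water_params = debye_params())
  img_l <- spectral_images(cube_l, freqs = c(1.0, 2.0, 2.75))
  px <- c(8, 10)
  phases <- sapply(seq_along(img_l$freq_requested), function(q) {
    img_l$phase[[q]][px[1], px[2]]
  })
  expect_gt(abs(phases[3]), abs(phases[2]))
  expect_gt(abs(phases[2]), abs(phases[1]))
})

test_that("processing is invariant to trace scaling and exact on a unit mirror", {
  cfg <- small_tds_cfg(grid = c(6, 6))
  ref <- reference_pulse(cfg)
  n <- length(ref$trace)
  traces <- aperm(array(ref$trace, c(n, 6, 6)), c(2, 3, 1))
  cube <- structure(
    list(
      traces = traces, time_ps = ref$time_ps, freq_THz = ref$freq_THz,
      timestamps_min = matrix(seq_len(36) / 100, 6, 6, byrow = TRUE),
      leaf_mask = matrix(FALSE, 6, 6), vein_mask = matrix(FALSE, 6, 6),
      cfg = cfg, start_min = 0, ref_t0_ps = ref$t0_ps
    ),
    class = "tds_cube"
  )
  img <- spectral_images(cube, freqs = c(1.0, 2.0))
  # r == 1 everywhere: normalized amplitude 1, phase 0
  for (q in 1:2) {
    expect_equal(img$amplitude[[q]], matrix(1, 6, 6), tolerance = 1e-12)
    expect_equal(img$phase[[q]], matrix(0, 6, 6), tolerance = 1e-9)
  }
  # positive scaling leaves normalized amplitudes unchanged
  cube2 <- cube
  cube2$traces <- cube$traces * 37.5
  img2 <- spectral_images(cube2, freqs = c(1.0, 2.0))
  expect_equal(img2$amplitude[[1]], img$amplitude[[1]], tolerance = 1e-12)
})

test_that("two-pass absorbance is recovered from a noise-free cube", {
  ph <- uniform_phantom(20, 20, f_water = 0.4, f_dry = 0.2)
  cfg <- small_tds_cfg(grid = c(20, 20))
  cube <- raster_scan_tds(ph, static_curve(), cfg)
  rec <- recover_echo_absorbance(cube, pixel = c(10, 12), freq_THz = 1.0)
  pred <- echo_absorbance_predicted(0.4, 0.2, 200, rec$freq_THz,
                                    incidence_deg = 8)
  expect_lt(abs(rec$absorbance - pred) / pred, 0.05)
})

test_that("penetration surface falls with frequency and rises with drying", {
  pm <- penetration_map(
    0.45, times_min = c(0, 30, 90, 200),
    freq_THz = seq(0.4, 3.2, by = 0.4)
  )
  # decreasing in f at fixed t
  for (tm in unique(pm$time_min)) {
    d <- pm$delta_um[pm$time_min == tm]
    expect_true(all(diff(d) < 0))
  }
  # non-decreasing in t at fixed f
  for (fq in unique(pm$freq_THz)) {
    d <- pm$delta_um[pm$freq_THz == fq]
    expect_true(all(diff(d) >= 0))
  }
  # pure calibrated water at the anchor frequency: 20 um
  pw <- penetration_map(1, c(0, 1), 2.71, curve = static_curve(), f_dry = 0)
  expect_equal(pw$delta_um, rep(20, 2), tolerance = 1e-9)
  expect_error(penetration_map(0.4, times_min = 5, freq_THz = 1), ">= 2")
})
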