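# Self-mixing LFI simulation, amplitude recovery and hydration statistics.

test_that("the intra-pulse sweep is linear from carrier to carrier + span", {
  cfg <- lfi_config()
  expect_equal(sweep_frequency(0, cfg), 2.71e12)
  expect_equal(sweep_frequency(500, cfg), 2.71e12 + 600e6)
  expect_equal(sweep_frequency(250, cfg), 2.71e12 + 300e6)
  expect_error(sweep_frequency(501, cfg), "pulse")
})

test_that("excess-phase solver satisfies its defining relation", {
  # identity at C = 0
  ps <- seq(-30, 30, length.out = 101)
  expect_equal(as.vector(excess_phase(ps, 0)), ps, tolerance = 1e-14)
  # residual of the defining equation over random (phi_s, C <= 1)
  set.seed(11)
  phis <- runif(2000, -50, 50)
  Cs <- runif(2000, 0, 1)
  phi <- excess_phase(phis, Cs)
  res <- abs(phi + Cs * sin(phi + atan(3)) - phis)
  expect_lt(max(res), 1e-10)
  # 2 pi periodicity
  p1 <- excess_phase(1.234, 0.3)
  p2 <- excess_phase(1.234 + 2 * pi, 0.3)
  expect_equal(as.vector(p2 - p1), 2 * pi, tolerance = 1e-9)
  # moderate feedback (C >= 1) still satisfies the relation on a ramp
  ramp <- seq(0, 40, length.out = 400)
  phi2 <- excess_phase(ramp, 2.5)
  expect_lt(max(abs(phi2 + 2.5 * sin(phi2 + atan(3)) - ramp)), 1e-10)
  expect_false(attr(phi2, "multistable"))
  expect_true(attr(excess_phase(ramp, 5), "multistable"))
  expect_error(excess_phase(1, -0.1), ">= 0")
})

test_that("interferograms carry the cavity-length fringe count", {
  cfg <- lfi_config()
  ig <- simulate_interferogram(1, 0, cfg)
  # 2 L df / c = 4.8 fringes for 1.2 m and 600 MHz
  expect_lt(abs(fringe_count(ig) - 4.8), 0.5)
  # doubling the cavity doubles the count (within quantisation)
  cfg2 <- lfi_config(cavity_length_m = 2.4)
  expect_lt(abs(fringe_count(simulate_interferogram(1, 0, cfg2)) - 9.6), 1.0)
  # no target return: DC-only trace
  ig0 <- simulate_interferogram(0, 0, cfg, dc = 0.7)
  expect_true(all(ig0$voltage == 0.7))
  expect_error(simulate_interferogram(1.2, 0, cfg), "0, 1")
})

test_that("amplitude recovery is exact for tones and robust to DC and phase", {
  n <- 512
  tt <- 0:(n - 1)
  # integer bin: machine-level accuracy at any phase
  for (phs in c(0, 1.1, 2.7)) {
    v <- 3.7 * cos(2 * pi * 20 * tt / n + phs)
    expect_lt(abs(recover_amplitude(v) - 3.7) / 3.7, 1e-9)
  }
  # off-bin (the physical 4.8-fringe case): well within 2%
  for (phs in c(0, 0.9, 2.2)) {
    v <- 2.2 * cos(2 * pi * 4.8 * tt / n + phs)
    expect_lt(abs(recover_amplitude(v) - 2.2) / 2.2, 0.02)
    # the uninterpolated Hann estimate is also within a few percent
    expect_lt(abs(recover_amplitude(v, refine = FALSE) - 2.2) / 2.2, 0.02)
  }
  # DC offset leaves the result unchanged
  v <- 1.5 * cos(2 * pi * 4.8 * tt / n + 0.7)
  expect_equal(recover_amplitude(v + 10), recover_amplitude(v),
               tolerance = 1e-12)
  # zero trace
  expect_equal(recover_amplitude(rep(0, 64)), 0)
  # positive homogeneity
  expect_equal(recover_amplitude(3 * v), 3 * recover_amplitude(v),
               tolerance = 1e-12)
  expect_error(recover_amplitude(rep(1, 8)), "16")
})

test_that("recovered amplitude ignores the field-curvature phase", {
  # linear (weak-feedback) regime: a per-pixel phase offset must not move
  # the recovered amplitude at all
  cfg <- lfi_config()
  nsmp <- cfg$samples_per_pulse
  t_ns <- (seq_len(nsmp) - 1) / nsmp * cfg$pulse_duration_ns
  phi_s <- 4 * pi * cfg$cavity_length_m * sweep_frequency(t_ns, cfg) / 299792458
  a0 <- recover_amplitude(0.4 * cos(phi_s))
  for (psi in c(0.8, 2.9, 5.5)) {
    expect_lt(abs(recover_amplitude(0.4 * cos(phi_s + psi)) - a0) / a0, 1e-6)
  }
  # operating feedback level: harmonic distortion couples the phase in only
  # weakly
  igA <- simulate_interferogram(0.6, 0, cfg)
  igB <- simulate_interferogram(0.6, 3.1, cfg)
  expect_lt(abs(recover_amplitude(igA) - recover_amplitude(igB)) /
              recover_amplitude(igA), 0.01)
})

test_that("weak feedback makes recovery linear in target reflectivity", {
  cfg <- lfi_config(feedback_C = 0.05)
  ramps <- seq(0.05, 1, length.out = 8)
  amps <- sapply(ramps, function(ra) {
    recover_amplitude(simulate_interferogram(ra, 0.4, cfg))
  })
  ratio <- amps / ramps
  expect_lt(diff(range(ratio)) / mean(ratio), 0.02)
})

test_that("frames map bare metal to 0 dB and wet veins below -60 dB", {
  cfg <- lfi_config(grid = c(40, 45), extent_mm = c(8, 9))
  # all-metal: flat 0 dB map
  metal <- uniform_phantom(40, 45, metal_cols = 45)
  fr0 <- scan_frame(metal, static_curve(), 0, cfg)
  expect_true(all(fr0$db_map == 0))
  expect_error(blue_fraction(fr0), "leaf mask")
  # default drying-leaf fixture at t = 0
  ph <- generate_phantom("parallel_venation", shape = c(40, 45), seed = 3)
  fr <- scan_frame(ph, drying_curve(), 0, cfg)
  expect_equal(max(fr$db_map), 0)
  expect_true(all(fr$db_map[!fr$leaf_mask] == 0)) # bare metal at frame peak
  # areal-water criterion: nominal vein composition (0.8 water over 200 um)
  wet_vein <- fr$vein_mask &
    ph$water_fraction * ph$thickness_um / 200 >= 0.8
  expect_gt(sum(wet_vein), 10)
  expect_true(all(fr$db_map[wet_vein] < -60))
  lam <- fr$leaf_mask & !fr$vein_mask
  expect_true(mean(fr$db_map[lam] > -60) > 0.9) # lamina mostly above
  # frame time metadata: pixels x dwell
  expect_equal(fr$frame_seconds, 40 * 45 * 0.1 / 1000)
})

test_that("interferogram and linearised frame methods agree", {
  cfg <- lfi_config(grid = c(16, 16), extent_mm = c(4, 4))
  ph <- generate_phantom("parallel_venation", shape = c(16, 16), seed = 6)
  fa <- scan_frame(ph, drying_curve(), 10, cfg, method = "amplitude")
  fi <- scan_frame(ph, drying_curve(), 10, cfg, method = "interferogram")
  keep <- fa$db_map > -75 # above the deep-attenuation regime
  expect_lt(max(abs(fa$db_map[keep] - fi$db_map[keep])), 0.5)
})

test_that("blue fraction counts thresholded leaf pixels", {
  leaf <- matrix(TRUE, 10, 10)
  db <- matrix(0, 10, 10)
  fr <- frame_from_db(db, leaf)
  expect_equal(blue_fraction(fr, -60), 0)
  db2 <- db
  db2[1:5, ] <- -70 # exactly half the leaf
  expect_equal(blue_fraction(frame_from_db(db2, leaf), -60), 0.5)
  # more negative thresholds never increase the fraction
  fracs <- sapply(c(-40, -60, -80), function(th) {
    blue_fraction(frame_from_db(db2, leaf), th)
  })
  expect_true(all(diff(fracs) <= 0))
})

test_that("hydration series assembles frames and round-trips via CSV", {
  leaf <- matrix(TRUE, 10, 10)
  mk <- function(frac, tm) {
    db <- matrix(0, 10, 10)
    db[seq_len(frac * 100)] <- -70
    frame_from_db(db, leaf, time_min = tm)
  }
  frames <- list(mk(0.4, 0), mk(0.3, 7), mk(0.1, 30)) # gap preserved
  ser <- hydration_series(frames, threshold_db = -60)
  expect_equal(ser$time_min, c(0, 7, 30))
  expect_equal(ser$blue_fraction, c(0.4, 0.3, 0.1), tolerance = 1e-12)
  expect_error(hydration_series(frames[c(2, 1, 3)]), "increasing")
  expect_error(hydration_series(frames[1:2]), ">= 3")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hydration_csv(ser, path)
  back <- read_hydration_csv(path)
  expect_identical(back$time_min, ser$time_min)
  expect_identical(back$blue_fraction, ser$blue_fraction)
})

test_that("noise-free dehydration series is non-increasing", {
  cfg <- lfi_config(grid = c(40, 45), extent_mm = c(8, 9))
  ph <- generate_phantom("parallel_venation", shape = c(40, 45), seed = 3)
  ser <- simulate_hydration_series(
    ph, drying_curve(), times_min = seq(0, 300, by = 15), cfg = cfg
  )
  expect_true(all(diff(ser$blue_fraction) <= 1e-12))
  expect_gt(ser$blue_fraction[1], 0)
})
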