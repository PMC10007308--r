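#' Broadband TDS imaging configuration
#'
#' Acquisition parameters of the reflection-mode terahertz time-domain
#' raster scanner. Defaults mirror a photoconductive-antenna system: 0.6 ps
#' pulses covering 0.2-4 THz, 630 ms per pixel on an 80 x 90 grid spanning
#' 16 x 18 mm, 8 degree incidence, and a 90 dB peak dynamic range at
#' 0.9 THz.
#'
#' @param pulse_width_ps Envelope FWHM of the emitted pulse, ps.
#' @param band_THz Usable band `c(lo, hi)` in THz.
#' @param time_window_ps Length of the recorded trace, ps. Must comfortably
#'   cover the metal-echo delay.
#' @param sample_step_ps Sampling step, ps; must be < `pulse_width_ps / 4`.
#' @param pixel_dwell_ms Acquisition time per pixel, ms.
#' @param grid Image size `c(rows, cols)` in pixels.
#' @param extent_mm Physical scan extent `c(height, width)` in mm.
#' @param incidence_deg Angle of incidence, degrees.
#' @param dynamic_range_db Peak dynamic range target (dB) at `dr_freq_THz`;
#'   sets the additive white time-domain noise level.
#' @param dr_freq_THz Frequency at which the dynamic range is specified.
#' @param noise Logical: add detector noise.
#' @param serpentine Logical: serpentine instead of row-major raster.
#' @param seed RNG seed for the noise stream.
#' @return An object of class `tds_config`.
#' @export
tds_config <- function(pulse_width_ps = 0.6, band_THz = c(0.2, 4),
                       time_window_ps = 30, sample_step_ps = 0.1,
                       pixel_dwell_ms = 630, grid = c(80, 90),
                       extent_mm = c(16, 18), incidence_deg = 8,
                       dynamic_range_db = 90, dr_freq_THz = 0.9,
                       noise = TRUE, serpentine = FALSE, seed = 1) {
  stopifnot_scalar(pulse_width_ps, "pulse_width_ps")
  stopifnot_scalar(time_window_ps, "time_window_ps")
  stopifnot_scalar(sample_step_ps, "sample_step_ps")
  if (sample_step_ps >= pulse_width_ps / 4) {
    abort("`sample_step_ps` must be < pulse_width_ps / 4")
  }
  if (time_window_ps < 8 * pulse_width_ps) {
    abort("time window too short for the pulse")
  }
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1)) abort("`grid` must be c(rows, cols)")
  structure(
    list(
      pulse_width_ps = pulse_width_ps, band_THz = band_THz,
      time_window_ps = time_window_ps, sample_step_ps = sample_step_ps,
      pixel_dwell_ms = pixel_dwell_ms, grid = grid, extent_mm = extent_mm,
      incidence_deg = incidence_deg, dynamic_range_db = dynamic_range_db,
      dr_freq_THz = dr_freq_THz, noise = noise, serpentine = serpentine,
      seed = as.integer(seed)
    ),
    class = "tds_config"
  )
}

#' @export
print.tds_config <- function(x, ...) {
  cat(sprintf(
    "<tds_config> %.2f ps pulse, %g-%g THz, %dx%d px @ %.0f ms, %.1f deg\n",
    x$pulse_width_ps, x$band_THz[1], x$band_THz[2],
    x$grid[1], x$grid[2], x$pixel_dwell_ms, x$incidence_deg
  ))
  invisible(x)
}

# number of samples and time axis for a config
tds_time_axis <- function(cfg) {
  n <- round(cfg$time_window_ps / cfg$sample_step_ps)
  (0:(n - 1)) * cfg$sample_step_ps
}

# positive-frequency FFT grid in THz (step = 1/window when t is in ps)
tds_freq_axis <- function(cfg) {
  t <- tds_time_axis(cfg)
  n <- length(t)
  (0:(n %/% 2)) / (n * cfg$sample_step_ps)
}

# envelope-FWHM / gaussian-sigma ratio of a first-derivative-of-Gaussian
# pulse (numerically determined constant)
.DGAUSS_ENV_RATIO <- 3.66

#' Reference (emitter) pulse
#'
#' First-derivative-of-Gaussian field trace with the configured envelope
#' FWHM, zero mean, unit peak, centred at a quarter of the time window so
#' that sample echoes stay inside the record.
#'
#' @param cfg A [tds_config()].
#' @return A list with `time_ps`, `trace`, `t0_ps` (pulse centre) and
#'   `freq_THz` (the positive FFT grid).
#' @export
reference_pulse <- function(cfg) {
  t <- tds_time_axis(cfg)
  n <- length(t)
  if (n < 64) abort("time window too short")
  tau <- cfg$pulse_width_ps / .DGAUSS_ENV_RATIO
  t0 <- t[floor(n / 4) + 1]
  x <- t - t0
  p <- -x / tau^2 * exp(-x^2 / (2 * tau^2))
  p <- p / max(abs(p))
  list(time_ps = t, trace = p, t0_ps = t0, freq_THz = tds_freq_axis(cfg))
}

# time-domain white-noise sd that realises the configured dynamic range at
# cfg$dr_freq_THz: mean noise-bin magnitude = |S(f_dr)| / 10^(DR/20)
tds_noise_sd <- function(cfg, ref = reference_pulse(cfg)) {
  S <- rfft_bins(ref$trace)
  f <- ref$freq_THz
  bin <- which.min(abs(f - cfg$dr_freq_THz))
  target <- Mod(S[bin]) / 10^(cfg$dynamic_range_db / 20)
  n <- length(ref$trace)
  target / (sqrt(n * pi) / 2)
}

#' Simulate one pixel's time-domain waveform
#'
#' Inverse FFT of the reference pulse spectrum multiplied by the sample's
#' complex reflection coefficient, plus (optionally) seeded white detector
#' noise at the configured floor.
#'
#' @param r Complex reflection coefficient evaluated on the cube's
#'   positive-frequency FFT grid (`tds_freq_axis` length).
#' @param cfg A [tds_config()].
#' @param seed Optional seed for the noise draw; `NULL` draws from the
#'   current RNG stream. Ignored when `cfg$noise` is `FALSE`.
#' @param ref Reference pulse (recomputed if omitted).
#' @return Numeric field trace.
#' @export
pixel_waveform <- function(r, cfg, seed = NULL, ref = reference_pulse(cfg)) {
  n <- length(ref$trace)
  if (length(r) != n %/% 2 + 1) {
    abort(sprintf(
      "`r` must be on the cube's FFT grid (%d positive bins)", n %/% 2 + 1
    ))
  }
  S <- rfft_bins(ref$trace)
  # r carries the exp(-iwt) physics convention; R's FFT kernel is the
  # engineering one, so conjugate to make positive delays arrive later
  tr <- irfft_real(S * Conj(r), n)
  if (isTRUE(cfg$noise)) {
    sdv <- tds_noise_sd(cfg, ref)
    noise_draw <- function() rnorm(n, 0, sdv)
    tr <- tr + if (is.null(seed)) noise_draw() else with_seed(seed, noise_draw())
  }
  tr
}

#' Raster-scanned TDS waveform cube of a drying leaf
#'
#' Visits pixels row-major from the top row (serpentine optional). Pixel k
#' (0-based raster index) is simulated from the phantom dried to
#' `start_min + k * dwell`, so slow scans imprint the drying dynamics as a
#' top-to-bottom gradient. Timestamps record each pixel's acquisition
#' completion time; total scan duration is `rows * cols * dwell`.
#'
#' @param phantom A [generate_phantom()] phantom matching `cfg$grid`.
#' @param curve A [drying_curve()].
#' @param cfg A [tds_config()].
#' @param water_params Water model; defaults to the Table-anchored
#'   calibration of [calibrated_water_params()].
#' @param start_min Scan start time in minutes since plucking.
#' @return An object of class `tds_cube`: `traces` array (row, col, time),
#'   `time_ps`, `freq_THz`, `timestamps_min`, masks and configuration.
#' @export
raster_scan_tds <- function(phantom, curve, cfg,
                            water_params = calibrated_water_params(),
                            start_min = 0) {
  if (!inherits(phantom, "leaf_phantom")) {
    abort("`phantom` must be a `leaf_phantom`")
  }
  d <- dim(phantom$water_fraction)
  if (!all(d == cfg$grid)) {
    abort("phantom grid does not match cfg$grid")
  }
  ref <- reference_pulse(cfg)
  n <- length(ref$trace)
  f <- ref$freq_THz
  S <- rfft_bins(ref$trace)
  nw <- interp_index(water_permittivity(f, water_params), f)
  nd <- interp_index(dry_matter_spectrum(f), f)
  sdv <- if (isTRUE(cfg$noise)) tds_noise_sd(cfg, ref) else 0
  dwell_min <- cfg$pixel_dwell_ms / 60000

  nr <- d[1]
  nc <- d[2]
  traces <- array(NA_real_, c(nr, nc, n))
  stamps <- matrix(NA_real_, nr, nc)
  bare <- irfft_real(-S, n)

  with_seed(cfg$seed, {
    k <- 0
    for (i in seq_len(nr)) {
      jorder <- if (cfg$serpentine && i %% 2 == 0) rev(seq_len(nc)) else seq_len(nc)
      for (j in jorder) {
        t_sim <- start_min + k * dwell_min
        if (phantom$leaf_mask[i, j]) {
          on_v <- phantom$vein_mask[i, j]
          m <- drying_multiplier(t_sim, curve, on_vein = on_v)
          fw <- phantom$water_fraction[i, j] * m
          fd <- phantom$dry_fraction[i, j]
          fa <- pmax(1 - fw - fd, 0)
          neff <- fw * nw + fd * nd + fa
          r <- uniform_layer_pec_r(
            f, neff, phantom$thickness_um[i, j],
            incidence_deg = cfg$incidence_deg, polarization = "s"
          )$total
          tr <- irfft_real(S * Conj(r), n)
        } else {
          tr <- bare
        }
        if (sdv > 0) tr <- tr + rnorm(n, 0, sdv)
        traces[i, j, ] <- tr
        stamps[i, j] <- start_min + (k + 1) * dwell_min
        k <- k + 1
      }
    }
  })

  structure(
    list(
      traces = traces, time_ps = ref$time_ps, freq_THz = f,
      timestamps_min = stamps, leaf_mask = phantom$leaf_mask,
      vein_mask = phantom$vein_mask, cfg = cfg, start_min = start_min,
      ref_t0_ps = ref$t0_ps
    ),
    class = "tds_cube"
  )
}

#' @export
print.tds_cube <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf(
    "<tds_cube> %dx%d px, %d samples (%.1f ps), scan %.1f-%.1f min\n",
    d[1], d[2], d[3], x$cfg$time_window_ps,
    x$start_min, max(x$timestamps_min)
  ))
  invisible(x)
}

#' Frequency-resolved amplitude and phase images from a waveform cube
#'
#' Windowed per-pixel FFT (Tukey, alpha = 0.25) of the cube, sampled at the
#' nearest FFT bin to each requested frequency line. Amplitude images are
#' normalised to each image's maximum; phase is taken relative to a
#' bare-metal reference pixel and unwrapped along the frequency axis from
#' the low band edge before the line is sampled.
#'
#' @param cube A [raster_scan_tds()] cube.
#' @param freqs Frequency lines in THz (must lie inside `cfg$band_THz`).
#' @param metal_ref `c(row, col)` of a bare-metal pixel; defaults to the
#'   first off-leaf pixel in raster order.
#' @return An object of class `tds_image_set`: per-line amplitude and phase
#'   matrices plus normalisation constants and bin metadata.
#' @export
spectral_images <- function(cube, freqs = c(1.0, 2.0, 2.75),
                            metal_ref = NULL) {
  if (!inherits(cube, "tds_cube")) abort("`cube` must be a `tds_cube`")
  band <- cube$cfg$band_THz
  if (any(freqs < band[1]) || any(freqs > band[2])) {
    abort("requested frequencies fall outside the configured band")
  }
  d <- dim(cube$traces)
  n <- d[3]
  npx <- d[1] * d[2]
  if (is.null(metal_ref)) {
    off <- which(!cube$leaf_mask)
    if (length(off) == 0) abort("no off-leaf pixel available; give `metal_ref`")
    metal_ref <- c(
      row = (off[1] - 1) %% d[1] + 1,
      col = (off[1] - 1) %/% d[1] + 1
    )
  }
  w <- tukey_window(n, 0.25)
  M <- matrix(aperm(cube$traces, c(3, 1, 2)), nrow = n) * w
  X <- stats::mvfft(M) # columns are pixels in column-major (row, col) order
  nh <- n %/% 2 + 1
  X <- X[1:nh, , drop = FALSE]
  f <- cube$freq_THz
  ref_idx <- (metal_ref[2] - 1) * d[1] + metal_ref[1]

  bandbins <- which(f >= band[1] & f <= band[2])
  wrapped <- Arg(X[bandbins, , drop = FALSE] *
                   Conj(X[bandbins, ref_idx]))
  unwrapped <- unwrap_phase(wrapped)

  amplitude <- list()
  phase <- list()
  norm_const <- numeric(length(freqs))
  bin_index <- integer(length(freqs))
  for (q in seq_along(freqs)) {
    b <- which.min(abs(f - freqs[q]))
    bin_index[q] <- b
    amp <- matrix(Mod(X[b, ]), d[1], d[2])
    norm_const[q] <- max(amp)
    amplitude[[q]] <- amp / norm_const[q]
    brow <- which(bandbins == b)
    if (length(brow) == 0) abort("frequency line outside the band bins")
    phase[[q]] <- matrix(unwrapped[brow, ], d[1], d[2])
  }
  structure(
    list(
      freq_requested = freqs, freq_bin_THz = f[bin_index],
      bin_index = bin_index, amplitude = amplitude, phase = phase,
      norm_const = norm_const, metal_ref = metal_ref,
      leaf_mask = cube$leaf_mask, cfg = cube$cfg
    ),
    class = "tds_image_set"
  )
}

#' @method as_tibble tds_image_set
#' @export
as_tibble.tds_image_set <- function(x, ...) {
  d <- dim(x$amplitude[[1]])
  purrr::map2(seq_along(x$freq_requested), x$freq_requested, function(q, fq) {
    tibble(
      freq_THz = fq,
      row = rep(seq_len(d[1]), d[2]),
      col = rep(seq_len(d[2]), each = d[1]),
      amplitude = as.vector(x$amplitude[[q]]),
      phase = as.vector(x$phase[[q]]),
      leaf = as.vector(x$leaf_mask)
    )
  }) |> bind_rows()
}

#' @method autoplot tds_image_set
#' @export
autoplot.tds_image_set <- function(object, what = c("amplitude", "phase"),
                                   ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data[[what]])) +
    geom_raster() +
    scale_y_reverse() +
    facet_wrap(~freq_THz, labeller = label_both) +
    scale_fill_viridis_c(option = if (what == "amplitude") "inferno" else "viridis") +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Drying gradient statistic of a TDS amplitude image
#'
#' Mean normalised amplitude of leaf pixels in the bottom rows minus the
#' top rows at a chosen frequency line. A slow raster scan of a drying leaf
#' makes later (bottom) rows drier and therefore brighter, so the statistic
#' is positive and grows with pixel dwell time.
#'
#' @param images A [spectral_images()] set.
#' @param freq_THz Which line to use (nearest requested line is taken).
#' @param n_rows Number of rows in each of the top and bottom bands.
#' @return A tibble with `top_mean`, `bottom_mean` and `gradient`
#'   (bottom - top).
#' @export
tds_drying_gradient <- function(images, freq_THz = 1.0, n_rows = 10) {
  if (!inherits(images, "tds_image_set")) {
    abort("`images` must be a `tds_image_set`")
  }
  q <- which.min(abs(images$freq_requested - freq_THz))
  amp <- images$amplitude[[q]]
  leaf <- images$leaf_mask
  nr <- nrow(amp)
  top <- seq_len(n_rows)
  bot <- seq(nr - n_rows + 1, nr)
  top_vals <- amp[top, ][leaf[top, ]]
  bot_vals <- amp[bot, ][leaf[bot, ]]
  if (length(top_vals) == 0 || length(bot_vals) == 0) {
    abort("no leaf pixels inside the requested row bands")
  }
  tibble(
    freq_THz = images$freq_bin_THz[q],
    top_mean = mean(top_vals), bottom_mean = mean(bot_vals),
    gradient = mean(bot_vals) - mean(top_vals)
  )
}

#' Penetration-depth surface over frequency and drying time
#'
#' For each (frequency, time) pair, the leaf composition is dried with the
#' curve, converted to an effective medium, and the power 1/e penetration
#' depth `1/alpha` evaluated. Frequencies where water dominates give
#' shallow depths; drying increases them.
#'
#' @param f_water0 Initial water volume fraction.
#' @param times_min Drying times in minutes (>= 2 values).
#' @param freq_THz Frequency grid in THz.
#' @param curve A [drying_curve()].
#' @param water_params Water model (calibrated by default).
#' @param f_dry Dry-matter fraction.
#' @param on_vein Evaluate the vein branch of the drying curve.
#' @param cap_um Depth cap for near-lossless media, um.
#' @return A tibble of class `penetration_map` with columns `time_min`,
#'   `freq_THz`, `alpha_cm`, `delta_um`.
#' @export
penetration_map <- function(f_water0, times_min, freq_THz,
                            curve = drying_curve(),
                            water_params = calibrated_water_params(),
                            f_dry = 0.2, on_vein = FALSE, cap_um = 5000) {
  if (length(times_min) < 2) abort("need >= 2 time points")
  water <- water_permittivity(freq_THz, water_params)
  dry <- dry_matter_spectrum(freq_THz)
  out <- purrr::map(times_min, function(tm) {
    fw <- f_water0 * drying_multiplier(tm, curve, on_vein = on_vein)
    eff <- effective_leaf_index(fw, f_dry, water = water, dry = dry)
    ac <- absorption_coefficient(eff)
    tibble(
      time_min = tm, freq_THz = freq_THz, alpha_cm = ac$alpha_cm,
      delta_um = penetration_depth(ac$alpha_cm, cap_um)
    )
  }) |> bind_rows()
  class(out) <- c("penetration_map", class(out))
  out
}

#' @method autoplot penetration_map
#' @export
autoplot.penetration_map <- function(object, ...) {
  ggplot(object, aes(x = .data$freq_THz, y = .data$time_min,
                     fill = .data$delta_um)) +
    geom_raster() +
    scale_fill_viridis_c(trans = "log10", name = "depth (um)") +
    labs(x = "frequency (THz)", y = "time since plucking (min)") +
    theme_minimal()
}

#' Recover the two-pass optical absorbance from a waveform cube
#'
#' Time-gates a leaf pixel's trace past the front-surface reflection,
#' isolating the metal echo that traversed the leaf twice, and returns the
#' negative log ratio of its spectral amplitude to a bare-metal reference
#' pixel at the chosen frequency line. For a uniform leaf this estimates
#' the round-trip field absorbance `alpha_eff * d / cos(theta_int)`
#' (power absorption coefficient times the double-pass path over 2).
#'
#' @param cube A [raster_scan_tds()] cube.
#' @param pixel `c(row, col)` of a leaf pixel.
#' @param metal_pixel `c(row, col)` of a bare-metal pixel (default: first
#'   off-leaf pixel).
#' @param freq_THz Evaluation frequency (nearest bin used).
#' @param gate_start_ps Start of the echo gate relative to trace start;
#'   defaults to the reference pulse centre plus twice the pulse width.
#' @return A tibble with `freq_THz` (bin) and `absorbance` (natural log
#'   units).
#' @export
recover_echo_absorbance <- function(cube, pixel, metal_pixel = NULL,
                                    freq_THz = 1.0, gate_start_ps = NULL) {
  if (!inherits(cube, "tds_cube")) abort("`cube` must be a `tds_cube`")
  d <- dim(cube$traces)
  if (is.null(metal_pixel)) {
    off <- which(!cube$leaf_mask)
    if (length(off) == 0) abort("no off-leaf pixel; give `metal_pixel`")
    metal_pixel <- c((off[1] - 1) %% d[1] + 1, (off[1] - 1) %/% d[1] + 1)
  }
  v <- cube$traces[pixel[1], pixel[2], ]
  ref <- cube$traces[metal_pixel[1], metal_pixel[2], ]
  t <- cube$time_ps
  t0 <- t[which.max(abs(ref))]
  if (is.null(gate_start_ps)) {
    gate_start_ps <- t0 + 2 * cube$cfg$pulse_width_ps
  }
  gated <- v
  gated[t < gate_start_ps] <- 0
  Sg <- Mod(rfft_bins(gated))
  Sr <- Mod(rfft_bins(ref))
  b <- which.min(abs(cube$freq_THz - freq_THz))
  tibble(
    freq_THz = cube$freq_THz[b],
    absorbance = -log(Sg[b] / Sr[b]),
    gate_start_ps = gate_start_ps
  )
}

#' Model-predicted two-pass absorbance of a uniform leaf
#'
#' The exact round-trip field attenuation exponent
#' `2 k0 Im(q) d` of a uniform effective-medium layer at oblique incidence
#' (`q` the complex direction cosine), the quantity
#' [recover_echo_absorbance()] estimates from data.
#'
#' @param f_water,f_dry Volume fractions.
#' @param thickness_um Layer thickness, um.
#' @param freq_THz Frequency, THz.
#' @param water_params Water model.
#' @param incidence_deg Angle of incidence from air.
#' @return Absorbance in natural log units.
#' @export
echo_absorbance_predicted <- function(f_water, f_dry, thickness_um,
                                      freq_THz,
                                      water_params = calibrated_water_params(),
                                      incidence_deg = 8) {
  water <- water_permittivity(freq_THz, water_params)
  dry <- dry_matter_spectrum(freq_THz)
  eff <- effective_leaf_index(f_water, f_dry, water = water, dry = dry)
  nc <- complex(real = eff$n, imaginary = eff$k)
  s2 <- sin(incidence_deg * pi / 180)^2
  q <- tilt_q(Conj(nc), s2) # Im <= 0 internal convention
  k0 <- 2 * pi * freq_THz * 1e12 / .c0
  2 * k0 * abs(Im(q)) * thickness_um * 1e-6
}

#' Table-anchored water model
#'
#' The default double-Debye water parameters calibrated so the power
#' absorption coefficient equals 500 cm^-1 at 2.71 THz (the published
#' anchor for liquid water at the LFI operating frequency).
#'
#' @return A calibrated [debye_params()] object.
#' @export
calibrated_water_params <- function() {
  calibrate_absorption(
    debye_params(),
    data.frame(freq_THz = 2.71, alpha_cm = 500)
  )
}
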