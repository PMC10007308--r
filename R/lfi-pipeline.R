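#' Swept-frequency LFI imaging configuration
#'
#' Acquisition parameters of the quantum-cascade-laser laser-feedback
#' interferometer: a 2.71 THz carrier swept by 600 MHz over each 500 ns
#' drive pulse, a ~1.2 m external cavity to the leaf, 0.1 ms per pixel on a
#' 500 x 500 grid spanning 25 x 25 mm (25 s per frame). The post-objective
#' scan introduces a quadratic (field-curvature) phase across the image,
#' which is why only amplitude is recovered.
#'
#' @param carrier_THz Laser operating frequency, THz.
#' @param sweep_span_MHz Intra-pulse frequency sweep, MHz.
#' @param pulse_duration_ns Drive pulse length, ns.
#' @param samples_per_pulse Samples digitised per pulse.
#' @param cavity_length_m External cavity (laser-to-target) length, m.
#' @param feedback_C Acket feedback parameter C at unit target reflectivity.
#' @param henry_alpha Linewidth-enhancement factor.
#' @param pixel_dwell_ms Time per pixel, ms.
#' @param grid Image size `c(rows, cols)`.
#' @param extent_mm Scan extent `c(height, width)`, mm.
#' @param field_curvature_rad Peak-to-corner quadratic phase across the
#'   field, radians (0 disables).
#' @param blue_threshold_db Hydration ("blue pixel") threshold in dB
#'   relative to the frame peak.
#' @param noise_sd Additive voltage noise sd (interferogram units).
#' @param seed RNG seed.
#' @return An object of class `lfi_config`.
#' @export
lfi_config <- function(carrier_THz = 2.71, sweep_span_MHz = 600,
                       pulse_duration_ns = 500, samples_per_pulse = 512,
                       cavity_length_m = 1.2, feedback_C = 0.3,
                       henry_alpha = 3.0, pixel_dwell_ms = 0.1,
                       grid = c(500, 500), extent_mm = c(25, 25),
                       field_curvature_rad = 8, blue_threshold_db = -60,
                       noise_sd = 0, seed = 1) {
  stopifnot_scalar(sweep_span_MHz, "sweep_span_MHz")
  stopifnot_scalar(pulse_duration_ns, "pulse_duration_ns")
  if (feedback_C < 0) abort("`feedback_C` must be >= 0")
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1)) abort("`grid` must be c(rows, cols)")
  if (samples_per_pulse < 16) abort("`samples_per_pulse` must be >= 16")
  structure(
    list(
      carrier_THz = carrier_THz, sweep_span_MHz = sweep_span_MHz,
      pulse_duration_ns = pulse_duration_ns,
      samples_per_pulse = as.integer(samples_per_pulse),
      cavity_length_m = cavity_length_m, feedback_C = feedback_C,
      henry_alpha = henry_alpha, pixel_dwell_ms = pixel_dwell_ms,
      grid = grid, extent_mm = extent_mm,
      field_curvature_rad = field_curvature_rad,
      blue_threshold_db = blue_threshold_db, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "lfi_config"
  )
}

#' @export
print.lfi_config <- function(x, ...) {
  cat(sprintf(
    "<lfi_config> %.2f THz + %g MHz sweep / %g ns, L = %.2f m, C = %.2f, %dx%d px\n",
    x$carrier_THz, x$sweep_span_MHz, x$pulse_duration_ns,
    x$cavity_length_m, x$feedback_C, x$grid[1], x$grid[2]
  ))
  invisible(x)
}

# frame acquisition time in seconds
lfi_frame_seconds <- function(cfg) {
  prod(cfg$grid) * cfg$pixel_dwell_ms / 1000
}

#' Instantaneous optical frequency during the drive pulse
#'
#' Linear ramp from the carrier to carrier + sweep span over the pulse.
#'
#' @param t_ns Time(s) within the pulse, ns, in `[0, pulse_duration_ns]`.
#' @param cfg An [lfi_config()].
#' @return Optical frequency in Hz.
#' @export
#' @examples
#' sweep_frequency(c(0, 250, 500), lfi_config())
sweep_frequency <- function(t_ns, cfg) {
  if (any(t_ns < 0) || any(t_ns > cfg$pulse_duration_ns)) {
    abort("`t_ns` must lie within the drive pulse")
  }
  cfg$carrier_THz * 1e12 +
    cfg$sweep_span_MHz * 1e6 * t_ns / cfg$pulse_duration_ns
}

#' Steady-state excess-phase equation of laser feedback interferometry
#'
#' Solves `phi_s = phi_fb + C * sin(phi_fb + atan(henry_alpha))` for the
#' feedback-perturbed interferometric phase `phi_fb`, vectorised over
#' `phi_s` (and `C`). For `C < 1` the solution is unique and found by a
#' safeguarded Newton iteration; for `C >= 1` the solver tracks the branch
#' continuous in `phi_s` by continuation along the input order. The result
#' carries a `multistable` attribute, `TRUE` when `C >= 4.6` (strong
#' feedback with multiple coexisting branches).
#'
#' @param phi_s Free-running interferometric phase(s), radians.
#' @param C Feedback level(s), >= 0.
#' @param henry_alpha Linewidth-enhancement factor.
#' @param tol Residual tolerance.
#' @return `phi_fb` with attribute `multistable`.
#' @export
#' @examples
#' excess_phase(1.3, C = 0.3)
excess_phase <- function(phi_s, C, henry_alpha = 3.0, tol = 1e-12) {
  if (any(C < 0)) abort("`C` must be >= 0")
  th <- atan(henry_alpha)
  nph <- length(phi_s)
  Cv <- rep_len(C, nph)

  newton <- function(phi, phis, Cc) {
    for (it in 1:200) {
      fv <- phi + Cc * sin(phi + th) - phis
      if (max(abs(fv)) < tol) break
      fp <- 1 + Cc * cos(phi + th)
      fp[abs(fp) < 1e-3] <- sign(fp[abs(fp) < 1e-3] + 1e-12) * 1e-3
      step <- fv / fp
      step <- pmax(pmin(step, 1), -1)
      phi <- phi - step
    }
    phi
  }

  # bisection on the root bracket nearest `init` (robust near folds)
  bisect_near <- function(phis, Cc, init) {
    f <- function(p) p + Cc * sin(p + th) - phis
    gr <- seq(phis - Cc - 0.5, phis + Cc + 0.5, length.out = 512)
    fg <- f(gr)
    sw <- which(fg[-1] * fg[-length(fg)] <= 0)
    if (length(sw) == 0) return(newton(init, phis, Cc))
    mids <- (gr[sw] + gr[sw + 1]) / 2
    j <- sw[which.min(abs(mids - init))]
    lo <- gr[j]
    hi <- gr[j + 1]
    for (it in 1:100) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }

  if (all(Cv < 1)) {
    out <- newton(phi_s, phi_s, Cv)
  } else {
    # branch tracking: warm-start each solve from the previous solution
    out <- numeric(nph)
    prev <- phi_s[1]
    for (i in seq_len(nph)) {
      init <- if (i == 1) phi_s[1] else prev + (phi_s[i] - phi_s[i - 1])
      cand <- newton(init, phi_s[i], Cv[i])
      if (abs(cand + Cv[i] * sin(cand + th) - phi_s[i]) > tol ||
          Cv[i] >= 1) {
        cand2 <- bisect_near(phi_s[i], Cv[i], init)
        if (abs(cand2 + Cv[i] * sin(cand2 + th) - phi_s[i]) <
            abs(cand + Cv[i] * sin(cand + th) - phi_s[i]) ||
            abs(cand2 - init) < abs(cand - init)) {
          cand <- cand2
        }
      }
      out[i] <- cand
      prev <- out[i]
    }
  }
  res <- abs(out + Cv * sin(out + th) - phi_s)
  bad <- which(res > tol * 10)
  if (length(bad) > 0) {
    for (i in bad) out[i] <- bisect_near(phi_s[i], Cv[i], out[i])
    res <- abs(out + Cv * sin(out + th) - phi_s)
  }
  if (max(res) > 1e-10) {
    warn(sprintf("excess-phase residual %.2e above 1e-10", max(res)))
  }
  attr(out, "multistable") <- any(Cv >= 4.6)
  out
}

#' Simulate one pixel's self-mixing interferogram
#'
#' The intra-pulse frequency sweep winds the round-trip interferometric
#' phase `phi_s(t) = 4 pi L f(t) / c + r_phase` through
#' `2 L df / c` fringes (about 4.8 for 1.2 m and 600 MHz). The terminal
#' voltage is modelled as `C_eff * cos(phi_fb)` with `C_eff = C * r_amp`,
#' so a vanishing target return gives a DC-only trace and weak feedback is
#' linear in target amplitude.
#'
#' @param r_amp Target field reflectivity magnitude in `[0, 1]`.
#' @param r_phase Target phase, radians (includes any field-curvature
#'   contribution).
#' @param cfg An [lfi_config()].
#' @param seed Optional seed for the noise draw (`cfg$noise_sd`).
#' @param dc DC voltage offset.
#' @return An object of class `lfi_interferogram`: `t_ns`, `voltage`.
#' @export
simulate_interferogram <- function(r_amp, r_phase = 0, cfg = lfi_config(),
                                   seed = NULL, dc = 0) {
  if (r_amp < 0 || r_amp > 1) abort("`r_amp` must lie in [0, 1]")
  nsmp <- cfg$samples_per_pulse
  t_ns <- (seq_len(nsmp) - 1) / nsmp * cfg$pulse_duration_ns
  fHz <- sweep_frequency(t_ns, cfg)
  phi_s <- 4 * pi * cfg$cavity_length_m * fHz / .c0 + r_phase
  C_eff <- cfg$feedback_C * r_amp
  v <- if (C_eff == 0) {
    rep(0, nsmp)
  } else {
    C_eff * cos(excess_phase(phi_s, C_eff, cfg$henry_alpha))
  }
  v <- v + dc
  if (cfg$noise_sd > 0) {
    draw <- function() rnorm(nsmp, 0, cfg$noise_sd)
    v <- v + if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  structure(list(t_ns = t_ns, voltage = v), class = "lfi_interferogram")
}

#' Count interferometric fringes in a trace
#'
#' Zero crossings of the mean-removed voltage divided by two.
#'
#' @param ig An [simulate_interferogram()] object or numeric trace.
#' @return Fringe count (possibly half-integer).
#' @export
fringe_count <- function(ig) {
  v <- if (inherits(ig, "lfi_interferogram")) ig$voltage else ig
  v <- v - mean(v)
  sum(diff(sign(v)) != 0) / 2
}

# Hann DTFT magnitude relative shape at fractional bin offset d (g(0)=0.5)
hann_shape <- function(d) {
  ifelse(abs(d) < 1e-9, 0.5, sin(pi * d) * 0.5 / (pi * d * (1 - d^2)))
}

#' Recover the fringe amplitude of an interferogram
#'
#' Removes the mean, applies a Hann window, and takes the dominant non-DC
#' FFT peak. The fractional bin offset is estimated from the two
#' neighbouring bins (Grandke interpolation for the Hann window) and the
#' peak magnitude corrected for window gain and scalloping; optionally the
#' estimate is refined by a least-squares single-tone fit (exact for a pure
#' cosine, at any phase and DC offset).
#'
#' @param ig An `lfi_interferogram` or a numeric voltage trace (length >=
#'   16).
#' @param refine Logical: refine with the least-squares tone fit
#'   (default `TRUE`).
#' @return Amplitude scalar (>= 0); 0 for an all-zero trace.
#' @export
recover_amplitude <- function(ig, refine = TRUE) {
  v <- if (inherits(ig, "lfi_interferogram")) ig$voltage else ig
  if (length(v) < 16) abort("trace length must be >= 16")
  v <- v - mean(v)
  if (all(v == 0)) return(0)
  n <- length(v)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  X <- fft(v * w)
  half <- 2:(n %/% 2)
  k <- half[which.max(Mod(X[half]))]
  mk <- Mod(X[k])
  ml <- Mod(X[k - 1])
  mr <- Mod(X[k + 1])
  if (mr >= ml) {
    b <- mr / mk
    d <- (2 * b - 1) / (1 + b)
  } else {
    b <- ml / mk
    d <- -(2 * b - 1) / (1 + b)
  }
  a <- 2 * mk / (n * hann_shape(d))
  if (!refine) return(a)

  f0 <- (k - 1 + d) / n
  tt <- 0:(n - 1)
  sse <- function(fr) {
    Cc <- cos(2 * pi * fr * tt)
    Ss <- sin(2 * pi * fr * tt)
    sum(.lm.fit(cbind(1, Cc, Ss), v)$residuals^2)
  }
  o <- optimize(sse, c(f0 - 1 / n, f0 + 1 / n), tol = 1e-10)
  fr <- o$minimum
  h <- 1e-9 / n
  for (it in 1:4) {
    s0 <- sse(fr - h)
    s1 <- sse(fr)
    s2 <- sse(fr + h)
    den <- s0 - 2 * s1 + s2
    if (is.finite(den) && den > 0) {
      step <- h * (s0 - s2) / (2 * den)
      if (abs(step) < 1 / n) fr <- fr + step
    }
  }
  Cc <- cos(2 * pi * fr * tt)
  Ss <- sin(2 * pi * fr * tt)
  cf <- .lm.fit(cbind(1, Cc, Ss), v)$coefficients
  sqrt(cf[2]^2 + cf[3]^2)
}

# quadratic field-curvature phase map across the grid (peak at corners)
curvature_phase <- function(cfg) {
  nr <- cfg$grid[1]
  nc <- cfg$grid[2]
  ry <- (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2)
  rx <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2)
  cfg$field_curvature_rad * outer(ry^2, rx^2, `+`) / 2
}

#' Acquire one LFI frame of the drying leaf
#'
#' Per pixel: the leaf-on-metal reflection coefficient at the carrier
#' (normal incidence, metal-echo component — the sub-surface return that
#' carries the hydration contrast), then either a direct amplitude map
#' (`method = "amplitude"`, the weak-feedback linearisation; fast) or a
#' full self-mixing simulation with [simulate_interferogram()] +
#' [recover_amplitude()] per pixel (`method = "interferogram"`). The frame
#' is stamped at `frame_start_min`; drying within the ~25 s frame is
#' neglected, as it is slow compared to the frame time. The dB map is
#' referenced to the frame peak (the bare-metal region).
#'
#' @param phantom A [generate_phantom()] phantom matching `cfg$grid`.
#' @param curve A [drying_curve()].
#' @param frame_start_min Frame time in minutes since plucking.
#' @param cfg An [lfi_config()].
#' @param water_params Water model (calibrated by default).
#' @param method `"amplitude"` or `"interferogram"`.
#' @return An object of class `lfi_frame`: `amplitude`, `db_map`,
#'   `frame_time_min`, `frame_seconds`, masks.
#' @export
scan_frame <- function(phantom, curve, frame_start_min, cfg = lfi_config(),
                       water_params = calibrated_water_params(),
                       method = c("amplitude", "interferogram")) {
  method <- match.arg(method)
  if (!inherits(phantom, "leaf_phantom")) {
    abort("`phantom` must be a `leaf_phantom`")
  }
  d <- dim(phantom$water_fraction)
  if (!all(d == cfg$grid)) abort("phantom grid does not match cfg$grid")

  st <- phantom_at(phantom, curve, frame_start_min)
  wspec <- water_permittivity(cfg$carrier_THz, water_params)
  dspec <- dry_matter_spectrum(cfg$carrier_THz)
  nw <- complex(real = wspec$n, imaginary = wspec$k)
  ndm <- complex(real = dspec$n, imaginary = dspec$k)

  fw <- as.vector(st$water_fraction)
  fd <- as.vector(st$dry_fraction)
  fa <- pmax(1 - fw - fd, 0)
  neff <- fw * nw + fd * ndm + fa
  th <- as.vector(st$thickness_um)
  leaf <- as.vector(st$leaf_mask)

  r_echo <- rep(-1 + 0i, length(fw)) # bare metal
  if (any(leaf)) {
    rl <- uniform_layer_pec_r(
      cfg$carrier_THz, neff[leaf], th[leaf],
      incidence_deg = 0, polarization = "s"
    )
    r_echo[leaf] <- rl$total - rl$front
  }

  if (method == "amplitude") {
    amp <- Mod(r_echo)
  } else {
    psi <- as.vector(curvature_phase(cfg))
    amp <- numeric(length(r_echo))
    for (i in seq_along(r_echo)) {
      ig <- simulate_interferogram(
        min(Mod(r_echo[i]), 1), Arg(r_echo[i]) + psi[i], cfg
      )
      amp[i] <- recover_amplitude(ig)
    }
  }
  amp <- matrix(amp, d[1], d[2])
  db <- 20 * log10(pmax(amp, .Machine$double.xmin) / max(amp))
  structure(
    list(
      amplitude = amp, db_map = db, frame_time_min = frame_start_min,
      frame_seconds = lfi_frame_seconds(cfg),
      leaf_mask = phantom$leaf_mask, vein_mask = phantom$vein_mask,
      cfg = cfg, method = method
    ),
    class = "lfi_frame"
  )
}

#' @export
print.lfi_frame <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<lfi_frame> %dx%d px at t = %.1f min (%.1f s frame, %s method)\n",
    d[1], d[2], x$frame_time_min, x$frame_seconds, x$method
  ))
  invisible(x)
}

#' @method autoplot lfi_frame
#' @export
autoplot.lfi_frame <- function(object, ...) {
  d <- dim(object$db_map)
  df <- tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    db = as.vector(object$db_map)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$db)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(option = "turbo", name = "dB") +
    coord_equal() +
    labs(
      x = NULL, y = NULL,
      title = sprintf("LFI frame, t = %.0f min", object$frame_time_min)
    ) +
    theme_minimal()
}

#' Fraction of leaf pixels below the hydration threshold
#'
#' The "blue pixel" statistic: the fraction of leaf-mask pixels whose
#' reflectivity amplitude lies at or below `threshold_db` relative to the
#' frame peak — a proxy for highly hydrated area.
#'
#' @param frame An [scan_frame()] frame.
#' @param threshold_db Threshold in dB (default the config's, -60).
#' @return A scalar in `[0, 1]`.
#' @export
blue_fraction <- function(frame, threshold_db = NULL) {
  if (!inherits(frame, "lfi_frame")) abort("`frame` must be an `lfi_frame`")
  threshold_db <- threshold_db %||% frame$cfg$blue_threshold_db
  if (sum(frame$leaf_mask) == 0) abort("empty leaf mask")
  mean(frame$db_map[frame$leaf_mask] <= threshold_db)
}

#' Assemble a hydration time series from LFI frames
#'
#' Blue-pixel fraction per frame against frame time.
#'
#' @param frames List of [scan_frame()] frames with strictly increasing
#'   times (>= 3 frames).
#' @param threshold_db Threshold passed to [blue_fraction()].
#' @return A tibble of class `hydration_series` with columns `time_min`,
#'   `blue_fraction`.
#' @export
hydration_series <- function(frames, threshold_db = NULL) {
  if (length(frames) < 3) abort("need >= 3 frames")
  times <- map_dbl(frames, "frame_time_min")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("frames must have strictly increasing times")
  }
  bf <- map_dbl(frames, blue_fraction, threshold_db = threshold_db)
  new_hydration_series(times, bf)
}

#' @rdname hydration_series
#' @param time_min,blue_fraction Raw vectors for direct construction.
#' @export
new_hydration_series <- function(time_min, blue_fraction) {
  if (length(time_min) != length(blue_fraction)) {
    abort("`time_min` and `blue_fraction` lengths differ")
  }
  out <- tibble(time_min = as.double(time_min),
                blue_fraction = as.double(blue_fraction))
  class(out) <- c("hydration_series", class(out))
  out
}

#' @method autoplot hydration_series
#' @export
autoplot.hydration_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$blue_fraction)) +
    geom_line(colour = "grey50") +
    geom_point(size = 0.8) +
    labs(x = "time since plucking (min)", y = "blue-pixel fraction") +
    theme_minimal()
}

#' Simulate a full dehydration image series
#'
#' Runs [scan_frame()] at each requested time and assembles the
#' [hydration_series()].
#'
#' @param phantom,curve,cfg,water_params,method As in [scan_frame()].
#' @param times_min Frame times, minutes (default one frame per 25 s over
#'   300 min would be 720 frames; pass fewer for quick looks).
#' @param threshold_db Blue threshold.
#' @return A `hydration_series`.
#' @export
simulate_hydration_series <- function(phantom, curve,
                                      times_min = seq(0, 300, by = 25 / 60),
                                      cfg = lfi_config(),
                                      water_params = calibrated_water_params(),
                                      method = "amplitude",
                                      threshold_db = NULL) {
  frames <- purrr::map(times_min, function(tm) {
    scan_frame(phantom, curve, tm, cfg, water_params, method = method)
  })
  hydration_series(frames, threshold_db = threshold_db)
}

#' Lossless CSV round trip for hydration series
#'
#' @param series A `hydration_series`.
#' @param path File path.
#' @return `write_hydration_csv()` returns `path` invisibly;
#'   `read_hydration_csv()` returns the series.
#' @export
write_hydration_csv <- function(series, path) {
  df <- data.frame(
    time_min = format(series$time_min, digits = 17, trim = TRUE),
    blue_fraction = format(series$blue_fraction, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hydration_csv
#' @export
read_hydration_csv <- function(path) {
  df <- read.csv(path)
  new_hydration_series(df$time_min, df$blue_fraction)
}
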