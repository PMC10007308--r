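#' Dielectric spectrum of a leaf constituent
#'
#' A `thz_spectrum` is a tibble holding the complex optical response of one
#' material on an ascending terahertz frequency grid: relative permittivity
#' (`eps_real`, `eps_imag`) together with the derived complex refractive
#' index (`n`, `k`) from the principal square root. The sign convention is
#' passive (`eps_imag >= 0`, `k >= 0`, time dependence `exp(-i w t)`).
#'
#' @param freq_THz Strictly increasing frequency grid in THz.
#' @param eps_real,eps_imag Real and imaginary relative permittivity. Supply
#'   either these or `n`/`k`.
#' @param n,k Refractive index and extinction coefficient. If given,
#'   permittivity is derived as `(n + ik)^2`.
#' @return A tibble of class `thz_spectrum` with columns `freq_THz`,
#'   `eps_real`, `eps_imag`, `n`, `k`.
#' @export
#' @examples
#' dielectric_spectrum(c(0.5, 1, 2), n = c(1.5, 1.5, 1.5), k = c(0, 0, 0))
dielectric_spectrum <- function(freq_THz, eps_real = NULL, eps_imag = NULL,
                                n = NULL, k = NULL) {
  if (!is.numeric(freq_THz) || anyNA(freq_THz)) {
    abort("`freq_THz` must be numeric without NA")
  }
  if (is.unsorted(freq_THz, strictly = TRUE)) {
    abort("`freq_THz` must be strictly increasing")
  }
  if (!is.null(n)) {
    if (is.null(k)) abort("supply both `n` and `k`")
    ec <- (n + 1i * k)^2
    eps_real <- Re(ec)
    eps_imag <- Im(ec)
  } else {
    if (is.null(eps_real) || is.null(eps_imag)) {
      abort("supply `eps_real`/`eps_imag` or `n`/`k`")
    }
    nk <- sqrt(complex(real = eps_real, imaginary = eps_imag))
    n <- Re(nk)
    k <- Im(nk)
  }
  if (any(eps_imag < -1e-12)) abort("`eps_imag` must be >= 0 (passive medium)")
  if (any(n < 1e-6)) abort("`n` must be >= 1e-6")
  if (any(k < -1e-12)) abort("`k` must be >= 0")
  out <- tibble(
    freq_THz = as.double(freq_THz),
    eps_real = as.double(eps_real),
    eps_imag = pmax(as.double(eps_imag), 0),
    n = as.double(n),
    k = pmax(as.double(k), 0)
  )
  class(out) <- c("thz_spectrum", class(out))
  out
}

#' Double-Debye relaxation parameters for liquid water
#'
#' Parameter container for the two-relaxation Debye description of liquid
#' water in the terahertz band, plus a scalar extinction calibration factor
#' (`calib_scale`, multiplies `k`) used to pin the absorption coefficient to
#' a measured anchor (see [calibrate_absorption()]). Defaults follow
#' commonly used literature values for water at room temperature.
#'
#' @param eps_static Static relative permittivity (f -> 0 limit).
#' @param eps_intermediate Intermediate permittivity between the two
#'   relaxations.
#' @param eps_inf High-frequency permittivity (f -> infinity limit).
#' @param tau1_ps,tau2_ps Slow and fast relaxation times in picoseconds.
#' @param calib_scale Unitless multiplier applied to the extinction
#'   coefficient after calibration.
#' @return An object of class `debye_params`.
#' @export
debye_params <- function(eps_static = 78.36, eps_intermediate = 4.93,
                         eps_inf = 3.48, tau1_ps = 8.24, tau2_ps = 0.18,
                         calib_scale = 1) {
  for (nm in c("eps_static", "eps_intermediate", "eps_inf", "tau1_ps",
               "tau2_ps", "calib_scale")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (!(eps_static > eps_intermediate && eps_intermediate > eps_inf &&
        eps_inf > 1)) {
    abort("need eps_static > eps_intermediate > eps_inf > 1")
  }
  if (!(tau1_ps > tau2_ps && tau2_ps > 0)) {
    abort("need tau1_ps > tau2_ps > 0")
  }
  structure(
    list(
      eps_static = eps_static, eps_intermediate = eps_intermediate,
      eps_inf = eps_inf, tau1_ps = tau1_ps, tau2_ps = tau2_ps,
      calib_scale = calib_scale
    ),
    class = "debye_params"
  )
}

#' @export
print.debye_params <- function(x, ...) {
  cat("<debye_params>\n")
  cat(sprintf(
    "  eps_s = %.3f, eps_i = %.3f, eps_inf = %.3f\n",
    x$eps_static, x$eps_intermediate, x$eps_inf
  ))
  cat(sprintf("  tau1 = %.3f ps, tau2 = %.3f ps\n", x$tau1_ps, x$tau2_ps))
  cat(sprintf("  calib_scale = %.6f\n", x$calib_scale))
  invisible(x)
}

#' Complex permittivity of liquid water from the double-Debye model
#'
#' Evaluates `eps(w) = eps_inf + (eps_s - eps_i)/(1 - i w tau1) +
#' (eps_i - eps_inf)/(1 - i w tau2)` on a THz frequency grid, derives
#' `n + ik` from the principal square root, and applies the calibration
#' factor to `k` (the permittivity columns are kept consistent with the
#' scaled index).
#'
#' @param freq_THz Frequency grid in THz, within 0 to 6.5 THz, strictly
#'   increasing.
#' @param params A [debye_params()] object.
#' @return A [dielectric_spectrum()] tibble.
#' @export
#' @examples
#' water_permittivity(c(0.5, 1, 2), debye_params())
water_permittivity <- function(freq_THz, params = debye_params()) {
  if (!inherits(params, "debye_params")) {
    abort("`params` must be a `debye_params` object")
  }
  if (any(freq_THz < 0) || any(freq_THz > 6.5)) {
    abort("`freq_THz` must lie within 0-6.5 THz")
  }
  w <- 2 * pi * freq_THz * 1e12
  eps <- params$eps_inf +
    (params$eps_static - params$eps_intermediate) /
      (1 - 1i * w * params$tau1_ps * 1e-12) +
    (params$eps_intermediate - params$eps_inf) /
      (1 - 1i * w * params$tau2_ps * 1e-12)
  nk <- sqrt(eps)
  dielectric_spectrum(
    freq_THz,
    n = Re(nk),
    k = Im(nk) * params$calib_scale
  )
}

#' Dry plant matter spectrum
#'
#' Constant refractive index with a power absorption coefficient rising
#' linearly with frequency (cellulose-like low-loss dielectric): the default
#' gives 10 cm^-1 at 1 THz, which corresponds to a constant extinction
#' coefficient.
#'
#' @param freq_THz Frequency grid in THz.
#' @param n Refractive index (default 1.5).
#' @param alpha_1THz_cm Power absorption coefficient at 1 THz in cm^-1.
#' @return A [dielectric_spectrum()] tibble.
#' @export
dry_matter_spectrum <- function(freq_THz, n = 1.5, alpha_1THz_cm = 10) {
  # alpha[cm^-1] = 4 pi f k / c / 100; linear-in-f alpha means constant k
  k <- alpha_1THz_cm * 100 * .c0 / (4 * pi * 1e12)
  dielectric_spectrum(
    freq_THz,
    n = rep(n, length(freq_THz)),
    k = rep(k, length(freq_THz))
  )
}

#' Power absorption coefficient of a spectrum
#'
#' `alpha = 4 pi f k / c`, returned in cm^-1.
#'
#' @param spec A [dielectric_spectrum()] tibble.
#' @return A tibble with columns `freq_THz` and `alpha_cm`.
#' @export
#' @examples
#' absorption_coefficient(water_permittivity(c(1, 2.71)))
absorption_coefficient <- function(spec) {
  if (!inherits(spec, "thz_spectrum")) {
    abort("`spec` must be a `thz_spectrum`")
  }
  tibble(
    freq_THz = spec$freq_THz,
    alpha_cm = 4 * pi * spec$freq_THz * 1e12 * spec$k / .c0 / 100
  )
}

#' Power 1/e penetration depth
#'
#' `delta = 1/alpha`, converted to micrometres, clipped at `cap_um` for
#' near-lossless media.
#'
#' @param alpha_cm Power absorption coefficient(s) in cm^-1 (vectorised), or
#'   the tibble returned by [absorption_coefficient()].
#' @param cap_um Display cap in micrometres (default 5000).
#' @return Numeric vector of depths in um, or (for tibble input) the input
#'   tibble with a `delta_um` column appended.
#' @export
#' @examples
#' penetration_depth(500) # 20 um
penetration_depth <- function(alpha_cm, cap_um = 5000) {
  stopifnot_scalar(cap_um, "cap_um")
  if (is.data.frame(alpha_cm)) {
    alpha_cm$delta_um <- penetration_depth(alpha_cm$alpha_cm, cap_um)
    return(alpha_cm)
  }
  if (any(alpha_cm < 0)) abort("`alpha_cm` must be >= 0")
  pmin(ifelse(alpha_cm > 0, 1e4 / alpha_cm, Inf), cap_um)
}

#' Calibrate the water extinction against measured absorption anchors
#'
#' Sets `calib_scale` of a [debye_params()] object by least squares so that
#' the model's power absorption coefficient passes through the supplied
#' anchors. Since `alpha` is linear in `k`, the optimal scale has the closed
#' form `sum(alpha0 * anchor) / sum(alpha0^2)` where `alpha0` is the
#' uncalibrated model. With a single anchor the match is exact. Calibration
#' always restarts from `calib_scale = 1`, so it is idempotent.
#'
#' @param params A [debye_params()] object.
#' @param anchors A data frame with columns `freq_THz` and `alpha_cm`
#'   (anchor frequencies in THz within the model's validity range, measured
#'   power absorption in cm^-1).
#' @return The calibrated `debye_params` object.
#' @export
#' @examples
#' calibrate_absorption(debye_params(),
#'                      data.frame(freq_THz = 2.71, alpha_cm = 500))
calibrate_absorption <- function(params, anchors) {
  if (!inherits(params, "debye_params")) {
    abort("`params` must be a `debye_params` object")
  }
  if (!is.data.frame(anchors) ||
      !all(c("freq_THz", "alpha_cm") %in% names(anchors)) ||
      nrow(anchors) < 1) {
    abort("`anchors` needs columns `freq_THz`, `alpha_cm` and >= 1 row")
  }
  f <- sort(anchors$freq_THz)
  a <- anchors$alpha_cm[order(anchors$freq_THz)]
  if (any(f <= 0) || any(f > 6.5)) {
    abort("anchor frequencies must lie inside the model range (0, 6.5] THz")
  }
  base <- params
  base$calib_scale <- 1
  spec0 <- water_permittivity(f, base)
  if (any(spec0$k <= 0)) {
    abort("anchor frequency with zero extinction cannot be calibrated")
  }
  alpha0 <- absorption_coefficient(spec0)$alpha_cm
  params$calib_scale <- sum(alpha0 * a) / sum(alpha0^2)
  params
}

#' Effective refractive index of leaf tissue
#'
#' Volume-fraction-weighted linear mixing of the complex refractive indices
#' of the three leaf constituents: water, dry matter and air (n = 1 + 0i).
#' Fractions must be non-negative and sum to one.
#'
#' @param f_water,f_dry,f_air Volume fractions. `f_air` defaults to the
#'   complement of the other two.
#' @param water,dry [dielectric_spectrum()] tibbles for liquid water and dry
#'   matter, on identical frequency grids.
#' @param mixing Mixing rule; only `"linear"` is currently implemented (the
#'   option exists so alternative effective-medium rules can slot in).
#' @return A [dielectric_spectrum()] tibble for the composite.
#' @export
effective_leaf_index <- function(f_water, f_dry,
                                 f_air = 1 - f_water - f_dry,
                                 water, dry, mixing = "linear") {
  mixing <- match.arg(mixing, "linear")
  fr <- c(f_water, f_dry, f_air)
  if (length(fr) != 3 || any(fr < -1e-12)) {
    abort("volume fractions must be scalar and >= 0")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    abort("volume fractions must sum to 1 (within 1e-9)")
  }
  if (!identical(water$freq_THz, dry$freq_THz)) {
    abort("`water` and `dry` must share one frequency grid")
  }
  nc <- f_water * complex(real = water$n, imaginary = water$k) +
    f_dry * complex(real = dry$n, imaginary = dry$k) +
    f_air * (1 + 0i)
  dielectric_spectrum(water$freq_THz, n = Re(nc), k = Im(nc))
}

#' Read or write a material spectrum as CSV
#'
#' Plain-text interchange of [dielectric_spectrum()] objects with columns
#' `freq_THz`, `eps_real`, `eps_imag` (the refractive index is re-derived on
#' read).
#'
#' @param spec A `thz_spectrum`.
#' @param path File path.
#' @return `write_spectrum_csv()` returns `path` invisibly;
#'   `read_spectrum_csv()` returns a `thz_spectrum`.
#' @export
write_spectrum_csv <- function(spec, path) {
  if (!inherits(spec, "thz_spectrum")) abort("`spec` must be a `thz_spectrum`")
  df <- data.frame(
    freq_THz = format(spec$freq_THz, digits = 17, trim = TRUE),
    eps_real = format(spec$eps_real, digits = 17, trim = TRUE),
    eps_imag = format(spec$eps_imag, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  dielectric_spectrum(df$freq_THz, eps_real = df$eps_real,
                      eps_imag = df$eps_imag)
}
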