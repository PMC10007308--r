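#' Layered sample description for reflectivity calculations
#'
#' Represents the sample seen by the imaging beam: an ordered list of plane
#' layers (top first) on either an ideal metal backing (perfect electric
#' conductor, reflection -1 at the final interface) or free space.
#'
#' @param layers List of layers, each a `list(thickness_um = , spec = )`
#'   where `spec` is a [dielectric_spectrum()]. May be empty (bare backing).
#' @param backing `"perfect_conductor"` (default) or `"free_space"`.
#' @param incidence_deg Angle of incidence from air, in degrees (0 to < 90).
#' @param polarization `"s"` (default) or `"p"`.
#' @return An object of class `layer_stack`.
#' @export
#' @examples
#' wat <- water_permittivity(c(1, 2, 3))
#' layer_stack(list(list(thickness_um = 200, spec = wat)), incidence_deg = 8)
layer_stack <- function(layers = list(),
                        backing = c("perfect_conductor", "free_space"),
                        incidence_deg = 0, polarization = c("s", "p")) {
  backing <- match.arg(backing)
  polarization <- match.arg(polarization)
  stopifnot_scalar(incidence_deg, "incidence_deg", positive = FALSE)
  if (incidence_deg < 0 || incidence_deg >= 90) {
    abort("`incidence_deg` must satisfy 0 <= angle < 90")
  }
  for (ly in layers) {
    if (!is.list(ly) || is.null(ly$thickness_um) || is.null(ly$spec)) {
      abort("each layer needs `thickness_um` and `spec`")
    }
    stopifnot_scalar(ly$thickness_um, "thickness_um")
    if (!inherits(ly$spec, "thz_spectrum")) {
      abort("layer `spec` must be a `thz_spectrum`")
    }
  }
  structure(
    list(
      layers = layers, backing = backing,
      incidence_deg = incidence_deg, polarization = polarization
    ),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf(
    "<layer_stack> %d layer(s) on %s, %.1f deg, %s-pol\n",
    length(x$layers), x$backing, x$incidence_deg, x$polarization
  ))
  invisible(x)
}

# Linear interpolation of the complex index of a spectrum onto a new grid.
interp_index <- function(spec, freq_THz) {
  if (length(spec$freq_THz) == length(freq_THz) &&
      all(spec$freq_THz == freq_THz)) {
    return(complex(real = spec$n, imaginary = spec$k))
  }
  rng <- range(spec$freq_THz)
  if (any(freq_THz < rng[1] - 1e-9) || any(freq_THz > rng[2] + 1e-9)) {
    abort("requested frequencies fall outside the spectrum's grid")
  }
  nn <- stats::approx(spec$freq_THz, spec$n, xout = freq_THz, rule = 2)$y
  kk <- stats::approx(spec$freq_THz, spec$k, xout = freq_THz, rule = 2)$y
  complex(real = nn, imaginary = kk)
}

# Transverse wavevector component and tilted admittance, Macleod (exp(+iwt))
# internal convention: complex index conjugated on entry, result conjugated
# on exit, so the public convention stays exp(-iwt) with k >= 0.
tilt_q <- function(n_conj, s2) {
  q <- sqrt(n_conj^2 - s2 + 0i)
  flip <- Im(q) > 0
  q[flip] <- -q[flip]
  q
}

# Closed-form reflection of a single uniform layer on a perfect conductor,
# vectorised elementwise over (freq, n, d). The workhorse for per-pixel
# simulation. Returns list(total =, front =) complex vectors.
uniform_layer_pec_r <- function(freq_THz, n_complex, d_um,
                                incidence_deg = 0, polarization = "s") {
  s2 <- sin(incidence_deg * pi / 180)^2
  y0 <- if (polarization == "s") sqrt(1 - s2) else 1 / sqrt(1 - s2)
  nn <- Conj(n_complex)
  q <- tilt_q(nn, s2)
  eta <- if (polarization == "s") q else nn^2 / q
  k0 <- 2 * pi * freq_THz * 1e12 / .c0
  delta <- k0 * q * d_um * 1e-6
  front <- Conj((y0 - eta) / (y0 + eta))
  # opaque guard: cos/sin overflow for very absorbing layers, where the
  # response is the front Fresnel term anyway
  opaque <- abs(Im(delta)) > 200
  delta[opaque] <- 0
  num <- 1i * y0 * sin(delta) - eta * cos(delta)
  den <- 1i * y0 * sin(delta) + eta * cos(delta)
  total <- Conj(num / den)
  total[opaque] <- front[opaque]
  list(total = total, front = front)
}

#' Complex reflection coefficient of a layer stack
#'
#' Transfer-matrix reflection coefficient of the stack at its configured
#' incidence angle and polarization, evaluated on a THz frequency grid. A
#' perfect-conductor backing enforces a reflection of -1 at the final
#' interface; `|r| <= 1` for passive layers. `component = "echo"` removes
#' the front-surface Fresnel term, leaving the sub-surface (metal-echo)
#' contribution that dominates hydration contrast on a metal backing.
#'
#' @param stack A [layer_stack()].
#' @param freq_THz Frequency grid in THz; defaults to the grid of the first
#'   layer's spectrum (required for a bare backing).
#' @param component `"total"` (default) or `"echo"`.
#' @return A tibble with columns `freq_THz`, `r` (complex) and `modulus`.
#' @export
#' @examples
#' stack_reflectivity(layer_stack(), freq_THz = c(1, 2)) # bare mirror
stack_reflectivity <- function(stack, freq_THz = NULL,
                               component = c("total", "echo")) {
  if (!inherits(stack, "layer_stack")) abort("`stack` must be a `layer_stack`")
  component <- match.arg(component)
  if (is.null(freq_THz)) {
    if (length(stack$layers) == 0) {
      abort("`freq_THz` is required for a bare backing")
    }
    freq_THz <- stack$layers[[1]]$spec$freq_THz
  }
  nf <- length(freq_THz)
  s2 <- sin(stack$incidence_deg * pi / 180)^2
  pol <- stack$polarization
  y0 <- if (pol == "s") sqrt(1 - s2) else 1 / sqrt(1 - s2)

  if (length(stack$layers) == 0) {
    r <- if (stack$backing == "perfect_conductor") {
      rep(-1 + 0i, nf)
    } else {
      rep(0 + 0i, nf)
    }
    return(tibble(freq_THz = freq_THz, r = r, modulus = Mod(r)))
  }

  # tangential (E, H) propagated bottom-up as 2-vectors per frequency
  if (stack$backing == "perfect_conductor") {
    E <- rep(0 + 0i, nf)
    H <- rep(1 + 0i, nf)
  } else {
    ysub <- if (pol == "s") sqrt(1 - s2 + 0i) else 1 / sqrt(1 - s2 + 0i)
    E <- rep(1 + 0i, nf)
    H <- rep(ysub, nf)
  }
  k0 <- 2 * pi * freq_THz * 1e12 / .c0
  front <- NULL
  for (idx in rev(seq_along(stack$layers))) {
    ly <- stack$layers[[idx]]
    nn <- Conj(interp_index(ly$spec, freq_THz))
    q <- tilt_q(nn, s2)
    eta <- if (pol == "s") q else nn^2 / q
    delta <- k0 * q * ly$thickness_um * 1e-6
    big <- abs(Im(delta)) > 200
    delta[big] <- complex(real = Re(delta[big]), imaginary = -200)
    cd <- cos(delta)
    sdt <- sin(delta)
    E2 <- cd * E + (1i * sdt / eta) * H
    H2 <- (1i * eta * sdt) * E + cd * H
    # renormalise to keep magnitudes bounded; r depends only on H/E
    scl <- pmax(Mod(E2), Mod(H2))
    scl[scl == 0] <- 1
    E <- E2 / scl
    H <- H2 / scl
    if (idx == 1) front <- Conj((y0 - eta) / (y0 + eta))
  }
  r <- Conj((y0 * E - H) / (y0 * E + H))
  if (component == "echo") r <- r - front
  tibble(freq_THz = freq_THz, r = r, modulus = Mod(r))
}

#' Default leaf-on-metal stack
#'
#' Convenience constructor for the single-layer leaf sample on a metal
#' backing used throughout the package: effective leaf medium of the given
#' composition and thickness over a perfect conductor.
#'
#' @param f_water,f_dry Volume fractions of water and dry matter.
#' @param thickness_um Leaf thickness in micrometres.
#' @param freq_THz Frequency grid for the constituent spectra.
#' @param water_params [debye_params()] for the water model (calibrate
#'   first if desired).
#' @param incidence_deg,polarization Beam geometry.
#' @return A [layer_stack()].
#' @export
leaf_stack <- function(f_water, f_dry = min(0.2, 1 - f_water),
                       thickness_um = 200, freq_THz,
                       water_params = debye_params(),
                       incidence_deg = 0, polarization = "s") {
  water <- water_permittivity(freq_THz, water_params)
  dry <- dry_matter_spectrum(freq_THz)
  eff <- effective_leaf_index(f_water, f_dry, water = water, dry = dry)
  layer_stack(
    list(list(thickness_um = thickness_um, spec = eff)),
    backing = "perfect_conductor",
    incidence_deg = incidence_deg, polarization = polarization
  )
}
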