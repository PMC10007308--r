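# Independent oracles and fixtures used across the suite.

C0 <- 299792458

# --- multiple-reflection (bounce-series) reflectivity oracle ---------------
# layers: list of list(d_um =, n = complex); truncated Airy summation with
# `nb` bounces per layer, recursing into the stack below. Independent of the
# package's transfer-matrix implementation.
bounce_reflectivity <- function(f_THz, layers, backing = "pec",
                                angle = 0, pol = "s", nb = 30) {
  sapply(f_THz, function(f) {
    k0 <- 2 * pi * f * 1e12 / C0
    s2 <- sin(angle * pi / 180)^2
    ns <- c(1 + 0i, sapply(layers, function(L) L$n), 1 + 0i)
    qs <- sqrt(ns^2 - s2 + 0i)
    qs[Im(qs) < 0] <- -qs[Im(qs) < 0]
    rfres <- function(i, j) {
      if (pol == "s") {
        (qs[i] - qs[j]) / (qs[i] + qs[j])
      } else {
        # admittance-convention p-pol Fresnel (matches tilted-admittance TMM)
        (ns[i]^2 * qs[j] - ns[j]^2 * qs[i]) / (ns[i]^2 * qs[j] + ns[j]^2 * qs[i])
      }
    }
    nl <- length(layers)
    rec <- function(m) {
      if (m == nl + 1) {
        return(if (backing == "pec") -1 + 0i else rfres(nl + 1, nl + 2))
      }
      j <- m + 1
      ph <- exp(2i * k0 * qs[j] * layers[[m]]$d_um * 1e-6)
      rbel <- rec(j)
      r01 <- rfres(m, j)
      acc <- 0 + 0i
      term <- (1 - r01^2) * rbel * ph
      for (b in 0:(nb - 1)) {
        acc <- acc + term
        term <- term * (-r01 * rbel * ph)
      }
      r01 + acc
    }
    rec(1)
  })
}

# Build a layer_stack from raw complex indices at given frequencies.
stack_from_n <- function(freq_THz, n_list, d_um, backing = "perfect_conductor",
                         incidence_deg = 0, polarization = "s") {
  layers <- purrr::map2(n_list, d_um, function(nn, dd) {
    nn <- rep_len(nn, length(freq_THz))
    list(
      thickness_um = dd,
      spec = dielectric_spectrum(freq_THz, n = Re(nn), k = Im(nn))
    )
  })
  layer_stack(layers, backing = backing, incidence_deg = incidence_deg,
              polarization = polarization)
}

# random passive 1-3 layer stack (lossy enough for the truncated series)
random_stack <- function() {
  nl <- sample(1:3, 1)
  layers <- lapply(seq_len(nl), function(i) {
    list(
      d_um = runif(1, 50, 400),
      n = complex(real = runif(1, 1.2, 3), imaginary = runif(1, 0.05, 0.3))
    )
  })
  list(
    layers = layers,
    backing = sample(c("pec", "free_space"), 1),
    angle = runif(1, 0, 30),
    pol = sample(c("s", "p"), 1)
  )
}

# --- uniform leaf phantom fixture ------------------------------------------
# Homogeneous leaf occupying all but the first `metal_cols` columns; no
# veins, no spatial noise: every leaf pixel is identical.
uniform_phantom <- function(nr, nc, f_water = 0.4, f_dry = 0.2,
                            thickness_um = 200, metal_cols = 2) {
  leaf <- matrix(TRUE, nr, nc)
  leaf[, seq_len(metal_cols)] <- FALSE
  wf <- matrix(f_water, nr, nc)
  wf[!leaf] <- 0
  df <- matrix(f_dry, nr, nc)
  df[!leaf] <- 0
  th <- matrix(thickness_um, nr, nc)
  th[!leaf] <- 0
  structure(
    list(
      water_fraction = wf, dry_fraction = df, thickness_um = th,
      vein_mask = matrix(FALSE, nr, nc), leaf_mask = leaf,
      pixel_pitch_um = 200, preset = "uniform", seed = 0L
    ),
    class = "leaf_phantom"
  )
}

# small fast TDS config for tests
small_tds_cfg <- function(grid = c(20, 24), noise = FALSE, ...) {
  tds_config(grid = grid, extent_mm = grid / 5, noise = noise, ...)
}

# construct an lfi_frame directly from a db map (for counting oracles)
frame_from_db <- function(db, leaf_mask, time_min = 0, cfg = lfi_config()) {
  structure(
    list(
      amplitude = 10^(db / 20), db_map = db, frame_time_min = time_min,
      frame_seconds = 25, leaf_mask = leaf_mask,
      vein_mask = leaf_mask & FALSE, cfg = cfg, method = "constructed"
    ),
    class = "lfi_frame"
  )
}
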