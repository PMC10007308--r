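#' Staged drying dynamics of a plucked leaf
#'
#' Parameter container for the three-stage dehydration of a plucked leaf:
#' a rapid initial loss (stomata still open), a near-plateau once the leaf
#' shuts its stomata, and a resumed slow decay. The default breakpoints
#' (20 and 120 minutes) follow the staging observed in fast THz imaging of
#' drying leaves; the piecewise-exponential form itself is a generative
#' assumption of this package, not a fitted biophysical model.
#'
#' @param t_fast_end End of the rapid stage, minutes.
#' @param t_plateau_end End of the plateau stage, minutes.
#' @param rate_fast,rate_plateau,rate_slow Exponential decay rates per
#'   minute for the three stages; must satisfy
#'   `rate_fast > rate_slow > rate_plateau >= 0`.
#' @param floor Minimum retained water multiplier (tightly bound residual
#'   water), in `[0, 1)`.
#' @param vein_retention Factor (>= 1) by which vein pixels' rates are
#'   divided: veins hold water longer than the lamina.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(t_fast_end = 20, t_plateau_end = 120,
                         rate_fast = 0.04, rate_plateau = 0.001,
                         rate_slow = 0.008, floor = 0.15,
                         vein_retention = 3) {
  stopifnot_scalar(t_fast_end, "t_fast_end")
  stopifnot_scalar(t_plateau_end, "t_plateau_end")
  if (!(t_fast_end < t_plateau_end)) {
    abort("need 0 < t_fast_end < t_plateau_end")
  }
  if (!(rate_fast > rate_slow && rate_slow > rate_plateau &&
        rate_plateau >= 0)) {
    abort("need rate_fast > rate_slow > rate_plateau >= 0")
  }
  if (floor < 0 || floor >= 1) abort("`floor` must lie in [0, 1)")
  if (vein_retention < 1) abort("`vein_retention` must be >= 1")
  structure(
    list(
      t_fast_end = t_fast_end, t_plateau_end = t_plateau_end,
      rate_fast = rate_fast, rate_plateau = rate_plateau,
      rate_slow = rate_slow, floor = floor,
      vein_retention = vein_retention
    ),
    class = "drying_curve"
  )
}

#' Frozen (non-drying) curve
#'
#' A degenerate [drying_curve()] whose multiplier is identically 1: useful
#' for simulating a static sample.
#' @return A `drying_curve`.
#' @export
static_curve <- function() {
  structure(
    list(
      t_fast_end = 20, t_plateau_end = 120,
      rate_fast = 0, rate_plateau = 0, rate_slow = 0,
      floor = 0, vein_retention = 1
    ),
    class = "drying_curve"
  )
}

#' Water retention multiplier at elapsed time t
#'
#' Continuous piecewise-exponential decay: rate `rate_fast` before
#' `t_fast_end`, `rate_plateau` until `t_plateau_end`, `rate_slow` after.
#' Vein pixels use rates divided by `vein_retention`. Never drops below
#' `floor`. Vectorised over `t`.
#'
#' @param t_min Elapsed time(s) since plucking, minutes, >= 0.
#' @param curve A [drying_curve()].
#' @param on_vein Logical: evaluate the (slower) vein branch.
#' @return Multiplier(s) in `[floor, 1]`.
#' @export
#' @examples
#' drying_multiplier(c(0, 10, 60, 150), drying_curve())
drying_multiplier <- function(t_min, curve, on_vein = FALSE) {
  if (!inherits(curve, "drying_curve")) {
    abort("`curve` must be a `drying_curve`")
  }
  if (any(t_min < 0)) abort("`t_min` must be >= 0")
  ret <- if (isTRUE(on_vein)) curve$vein_retention else 1
  rf <- curve$rate_fast / ret
  rp <- curve$rate_plateau / ret
  rs <- curve$rate_slow / ret
  t1 <- curve$t_fast_end
  t2 <- curve$t_plateau_end
  lg <- -rf * pmin(t_min, t1) -
    rp * pmax(pmin(t_min, t2) - t1, 0) -
    rs * pmax(t_min - t2, 0)
  pmax(exp(lg), curve$floor)
}

#' Generate a synthetic drying-leaf phantom
#'
#' Procedurally draws a leaf on a bare-metal background: a leaf outline,
#' a vein network (midrib plus either parallel, grass-style secondaries or
#' branching, pinnate secondaries), per-pixel water and dry-matter volume
#' fractions with smooth spatial noise, and a thickness map. Vein pixels
#' carry substantially more water than the lamina, which is what produces
#' THz contrast. Fully deterministic for a given seed.
#'
#' @param preset `"parallel_venation"` (long leaf, parallel longitudinal
#'   veins) or `"pinnate_venation"` (midrib with branching secondaries).
#' @param shape Integer vector `c(rows, cols)`, at least 16 x 16.
#' @param pixel_pitch_um Physical pixel pitch in micrometres.
#' @param seed Integer RNG seed.
#' @param water_vein,water_lamina Mean water volume fractions on vein and
#'   lamina pixels.
#' @param thickness_um Mean leaf thickness, micrometres (+/- 10% smooth
#'   variation).
#' @param crease_ridge_um If > 0, adds a Gaussian ridge of this height to
#'   the thickness map, emulating a crease/curl in the blade (off by
#'   default).
#' @return An object of class `leaf_phantom`: a list with matrices
#'   `water_fraction`, `dry_fraction`, `thickness_um`, logical masks
#'   `vein_mask`, `leaf_mask`, and metadata.
#' @export
#' @examples
#' ph <- generate_phantom("parallel_venation", shape = c(32, 32), seed = 1)
#' mean(ph$water_fraction[ph$vein_mask])
generate_phantom <- function(preset = c("parallel_venation",
                                        "pinnate_venation"),
                             shape = c(80, 90), pixel_pitch_um = 200,
                             seed = 1,
                             water_vein = 0.8, water_lamina = 0.4,
                             thickness_um = 200, crease_ridge_um = 0) {
  preset <- match.arg(preset)
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 16)) {
    abort("`shape` must be c(rows, cols) with both >= 16")
  }
  nr <- shape[1]
  nc <- shape[2]
  with_seed(seed, {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cy <- (nr + 1) / 2
    cx <- (nc + 1) / 2
    # superellipse blade with a pointed tip, leaving a bare-metal margin
    ay <- 0.44 * nr
    ax <- 0.36 * nc
    leaf <- (abs((rows - cy) / ay)^2 + abs((cols - cx) / ax)^2.6) <= 1

    vein <- matrix(FALSE, nr, nc)
    mid <- round(cx)
    vein[, mid + (-1:0)] <- TRUE # midrib, 2 px wide
    if (preset == "parallel_venation") {
      spacing <- max(5, round(nc / 14))
      offs <- seq(spacing, floor(0.36 * nc), by = spacing)
      for (o in offs) {
        for (sgn in c(-1, 1)) {
          jit <- round(cumsum(rnorm(nr, 0, 0.35)))
          jit <- jit - round(mean(jit))
          cc <- pmin(pmax(mid + sgn * o + jit, 1), nc)
          vein[cbind(seq_len(nr), cc)] <- TRUE
        }
      }
    } else {
      step <- max(5, round(nr / 12))
      starts <- seq(ceiling(0.12 * nr), floor(0.88 * nr), by = step)
      for (s in starts) {
        for (sgn in c(-1, 1)) {
          slope <- runif(1, 0.5, 0.9)
          len <- floor(0.36 * nc)
          dj <- seq_len(len)
          rr <- pmin(pmax(round(s + slope * dj), 1), nr)
          cc <- pmin(pmax(mid + sgn * dj, 1), nc)
          vein[cbind(rr, cc)] <- TRUE
        }
      }
    }
    vein <- vein & leaf

    wf <- water_lamina + 0.08 * smooth_noise(nr, nc, sigma_px = 3)
    wf <- pmin(pmax(wf, 0.15), 0.6)
    wv <- water_vein + 0.10 * smooth_noise(nr, nc, sigma_px = 2)
    wv <- pmin(pmax(wv, 0.6), 0.95)
    wf[vein] <- wv[vein]
    wf[!leaf] <- 0
    df <- pmin(1 - wf, 0.2)
    df[!leaf] <- 0
    th <- thickness_um * (1 + 0.1 * smooth_noise(nr, nc, sigma_px = 4))
    if (crease_ridge_um > 0) {
      ridge_r <- runif(1, 0.3, 0.7) * nr
      th <- th + crease_ridge_um * exp(-((rows - ridge_r)^2) / (2 * (0.04 * nr)^2))
    }
    th[!leaf] <- 0

    structure(
      list(
        water_fraction = wf, dry_fraction = df, thickness_um = th,
        vein_mask = vein, leaf_mask = leaf,
        pixel_pitch_um = pixel_pitch_um, preset = preset, seed = seed
      ),
      class = "leaf_phantom"
    )
  })
}

#' @export
print.leaf_phantom <- function(x, ...) {
  d <- dim(x$water_fraction)
  cat(sprintf(
    "<leaf_phantom> %dx%d px (%s), pitch %.0f um, seed %d\n",
    d[1], d[2], x$preset, x$pixel_pitch_um, x$seed
  ))
  cat(sprintf(
    "  leaf %.0f%% of frame, veins %.1f%% of leaf; water vein %.2f / lamina %.2f\n",
    100 * mean(x$leaf_mask), 100 * sum(x$vein_mask) / sum(x$leaf_mask),
    mean(x$water_fraction[x$vein_mask]),
    mean(x$water_fraction[x$leaf_mask & !x$vein_mask])
  ))
  invisible(x)
}

#' Phantom state after t minutes of drying
#'
#' Multiplies the per-pixel water fraction by the vein-aware
#' [drying_multiplier()]; dry-matter fraction, thickness and masks are
#' unchanged, and the input phantom is not mutated.
#'
#' @param phantom A [generate_phantom()] object.
#' @param curve A [drying_curve()].
#' @param t_min Elapsed minutes since plucking (>= 0).
#' @return A new `leaf_phantom`.
#' @export
phantom_at <- function(phantom, curve, t_min) {
  if (!inherits(phantom, "leaf_phantom")) {
    abort("`phantom` must be a `leaf_phantom`")
  }
  stopifnot_scalar(t_min, "t_min", positive = FALSE)
  if (t_min < 0) abort("`t_min` must be >= 0")
  m_lam <- drying_multiplier(t_min, curve, on_vein = FALSE)
  m_vei <- drying_multiplier(t_min, curve, on_vein = TRUE)
  out <- phantom
  mult <- matrix(m_lam, nrow(phantom$water_fraction),
                 ncol(phantom$water_fraction))
  mult[phantom$vein_mask] <- m_vei
  out$water_fraction <- phantom$water_fraction * mult
  out
}

#' Total water content of a phantom
#'
#' Sum of water volume fraction times thickness over all pixels — an
#' un-normalised proxy for total water volume, used to track drying.
#'
#' @param phantom A `leaf_phantom`.
#' @return A scalar (um-weighted fraction units).
#' @export
total_water <- function(phantom) {
  sum(phantom$water_fraction * phantom$thickness_um)
}

#' @method as_tibble leaf_phantom
#' @export
as_tibble.leaf_phantom <- function(x, ...) {
  d <- dim(x$water_fraction)
  tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    water_fraction = as.vector(x$water_fraction),
    dry_fraction = as.vector(x$dry_fraction),
    thickness_um = as.vector(x$thickness_um),
    vein = as.vector(x$vein_mask),
    leaf = as.vector(x$leaf_mask)
  )
}

#' @method autoplot leaf_phantom
#' @export
autoplot.leaf_phantom <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$water_fraction)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(name = "water\nfraction") +
    coord_equal() +
    labs(x = NULL, y = NULL, title = "Leaf phantom water map") +
    theme_minimal()
}
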