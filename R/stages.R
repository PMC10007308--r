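#' Fit dehydration stages as a continuous piecewise-linear model
#'
#' Least-squares fit of a continuous piecewise-linear function with
#' `n_breaks` breakpoints to a hydration time series, by exhaustive search
#' over breakpoint locations on the observed time grid (a coarse pass
#' followed by full-resolution refinement around the optimum; set
#' `exhaustive = TRUE` to force the complete grid). Ties are broken toward
#' earlier breakpoints. With `n_breaks = 0` this is an ordinary
#' least-squares line. The staging is this package's construction for
#' locating the dehydration-stage transitions (nominally near 20 and 120
#' minutes); it is a descriptive fit, not a mechanistic model.
#'
#' @param series A [hydration_series()] (or any data frame with `time_min`
#'   and `blue_fraction`).
#' @param n_breaks Number of breakpoints (0, 1 or 2).
#' @param exhaustive Search every admissible breakpoint pair instead of
#'   coarse-plus-refine.
#' @return An object of class `stage_fit`.
#' @export
#' @examples
#' s <- new_hydration_series(0:49, pmax(1 - 0.02 * (0:49), 0.4))
#' fit_breakpoints(s, n_breaks = 1)
fit_breakpoints <- function(series, n_breaks = 2, exhaustive = FALSE) {
  if (!all(c("time_min", "blue_fraction") %in% names(series))) {
    abort("`series` needs columns `time_min` and `blue_fraction`")
  }
  if (!n_breaks %in% 0:2) abort("`n_breaks` must be 0, 1 or 2")
  t <- series$time_min
  y <- series$blue_fraction
  n <- length(t)
  if (is.unsorted(t, strictly = TRUE)) abort("times must be increasing")
  if (n < 5 * (n_breaks + 1)) {
    abort(sprintf("need >= %d points for %d breaks", 5 * (n_breaks + 1),
                  n_breaks))
  }

  hinge <- function(b) pmax(t - b, 0)
  fit_at <- function(bks) {
    X <- cbind(1, t)
    for (b in bks) X <- cbind(X, hinge(b))
    f <- .lm.fit(X, y)
    list(sse = sum(f$residuals^2), coef = f$coefficients, X = X)
  }

  line_fit <- fit_at(numeric(0))
  sse_line <- line_fit$sse
  ss_total <- sum((y - mean(y))^2)

  min_seg <- 3
  cand <- seq(min_seg, n - min_seg) # indices usable as breakpoints

  best <- NULL
  if (n_breaks == 0) {
    best <- list(idx = integer(0), sse = sse_line, coef = line_fit$coef)
  } else if (n_breaks == 1) {
    best <- list(idx = NA, sse = Inf, coef = NULL)
    for (i in cand) {
      f <- fit_at(t[i])
      if (f$sse < best$sse - 1e-15) best <- list(idx = i, sse = f$sse, coef = f$coef)
    }
    best$idx <- as.integer(best$idx)
  } else {
    search_pairs <- function(i1set, i2set) {
      bb <- list(idx = c(NA, NA), sse = Inf, coef = NULL)
      for (i1 in i1set) {
        h1 <- hinge(t[i1])
        for (i2 in i2set) {
          if (i2 < i1 + min_seg) next
          f <- .lm.fit(cbind(1, t, h1, hinge(t[i2])), y)
          sse <- sum(f$residuals^2)
          if (sse < bb$sse - 1e-15) {
            bb <- list(idx = c(i1, i2), sse = sse, coef = f$coefficients)
          }
        }
      }
      bb
    }
    if (exhaustive || length(cand) <= 120) {
      best <- search_pairs(cand, cand)
    } else {
      stride <- max(1L, floor(length(cand) / 90))
      coarse <- cand[seq(1, length(cand), by = stride)]
      b0 <- search_pairs(coarse, coarse)
      win <- 2 * stride
      i1set <- cand[cand >= b0$idx[1] - win & cand <= b0$idx[1] + win]
      i2set <- cand[cand >= b0$idx[2] - win & cand <= b0$idx[2] + win]
      best <- search_pairs(i1set, i2set)
      if (best$sse > b0$sse) best <- b0
    }
    best$idx <- as.integer(best$idx)
  }

  bks <- t[best$idx]
  ff <- fit_at(bks)
  improvement <- sse_line - ff$sse
  structure(
    list(
      series = new_hydration_series(t, y),
      n_breaks = n_breaks,
      breakpoints = bks,
      break_index = best$idx,
      coefficients = ff$coef,
      fitted = as.vector(ff$X %*% ff$coef),
      sse = ff$sse,
      sse_line = sse_line,
      ss_total = ss_total,
      improvement_frac = if (ss_total > 0) improvement / ss_total else 0,
      significant = ss_total > 0 && improvement >= 0.01 * ss_total
    ),
    class = "stage_fit"
  )
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("<stage_fit> %d breakpoint(s)", x$n_breaks))
  if (x$n_breaks > 0) {
    cat(sprintf(
      " at %s min (%s)",
      paste(sprintf("%.2f", x$breakpoints), collapse = ", "),
      if (x$significant) "significant" else "non-significant"
    ))
  }
  cat(sprintf("; SSE %.4g (line %.4g)\n", x$sse, x$sse_line))
  invisible(x)
}

#' @method tidy stage_fit
#' @export
tidy.stage_fit <- function(x, ...) {
  t <- x$series$time_min
  edges <- c(t[1], x$breakpoints, t[length(t)])
  base_slope <- x$coefficients[2]
  hinge_coefs <- if (x$n_breaks > 0) x$coefficients[-(1:2)] else numeric(0)
  slopes <- base_slope + cumsum(c(0, hinge_coefs))
  tibble(
    segment = seq_len(x$n_breaks + 1),
    t_start = edges[-length(edges)],
    t_end = edges[-1],
    slope = as.double(slopes)
  )
}

#' @method glance stage_fit
#' @export
glance.stage_fit <- function(x, ...) {
  tibble(
    n_breaks = x$n_breaks,
    sse = x$sse,
    sse_line = x$sse_line,
    improvement_frac = x$improvement_frac,
    significant = x$significant,
    r_squared = if (x$ss_total > 0) 1 - x$sse / x$ss_total else NA_real_,
    nobs = nrow(x$series)
  )
}

#' @export
predict.stage_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$time_min else newdata
  X <- cbind(1, t)
  for (b in object$breakpoints) X <- cbind(X, pmax(t - b, 0))
  as.vector(X %*% object$coefficients)
}

#' @method autoplot stage_fit
#' @export
autoplot.stage_fit <- function(object, ...) {
  df <- object$series
  df$fitted <- object$fitted
  p <- ggplot(df, aes(x = .data$time_min)) +
    geom_point(aes(y = .data$blue_fraction), size = 0.7, colour = "grey40") +
    geom_line(aes(y = .data$fitted), colour = "firebrick", linewidth = 0.8) +
    labs(x = "time since plucking (min)", y = "blue-pixel fraction") +
    theme_minimal()
  if (object$n_breaks > 0) {
    p <- p + geom_vline(
      xintercept = object$breakpoints,
      linetype = "dashed", colour = "steelblue"
    )
  }
  p
}

#' Piecewise-linear synthetic hydration series
#'
#' Generates a noise-free three-stage piecewise-linear blue-fraction series
#' with the given breakpoints and stage slopes — the reference input for
#' validating breakpoint recovery.
#'
#' @param times_min Sample times (e.g. one frame per 25 s).
#' @param breaks_min Two breakpoint times.
#' @param start Initial blue fraction.
#' @param slopes Stage slopes per minute (length 3; negative = drying).
#' @param noise_sd Optional additive Gaussian noise sd.
#' @param seed Seed for the noise draw.
#' @return A [hydration_series()].
#' @export
synthetic_staged_series <- function(times_min = seq(0, 300, by = 25 / 60),
                                    breaks_min = c(20, 120),
                                    start = 0.5,
                                    slopes = c(-0.012, -0.0005, -0.001),
                                    noise_sd = 0, seed = 1) {
  if (length(breaks_min) != 2 || length(slopes) != 3) {
    abort("need 2 breakpoints and 3 slopes")
  }
  t <- times_min
  y <- start + slopes[1] * pmin(t, breaks_min[1]) +
    slopes[2] * pmax(pmin(t, breaks_min[2]) - breaks_min[1], 0) +
    slopes[3] * pmax(t - breaks_min[2], 0)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  new_hydration_series(t, pmax(y, 0))
}
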