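#' TIMESAT-style upper-envelope weight update
#'
#' Points at or above the fitted curve keep their weight; points below are
#' down-weighted multiplicatively in proportion to the normalized negative
#' residual magnitude, `w * max(floor_frac, 1 - |r| / (3 * sd(r)))`, so a
#' point three residual standard deviations below the curve reaches the
#' floor `floor_frac * w`. Weights are never increased, zero weights stay
#' zero, and missing values keep their weight unchanged. This drives the
#' fit toward the upper envelope of the series, where negatively biased
#' contamination (clouds, snow) has not depressed the signal.
#'
#' @param values observed series.
#' @param fitted fitted curve on the same grid.
#' @param weights current (usually original) non-negative weights.
#' @param floor_frac lower bound on the retained weight fraction.
#' @return updated weight vector.
#' @export
wtsm_update <- function(values, fitted, weights, floor_frac = 0.05) {
  stopifnot(length(values) == length(fitted),
            length(values) == length(weights))
  r <- values - fitted
  ok <- weights > 0 & !is.na(r)
  sd_r <- stats::sd(r[ok])
  if (!is.finite(sd_r) || sd_r == 0) return(weights)
  fac <- rep(1, length(values))
  below <- ok & r < 0
  fac[below] <- pmax(floor_frac, 1 - (-r[below]) / (3 * sd_r))
  weights * fac
}

#' Weighted harmonic (HANTS-style) rough fit
#'
#' Weighted least-squares fit of
#' `y ~ a0 + sum_k a_k cos(2 pi k t / period) + b_k sin(2 pi k t / period)`,
#' iterated with the upper-envelope weight rule of [wtsm_update()]: after
#' each of the `n_outer_iter` passes (except the last) the weights are
#' recomputed from the original weights and the current fit. Missing values
#' get weight zero. The rough fit captures the periodic seasonal structure
#' and is used to divide growing seasons and initialize the fine fit.
#'
#' @param doy time coordinate (days).
#' @param values series values (missing allowed).
#' @param weights initial non-negative weights (default all 1).
#' @param n_harmonics number of harmonics (default 3).
#' @param n_outer_iter total number of fitting passes (default 3; 1 gives
#'   the plain single-pass weighted fit).
#' @param period fundamental period in days (default 365).
#' @param label optional pixel label used in error messages.
#' @return object of class `"hants_fit"` with coefficients, the fitted
#'   values on the input grid, and the final weights.
#' @export
whants_fit <- function(doy, values, weights = NULL, n_harmonics = 3,
                       n_outer_iter = 3, period = 365, label = NULL) {
  n <- length(values)
  weights <- weights %||% rep(1, n)
  stopifnot(length(doy) == n, length(weights) == n, all(weights >= 0))
  w0 <- weights
  w0[is.na(values)] <- 0
  y <- ifelse(is.na(values), 0, values)

  npar <- 2L * n_harmonics + 1L
  if (sum(w0 > 0) < npar) {
    stop(sprintf("too few usable points (%d) for %d harmonic parameters%s",
                 sum(w0 > 0), npar,
                 if (is.null(label)) "" else paste0(" at pixel ", label)))
  }
  ang <- outer(doy, seq_len(n_harmonics)) * (2 * pi / period)
  X <- cbind(1, cos(ang), sin(ang))

  w <- w0
  coef <- NULL
  fitted <- NULL
  for (it in seq_len(max(1L, n_outer_iter))) {
    fit <- stats::lm.wfit(X, y, w)
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    fitted <- drop(X %*% coef)
    if (it < n_outer_iter) w <- wtsm_update(values, fitted, w0)
  }
  structure(list(coef = coef, n_harmonics = n_harmonics, period = period,
                 doy = doy, fitted = fitted, weights = w,
                 a0 = coef[1]),
            class = "hants_fit")
}

#' Evaluate a harmonic rough fit on new time points
#' @param object a `"hants_fit"`.
#' @param doy days at which to evaluate (any real values; the basis is
#'   periodic).
#' @param ... unused.
#' @return numeric vector of fitted values.
#' @export
predict.hants_fit <- function(object, doy, ...) {
  ang <- outer(doy, seq_len(object$n_harmonics)) * (2 * pi / object$period)
  drop(cbind(1, cos(ang), sin(ang)) %*% object$coef)
}

#' Divide the record into growing-season windows
#'
#' Single-season convention: the season peak is the day of the rough-fit
#' maximum inside the calendar year (ties to the earliest day); the window
#' ends are the days of the rough-fit minima on either side of the peak
#' (the troughs between adjacent annual peaks, located on the periodic
#' extension of the harmonic fit), clipped to the year plus/minus 90 days.
#' A rough fit whose annual amplitude falls below `amplitude_floor` is
#' reported as having no seasonality and is skipped downstream.
#'
#' @param rough a `"hants_fit"`.
#' @param year calendar year label carried through (optional).
#' @param amplitude_floor minimum rough-fit amplitude (VI units).
#' @return list with `year`, `t_start`, `peak_doy`, `t_end`, `amplitude`
#'   and `no_seasonality`; when `no_seasonality` is `TRUE` the window
#'   fields are `NA`.
#' @export
divide_seasons <- function(rough, year = NA_integer_,
                           amplitude_floor = 0.02) {
  t_year <- seq_len(365)
  v_year <- predict(rough, t_year)
  amplitude <- max(v_year) - min(v_year)
  if (!is.finite(amplitude) || amplitude < amplitude_floor) {
    return(list(year = year, t_start = NA_real_, peak_doy = NA_real_,
                t_end = NA_real_, amplitude = amplitude,
                no_seasonality = TRUE))
  }
  peak <- t_year[which.max(v_year)]

  t_left <- seq(max(peak - 183, -89), peak - 1)
  t_right <- seq(peak + 1, min(peak + 183, 455))
  v_left <- predict(rough, t_left)
  v_right <- predict(rough, t_right)
  list(year = year,
       t_start = t_left[which.min(v_left)],
       peak_doy = peak,
       t_end = t_right[which.min(v_right)],
       amplitude = amplitude,
       no_seasonality = FALSE)
}

# The Beck double logistic and its analytic parameter Jacobian.
beck_model <- function(p, t) {
  s1 <- logistic(p[["rsp"]] * (t - p[["sos"]]))
  s2 <- logistic(-p[["rau"]] * (t - p[["eos"]]))
  p[["mn"]] + (p[["mx"]] - p[["mn"]]) * (s1 + s2 - 1)
}

beck_jac <- function(p, t) {
  A <- p[["mx"]] - p[["mn"]]
  s1 <- logistic(p[["rsp"]] * (t - p[["sos"]]))
  s2 <- logistic(-p[["rau"]] * (t - p[["eos"]]))
  d1 <- s1 * (1 - s1)
  d2 <- s2 * (1 - s2)
  cbind(mn = 2 - s1 - s2,
        mx = s1 + s2 - 1,
        sos = -A * p[["rsp"]] * d1,
        rsp = A * (t - p[["sos"]]) * d1,
        eos = A * p[["rau"]] * d2,
        rau = -A * (t - p[["eos"]]) * d2)
}

#' Initial Beck parameters from a season window
#'
#' `mn`/`mx` are the 5th/95th percentiles of the values; `sos`/`eos` are
#' the days where the rough curve first/last crosses the half-amplitude
#' level; the rates start at `16 / (eos - sos)` (so the logistic transition
#' spans about a quarter of the season), clipped to `(0.01, 1]`. When no
#' crossings exist (e.g. a monotone ramp) the window quartile days are used
#' with a warning.
#'
#' @param doy observation days within the season window.
#' @param values observed VI values.
#' @param rough optional `"hants_fit"` whose daily curve locates the
#'   half-amplitude crossings; defaults to linear interpolation of the
#'   observations.
#' @return named list with `mn`, `mx`, `sos`, `rsp`, `eos`, `rau`.
#' @export
beck_init <- function(doy, values, rough = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 10) stop("beck_init needs at least 10 observations")
  qs <- stats::quantile(values[ok], c(0.05, 0.95), names = FALSE)
  mn <- qs[1]; mx <- qs[2]
  half <- (mn + mx) / 2

  grid <- seq(floor(min(doy)), ceiling(max(doy)))
  curve <- if (is.null(rough)) {
    stats::approx(doy[ok], values[ok], xout = grid, rule = 2)$y
  } else {
    predict(rough, grid)
  }
  above <- curve >= half
  up <- which(!above[-length(above)] & above[-1])
  down <- which(above[-length(above)] & !above[-1])
  if (length(up) && length(down) && grid[max(down)] > grid[min(up)]) {
    sos <- grid[min(up)]
    eos <- grid[max(down)] + 1
  } else {
    warning("no half-amplitude crossings; falling back to window quartiles")
    span <- range(grid)
    sos <- span[1] + 0.25 * diff(span)
    eos <- span[1] + 0.75 * diff(span)
  }
  r0 <- min(max(16 / max(eos - sos, 1), 0.01), 1)
  list(mn = mn, mx = mx, sos = sos, rsp = r0, eos = eos, rau = r0)
}

#' Fine fit of the Beck double logistic
#'
#' Bounded weighted nonlinear least squares (Levenberg-Marquardt with the
#' analytic Jacobian) of
#' `VI(t) = mn + (mx - mn) * (plogis(rsp*(t - sos)) + plogis(-rau*(t - eos)) - 1)`.
#' Bounds: `mn`/`mx` within the data range plus/minus 0.2 amplitude,
#' `sos`/`eos` within the season window plus/minus 30 days, rates in
#' `(0.001, 2]`. After convergence the weights are updated once per
#' `envelope_iters` with [wtsm_update()] (applied to the original weights)
#' and the fit repeated, pulling the curve to the upper envelope.
#' Non-convergence returns the best parameters found with
#' `converged = FALSE`; callers may skip such pixel-seasons.
#'
#' @param doy observation days.
#' @param values observed VI values.
#' @param weights non-negative weights (default all 1).
#' @param init initial parameters, e.g. from [beck_init()].
#' @param window season window `c(t_start, t_end)` bounding `sos`/`eos`
#'   (default the data range).
#' @param envelope_iters number of envelope reweight-and-refit cycles
#'   after the first convergence (default 1).
#' @param max_iter maximum optimizer iterations per cycle.
#' @param ptol parameter tolerance of the optimizer.
#' @return object of class `"beck_fit"`: `par` (named list), `converged`,
#'   `rmse` (weighted), `niter`, `weights` (final), `window`.
#' @export
beck_fit <- function(doy, values, weights = NULL, init, window = NULL,
                     envelope_iters = 1, max_iter = 200, ptol = 1e-8) {
  n <- length(values)
  weights <- weights %||% rep(1, n)
  use <- weights > 0 & !is.na(values)
  if (sum(use) < 7) {
    stop("fewer than 7 usable points for the 6-parameter Beck fit")
  }
  t <- doy[use]; y <- values[use]; w0 <- weights[use]
  window <- window %||% range(t)

  rng <- range(y)
  amp <- max(diff(rng), 1e-6)
  lower <- c(mn = rng[1] - 0.2 * amp, mx = rng[1] - 0.2 * amp,
             sos = window[1] - 30, rsp = 0.001,
             eos = window[1] - 30, rau = 0.001)
  upper <- c(mn = rng[2] + 0.2 * amp, mx = rng[2] + 0.2 * amp,
             sos = window[2] + 30, rsp = 2,
             eos = window[2] + 30, rau = 2)
  p0 <- pmin(pmax(unlist(init)[names(lower)], lower), upper)

  do_fit <- function(p_start, w) {
    sw <- sqrt(w)
    minpack.lm::nls.lm(
      par = p_start,
      fn = function(p) sw * (beck_model(p, t) - y),
      jac = function(p) sw * beck_jac(p, t),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = ptol))
  }

  fit <- do_fit(p0, w0)
  w <- w0
  for (i in seq_len(envelope_iters)) {
    w <- wtsm_update(y, beck_model(fit$par, t), w0)
    fit <- do_fit(unlist(fit$par), w)
  }
  par <- as.list(unlist(fit$par))
  resid <- beck_model(unlist(par), t) - y
  structure(list(par = par,
                 converged = fit$info %in% 1:3,
                 rmse = sqrt(sum(w * resid^2) / sum(w)),
                 niter = fit$niter,
                 weights = w, window = window),
            class = "beck_fit")
}

#' Evaluate a Beck curve and its exact first derivative
#'
#' @param par named list/vector with `mn`, `mx`, `sos`, `rsp`, `eos`,
#'   `rau` (a `"beck_fit"` is also accepted).
#' @param doy days at which to evaluate.
#' @return list with `doy`, `value` and the analytic `deriv` (VI units per
#'   day). For well-separated seasons the rise-term derivative at
#'   `t = sos` equals `(mx - mn) * rsp / 4`.
#' @export
beck_eval <- function(par, doy) {
  if (inherits(par, "beck_fit")) par <- par$par
  p <- unlist(par)
  A <- p[["mx"]] - p[["mn"]]
  s1 <- logistic(p[["rsp"]] * (doy - p[["sos"]]))
  s2 <- logistic(-p[["rau"]] * (doy - p[["eos"]]))
  list(doy = doy,
       value = p[["mn"]] + A * (s1 + s2 - 1),
       deriv = A * (p[["rsp"]] * s1 * (1 - s1) -
                      p[["rau"]] * s2 * (1 - s2)))
}
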