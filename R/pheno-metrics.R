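#' Construct the Gu-method geometry from a fitted daily curve
#'
#' The baseline and maxline are the minimum and maximum of the fitted
#' curve inside the season window. The recovery line is the tangent at the
#' day of maximum derivative before the curve peak, the senescence line the
#' tangent at the day of minimum derivative after the peak (ties broken to
#' the earliest day). The plateau line is the ordinary least-squares line
#' through the curve between the stabilization date (recovery line crossing
#' the maxline) and the initial downturn date (senescence line crossing the
#' maxline); it captures mid-season greendown. A window without a genuine
#' rise and fall (non-positive maximum derivative or non-negative minimum
#' derivative) flags the whole geometry invalid instead of raising.
#'
#' @param doy integer-day grid across the season window.
#' @param value fitted curve values on `doy`.
#' @param deriv first derivative of the curve on `doy` (e.g. from
#'   [beck_eval()]).
#' @return object of class `"gu_lines"`: `baseline`, `maxline`,
#'   `recovery`/`senescence` (each `slope`, `intercept`, `t`), `plateau`
#'   (`slope`, `intercept`, or `NULL` when undefined), `window`, `valid`.
#' @export
build_gu_lines <- function(doy, value, deriv) {
  stopifnot(length(doy) == length(value), length(doy) == length(deriv))
  window <- range(doy)
  baseline <- min(value)
  maxline <- max(value)
  ipk <- which.max(value)

  invalid <- function() {
    structure(list(baseline = baseline, maxline = maxline,
                   recovery = NULL, senescence = NULL, plateau = NULL,
                   window = window, valid = FALSE), class = "gu_lines")
  }
  pre <- seq_len(ipk)
  post <- seq(ipk, length(doy))
  if (length(pre) < 2 || length(post) < 2) return(invalid())

  i_r <- pre[which.max(deriv[pre])]
  i_s <- post[which.min(deriv[post])]
  m_r <- deriv[i_r]
  m_s <- deriv[i_s]
  if (m_r <= 0 || m_s >= 0) return(invalid())

  recovery <- list(slope = m_r, intercept = value[i_r] - m_r * doy[i_r],
                   t = doy[i_r])
  senescence <- list(slope = m_s, intercept = value[i_s] - m_s * doy[i_s],
                     t = doy[i_s])

  sd_ <- (maxline - recovery$intercept) / recovery$slope
  dd0 <- (maxline - senescence$intercept) / senescence$slope
  plateau <- NULL
  sel <- doy >= sd_ & doy <= dd0
  if (sum(sel) >= 2) {
    cf <- stats::lm.fit(cbind(1, doy[sel]), value[sel])$coefficients
    plateau <- list(slope = cf[[2]], intercept = cf[[1]])
  }
  structure(list(baseline = baseline, maxline = maxline,
                 recovery = recovery, senescence = senescence,
                 plateau = plateau, window = window, valid = TRUE),
            class = "gu_lines")
}

#' Solve the Gu transition dates from the line geometry
#'
#' Analytic line intersections: UD = recovery x baseline, SD = recovery x
#' maxline, DD0 = senescence x maxline, RD = senescence x baseline, and the
#' plateau-adjusted DD = senescence x plateau line. Near-parallel lines
#' (slope difference below `1e-9`) invalidate only the affected metric, as
#' does a date falling outside the window by more than `slack` days.
#'
#' @param lines a `"gu_lines"` object.
#' @param slack days beyond the season window a metric may fall before
#'   being flagged invalid (default 60).
#' @return list of class `"pheno_metrics"`: numeric `metrics` (`UD`, `SD`,
#'   `DD0`, `DD`, `RD`, real-valued day of year) and logical `valid` per
#'   metric.
#' @export
extract_gu_metrics <- function(lines, slack = 60) {
  nm <- c("UD", "SD", "DD0", "DD", "RD")
  if (!isTRUE(lines$valid)) {
    return(structure(list(metrics = stats::setNames(rep(NA_real_, 5), nm),
                          valid = stats::setNames(rep(FALSE, 5), nm)),
                     class = "pheno_metrics"))
  }
  rec <- lines$recovery; sen <- lines$senescence
  cross_level <- function(line, level) (level - line$intercept) / line$slope
  m <- c(UD = cross_level(rec, lines$baseline),
         SD = cross_level(rec, lines$maxline),
         DD0 = cross_level(sen, lines$maxline),
         DD = NA_real_,
         RD = cross_level(sen, lines$baseline))
  valid <- !is.na(m)
  if (!is.null(lines$plateau)) {
    dm <- sen$slope - lines$plateau$slope
    if (abs(dm) >= 1e-9) {
      m[["DD"]] <- (lines$plateau$intercept - sen$intercept) / dm
      valid[["DD"]] <- TRUE
    }
  }
  lo <- lines$window[1] - slack
  hi <- lines$window[2] + slack
  out_of_window <- !is.na(m) & (m < lo | m > hi)
  valid[out_of_window] <- FALSE
  structure(list(metrics = m, valid = valid), class = "pheno_metrics")
}

#' Closed-form Gu metrics for a pure Beck curve
#'
#' For well-separated seasons the tangent of the Beck rise at `t = sos` has
#' slope `(mx - mn) * rsp / 4` through the half-amplitude point, giving
#' `UD = sos - 2/rsp`, `SD = sos + 2/rsp`, and by symmetry
#' `DD0 = eos - 2/rau`, `RD = eos + 2/rau`; the flat-plateau curve has
#' `DD = DD0`. Used as the independent oracle in tests and to score
#' synthetic-scene recovery; it is only valid when
#' `eos - sos > 2/rsp + 2/rau + 10`.
#'
#' @param par named list/vector with `mn`, `mx`, `sos`, `rsp`, `eos`,
#'   `rau`.
#' @return a `"pheno_metrics"` object (all metrics valid).
#' @export
gu_closed_form <- function(par) {
  p <- unlist(if (inherits(par, "beck_fit")) par$par else par)
  if (p[["eos"]] - p[["sos"]] <=
        2 / p[["rsp"]] + 2 / p[["rau"]] + 10) {
    stop("seasons not separated enough for the closed-form Gu oracle")
  }
  m <- c(UD = p[["sos"]] - 2 / p[["rsp"]],
         SD = p[["sos"]] + 2 / p[["rsp"]],
         DD0 = p[["eos"]] - 2 / p[["rau"]],
         DD = p[["eos"]] - 2 / p[["rau"]],
         RD = p[["eos"]] + 2 / p[["rau"]])
  structure(list(metrics = m,
                 valid = stats::setNames(rep(TRUE, 5), names(m))),
            class = "pheno_metrics")
}

#' Fit one pixel-season and extract its Gu metrics
#'
#' Convenience wrapper chaining [whants_fit()], [divide_seasons()],
#' [beck_init()], [beck_fit()], [beck_eval()], [build_gu_lines()] and
#' [extract_gu_metrics()] for a single year of composites. Failure at any
#' stage (no seasonality, too few points, non-convergence when
#' `require_convergence`) yields an all-missing row rather than an error.
#'
#' @param doy composite time coordinates (window midpoints).
#' @param values composite VI values.
#' @param weights composite weights.
#' @param control list of tuning parameters: `n_harmonics`, `n_outer_iter`,
#'   `amplitude_floor`, `envelope_iters`, `max_iter`,
#'   `require_convergence`.
#' @return one-row data frame with `UD`, `SD`, `DD0`, `DD`, `RD`,
#'   `valid` (all five metrics valid), `converged`, `rmse`, `status`.
#' @export
fit_pixel_season <- function(doy, values, weights = NULL, control = list()) {
  ctl <- utils::modifyList(
    list(n_harmonics = 3, n_outer_iter = 3, amplitude_floor = 0.02,
         envelope_iters = 1, max_iter = 200, require_convergence = FALSE),
    control)
  na_row <- function(status) {
    data.frame(UD = NA_real_, SD = NA_real_, DD0 = NA_real_, DD = NA_real_,
               RD = NA_real_, valid = FALSE, converged = FALSE,
               rmse = NA_real_, status = status)
  }
  ok <- !is.na(values) & (weights %||% rep(1, length(values))) > 0
  if (sum(ok) < max(7, 2 * ctl$n_harmonics + 1)) return(na_row("too_few_points"))

  rough <- try(whants_fit(doy, values, weights, ctl$n_harmonics,
                          ctl$n_outer_iter), silent = TRUE)
  if (inherits(rough, "try-error")) return(na_row("rough_fit_failed"))
  season <- divide_seasons(rough, amplitude_floor = ctl$amplitude_floor)
  if (isTRUE(season$no_seasonality)) return(na_row("no_seasonality"))

  in_win <- doy >= season$t_start & doy <= season$t_end
  fit <- try({
    init <- beck_init(doy[in_win], values[in_win], rough)
    beck_fit(doy[in_win], values[in_win],
             (weights %||% rep(1, length(values)))[in_win],
             init = init, window = c(season$t_start, season$t_end),
             envelope_iters = ctl$envelope_iters, max_iter = ctl$max_iter)
  }, silent = TRUE)
  if (inherits(fit, "try-error")) return(na_row("fine_fit_failed"))
  if (ctl$require_convergence && !fit$converged) {
    return(na_row("not_converged"))
  }

  grid <- seq(ceiling(season$t_start), floor(season$t_end))
  ev <- beck_eval(fit, grid)
  pm <- extract_gu_metrics(build_gu_lines(ev$doy, ev$value, ev$deriv))
  mm <- ifelse(pm$valid, pm$metrics, NA_real_)
  data.frame(UD = mm[["UD"]], SD = mm[["SD"]], DD0 = mm[["DD0"]],
             DD = mm[["DD"]], RD = mm[["RD"]],
             valid = all(pm$valid), converged = fit$converged,
             rmse = fit$rmse, status = "ok")
}

#' Extract Gu metrics for every pixel and year of a VI cube
#'
#' Applies [fit_pixel_season()] to each pixel-year of a composited
#' [compute_vi_cube()] result. Non-vegetated pixels (all-missing series,
#' e.g. where the PPI canopy maximum is undefined) and failed fits
#' propagate as missing rows.
#'
#' @param vi a `"vi_cube"`.
#' @param control see [fit_pixel_season()].
#' @return tidy data frame: `row`, `col`, `year`, `index`, `UD`, `SD`,
#'   `DD0`, `DD`, `RD`, `valid`, `converged`, `rmse`, `status`.
#' @export
extract_phenology <- function(vi, control = list()) {
  ny <- dim(vi$values)[2]; nx <- dim(vi$values)[3]
  years <- unique(vi$year)
  mid <- vi$doy_start + 3.5
  out <- vector("list", ny * nx * length(years))
  n <- 0L
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      for (k in seq_along(years)) {
        rows <- which(vi$year == years[k])
        res <- fit_pixel_season(mid[rows], vi$values[rows, i, j],
                                vi$weights[rows, i, j], control)
        n <- n + 1L
        out[[n]] <- cbind(data.frame(row = i, col = j, year = years[k],
                                     index = vi$index), res)
      }
    }
  }
  do.call(rbind, out)
}
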