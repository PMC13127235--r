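#' Enhanced vegetation index
#'
#' `EVI = 2.5 * (nir - red) / (nir + 6*red - 7.5*blue + 1)`, the standard
#' three-band formulation with gain 2.5, canopy background adjustment 1 and
#' aerosol resistance coefficients 6 and 7.5. Missing inputs propagate to
#' missing output; denominators at or below `1e-9` (including negative ones,
#' which arise from contaminated reflectance) yield missing output rather
#' than an exception.
#'
#' @param nir,red,blue surface reflectance in `[0, 1]` (vectors recycle).
#' @return numeric EVI vector.
#' @export
compute_evi <- function(nir, red, blue) {
  denom <- nir + 6 * red - 7.5 * blue + 1
  out <- 2.5 * (nir - red) / denom
  out[!is.na(denom) & denom <= 1e-9] <- NA_real_
  out
}

#' Kernel NDVI
#'
#' `kNDVI = tanh(((nir - red) / (2*sigma))^2)`. With the recommended
#' length scale `sigma = 0.5 * (nir + red)` (the default) this reduces
#' algebraically to `tanh(NDVI^2)`, bounded in `[0, 1)`. A zero `nir + red`
#' under the default sigma yields missing.
#'
#' @param nir,red surface reflectance.
#' @param sigma optional kernel length scale; default `0.5 * (nir + red)`.
#' @return numeric kNDVI vector in `[0, 1)`.
#' @export
compute_kndvi <- function(nir, red, sigma = NULL) {
  if (is.null(sigma)) sigma <- 0.5 * (nir + red)
  out <- tanh(((nir - red) / (2 * sigma))^2)
  out[!is.na(sigma) & sigma == 0] <- NA_real_
  out
}

#' Difference vegetation index
#'
#' `DVI = nir - red`; missing values propagate.
#' @param nir,red surface reflectance.
#' @return numeric DVI vector.
#' @export
compute_dvi <- function(nir, red) nir - red

#' Gain factor K of the plant phenology index
#'
#' `K = (0.25 * cos(theta) / ((1 - dc) * G + dc * cos(theta))) *
#' ((1 + M) / (1 - M))`: the solar/canopy geometry term times the
#' canopy-maximum amplification. With `dc = 1` the geometry term collapses
#' to 0.25 independent of `G`.
#'
#' @param theta solar zenith angle in radians, in `[0, pi/2)`.
#' @param dc instantaneous diffuse fraction of solar radiation in `[0, 1]`.
#' @param G leaf angular distribution geometry function (0.5 for a
#'   spherical leaf-angle distribution).
#' @param M canopy maximum DVI, `DVIs < M < 1`.
#' @return positive gain K.
#' @export
ppi_gain_k <- function(theta, dc = 0, G = 0.5, M) {
  if (any(M >= 1, na.rm = TRUE)) stop("canopy maximum DVI must be < 1")
  if (any(dc < 0 | dc > 1, na.rm = TRUE)) stop("dc must lie in [0, 1]")
  if (any(theta < 0 | theta >= pi / 2, na.rm = TRUE)) {
    stop("theta must lie in [0, pi/2)")
  }
  (0.25 * cos(theta) / ((1 - dc) * G + dc * cos(theta))) * ((1 + M) / (1 - M))
}

#' Plant phenology index
#'
#' `PPI = -K * ln((M - DVI) / (M - DVIs))` (units m^2 m^-2), the inversion
#' of a modified Beer's-law canopy reflectance model; it is near-linear in
#' leaf area index. DVI is clamped to `[DVIs, M - eps]` before the log, so
#' PPI is non-negative, finite (a record-maximum DVI necessarily touches
#' `M`) and monotone non-decreasing in DVI. Missing DVI propagates.
#'
#' @param dvi difference vegetation index values.
#' @param M canopy maximum DVI (scalar or recycled per element).
#' @param K gain from [ppi_gain_k()].
#' @param DVIs bare-soil DVI (default 0.09).
#' @param eps clamp margin in DVI units guarding the log singularity. The
#'   default 0.01 is the scale of composite measurement noise: DVI
#'   excursions closer to `M` than the noise floor carry no information,
#'   and a smaller margin lets the observation nearest the record maximum
#'   explode into a high outlier that upper-envelope weighting (which only
#'   down-weights low points) cannot suppress.
#' @return numeric PPI vector (>= 0).
#' @export
compute_ppi <- function(dvi, M, K, DVIs = 0.09, eps = 0.01) {
  if (any(M <= DVIs, na.rm = TRUE)) {
    stop("M must exceed DVIs; mask non-vegetated pixels upstream")
  }
  d <- pmin(pmax(dvi, DVIs), M - eps)
  -K * log((M - d) / (M - DVIs))
}

#' Solar zenith angle at local solar noon
#'
#' Uses the standard solar declination approximation
#' `decl = 23.45 * sin(2*pi*(284 + doy)/365)` degrees; the noon zenith is
#' `|latitude - decl|`, clipped just below 90 degrees, returned in radians.
#'
#' @param latitude_deg latitude in degrees, `|latitude| <= 90`.
#' @param doy day of year in `[1, 366]`.
#' @return zenith angle theta in radians.
#' @export
solar_zenith_noon <- function(latitude_deg, doy) {
  if (any(abs(latitude_deg) > 90)) stop("|latitude| must be <= 90 degrees")
  if (any(doy < 1 | doy > 366)) stop("doy must lie in [1, 366]")
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  theta_deg <- pmin(abs(latitude_deg - decl), 90 - 1e-9)
  theta_deg * pi / 180
}

#' Fixed 8-day composite grid
#'
#' Window start days of the MODIS-convention composite grid: DOY
#' 1, 9, ..., 361, 46 windows per year (the last window holds 5 days on
#' the 365-day calendar used throughout).
#' @return integer vector of 46 window start days.
#' @export
composite_starts <- function() seq(1L, 361L, by = 8L)

#' Composite a daily series to the fixed 8-day grid
#'
#' Windows are half-open `[start, start + 8)` anchored at DOY
#' 1, 9, ..., 361 (46 per year; the final window is short). Each composite
#' is the mean of good-QA daily values in its window; a window with no good
#' observations is missing with weight 0. Weights are `n_good / window
#' length`, the initial weights used by the curve-fitting stage.
#'
#' @param values daily values (length 365/366, or matching `doy`).
#' @param doy day-of-year per value (default `seq_along(values)`).
#' @param qa_good logical good-quality flag per value (default all good);
#'   missing values are treated as poor.
#' @return data frame with `doy_start`, `value`, `weight`, `n_good`.
#' @export
composite_8day <- function(values, doy = seq_along(values), qa_good = NULL) {
  if (is.null(qa_good)) qa_good <- rep(TRUE, length(values))
  good <- qa_good & !is.na(values)
  starts <- composite_starts()
  win <- findInterval(doy, starts)
  win_len <- tabulate(findInterval(seq_len(365), starts), nbins = 46L)

  num <- rowsum(ifelse(good, values, 0), win, reorder = TRUE)
  cnt <- rowsum(as.numeric(good), win, reorder = TRUE)
  value <- rep(NA_real_, 46L)
  n_good <- rep(0, 46L)
  present <- as.integer(rownames(num))
  n_good[present] <- cnt[, 1]
  value[present] <- ifelse(cnt[, 1] > 0, num[, 1] / cnt[, 1], NA_real_)
  data.frame(doy_start = starts, value = value,
             weight = n_good / win_len, n_good = n_good)
}

#' Climatological fill of leading first-year gaps
#'
#' Sensor records often start mid-winter, leaving the leading composites of
#' the first year missing. Each missing composite in the leading run of the
#' first column is replaced by the mean of the same composite position over
#' all later years; positions where no later year has data stay missing
#' with a warning.
#'
#' @param values matrix of composite values, 46 rows (composite position)
#'   by one column per year, in year order.
#' @return list with `values` (filled matrix) and `filled` (logical matrix
#'   marking substituted entries).
#' @export
fill_leading_gap <- function(values) {
  stopifnot(is.matrix(values))
  filled <- array(FALSE, dim = dim(values))
  if (ncol(values) < 2) return(list(values = values, filled = filled))
  lead <- which(cumprod(is.na(values[, 1])) == 1)
  for (i in lead) {
    clim <- mean(values[i, -1], na.rm = TRUE)
    if (is.nan(clim)) {
      warning(sprintf(
        "composite position %d missing in every later year; left missing", i))
    } else {
      values[i, 1] <- clim
      filled[i, 1] <- TRUE
    }
  }
  list(values = values, filled = filled)
}

#' Per-pixel canopy maximum DVI
#'
#' `M` is the maximum non-missing composited DVI over the full record for
#' each pixel. Pixels whose maximum does not exceed the bare-soil DVI by
#' more than `eps` (including all-missing pixels) are returned as missing:
#' they are non-vegetated and PPI is undefined there.
#'
#' @param dvi matrix/array of composited DVI with time in the first
#'   dimension, or a vector for a single pixel.
#' @param DVIs bare-soil DVI.
#' @param eps vegetation margin above `DVIs`.
#' @return per-pixel M (scalar, or array dropping the time dimension).
#' @export
per_pixel_max_dvi <- function(dvi, DVIs = 0.09, eps = 1e-6) {
  if (is.null(dim(dvi))) {
    m <- suppressWarnings(max(dvi, na.rm = TRUE))
    if (!is.finite(m) || m <= DVIs + eps) return(NA_real_)
    return(m)
  }
  m <- apply(dvi, seq_along(dim(dvi))[-1], function(x) {
    suppressWarnings(max(x, na.rm = TRUE))
  })
  m[!is.finite(m) | m <= DVIs + eps] <- NA_real_
  m
}

#' Composite a vegetation index cube from a scene
#'
#' Computes the requested index from daily reflectance, applies QA
#' filtering and 8-day compositing, fills leading first-year gaps
#' climatologically, and (for PPI) derives the per-pixel canopy maximum `M`
#' as the maximum of the daily good-QA DVI record and the solar-zenith
#' gain `K` per composite mid-date at the scene latitude. Estimating `M`
#' from the daily record keeps the PPI log transform well conditioned:
#' the daily maximum sits a few noise standard deviations above the
#' seasonal plateau of the composites. With noise-free input the record
#' maximum coincides with the plateau and PPI saturates near the peak;
#' supply the asymptotic canopy maximum through `M_override` in that
#' regime.
#'
#' @param scene an `"lsp_scene"` (or any list with `blue`, `red`, `nir`,
#'   `qa` arrays `[time, row, col]` plus `year`, `doy` vectors and a
#'   `config` holding `latitude`).
#' @param index one of `"evi"`, `"kndvi"`, `"ppi"`, `"dvi"`.
#' @param dc diffuse fraction for the PPI gain (default 0, pure direct
#'   beam: the value is instrument/atmosphere specific and must be chosen
#'   by the user).
#' @param theta_mode `"fixed"` (default) uses one solar zenith angle for
#'   the whole record — `theta_fixed`, or the equinox noon zenith at the
#'   scene latitude when `theta_fixed` is `NULL`. `"noon"` evaluates the
#'   zenith per composite mid-date; use it only for reflectance whose
#'   seasonal solar-geometry signal is physically present (the K gain then
#'   corrects it). Applying a seasonally varying K to reflectance that
#'   carries no solar-geometry seasonality (such as these synthetic
#'   scenes) would imprint a spurious autumn decline on PPI; with a
#'   constant K the Gu dates are invariant to the choice of angle, since
#'   K is then a pure scale factor.
#' @param theta_fixed zenith angle in radians used when
#'   `theta_mode = "fixed"`; `NULL` means the DOY-80 (equinox) noon zenith
#'   at the scene latitude.
#' @param DVIs bare-soil DVI for PPI.
#' @param eps PPI clamp margin, see [compute_ppi()].
#' @param M_margin inflation of the record-maximum DVI used as the canopy
#'   maximum: `M = DVIs + (1 + M_margin) * (max - DVIs)`. The record
#'   maximum underestimates the Beer's-law asymptote by
#'   `exp(-k * LAI_peak)` of the dynamic range (0.1-0.3 for peak LAI
#'   2.5-4.5), which over-sharpens the log transform near the seasonal
#'   peak; the default 0.15 compensates the middle of that range.
#' @param M_override optional canopy-maximum grid (matrix `[row, col]` or
#'   scalar) replacing the estimate entirely, e.g. the known asymptote of
#'   a noise-free synthetic scene.
#' @return list of class `"vi_cube"`: `index`, `values` and `weights`
#'   arrays `[46 * n_years, row, col]`, `doy_start` and `year` axis
#'   vectors, `filled` logical array, and for PPI the `M` grid and `K`
#'   vector per composite.
#' @export
compute_vi_cube <- function(scene, index = c("evi", "kndvi", "ppi", "dvi"),
                            dc = 0, theta_mode = c("fixed", "noon"),
                            theta_fixed = NULL, DVIs = 0.09, eps = 0.01,
                            M_margin = 0.15, M_override = NULL) {
  index <- match.arg(index)
  theta_mode <- match.arg(theta_mode)
  ny <- dim(scene$red)[2]; nx <- dim(scene$red)[3]
  years <- unique(scene$year)
  starts <- composite_starts()
  ncomp <- 46L * length(years)

  daily <- switch(index,
    evi = compute_evi(scene$nir, scene$red, scene$blue),
    kndvi = compute_kndvi(scene$nir, scene$red),
    ppi = compute_dvi(scene$nir, scene$red),  # composited DVI -> PPI below
    dvi = compute_dvi(scene$nir, scene$red))

  values <- array(NA_real_, dim = c(ncomp, ny, nx))
  weights <- array(0, dim = c(ncomp, ny, nx))
  filled <- array(FALSE, dim = c(ncomp, ny, nx))
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      for (k in seq_along(years)) {
        tsel <- scene$year == years[k]
        comp <- composite_8day(daily[tsel, i, j], scene$doy[tsel],
                               scene$qa[tsel, i, j])
        rows <- (k - 1L) * 46L + seq_len(46L)
        values[rows, i, j] <- comp$value
        weights[rows, i, j] <- comp$weight
      }
      if (length(years) > 1) {
        vm <- matrix(values[, i, j], nrow = 46L)
        fg <- fill_leading_gap(vm)
        values[, i, j] <- c(fg$values)
        filled[, i, j] <- c(fg$filled)
        # a climatological fill is a full-confidence pseudo-observation
        weights[, i, j][c(fg$filled)] <- 1
      }
    }
  }

  out <- list(index = index, values = values, weights = weights,
              doy_start = rep(starts, times = length(years)),
              year = rep(years, each = 46L), filled = filled)

  if (index == "ppi") {
    M <- if (!is.null(M_override)) {
      if (length(M_override) == 1) matrix(M_override, ny, nx) else M_override
    } else {
      dvi_daily <- daily
      dvi_daily[!scene$qa] <- NA_real_
      Mrec <- per_pixel_max_dvi(dvi_daily, DVIs = DVIs)
      pmin(DVIs + (1 + M_margin) * (Mrec - DVIs), 1 - 1e-6)
    }
    lat <- scene$config$latitude %||% 35
    theta <- if (theta_mode == "noon") {
      solar_zenith_noon(lat[1], pmin(starts + 3.5, 365))
    } else {
      rep(theta_fixed %||% solar_zenith_noon(lat[1], 80), 46L)
    }
    K_by_comp <- rep(NA_real_, ncomp)
    ppi_vals <- array(NA_real_, dim = dim(values))
    for (i in seq_len(ny)) {
      for (j in seq_len(nx)) {
        if (is.na(M[i, j])) next  # non-vegetated: PPI undefined
        K <- ppi_gain_k(theta, dc = dc, M = M[i, j])
        Kfull <- rep(K, times = length(years))
        ppi_vals[, i, j] <- compute_ppi(values[, i, j], M = M[i, j],
                                        K = Kfull, DVIs = DVIs, eps = eps)
      }
    }
    out$M <- M
    out$theta <- theta
    out$values <- ppi_vals
  }
  class(out) <- "vi_cube"
  out
}
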