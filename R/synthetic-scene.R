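#' Configuration for a synthetic reflectance scene
#'
#' Builds the full set of generator parameters for [simulate_scene()]: grid
#' size, simulated calendar years, canopy optics linking leaf area index
#' (LAI) to the difference vegetation index (DVI), observation noise,
#' cloud/snow contamination with quality-assurance (QA) flags, and the
#' photosynthesis proxies (GPP and SIF) whose autumn decline leads the
#' structural greenness decline.
#'
#' The generator works on a 365-day calendar (leap days are not simulated)
#' and produces one growing season per calendar year, the temperate regime
#' the pipeline targets.
#'
#' @param ny,nx grid dimensions (rows, columns); rows run north to south.
#' @param years integer vector of calendar years to simulate.
#' @param optics list with entries `M_true` (asymptotic canopy maximum DVI),
#'   `DVIs_true` (bare-soil DVI), `c_lai2dvi` (Beer's-law extinction
#'   coefficient coupling LAI to DVI, m^-2 m^2), `red_base`, `blue_base`
#'   (background reflectance of the red and blue bands).
#' @param noise_sd standard deviation of the additive Gaussian reflectance
#'   noise (reflectance units).
#' @param cloud_prob per pixel-day probability of cloud contamination.
#' @param cloud_vi_bias mean DVI depression on cloud-contaminated days
#'   (negative; clouds darken NIR and brighten red).
#' @param cloud_qa_flag_prob probability that a cloudy observation is
#'   correctly flagged poor by QA; the remainder escape screening, which is
#'   what upper-envelope fitting must absorb.
#' @param snow_window DOY range `c(start, end)` inside which snow can occur;
#'   `start > end` wraps across the new year.
#' @param snow_prob per pixel-day snow probability inside the window.
#' @param snow_qa_miss_prob probability that a snowy observation escapes QA.
#' @param sif_gpp list with `lue` (light-use-efficiency scalar, g C m^-2
#'   day^-1 at full light absorption), `k_sif` (SIF per unit GPP),
#'   `autumn_lead_days` (days by which the photosynthetic autumn decline
#'   leads the structural one; must be >= 0) and `noise_sd` (SIF noise).
#' @param truth list of baseline phenological truth; see [make_truth()].
#' @param latitude scene latitude in degrees (scalar or length-`ny` vector,
#'   one value per row), used downstream for the PPI solar-zenith gain.
#' @param include_fluxes logical; generate GPP/SIF proxy cubes.
#' @param seed integer seed governing every random draw in the scene.
#'
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(ny = 20, nx = 20, years = 2000,
                         optics = list(),
                         noise_sd = 0.02,
                         cloud_prob = 0.2,
                         cloud_vi_bias = -0.15,
                         cloud_qa_flag_prob = 0.9,
                         snow_window = c(320, 60),
                         snow_prob = 0.15,
                         snow_qa_miss_prob = 0.1,
                         sif_gpp = list(),
                         truth = list(),
                         latitude = 35,
                         include_fluxes = TRUE,
                         seed = 1) {
  opt <- utils::modifyList(
    list(M_true = 0.7, DVIs_true = 0.09, c_lai2dvi = 0.5,
         red_base = 0.05, blue_base = 0.03),
    optics)
  sg <- utils::modifyList(
    list(lue = 8, k_sif = 0.05, autumn_lead_days = 20, noise_sd = 0.2),
    sif_gpp)
  tr <- utils::modifyList(
    list(mn_lai = 0.2, mx_lai = 3, sos = 130, rsp = 0.2,
         eos = 285, rau = 0.15, plateau_slope = 0,
         sos_trend = 0, eos_trend = 0, jitter_sd = 2,
         sos_gradient = 10, eos_gradient = 10, mx_gradient = 0.5),
    truth)

  if (!(ny >= 1 && nx >= 1)) stop("grid must contain at least one pixel")
  if (length(years) < 1) stop("at least one year must be simulated")
  stop_if_not_scalar_prob(cloud_prob, "cloud_prob")
  stop_if_not_scalar_prob(cloud_qa_flag_prob, "cloud_qa_flag_prob")
  stop_if_not_scalar_prob(snow_prob, "snow_prob")
  stop_if_not_scalar_prob(snow_qa_miss_prob, "snow_qa_miss_prob")
  if (!(opt$DVIs_true < opt$M_true && opt$M_true < 1)) {
    stop("optics must satisfy DVIs_true < M_true < 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (sg$autumn_lead_days < 0) stop("autumn_lead_days must be >= 0")
  if (cloud_vi_bias > 0) stop("cloud_vi_bias must be <= 0 (clouds depress the VI)")
  if (!length(latitude) %in% c(1L, ny)) {
    stop("latitude must be a scalar or one value per grid row")
  }

  structure(list(ny = as.integer(ny), nx = as.integer(nx),
                 years = as.integer(sort(years)),
                 optics = opt, noise_sd = noise_sd,
                 cloud_prob = cloud_prob, cloud_vi_bias = cloud_vi_bias,
                 cloud_qa_flag_prob = cloud_qa_flag_prob,
                 snow_window = snow_window, snow_prob = snow_prob,
                 snow_qa_miss_prob = snow_qa_miss_prob,
                 sif_gpp = sg, truth = tr, latitude = latitude,
                 include_fluxes = isTRUE(include_fluxes),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Per-pixel, per-year phenological ground truth
#'
#' Expands the baseline truth parameters of a [scene_config()] into a table
#' with one row per pixel and year: smooth spatial gradients are applied to
#' the spring inflection (`sos`, across columns), the autumn inflection
#' (`eos`, across rows) and the peak LAI (`mx_lai`, along the diagonal);
#' interannual linear trends (`sos_trend`, `eos_trend`, days per year) plus
#' zero-mean Gaussian jitter of sd `jitter_sd` are applied across years.
#'
#' @param config a [scene_config()].
#' @return data frame with columns `row`, `col`, `year`, `mn_lai`, `mx_lai`,
#'   `sos`, `rsp`, `eos`, `rau`, `plateau_slope`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  tr <- config$truth
  ny <- config$ny; nx <- config$nx; years <- config$years
  grid <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  cx <- (grid$col - 0.5) / nx - 0.5
  cy <- (grid$row - 0.5) / ny - 0.5

  sos0 <- tr$sos + tr$sos_gradient * cx
  eos0 <- tr$eos + tr$eos_gradient * cy
  mx0 <- tr$mx_lai + tr$mx_gradient * (cx + cy) / 2

  out <- with_seed(child_seed(config$seed, 1L), {
    rows <- lapply(seq_along(years), function(k) {
      dy <- years[k] - years[1]
      jit_s <- stats::rnorm(nrow(grid), 0, tr$jitter_sd)
      jit_e <- stats::rnorm(nrow(grid), 0, tr$jitter_sd)
      data.frame(row = grid$row, col = grid$col, year = years[k],
                 mn_lai = tr$mn_lai, mx_lai = mx0,
                 sos = sos0 + tr$sos_trend * dy + jit_s,
                 rsp = tr$rsp,
                 eos = eos0 + tr$eos_trend * dy + jit_e,
                 rau = tr$rau,
                 plateau_slope = tr$plateau_slope)
    })
    do.call(rbind, rows)
  })

  bad <- which(out$eos - out$sos <= 2 / out$rsp + 2 / out$rau)
  if (length(bad)) {
    b <- out[bad[1], ]
    stop(sprintf(paste0("truth parameters violate season separation at pixel",
                        " (%d, %d), year %d: eos - sos = %.1f days"),
                 b$row, b$col, b$year, b$eos - b$sos))
  }
  if (any(out$mx_lai <= out$mn_lai) || any(out$mn_lai < 0)) {
    stop("truth must satisfy mx_lai > mn_lai >= 0")
  }
  out
}

#' Daily leaf-area-index trajectory from Beck-type truth parameters
#'
#' The double-logistic seasonal model
#' `LAI(t) = mn + (mx - mn) * (plogis(rsp*(t - sos)) + plogis(-rau*(t - eos)) - 1)`,
#' optionally with a linear greendown of slope `plateau_slope` (LAI per day,
#' usually <= 0) applied on the open plateau interval
#' `(sos + 2/rsp, eos - 2/rau)` and clipped below at `mn`.
#'
#' @param truth a single-row slice of the [make_truth()] table (or any list
#'   with fields `mn_lai`, `mx_lai`, `sos`, `rsp`, `eos`, `rau`,
#'   `plateau_slope`).
#' @param doy numeric vector of days of year.
#' @return numeric LAI vector, same length as `doy`.
#' @export
lai_series <- function(truth, doy) {
  mn <- truth$mn_lai; mx <- truth$mx_lai
  lai <- mn + (mx - mn) *
    (logistic(truth$rsp * (doy - truth$sos)) +
       logistic(-truth$rau * (doy - truth$eos)) - 1)
  ps <- truth$plateau_slope %||% 0
  if (!is.null(ps) && ps != 0) {
    lo <- truth$sos + 2 / truth$rsp
    hi <- truth$eos - 2 / truth$rau
    on_plateau <- doy > lo & doy < hi
    lai[on_plateau] <- lai[on_plateau] + ps * (doy[on_plateau] - lo)
    lai <- pmax(lai, mn)
  }
  lai
}

#' Reflectance bands from a LAI trajectory
#'
#' Inverts the Beer's-law construction that PPI is later built on:
#' `DVI = M_true - (M_true - DVIs_true) * exp(-c_lai2dvi * LAI)`, then
#' `red = red_base + noise`, `nir = red + DVI + noise`,
#' `blue = blue_base + noise`, each clipped to `[0, 1]`. Noise is zero-mean
#' Gaussian of sd `noise_sd` drawn from the current RNG state (seed it via
#' the `seed` argument or an enclosing [with_seed()]).
#'
#' @param lai numeric vector/array of LAI values (>= 0).
#' @param optics the optics list of a [scene_config()].
#' @param noise_sd reflectance noise standard deviation.
#' @param seed optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG state.
#' @return list with `blue`, `red`, `nir` and the noise-free `dvi`, each
#'   shaped like `lai`.
#' @export
reflectance_from_lai <- function(lai, optics, noise_sd = 0, seed = NULL) {
  if (any(lai < 0, na.rm = TRUE)) stop("lai must be non-negative")
  dvi <- optics$M_true -
    (optics$M_true - optics$DVIs_true) * exp(-optics$c_lai2dvi * lai)
  if (any(dvi > optics$M_true, na.rm = TRUE)) {
    stop("internal error: generated DVI exceeded the canopy maximum")
  }
  # extreme LAI underflows exp() to zero; keep DVI strictly below M
  dvi <- pmin(dvi, optics$M_true * (1 - 1e-12))
  draw <- function() {
    n <- length(lai)
    noise <- function() {
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    }
    red <- optics$red_base + noise()
    nir <- red + c(dvi) + noise()
    blue <- optics$blue_base + noise()
    clip <- function(x) {
      x <- pmin(pmax(x, 0), 1)
      if (!is.null(dim(lai))) dim(x) <- dim(lai)
      x
    }
    list(blue = clip(blue), red = clip(red), nir = clip(nir), dvi = dvi)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Inject cloud and snow contamination with QA flags
#'
#' Cloud days (Bernoulli `cloud_prob` per pixel-day) have NIR depressed and
#' red raised so the DVI drops by on average `|cloud_vi_bias|`; each cloudy
#' observation is flagged poor with probability `cloud_qa_flag_prob` (the
#' remainder escape QA, exercising the upper-envelope weighting downstream).
#' Snow days inside `snow_window` raise red and blue toward 0.7 and pull NIR
#' to red (DVI near 0); they are flagged poor except with probability
#' `snow_qa_miss_prob`. All bands stay in `[0, 1]`.
#'
#' @param scene a scene list as produced by [simulate_scene()] (fields
#'   `blue`, `red`, `nir`, `qa`, `doy`).
#' @param config the [scene_config()] used to build the scene.
#' @param seed integer seed for the contamination draws.
#' @return the scene with contaminated bands and updated `qa`.
#' @export
contaminate <- function(scene, config, seed = NULL) {
  seed <- seed %||% child_seed(config$seed, 2L)
  n <- length(scene$red)
  doy_all <- rep(scene$doy, times = n / length(scene$doy))

  with_seed(seed, {
    if (config$cloud_prob > 0) {
      cloudy <- stats::runif(n) < config$cloud_prob
      idx <- which(cloudy)
      if (length(idx)) {
        drop <- abs(config$cloud_vi_bias) * stats::runif(length(idx), 0.5, 1.5)
        scene$nir[idx] <- pmax(scene$nir[idx] - drop / 2, 0)
        scene$red[idx] <- pmin(scene$red[idx] + drop / 2, 1)
        flagged <- stats::runif(length(idx)) < config$cloud_qa_flag_prob
        scene$qa[idx[flagged]] <- FALSE
      }
    }
    if (config$snow_prob > 0) {
      win <- config$snow_window
      in_win <- if (win[1] <= win[2]) {
        doy_all >= win[1] & doy_all <= win[2]
      } else {
        doy_all >= win[1] | doy_all <= win[2]
      }
      snowy <- in_win & stats::runif(n) < config$snow_prob
      idx <- which(snowy)
      if (length(idx)) {
        bright <- 0.6 + 0.1 * stats::runif(length(idx))
        scene$red[idx] <- bright
        scene$blue[idx] <- pmin(bright + stats::rnorm(length(idx), 0, 0.02), 1)
        scene$nir[idx] <- pmin(pmax(
          bright + stats::rnorm(length(idx), 0, 0.01), 0), 1)
        missed <- stats::runif(length(idx)) < config$snow_qa_miss_prob
        scene$qa[idx[!missed]] <- FALSE
      }
    }
  })
  scene
}

#' Photosynthesis proxies (GPP and SIF) for one pixel
#'
#' GPP is a light-use-efficiency product
#' `GPP(t) = lue * (1 - exp(-0.5 * LAI(t))) * S(t)` where the seasonal
#' scalar `S(t)` equals 1 before `t0 = eos - autumn_lead_days` and declines
#' logistically with the autumn rate `rau` thereafter
#' (`S(t) = 2 * plogis(-rau * (t - t0))`, continuous at `t0`). SIF is
#' `k_sif * GPP` plus seeded Gaussian noise, floored at zero. The lead makes
#' the photosynthetic autumn decline precede the structural (greenness) one,
#' the physiological structure the consistency statistics are designed to
#' detect.
#'
#' @param lai clean (noise-free) LAI vector for the pixel-year.
#' @param truth the matching truth row (fields `sos`, `eos`, `rau`).
#' @param sif_gpp the `sif_gpp` list of a [scene_config()].
#' @param doy day-of-year vector aligned with `lai`.
#' @param seed integer seed for the SIF noise.
#' @return list with numeric vectors `gpp` and `sif`.
#' @export
simulate_sif_gpp <- function(lai, truth, sif_gpp, doy, seed = 0) {
  t0 <- truth$eos - sif_gpp$autumn_lead_days
  if (t0 <= truth$sos) {
    stop("autumn_lead_days moves the photosynthetic decline before sos")
  }
  s <- ifelse(doy < t0, 1, 2 * logistic(-truth$rau * (doy - t0)))
  gpp <- sif_gpp$lue * (1 - exp(-0.5 * lai)) * s
  sif <- with_seed(seed, {
    pmax(sif_gpp$k_sif * gpp +
           stats::rnorm(length(gpp), 0, sif_gpp$noise_sd * sif_gpp$k_sif), 0)
  })
  list(gpp = pmax(gpp, 0), sif = sif)
}

#' Simulate a full synthetic scene with known phenological truth
#'
#' Chains [make_truth()], [lai_series()], [reflectance_from_lai()],
#' [contaminate()] and (optionally) [simulate_sif_gpp()] into a daily
#' multi-year reflectance cube with QA flags, plus the per-pixel-year truth
#' table including the closed-form Gu transition dates (`UD`, `SD`, `DD0`,
#' `DD`, `RD`) against which the pipeline can be scored.
#'
#' Arrays are dimensioned `[time, row, col]`; the time axis is a 365-day
#' calendar per simulated year (`year`/`doy` vectors give its coordinates).
#'
#' @param config a [scene_config()].
#' @return list of class `"lsp_scene"`: `blue`, `red`, `nir`, `clean_dvi`
#'   (noise-free DVI), `qa` (logical, `TRUE` = good), `year`, `doy`,
#'   `truth` (with true metrics appended), `gpp`, `sif` (when
#'   `include_fluxes`), and the `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  truth <- make_truth(config)
  ny <- config$ny; nx <- config$nx; years <- config$years
  doy1 <- seq_len(365)
  nt <- 365L * length(years)
  year_vec <- rep(years, each = 365L)
  doy_vec <- rep(doy1, times = length(years))

  lai <- array(NA_real_, dim = c(nt, ny, nx))
  for (k in seq_len(nrow(truth))) {
    tr <- truth[k, ]
    tsel <- which(year_vec == tr$year)
    lai[tsel, tr$row, tr$col] <- lai_series(tr, doy1)
  }

  refl <- reflectance_from_lai(lai, config$optics, config$noise_sd,
                               seed = child_seed(config$seed, 3L))
  scene <- list(blue = refl$blue, red = refl$red, nir = refl$nir,
                clean_dvi = refl$dvi,
                qa = array(TRUE, dim = c(nt, ny, nx)),
                year = year_vec, doy = doy_vec,
                truth = cbind(truth, true_metrics_closed_form(truth)),
                config = config)
  class(scene) <- "lsp_scene"
  scene <- contaminate(scene, config)

  if (config$include_fluxes) {
    gpp <- array(NA_real_, dim = c(nt, ny, nx))
    sif <- array(NA_real_, dim = c(nt, ny, nx))
    for (k in seq_len(nrow(truth))) {
      tr <- truth[k, ]
      tsel <- which(year_vec == tr$year)
      fl <- simulate_sif_gpp(lai[tsel, tr$row, tr$col], tr, config$sif_gpp,
                             doy1, seed = child_seed(config$seed, 100L + k))
      gpp[tsel, tr$row, tr$col] <- fl$gpp
      sif[tsel, tr$row, tr$col] <- fl$sif
    }
    scene$gpp <- gpp
    scene$sif <- sif
  }
  scene
}

# Closed-form Gu metrics for each truth row; DD equals DD0 for the
# flat-plateau generator and is left NA under nonzero greendown (the
# plateau-adjusted date then depends on the fitted plateau line).
true_metrics_closed_form <- function(truth) {
  ud <- truth$sos - 2 / truth$rsp
  sd_ <- truth$sos + 2 / truth$rsp
  dd0 <- truth$eos - 2 / truth$rau
  rd <- truth$eos + 2 / truth$rau
  dd <- ifelse((truth$plateau_slope %||% 0) == 0, dd0, NA_real_)
  data.frame(UD = ud, SD = sd_, DD0 = dd0, DD = dd, RD = rd)
}
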