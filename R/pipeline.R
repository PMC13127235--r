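#' Write / read a scene as long-format CSV
#'
#' Plain-text interchange for reflectance cubes: one row per observation
#' with columns `year`, `doy`, `row`, `col`, `blue`, `red`, `nir`, `qa`
#' (1 = good) and, when present, `gpp`/`sif`. Intended for site extracts
#' and test fixtures; full scenes are regenerated from their
#' [scene_config()] rather than shipped.
#'
#' @param scene an `"lsp_scene"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scene_csv <- function(scene, path) {
  ny <- dim(scene$red)[2]; nx <- dim(scene$red)[3]
  grid <- expand.grid(t = seq_along(scene$year),
                      row = seq_len(ny), col = seq_len(nx))
  df <- data.frame(year = scene$year[grid$t], doy = scene$doy[grid$t],
                   row = grid$row, col = grid$col,
                   blue = c(scene$blue), red = c(scene$red),
                   nir = c(scene$nir), qa = as.integer(c(scene$qa)))
  if (!is.null(scene$gpp)) df$gpp <- c(scene$gpp)
  if (!is.null(scene$sif)) df$sif <- c(scene$sif)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene_csv
#' @param latitude scene latitude attached to the reconstructed scene.
#' @return for `read_scene_csv`, an `"lsp_scene"`-like list (arrays
#'   `[time, row, col]`, `qa`, `year`, `doy`, minimal `config`).
#' @export
read_scene_csv <- function(path, latitude = 35) {
  df <- utils::read.csv(path)
  need <- c("year", "doy", "row", "col", "blue", "red", "nir", "qa")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  ny <- max(df$row); nx <- max(df$col)
  tkey <- df$year * 1000 + df$doy
  tlev <- sort(unique(tkey))
  px1 <- df$row == 1 & df$col == 1
  if (is.unsorted(tkey[px1])) {
    stop(sprintf("%s: time axis is not monotone (column doy)", path))
  }
  nt <- length(tlev)
  ti <- match(tkey, tlev)
  idx <- cbind(ti, df$row, df$col)
  mk <- function(v) {
    a <- array(NA_real_, dim = c(nt, ny, nx))
    a[idx] <- v
    a
  }
  scene <- list(blue = mk(df$blue), red = mk(df$red), nir = mk(df$nir),
                qa = array(as.logical(mk(df$qa)), dim = c(nt, ny, nx)),
                year = tlev %/% 1000, doy = tlev %% 1000,
                config = list(latitude = latitude))
  if (!is.null(df$gpp)) scene$gpp <- mk(df$gpp)
  if (!is.null(df$sif)) scene$sif <- mk(df$sif)
  class(scene) <- "lsp_scene"
  scene
}

#' Read a tower-style daily series CSV
#'
#' Expects columns `year`, `doy`, `gpp` and optionally `sif`.
#' @param path CSV path.
#' @return data frame in time order.
#' @export
read_tower_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "doy", "gpp")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  df[order(df$year, df$doy), , drop = FALSE]
}

#' Write a phenology metrics table as CSV
#'
#' Deterministic plain-text output of [extract_phenology()] results:
#' identical runs produce byte-identical files.
#' @param metrics metrics data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Demo pipeline configuration
#'
#' A small but complete study: an 8 x 8 grid over six years with the
#' default phenological truth, imposed spring-advance trend of -0.5 days
#' per year, moderate noise and contamination. Used by examples, the
#' vignette and the determinism checks.
#'
#' @param seed integer seed.
#' @return a [scene_config()].
#' @export
demo_config <- function(seed = 1) {
  scene_config(ny = 8, nx = 8, years = 2000:2005,
               truth = list(sos_trend = -0.5),
               seed = seed)
}

#' Run the full phenology pipeline on a synthetic scene
#'
#' Chains scene synthesis, VI compositing ([compute_vi_cube()]),
#' curve fitting and Gu extraction ([extract_phenology()]) for each
#' requested index, and — when at least four years are simulated —
#' per-pixel Theil-Sen / Mann-Kendall trend maps per metric and index.
#' A manifest records the package version, the config and per-stage
#' timings; identical configs (same seed) give identical outputs.
#'
#' @param config a [scene_config()].
#' @param indices character subset of `c("evi", "kndvi", "ppi")`.
#' @param control curve-fit control list, see [fit_pixel_season()].
#' @param keep_scene logical; include the simulated scene in the result.
#' @return list of class `"lsp_run"`: `metrics` (tidy data frame over all
#'   indices), `trends` (named list `index.metric` of [trend_map()]
#'   results, or `NULL`), `scene` (optional), `manifest`.
#' @export
run_pipeline <- function(config, indices = c("evi", "kndvi", "ppi"),
                         control = list(), keep_scene = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  indices <- match.arg(indices, c("evi", "kndvi", "ppi"), several.ok = TRUE)
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, sec = proc.time()[["elapsed"]] - t0)
  }

  st <- tic(simulate_scene(config))
  scene <- st$val
  timings["synth"] <- st$sec

  metrics <- list()
  for (ix in indices) {
    vt <- tic(compute_vi_cube(scene, ix))
    timings[paste0("vi_", ix)] <- vt$sec
    pt <- tic(extract_phenology(vt$val, control))
    timings[paste0("pheno_", ix)] <- pt$sec
    metrics[[ix]] <- pt$val
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  trends <- NULL
  years <- config$years
  if (length(years) >= 4) {
    trends <- list()
    for (ix in indices) {
      for (mname in c("UD", "SD", "DD0", "DD", "RD")) {
        arr <- array(NA_real_, dim = c(length(years), config$ny, config$nx))
        sub <- metrics[metrics$index == ix, ]
        arr[cbind(match(sub$year, years), sub$row, sub$col)] <- sub[[mname]]
        trends[[paste(ix, mname, sep = ".")]] <- trend_map(arr, years)
      }
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("lspheno")),
    config = config,
    indices = indices,
    timings_sec = round(timings, 3),
    n_pixel_seasons = nrow(metrics),
    warnings = character())
  out <- list(metrics = metrics, trends = trends,
              scene = if (keep_scene) scene, manifest = manifest)
  class(out) <- "lsp_run"
  out
}
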