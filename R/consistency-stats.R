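#' Pearson correlation with missing-data and degeneracy guards
#'
#' Standard product-moment correlation over pairwise-complete
#' observations. Fewer than 3 complete pairs, or zero variance on either
#' side, gives `NA` with a warning rather than an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Per-pixel correlation map between a VI cube and a reference cube
#'
#' Computes [pearson_r()] for every pixel of two co-registered cubes on
#' the same composite grid and summarizes the distribution: median,
#' interquartile range and a fixed-bin histogram on `[-1, 1]` with bin
#' width 0.05.
#'
#' @param vi,ref arrays `[time, row, col]` on the same grid.
#' @return list with `r` (matrix), `median`, `iqr` and `hist` (data frame
#'   `lower`, `upper`, `count`).
#' @export
pearson_map <- function(vi, ref) {
  stopifnot(all(dim(vi) == dim(ref)))
  ny <- dim(vi)[2]; nx <- dim(vi)[3]
  r <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      r[i, j] <- suppressWarnings(pearson_r(vi[, i, j], ref[, i, j]))
    }
  }
  breaks <- seq(-1, 1, by = 0.05)
  rv <- r[!is.na(r)]
  counts <- tabulate(pmin(findInterval(rv, breaks), length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  list(r = r,
       median = stats::median(r, na.rm = TRUE),
       iqr = stats::IQR(r, na.rm = TRUE),
       hist = data.frame(lower = breaks[-length(breaks)],
                         upper = breaks[-1], count = counts))
}

#' Mean series over a 3x3 tower-footprint window
#'
#' Flux-tower footprints exceed a single 500 m pixel; the standard remedy
#' is the mean of the 3x3 neighborhood centred on the tower pixel,
#' ignoring missing values (an all-missing timestep stays missing).
#' Edge locations raise an error instructing the caller to pad or move
#' the site.
#'
#' @param cube array `[time, row, col]`.
#' @param row,col centre pixel, at least one pixel from every edge.
#' @return numeric series of per-timestep window means.
#' @export
tower_window_mean <- function(cube, row, col) {
  ny <- dim(cube)[2]; nx <- dim(cube)[3]
  if (row < 2 || col < 2 || row > ny - 1 || col > nx - 1) {
    stop("site pixel touches the grid edge; pad the grid or move the site")
  }
  block <- cube[, (row - 1):(row + 1), (col - 1):(col + 1), drop = FALSE]
  apply(block, 1, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
}

#' Bin a daily reference series onto the 8-day composite grid
#'
#' Window means on the fixed DOY `{1, 9, ..., 361}` grid. `shift_days`
#' uniformly shifts the series' time axis before binning — the mechanism
#' for aligning reference products whose reporting dates are offset from
#' the composite grid (e.g. a 3-day SIF alignment shift). Days shifted
#' outside `[1, 365]` are dropped.
#'
#' @param doy day-of-year per daily value.
#' @param values daily reference values (e.g. GPP).
#' @param shift_days signed uniform shift applied to `doy` before binning.
#' @return data frame `doy_start`, `value` (46 rows; empty windows `NA`).
#' @export
align_to_8day <- function(doy, values, shift_days = 0) {
  d <- doy + shift_days
  keep <- d >= 1 & d <= 365
  comp <- composite_8day(values[keep], d[keep])
  comp[, c("doy_start", "value")]
}

#' K-fold cross-validated simple linear regression
#'
#' One seeded shuffle assigns the data to `k` near-equal contiguous folds;
#' for each fold a line `y = a + b x` is fitted on the remaining folds and
#' the held-out fold predicted. Pooled out-of-fold predictions give
#' `R^2 = 1 - SS_res / SS_tot`, RMSE, and the median bias
#' `median(observed - estimated)` — negative bias therefore means
#' systematic overestimation. A training split with constant `x` skips
#' that fold with a warning.
#'
#' @param x predictor (e.g. a VI); `y` response (e.g. GPP). Missing pairs
#'   are dropped.
#' @param y response.
#' @param k number of folds (default 10).
#' @param seed integer seed for the single shuffle.
#' @return list of class `"cv_report"`: `r2`, `rmse`, `bias_median`, `n`,
#'   `fold_assignments`, and the pooled `predicted`/`observed` vectors
#'   (indexed over the complete pairs).
#' @export
cv_linear_regression <- function(x, y, k = 10, seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop(sprintf("n = %d is smaller than k = %d", n, k))

  # one seeded shuffle, then a contiguous split of the shuffled order
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]

  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (stats::sd(x[!test]) == 0) {
      warning(sprintf("fold %d skipped: constant predictor in training", f))
      next
    }
    cf <- stats::lm.fit(cbind(1, x[!test]), y[!test])$coefficients
    pred[test] <- cf[[1]] + cf[[2]] * x[test]
  }
  used <- !is.na(pred)
  resid <- y[used] - pred[used]
  ss_tot <- sum((y[used] - mean(y[used]))^2)
  structure(list(r2 = 1 - sum(resid^2) / ss_tot,
                 rmse = sqrt(mean(resid^2)),
                 bias_median = stats::median(resid),
                 n = n, fold_assignments = fold,
                 predicted = pred, observed = y),
            class = "cv_report")
}

#' Seasonal (DOY-binned) residual summary
#'
#' Residuals `observed - estimated` summarized over the phenologically
#' meaningful DOY bins `[1,60)`, `[60,150)`, `[150,240)` (peak growing
#' season), `[240,330)` and `[330,366)`: median, interquartile range and
#' count per bin; empty bins give missing summaries.
#'
#' @param residuals numeric residuals.
#' @param doy day-of-year label per residual, in `[1, 366)`.
#' @return data frame `bin`, `lower`, `upper`, `median`, `iqr`, `n`.
#' @export
residual_seasonal_bins <- function(residuals, doy) {
  stopifnot(length(residuals) == length(doy))
  if (any(doy < 1 | doy >= 366, na.rm = TRUE)) {
    stop("doy must lie in [1, 366)")
  }
  breaks <- c(1, 60, 150, 240, 330, 366)
  idx <- findInterval(doy, breaks)
  rows <- lapply(seq_len(5), function(b) {
    r <- residuals[idx == b & !is.na(residuals)]
    data.frame(bin = sprintf("[%d,%d)", breaks[b], breaks[b + 1]),
               lower = breaks[b], upper = breaks[b + 1],
               median = if (length(r)) stats::median(r) else NA_real_,
               iqr = if (length(r)) stats::IQR(r) else NA_real_,
               n = length(r))
  })
  do.call(rbind, rows)
}
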