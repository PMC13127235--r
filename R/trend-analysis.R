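#' Theil-Sen median slope
#'
#' The median of all `n*(n-1)/2` pairwise slopes
#' `(v_j - v_i) / (y_j - y_i)`, `i < j` — a robust trend estimator with a
#' 29% breakdown point that requires neither normality nor serial
#' independence. Missing pairs are dropped first.
#'
#' @param years time coordinate (e.g. calendar years).
#' @param values annual values.
#' @return slope in value units per year, or `NA` with fewer than two
#'   usable points.
#' @export
theil_sen <- function(years, values) {
  ok <- !is.na(values) & !is.na(years)
  y <- years[ok]; v <- values[ok]
  if (length(v) < 2) return(NA_real_)
  dy <- outer(y, y, "-")
  dv <- outer(v, v, "-")
  sel <- upper.tri(dy)
  stats::median(dv[sel] / dy[sel])
}

#' Mann-Kendall trend test with tie correction
#'
#' `S = sum_{i<j} sign(v_j - v_i)`;
#' `Var(S) = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18` over tie groups of
#' size `t`; the Z score uses the continuity correction
#' `Z = (S - 1)/sqrt(Var)` for positive `S`, `(S + 1)/sqrt(Var)` for
#' negative, 0 otherwise. Significance classes follow the fixed thresholds
#' `|Z| >= 1.96` (95%) and `|Z| > 2.56` (99%). An all-tied series has zero
#' variance and is classed non-significant.
#'
#' @param values series in time order (missing dropped).
#' @return list with `s`, `var_s`, `z` and `sig_class` (one of `"none"`,
#'   `"p<0.05"`, `"p<0.01"`).
#' @export
mann_kendall <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 4) stop("mann_kendall needs at least 4 non-missing values")
  sgn <- sign(outer(v, v, "-"))
  s <- sum(sgn[lower.tri(sgn)])  # [i, j] = v_i - v_j; lower.tri has i > j
  ties <- table(v)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s <= 0) 0 else if (s > 0) {
    (s - 1) / sqrt(var_s)
  } else if (s < 0) {
    (s + 1) / sqrt(var_s)
  } else 0
  sig <- if (abs(z) > 2.56) "p<0.01" else if (abs(z) >= 1.96) "p<0.05" else "none"
  list(s = s, var_s = var_s, z = z, sig_class = sig)
}

#' Per-pixel phenology trend map
#'
#' Theil-Sen slope and Mann-Kendall significance of a metric's annual
#' series at every pixel; pixels with fewer than 4 valid years are
#' missing. `sig` codes significance as 0 (none), 1 (`p < 0.05`),
#' 2 (`p < 0.01`).
#'
#' @param metric array `[year, row, col]` of annual metric values.
#' @param years calendar-year coordinate of the first dimension.
#' @return list with matrices `slope`, `z`, `sig`, `n`.
#' @export
trend_map <- function(metric, years = seq_len(dim(metric)[1])) {
  ny <- dim(metric)[2]; nx <- dim(metric)[3]
  slope <- z <- matrix(NA_real_, ny, nx)
  sig <- nvalid <- matrix(NA_integer_, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      v <- metric[, i, j]
      nv <- sum(!is.na(v))
      nvalid[i, j] <- nv
      if (nv < 4) next
      slope[i, j] <- theil_sen(years, v)
      mk <- mann_kendall(v)
      z[i, j] <- mk$z
      sig[i, j] <- switch(mk$sig_class, none = 0L, "p<0.05" = 1L,
                          "p<0.01" = 2L)
    }
  }
  list(slope = slope, z = z, sig = sig, n = nvalid)
}

#' Regional trend summary
#'
#' For each region label: the trend of the region-mean annual series
#' (pixels averaged first, then Theil-Sen + Mann-Kendall — the basin-mean
#' treatment), plus pixel-level fractions from the per-pixel trend map:
#' percent of pixels significant at 95%, and of those, the percent
#' advancing (slope < 0) and delaying (slope > 0). Empty regions give a
#' missing row.
#'
#' @param metric array `[year, row, col]`.
#' @param years calendar years.
#' @param mask integer matrix of region labels co-registered with the
#'   grid (`NA` = outside all regions).
#' @param trend optional precomputed [trend_map()] result.
#' @return data frame: `region`, `n_pixels`, `slope` (of the region-mean
#'   series), `z`, `sig_class`, `pct_sig`, `pct_sig_advancing`,
#'   `pct_sig_delaying`.
#' @export
region_summary <- function(metric, years, mask, trend = NULL) {
  stopifnot(all(dim(mask) == dim(metric)[2:3]))
  trend <- trend %||% trend_map(metric, years)
  regions <- sort(unique(mask[!is.na(mask)]))
  rows <- lapply(regions, function(r) {
    sel <- !is.na(mask) & mask == r
    n_pix <- sum(sel)
    if (n_pix == 0) {
      return(data.frame(region = r, n_pixels = 0L, slope = NA_real_,
                        z = NA_real_, sig_class = NA_character_,
                        pct_sig = NA_real_, pct_sig_advancing = NA_real_,
                        pct_sig_delaying = NA_real_))
    }
    series <- apply(metric, 1, function(sl) mean(sl[sel], na.rm = TRUE))
    series[is.nan(series)] <- NA_real_
    sl <- theil_sen(years, series)
    mk <- if (sum(!is.na(series)) >= 4) mann_kendall(series) else {
      list(z = NA_real_, sig_class = NA_character_)
    }
    sig_px <- trend$sig[sel]
    sl_px <- trend$slope[sel]
    is_sig <- !is.na(sig_px) & sig_px >= 1L
    n_sig <- sum(is_sig)
    data.frame(region = r, n_pixels = n_pix, slope = sl, z = mk$z,
               sig_class = mk$sig_class,
               pct_sig = 100 * n_sig / sum(!is.na(sig_px)),
               pct_sig_advancing =
                 if (n_sig) 100 * sum(sl_px[is_sig] < 0) / n_sig else NA_real_,
               pct_sig_delaying =
                 if (n_sig) 100 * sum(sl_px[is_sig] > 0) / n_sig else NA_real_)
  })
  do.call(rbind, rows)
}
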