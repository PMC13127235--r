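test_that("the harmonic fit represents band-limited series exactly", {
  t <- seq(1, 365, by = 8)
  y <- 0.3 + 0.2 * cos(2 * pi * t / 365)
  fit <- whants_fit(t, y, n_harmonics = 2, n_outer_iter = 1)
  expect_lt(max(abs(fit$fitted - y)), 1e-9)
  expect_equal(unname(fit$coef[2]), 0.2, tolerance = 1e-9)

  fitc <- whants_fit(t, rep(0.42, length(t)), n_harmonics = 3)
  expect_equal(unname(fitc$a0), 0.42, tolerance = 1e-9)
  expect_true(all(abs(fitc$coef[-1]) < 1e-9))
})

test_that("unit weights reproduce the ordinary least-squares solution", {
  set.seed(3)
  t <- seq(1, 365, by = 8)
  y <- 0.3 + 0.2 * sin(2 * pi * t / 365) + rnorm(length(t), 0, 0.05)
  fit_w <- whants_fit(t, y, weights = rep(1, length(t)),
                      n_harmonics = 2, n_outer_iter = 1)
  X <- cbind(1, cos(2 * pi * outer(t, 1:2) / 365),
             sin(2 * pi * outer(t, 1:2) / 365))
  beta <- qr.solve(X, y)
  expect_equal(unname(fit_w$coef), unname(beta), tolerance = 1e-9)
})

test_that("missing values and rank deficiency are handled", {
  t <- seq(1, 365, by = 8)
  y <- 0.3 + 0.2 * cos(2 * pi * t / 365)
  y[c(3, 10, 20)] <- NA
  fit <- whants_fit(t, y, n_harmonics = 2)
  expect_true(all(is.finite(fit$fitted)))
  expect_error(whants_fit(t[1:5], y[1:5], n_harmonics = 3,
                          label = "(3, 4)"),
               "too few usable points.*\\(3, 4\\)")
})

test_that("the envelope weight rule only moves weights down, with a floor", {
  v <- c(1, 2, 3, 4, 5)
  f <- c(1, 2, 3, 4, 5)
  w <- rep(1, 5)
  expect_equal(wtsm_update(v, f, w), w)  # all residuals zero

  # one point far below the curve among 20: beyond 3 residual SDs
  f2 <- as.numeric(1:20)
  v2 <- f2
  v2[4] <- f2[4] - 5
  r <- v2 - f2
  expect_gt(abs(r[4]), 3 * sd(r))
  w2 <- wtsm_update(v2, f2, rep(1, 20))
  expect_equal(w2[-4], rep(1, 19))  # at/above the curve: unchanged
  expect_equal(w2[4], 0.05)         # >= 3 residual SDs below: floor

  w3 <- wtsm_update(v2, f2, c(rep(1, 3), 0, rep(1, 16)))
  expect_equal(w3[4], 0)  # zero weights stay zero
  expect_true(all(w3 <= 1))
})

test_that("envelope iteration beats a single unweighted pass under
           negative contamination", {
  t <- composite_starts() + 3.5
  truth <- 0.1 + 0.5 * (plogis(0.2 * (t - 130)) +
                          plogis(-0.15 * (t - 285)) - 1)
  wins <- 0L
  for (s in 1:50) {
    set.seed(s)
    y <- truth + rnorm(46, 0, 0.02)
    hit <- runif(46) < 0.2
    y[hit] <- y[hit] - runif(sum(hit), 0.1, 0.3)
    rmse <- function(fit) sqrt(mean((fit$fitted - truth)^2))
    if (rmse(whants_fit(t, y, n_outer_iter = 3)) <
          rmse(whants_fit(t, y, n_outer_iter = 1))) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 45)
})

test_that("season division finds the peak, window and amplitude floor", {
  t <- seq(1, 365, by = 8)
  y <- 0.1 + 0.5 * exp(-((t - 200) / 60)^2)
  fit <- whants_fit(t, y, n_harmonics = 3)
  season <- divide_seasons(fit)
  expect_false(season$no_seasonality)
  expect_lt(abs(season$peak_doy - 200), 6)
  expect_lt(season$t_start, season$peak_doy)
  expect_gt(season$t_end, season$peak_doy)

  flat <- whants_fit(t, rep(0.3, length(t)))
  expect_true(divide_seasons(flat)$no_seasonality)
})

test_that("tangent-point ties break to the earliest day", {
  # two exactly tied maximum derivatives before the peak: the recovery
  # tangent must sit at the earlier one (and symmetrically for autumn)
  doy <- 1:11
  value <- c(0, 1, 2, 3, 4, 4.5, 4, 3, 2, 1, 0)
  deriv <- c(0.2, 1, 1, 0.8, 0.5, 0, -0.5, -1, -1, -0.8, -0.2)
  lines <- build_gu_lines(doy, value, deriv)
  expect_equal(lines$recovery$t, 2)
  expect_equal(lines$senescence$t, 8)
})

test_that("beck_init lands near the truth on generator output", {
  p <- beck_ref
  t <- composite_starts() + 3.5
  y <- beck_eval(p, t)$value
  init <- beck_init(t, y)
  expect_lt(abs(init$sos - p$sos), 8)
  expect_lt(abs(init$eos - p$eos), 8)
  expect_true(init$rsp > 0.01 && init$rsp <= 1)

  expect_warning(init2 <- beck_init(t, seq(0, 1, length.out = 46)),
                 "quartile")
  expect_true(all(is.finite(unlist(init2))))
  expect_error(beck_init(1:5, 1:5), "at least 10")
})

test_that("beck_fit recovers noise-free parameters to high precision", {
  p <- beck_ref
  t <- composite_starts() + 3.5
  y <- beck_eval(p, t)$value
  fit <- beck_fit(t, y, init = beck_init(t, y), window = c(60, 350))
  expect_true(fit$converged)
  expect_lt(abs(fit$par$mn - p$mn), 1e-3)
  expect_lt(abs(fit$par$mx - p$mx), 1e-3)
  expect_lt(abs(fit$par$sos - p$sos), 0.1)
  expect_lt(abs(fit$par$eos - p$eos), 0.1)
})

test_that("beck_fit median sos error stays within 2 days under noise", {
  p <- beck_ref
  t <- composite_starts() + 3.5
  clean <- beck_eval(p, t)$value
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    y <- clean + rnorm(46, 0, 0.02)
    fit <- suppressWarnings(
      beck_fit(t, y, init = beck_init(t, y), window = c(60, 350)))
    abs(fit$par$sos - p$sos)
  }, numeric(1))
  expect_lte(median(errs), 2)
})

test_that("beck_fit refuses under-determined inputs", {
  t <- c(100, 120, 140, 160, 180, 200)
  expect_error(beck_fit(t, rep(0.3, 6), init = beck_ref),
               "fewer than 7")
})

test_that("refitting model output returns the same parameters", {
  p <- beck_ref
  t <- seq(60, 350)
  y <- beck_eval(p, t)$value
  fit1 <- beck_fit(t, y, init = beck_init(t, y), window = c(60, 350))
  y2 <- beck_eval(fit1, t)$value
  fit2 <- beck_fit(t, y2, init = fit1$par, window = c(60, 350))
  expect_lt(max(abs(unlist(fit2$par) - unlist(fit1$par))), 1e-6)
})

test_that("beck_eval matches the closed-form value and derivative", {
  p <- beck_ref
  ev <- beck_eval(p, p$sos)
  expect_equal(ev$value, (p$mn + p$mx) / 2, tolerance = 1e-6)
  expect_equal(ev$deriv, (p$mx - p$mn) * p$rsp / 4, tolerance = 1e-6)
  expect_equal(beck_eval(p, -500)$value, p$mn, tolerance = 1e-9)
  expect_equal(beck_eval(p, 900)$value, p$mn, tolerance = 1e-9)
  # derivative agrees with a central finite difference everywhere
  t <- seq(60, 350, by = 0.5)
  ev2 <- beck_eval(p, t)
  fd <- (beck_eval(p, t + 1e-4)$value - beck_eval(p, t - 1e-4)$value) / 2e-4
  expect_equal(ev2$deriv, fd, tolerance = 1e-6)
})

test_that("fits are deterministic given identical inputs", {
  p <- beck_ref
  t <- composite_starts() + 3.5
  set.seed(11)
  y <- beck_eval(p, t)$value + rnorm(46, 0, 0.02)
  f1 <- beck_fit(t, y, init = beck_init(t, y), window = c(60, 350))
  f2 <- beck_fit(t, y, init = beck_init(t, y), window = c(60, 350))
  expect_identical(unlist(f1$par), unlist(f2$par))
})
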