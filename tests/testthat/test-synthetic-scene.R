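test_that("truth grids apply linear trends exactly and are reproducible", {
  cfg <- scene_config(ny = 3, nx = 3, years = 2000:2023,
                      truth = list(sos_trend = -0.5, jitter_sd = 0),
                      seed = 1)
  tr <- make_truth(cfg)
  first <- tr[tr$year == 2000, ]
  last <- tr[tr$year == 2023, ]
  expect_equal(last$sos - first$sos, rep(-0.5 * 23, 9))

  cfg0 <- scene_config(ny = 3, nx = 3, years = 2000:2002,
                       truth = list(jitter_sd = 0), seed = 1)
  tr0 <- make_truth(cfg0)
  for (y in 2001:2002) {
    expect_equal(tr0[tr0$year == y, -3], tr0[tr0$year == 2000, -3],
                 ignore_attr = TRUE)
  }

  expect_identical(make_truth(cfg), make_truth(cfg))
})

test_that("degenerate truth configurations error informatively", {
  expect_error(scene_config(ny = 0, nx = 5), "at least one pixel")
  cfg <- scene_config(ny = 2, nx = 2, years = 2000:2023,
                      truth = list(eos_trend = -6, jitter_sd = 0))
  expect_error(make_truth(cfg), "separation at pixel")
})

test_that("the LAI trajectory follows the double logistic", {
  tr <- data.frame(mn_lai = 0.2, mx_lai = 3, sos = 130, rsp = 0.2,
                   eos = 280, rau = 0.1, plateau_slope = 0)
  # logistic midpoint at t = sos (well-separated seasons)
  expect_equal(lai_series(tr, 130), (0.2 + 3) / 2, tolerance = 1e-5)
  # baseline asymptote far before sos
  expect_equal(lai_series(tr, 1), 0.2, tolerance = 1e-6)
  # mid-season value from independent logistic arithmetic
  expected <- 0.2 + 2.8 * (plogis(0.2 * (205 - 130)) +
                             plogis(-0.1 * (205 - 280)) - 1)
  expect_equal(lai_series(tr, 205), expected, tolerance = 1e-12)
  expect_equal(lai_series(tr, 205), 3.0, tolerance = 2e-3)
})

test_that("greendown slope acts only on the plateau and clips at baseline", {
  tr <- data.frame(mn_lai = 0.2, mx_lai = 3, sos = 130, rsp = 0.2,
                   eos = 280, rau = 0.1, plateau_slope = -0.01)
  flat <- within(tr, plateau_slope <- 0)
  expect_equal(lai_series(tr, 120), lai_series(flat, 120))
  mid <- 200  # inside (sos + 2/rsp, eos - 2/rau) = (140, 260)
  expect_equal(lai_series(tr, mid),
               lai_series(flat, mid) - 0.01 * (mid - 140),
               tolerance = 1e-12)
  steep <- within(tr, plateau_slope <- -1)
  expect_true(all(lai_series(steep, 140:260) >= 0.2))
})

test_that("reflectance inverts Beer's law and is exact with zero noise", {
  opt <- list(M_true = 0.7, DVIs_true = 0.09, c_lai2dvi = 0.5,
              red_base = 0.05, blue_base = 0.03)
  r0 <- reflectance_from_lai(0, opt, 0)
  expect_equal(r0$dvi, 0.09)
  r2 <- reflectance_from_lai(2, opt, 0)
  expect_equal(r2$dvi, 0.7 - 0.61 * exp(-1), tolerance = 1e-12)
  rbig <- reflectance_from_lai(500, opt, 0)
  expect_lt(rbig$dvi, 0.7)
  expect_equal(rbig$dvi, 0.7, tolerance = 1e-6)
  # invertibility: computing DVI back from the bands recovers the clean DVI
  expect_equal(compute_dvi(r2$nir, r2$red), r2$dvi, tolerance = 1e-12)
})

test_that("contamination is absent when disabled and total when forced", {
  cfg <- clean_config()
  sc <- simulate_scene(cfg)
  sc2 <- contaminate(sc, cfg, seed = 99)
  expect_identical(sc2$red, sc$red)
  expect_identical(sc2$qa, sc$qa)

  cfg_all <- scene_config(ny = 1, nx = 1, years = 2000, cloud_prob = 1,
                          cloud_qa_flag_prob = 1, snow_prob = 0, seed = 2)
  sc_all <- simulate_scene(cfg_all)
  expect_true(all(!sc_all$qa))
})

test_that("cloud contamination biases the DVI negative", {
  cfg <- scene_config(ny = 4, nx = 4, years = 2000, noise_sd = 0,
                      cloud_prob = 0.5, cloud_qa_flag_prob = 1,
                      snow_prob = 0, seed = 3)
  clean <- simulate_scene(scene_config(ny = 4, nx = 4, years = 2000,
                                       noise_sd = 0, cloud_prob = 0,
                                       snow_prob = 0, seed = 3))
  dirty <- simulate_scene(cfg)
  cloud_days <- !dirty$qa
  expect_gt(sum(cloud_days), 1000)
  d_clean <- compute_dvi(clean$nir, clean$red)[cloud_days]
  d_dirty <- compute_dvi(dirty$nir, dirty$red)[cloud_days]
  expect_lt(mean(d_dirty), mean(d_clean))
  # mean depression close to the configured bias magnitude
  expect_equal(mean(d_clean - d_dirty), 0.15, tolerance = 0.02)
})

test_that("snow days have near-zero DVI and bright visible bands", {
  cfg <- scene_config(ny = 2, nx = 2, years = 2000, noise_sd = 0,
                      cloud_prob = 0, snow_prob = 1,
                      snow_qa_miss_prob = 0, snow_window = c(330, 60),
                      seed = 4)
  sc <- simulate_scene(cfg)
  in_win <- sc$doy >= 330 | sc$doy <= 60
  snowy <- array(in_win, dim = dim(sc$qa))
  expect_true(all(!sc$qa[snowy]))
  expect_true(all(abs(compute_dvi(sc$nir, sc$red)[snowy]) < 0.1))
  expect_true(all(sc$red[snowy] > 0.5))
})

test_that("GPP/SIF proxies lead the structural autumn decline", {
  tr <- data.frame(mn_lai = 0.2, mx_lai = 3, sos = 130, rsp = 0.2,
                   eos = 280, rau = 0.15, plateau_slope = 0)
  doy <- 1:365
  lai <- lai_series(tr, doy)
  sg <- list(lue = 8, k_sif = 0.05, autumn_lead_days = 0, noise_sd = 0)

  # degenerate lead: steepest declines coincide
  fl0 <- simulate_sif_gpp(lai, tr, sg, doy, seed = 1)
  d_lai <- which.min(diff(lai))
  expect_lte(abs(which.min(diff(fl0$gpp)) - d_lai), 1)

  # 20-day lead: steepest GPP decline precedes steepest LAI decline
  sg$autumn_lead_days <- 20
  fl20 <- simulate_sif_gpp(lai, tr, sg, doy, seed = 1)
  expect_lte(abs((d_lai - which.min(diff(fl20$gpp))) - 20), 2)

  # zero light-use efficiency: GPP identically zero, SIF pure noise
  sg0 <- list(lue = 0, k_sif = 0.05, autumn_lead_days = 20, noise_sd = 0.3)
  flz <- simulate_sif_gpp(lai, tr, sg0, doy, seed = 1)
  expect_true(all(flz$gpp == 0))
  expect_true(all(flz$sif >= 0))

  # a lead reaching before sos is rejected
  sg_bad <- list(lue = 8, k_sif = 0.05, autumn_lead_days = 160,
                 noise_sd = 0)
  expect_error(simulate_sif_gpp(lai, tr, sg_bad, doy), "before sos")
})

test_that("identical config and seed give bit-identical scenes", {
  cfg <- tiny_config()
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$red, s2$red)
  expect_identical(s1$qa, s2$qa)
  expect_identical(s1$sif, s2$sif)
  expect_identical(s1$truth, s2$truth)
})

test_that("PPI computed with the generator's optics is linear in LAI", {
  cfg <- clean_config()
  sc <- simulate_scene(cfg)
  lai <- lai_series(sc$truth[1, ], 1:365)
  dvi <- compute_dvi(sc$nir[, 1, 1], sc$red[, 1, 1])
  K <- 1.3
  ppi <- compute_ppi(dvi, M = 0.7, K = K, DVIs = 0.09, eps = 0)
  expect_equal(ppi, K * 0.5 * lai, tolerance = 1e-9)
})

test_that("scene truth metrics are ordered UD < SD < DD0 < RD", {
  sc <- simulate_scene(tiny_config())
  with(sc$truth, {
    expect_true(all(UD < SD))
    expect_true(all(SD < DD0))
    expect_true(all(DD0 < RD))
  })
})
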