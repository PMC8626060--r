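# Synthetic regime design, reflectance model, cubes and growth records.

test_that("regime design reproduces the trial's application table", {
  d <- regime_design()
  expect_identical(d$regime, paste0("N", 1:6))
  expect_equal(d$total, c(145.6, 109.2, 91, 72.8, 54.6, 36.4))
  expect_equal(d$percent, c(160, 120, 100, 80, 60, 40))
  expect_equal(d$total, d$basal + d$top1 + d$top2)
  expect_equal(d$percent / 100, d$total / 91, tolerance = 1e-12)
})

test_that("zero pigment contents leave only floor + structural reflectance", {
  p <- sim_params(cab_n1 = c(flag_leaf = 0, second_leaf = 0, spike = 0),
                  cab_n6 = c(flag_leaf = 0, second_leaf = 0, spike = 0),
                  ccar_slope = 0, ccar_base = 0, cw = 0)
  r <- leaf_reflectance_model(p, "N1", 0.5, "flag_leaf")
  pnir <- p$pnir_n1[["flag_leaf"]]
  expected <- p$floor + (p$struct_base + (pnir - p$struct_base) *
                           plogis((p$grid - p$re_center) / p$re_width))
  expect_equal(r, expected, tolerance = 1e-12)
})

test_that("more chlorophyll darkens the visible range and spares the NIR", {
  p <- sim_params()
  cabs <- seq(0.5, 6, by = 0.5)
  grid <- p$grid
  vis <- grid >= 400 & grid <= 700
  spectra <- sapply(cabs, function(cb) {
    pi <- sim_params(cab_n1 = c(flag_leaf = cb, second_leaf = cb, spike = cb),
                     cab_n6 = c(flag_leaf = cb, second_leaf = cb, spike = cb))
    leaf_reflectance_model(pi, "N1", 0.5, "flag_leaf")
  })
  # non-increasing in Cab at every visible band
  expect_true(all(apply(spectra[vis, ], 1, function(x) all(diff(x) <= 1e-12))))
  b670 <- nearest_band(grid, 670)
  expect_true(all(diff(spectra[b670, ]) < 0))
  b900 <- nearest_band(grid, 900)
  expect_equal(max(abs(diff(spectra[b900, ]))), 0, tolerance = 1e-6)
})

test_that("nitrogen deficiency raises the green peak", {
  p <- sim_params()
  b550 <- nearest_band(p$grid, 550)
  r1 <- leaf_reflectance_model(p, "N1", 0.5, "flag_leaf")[b550]
  r6 <- leaf_reflectance_model(p, "N6", 0.5, "flag_leaf")[b550]
  expect_gt(r6, r1)
})

test_that("model reflectance stays inside (0, 1)", {
  p <- sim_params()
  for (org in c("flag_leaf", "second_leaf", "spike")) {
    for (rg in paste0("N", 1:6)) {
      r <- leaf_reflectance_model(p, rg, c(0, 0.25, 0.5, 0.75, 1), org)
      expect_true(all(r > 0 & r < 1))
    }
  }
})

test_that("cube simulation is deterministic given the seed", {
  p <- sim_params(cube_size = c(48, 48))
  a <- simulate_leaf_cube(p, "N3", "second_leaf", 125, seed = 99)
  b <- simulate_leaf_cube(p, "N3", "second_leaf", 125, seed = 99)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$labels$labels, b$labels$labels)
  c2 <- simulate_leaf_cube(p, "N3", "second_leaf", 125, seed = 100)
  expect_false(identical(a$cube$values, c2$cube$values))
})

test_that("noise-free cubes have identical spectra at equal axis position", {
  p <- sim_params(cube_size = c(48, 48),
                  glint_sigma = c(`105` = 0, `125` = 0),
                  pixel_noise_sd = 0, plant_cv = 0)
  sim <- simulate_leaf_cube(p, "N2", "flag_leaf", 105, seed = 1)
  v <- sim$cube$values
  row <- 24  # all foreground pixels of one row share s
  fgcols <- which(sim$labels$labels[row, ] > 0)
  expect_gt(length(fgcols), 3)
  for (cc in fgcols[-1]) {
    expect_identical(v[row, cc, ], v[row, fgcols[1], ])
  }
})

test_that("unknown organ and bad angle are rejected", {
  p <- sim_params()
  expect_error(simulate_leaf_cube(p, "N1", "stem", 105), "organ")
  expect_error(simulate_leaf_cube(p, "N1", "spike", 90), "angle")
})

test_that("zero-CV growth records hit the regime means exactly", {
  p <- sim_params()
  g <- simulate_growth_records(p, n_per_regime = 4, cv = 0, seed = 1)
  n1 <- g[g$regime == "N1", ]; n6 <- g[g$regime == "N6", ]
  expect_true(all(n6$leaf_n == 1.2))
  expect_true(all(n1$leaf_n == 2.1))
  expect_equal(100 * mean(n6$seed_weight) / mean(n1$seed_weight), 44.9)
  expect_equal(100 * mean(n6$lai) / mean(n1$lai), 44.1)
  expect_equal(100 * mean(n6$height) / mean(n1$height), 85.6)
  expect_equal(100 * mean(n6$spad) / mean(n1$spad), 64.9)
  n3 <- g[g$regime == "N3", ]
  expect_equal(mean(n6$seed_weight) / mean(n3$seed_weight), 0.54)
})

test_that("growth sampling concentrates on the mean as n grows", {
  p <- sim_params()
  g <- simulate_growth_records(p, n_per_regime = 1000, cv = 0.06, seed = 5)
  m <- mean(g$leaf_n[g$regime == "N1"])
  expect_lt(abs(m - 2.1), 0.02)
  expect_true(all(g$height > 0))
  expect_error(simulate_growth_records(p, 4, cv = -1), "cv")
  expect_error(simulate_growth_records(p, 1), "n_per_regime")
})

test_that("visible-ratio calibration is a fixed point at the current ratio", {
  p <- sim_params()
  cur <- measure_visible_ratio(p, "flag_leaf")
  pc <- calibrate_visible_ratio(p, "flag_leaf", target_ratio = cur)
  expect_equal(pc$cab_n1[["flag_leaf"]], p$cab_n1[["flag_leaf"]], tolerance = 0.02)
  expect_equal(measure_visible_ratio(pc, "flag_leaf"), cur, tolerance = 2e-4)
})

test_that("calibration hits its target and matches a grid-search oracle", {
  p <- sim_params()
  pc <- calibrate_visible_ratio(p, "flag_leaf", target_ratio = 0.808)
  expect_equal(measure_visible_ratio(pc, "flag_leaf"), 0.808, tolerance = 1e-3)
  # brute-force oracle over a fine Cab grid
  cabs <- seq(p$cab_n6[["flag_leaf"]] + 1e-3, 10, length.out = 2000)
  ratios <- sapply(cabs, function(cb) {
    pi <- p; pi$cab_n1[["flag_leaf"]] <- cb
    measure_visible_ratio(pi, "flag_leaf")
  })
  best <- cabs[which.min(abs(ratios - 0.808))]
  expect_equal(pc$cab_n1[["flag_leaf"]], best, tolerance = 0.01)
})

test_that("unreachable calibration targets report the achievable range", {
  p <- sim_params()
  expect_error(calibrate_visible_ratio(p, "flag_leaf", target_ratio = 0.9999),
               "achievable range")
})

test_that("area-weighted model mean matches a rendered noise-free cube", {
  p <- sim_params(cube_size = c(64, 64),
                  glint_sigma = c(`105` = 0, `125` = 0),
                  pixel_noise_sd = 0, plant_cv = 0)
  sim <- simulate_leaf_cube(p, "N1", "second_leaf", 105, seed = 2)
  measured <- region_mean_spectrum(sim$cube, sim$labels, "all")$reflectance
  model <- mean_leaf_spectrum(p, "N1", "second_leaf")$reflectance
  sel <- p$grid >= 500 & p$grid <= 700
  expect_equal(mean(measured[sel]), mean(model[sel]), tolerance = 0.01)
})
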