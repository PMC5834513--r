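test_that("mixed-layer depth interpolates the temperature threshold", {
  prof <- tibble::tibble(depth_m = c(0, 40, 60), temp_C = c(28, 28, 26))
  # 27.2 degrees falls 8/20 of the way from 40 m to 60 m
  expect_equal(mixed_layer_depth(prof, delta_t = 0.8), 48)

  iso <- tibble::tibble(depth_m = c(0, 50, 100), temp_C = c(25, 25, 25))
  expect_true(is.na(mixed_layer_depth(iso)))

  # threshold met exactly at a sample depth: no interpolation
  exact <- tibble::tibble(depth_m = c(0, 30, 80), temp_C = c(29, 28.2, 24))
  expect_equal(mixed_layer_depth(exact, delta_t = 0.8), 30)

  expect_error(mixed_layer_depth(tibble::tibble(depth_m = 0, temp_C = 28)),
               class = "n15rates_invalid_profile")
  bad <- tibble::tibble(depth_m = c(10, 5), temp_C = c(25, 26))
  expect_error(mixed_layer_depth(bad), class = "n15rates_invalid_profile")
})

test_that("nitracline midpoint locates the steepest-gradient range", {
  z <- seq(0, 200, by = 5)
  logi <- tibble::tibble(depth_m = z, no3 = 30 / (1 + exp(-(z - 70) / 8)))
  nc <- nitracline(logi)
  expect_lt(abs(nc$nitracline_depth - 70), 2.5)
  expect_equal(nc$nitracline_depth,
               (nc$nitracline_top + nc$nitracline_bottom) / 2)

  # eutrophic coastal case: nitrate high at every depth, no nitracline
  set.seed(2)
  flat <- tibble::tibble(depth_m = z, no3 = 12 + rnorm(length(z), 0, 0.02))
  expect_true(is.na(nitracline(flat)$nitracline_depth))

  # exactly linear increase: the tie spans the full profile
  lin <- tibble::tibble(depth_m = z, no3 = 0.1 * z)
  nc_lin <- nitracline(lin)
  expect_equal(nc_lin$nitracline_top, 0)
  expect_equal(nc_lin$nitracline_bottom, 200)
  expect_equal(nc_lin$nitracline_depth, 100)
})

test_that("nitracline detection is equivariant under depth translation", {
  z <- seq(0, 200, by = 5)
  base <- tibble::tibble(depth_m = z, no3 = 30 / (1 + exp(-(z - 70) / 8)))
  shifted <- tibble::tibble(depth_m = z + 15, no3 = base$no3)
  expect_equal(nitracline(shifted)$nitracline_depth,
               nitracline(base)$nitracline_depth + 15)
})

test_that("euphotic depth follows the exponential light model", {
  out <- euphotic_depth(k = 0.06)
  expect_equal(out$euphotic_depth, log(1000) / 0.06, tolerance = 1e-12)
  expect_equal(out$euphotic_depth, 115.1, tolerance = 1e-3)

  # the full light level is at the surface by definition
  expect_equal(euphotic_depth(k = 0.5, fraction = 1)$euphotic_depth, 0)

  # exact exponential profile: k recovered to machine-level accuracy
  z <- seq(0, 150, by = 10)
  prof <- tibble::tibble(depth_m = z, par = 100 * exp(-0.05 * z))
  fit <- euphotic_depth(prof)
  expect_equal(fit$attenuation_k, 0.05, tolerance = 1e-9)
  expect_equal(fit$euphotic_depth, log(1000) / 0.05, tolerance = 1e-6)

  # strictly decreasing in k
  ks <- c(0.03, 0.05, 0.07, 0.1)
  depths <- vapply(ks, function(k) euphotic_depth(k = k)$euphotic_depth,
                   numeric(1))
  expect_true(all(diff(depths) < 0))

  dark <- tibble::tibble(depth_m = z, par = 100 * exp(0.01 * z))
  expect_error(euphotic_depth(dark), class = "n15rates_invalid_optics")
})

test_that("extremum layers find PNM, DCM and the nitrate/silicate peak", {
  z <- seq(0, 200, by = 5)
  prof <- tibble::tibble(
    depth_m = z,
    no2 = 5 + 200 * exp(-(z - 85)^2 / (2 * 12^2)),
    chl_fluor = 0.05 + exp(-(z - 75)^2 / (2 * 15^2)),
    no3 = 30 / (1 + exp(-(z - 70) / 8)),
    sio4 = 1 + 28 / (1 + exp(-(z - 80) / 10))
  )
  ext <- extremum_layers(prof)
  expect_equal(ext$dcm_depth, 75)
  expect_equal(ext$pnm_depth, 85)
  expect_false(ext$pnm_boundary)
  expect_true(ext$no3_si_ratio_max_depth >= 0 &&
                ext$no3_si_ratio_max_depth <= 200)

  # monotone nitrite: the maximum sits on the boundary and is flagged
  mono <- tibble::tibble(depth_m = z, no2 = z * 0.1)
  expect_true(extremum_layers(mono)$pnm_boundary)

  # zero silicate excluded from the ratio
  zdiv <- tibble::tibble(depth_m = c(0, 10, 20),
                         no3 = c(1, 5, 2), sio4 = c(1, 0, 1))
  expect_equal(extremum_layers(zdiv)$no3_si_ratio_max_depth, 20)

  flat <- tibble::tibble(depth_m = z, chl_fluor = rep(1, length(z)))
  expect_true(is.na(extremum_layers(flat)$dcm_depth))
})

test_that("transition depth needs a persistent crossover", {
  z <- seq(0, 150, by = 5)
  up <- tibble::tibble(depth_m = z, rate = exp(-(z - 30)^2 / (2 * 25^2)))
  # anchor nitrification to cross uptake exactly at 62 m
  u62 <- exp(-(62 - 30)^2 / (2 * 25^2))
  nf <- tibble::tibble(
    depth_m = z,
    rate = u62 / exp(-(62 - 110)^2 / (2 * 30^2)) *
      exp(-(z - 110)^2 / (2 * 30^2))
  )
  td <- transition_depth(up, nf)
  expect_equal(td$transition_status, "transition")
  expect_lt(abs(td$transition_depth - 62), 2.5)

  # nitrification dominant from the surface down
  dom <- tibble::tibble(depth_m = z, rate = up$rate * 2 + 1)
  expect_equal(transition_depth(up, dom)$transition_status,
               "surface_dominated")

  # co-occurring comparable rates with single-sample flips: no transition
  set.seed(9)
  a <- tibble::tibble(depth_m = z, rate = 1 + 0.05 * (seq_along(z) %% 2))
  b <- tibble::tibble(depth_m = z, rate = 1 + 0.05 * ((seq_along(z) + 1) %% 2))
  expect_equal(transition_depth(a, b)$transition_status, "co_occurring")

  expect_error(
    transition_depth(up[1, ], nf[1, ]),
    class = "n15rates_insufficient_overlap"
  )
})

test_that("transition interpolation handles mismatched grids", {
  zf <- seq(0, 150, by = 5)
  zc <- seq(0, 150, by = 15)
  up <- tibble::tibble(depth_m = zf, rate = pmax(0, 2 - 0.03 * zf))
  nf <- tibble::tibble(depth_m = zc, rate = 0.03 * zc)
  td <- transition_depth(up, nf)
  # lines 2 - 0.03 z and 0.03 z cross at z = 33.33
  expect_equal(td$transition_depth, 100 / 3, tolerance = 0.01)
})

test_that("light/dark comparison reproduces the textbook t statistic", {
  same <- c(1, 1, 1)
  out <- paired_light_dark_test(same, same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)

  # hand-computed pooled two-sample t
  x <- c(2.1, 2.5, 2.3, 2.7)
  y <- c(1.6, 1.8, 1.5, 1.9)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  out2 <- paired_light_dark_test(x, y)
  expect_equal(out2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out2$p.value, 2 * stats::pt(-abs(t_hand), 6),
               tolerance = 1e-12)
  expect_equal(out2$mean_difference, mean(x) - mean(y))

  expect_error(paired_light_dark_test(1, c(1, 2)),
               class = "n15rates_insufficient_replicates")
})

test_that("rate-covariate regressions report OLS R-squared", {
  set.seed(14)
  z <- seq(0, 100, by = 5)
  prof <- tibble::tibble(depth_m = z, no3 = 0.2 * z,
                         rate = 1 + 0.4 * z + rnorm(length(z), 0, 0.01))
  out <- rate_correlations(prof, "rate", "no3")
  expect_gt(out$r_squared, 0.999)
  expect_equal(out$slope, 2, tolerance = 0.01)
})

test_that("all detected features lie inside the sampled depth span", {
  for (seed in 1:5) {
    st <- simulate_station(station_truth(), noise = TRUE, seed = seed)
    f <- profile_features(st)
    depths <- c(f$mld, f$nitracline_depth, f$pnm_depth, f$dcm_depth,
                f$transition_depth)
    depths <- depths[!is.na(depths)]
    expect_true(all(depths >= min(st$depth_m) & depths <= max(st$depth_m)))
  }
})
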