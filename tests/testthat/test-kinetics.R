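test_that("the saturation curve behaves as a rectangular hyperbola", {
  expect_equal(mm_rate(10, 250, 250), 5)           # half saturation
  expect_equal(mm_rate(22, 300, 2000), 19.13043, tolerance = 1e-6)
  expect_equal(mm_rate(10, 250, 1e12), 10, tolerance = 1e-6) # saturation
  s <- seq(0, 5000, by = 50)
  v <- mm_rate(22, 300, s)
  expect_true(all(v <= 22))
  expect_true(all(diff(v) > 0))          # monotone
  expect_true(all(diff(diff(v)) < 0))    # concave
  # the affinity is the initial slope
  expect_equal(mm_rate(22, 300, 1e-6) / 1e-6, 22 / 300, tolerance = 1e-6)
})

test_that("noise-free four-level designs are recovered exactly", {
  s <- c(30, 120, 520, 2020)
  series <- data.frame(s_total = s, rate = mm_rate(22, 300, s))
  fit <- fit_mm(series)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 22, tolerance = 1e-6)
  expect_equal(fit$ks, 300, tolerance = 1e-6)
  expect_equal(fit$alpha, fit$vmax / fit$ks)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("the fit agrees with a brute-force grid search", {
  set.seed(21)
  s <- rep(c(30, 120, 520, 2020), each = 2)
  r <- mm_rate(18, 420, s) * exp(rnorm(length(s), 0, 0.05))
  fit <- fit_mm(data.frame(s_total = s, rate = r))
  # independent oracle: exhaustive search on a lattice around the truth
  vgrid <- seq(10, 30, by = 0.05)
  kgrid <- seq(150, 900, by = 1)
  ssr <- outer(vgrid, kgrid, function(v, k) {
    vapply(seq_along(v), function(i) {
      sum((r - v[i] * s / (k[i] + s))^2)
    }, numeric(1))
  })
  best <- arrayInd(which.min(ssr), dim(ssr))
  expect_equal(fit$vmax, vgrid[best[1]], tolerance = 0.05 / 10)
  expect_equal(fit$ks, kgrid[best[2]], tolerance = 1 / 150)
  expect_lte(sum((r - predict(fit))^2), min(ssr) + 1e-9)
})

test_that("fit is invariant to point order and replicate duplication", {
  set.seed(5)
  s <- c(30, 120, 520, 2020)
  series <- data.frame(s_total = s,
                       rate = mm_rate(22, 300, s) * exp(rnorm(4, 0, 0.03)))
  fit <- fit_mm(series)
  shuffled <- fit_mm(series[c(3, 1, 4, 2), ])
  doubled <- fit_mm(rbind(series, series))
  expect_equal(shuffled$vmax, fit$vmax, tolerance = 1e-8)
  expect_equal(shuffled$ks, fit$ks, tolerance = 1e-8)
  expect_equal(doubled$vmax, fit$vmax, tolerance = 1e-6)
  expect_equal(doubled$ks, fit$ks, tolerance = 1e-6)
})

test_that("unidentifiable designs are rejected", {
  expect_error(fit_mm(data.frame(s_total = rep(100, 4), rate = 1:4)),
               class = "n15rates_unidentifiable_design")
  expect_error(fit_mm(data.frame(s_total = c(10, 10, 100, 100),
                                 rate = c(1, 1.1, 2, 2.1))),
               class = "n15rates_unidentifiable_design")
  expect_error(fit_mm(data.frame(s_total = c(-5, 10, 100), rate = 1:3)),
               class = "n15rates_invalid_series")
})

test_that("parameter recovery under 5% noise has small median bias", {
  tr <- incubation_truth(vmax = 22, ks = 300, ambient_substrate = 20)
  est <- purrr::map_dfr(1:60, function(i) {
    series <- simulate_kinetic_experiment(tr, noise = TRUE,
                                          rate_noise_cv = 0.05,
                                          seed = 5000 + i)
    glance(fit_mm(series))
  })
  expect_lt(abs(stats::median(est$vmax / 22 - 1)), 0.10)
  expect_lt(abs(stats::median(est$ks / 300 - 1)), 0.10)
  expect_true(all(est$converged))
})

test_that("poorly spanned designs inflate the ks uncertainty", {
  tr <- incubation_truth(vmax = 22, ks = 300, ambient_substrate = 20)
  rel_se <- function(levels, seed) {
    series <- simulate_kinetic_experiment(tr, levels = levels, noise = TRUE,
                                          rate_noise_cv = 0.05, seed = seed)
    fit <- fit_mm(series)
    fit$ks_se / fit$ks
  }
  seeds <- 1:15
  wide <- vapply(seeds, function(s) rel_se(c(10, 100, 500, 2000), s),
                 numeric(1))
  narrow <- vapply(seeds, function(s) rel_se(c(10, 30, 60, 100), s),
                   numeric(1))
  # paired simulations: every level stays below ks = 300 in the narrow
  # design, so ks is barely identified there
  expect_gt(stats::median(narrow, na.rm = TRUE),
            stats::median(wide, na.rm = TRUE))
})

test_that("affinity is vmax/ks and ranks competitive ability", {
  s <- c(10, 100, 500, 2000)
  fit_a <- fit_mm(data.frame(s_total = s, rate = mm_rate(10, 100, s)))
  fit_b <- fit_mm(data.frame(s_total = s, rate = mm_rate(20, 100, s)))
  expect_equal(affinity(fit_a), 0.1, tolerance = 1e-6)
  expect_equal(affinity(fit_b), 2 * affinity(fit_a), tolerance = 1e-6)
  # the higher-affinity process wins the low-substrate comparison
  expect_gt(affinity(fit_b), affinity(fit_a))
})

test_that("kinetic rate at ambient substrate evaluates the fitted curve", {
  s <- c(10, 100, 500, 2000)
  fit <- fit_mm(data.frame(s_total = s, rate = mm_rate(22, 300, s)))
  expect_equal(rate_kinetic_at(fit, 0)$value, 0)
  expect_equal(rate_kinetic_at(fit, 20)$value, 1.375, tolerance = 1e-4)
  ci <- c(5, 50, 500)
  expect_equal(rate_kinetic_at(fit, ci)$value,
               mm_rate(fit$vmax, fit$ks, ci))
})

test_that("estimator comparison reproduces the closed-form tracer bias", {
  tr <- incubation_truth(vmax = 22, ks = 1000, ambient_substrate = 20)
  fit <- fit_mm(simulate_kinetic_experiment(tr, noise = FALSE))

  # no tracer: nothing to overestimate (substrate pre-labelled so the
  # isotope balance stays informative; 15N accumulates at rate * f15)
  r_true <- mm_rate(22, 1000, 20)
  n0 <- natural_abundance()
  ct <- 1000 + r_true * 12
  rec0 <- make_record(c0 = 1000, n0 = n0, ct = ct,
                      nt = (1000 * n0 + r_true * 0.49 * 12) / ct,
                      ci = 20, spike = 0, f15 = 0.49, t_h = 12)
  cmp0 <- compare_estimators(rec0, fit)
  expect_equal(cmp0$overestimation_factor, 1, tolerance = 1e-6)

  # Ci = 20, Ct = 20, Ks = 1000: factor (Ci+Ct)(Ks+Ci)/[Ci(Ks+Ci+Ct)]
  rec <- simulate_incubation(tr, spike = 20, replicates = 1, light = "dark",
                             noise = FALSE)
  cmp <- suppressWarnings(compare_estimators(rec, fit))
  closed <- (40 * 1020) / (20 * 1040)
  expect_equal(cmp$overestimation_factor, closed, tolerance = 1e-4)
  expect_true(cmp$first_order)
})

test_that("tracer bias shrinks monotonically with ambient substrate", {
  tr0 <- incubation_truth(vmax = 22, ks = 1000)
  fit <- fit_mm(simulate_kinetic_experiment(tr0, noise = FALSE))
  ci <- c(5, 20, 50, 150, 400, 650)
  factors <- vapply(ci, function(c0) {
    tr <- incubation_truth(vmax = 22, ks = 1000, ambient_substrate = c0)
    rec <- simulate_incubation(tr, spike = 50, replicates = 1,
                               light = "dark", noise = FALSE)
    suppressWarnings(compare_estimators(rec, fit))$overestimation_factor
  }, numeric(1))
  expect_true(all(diff(factors) < 0))
  expect_gt(factors[1], factors[length(factors)])
})

test_that("tidy, glance and autoplot expose the fit", {
  s <- c(10, 100, 500, 2000)
  fit <- fit_mm(data.frame(s_total = s, rate = mm_rate(22, 300, s)))
  td <- tidy(fit)
  expect_equal(td$term, c("vmax", "ks", "alpha"))
  expect_equal(td$estimate[1], fit$vmax)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_output(print(fit), "vmax")
})
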