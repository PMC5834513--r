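# Synthetic incubation and station generators with known ground truth.
#
# Generated tables satisfy the invariants of the consuming functions and
# carry their generating parameters in a "truth" attribute (see sim_truth()),
# so every pipeline stage can be exercised in parameter-recovery tests
# without any field data.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Ground truth for a simulated incubation
#'
#' Bundles the Michaelis-Menten truth and ambient conditions of one
#' simulated water sample. Defaults describe an oligotrophic surface sample:
#' ambient ammonium of 20 nmol N per litre inside the observed 1-74 nmol
#' span, a product (NOx or PON) pool of 1000 nmol N per litre at natural
#' abundance, and nitrification reduced by half in the light.
#'
#' @param process `"nh4_oxidation"`, `"nh4_uptake"` or `"no3_uptake"`.
#' @param vmax,ks Michaelis-Menten truth (nmol N per litre per hour; nmol N
#'   per litre).
#' @param ambient_substrate ambient substrate concentration, nmol N per
#'   litre.
#' @param ambient_product initial product-pool concentration, nmol N per
#'   litre.
#' @param product_delta0 initial delta-15N of the product pool, permil.
#' @param light_inhibition multiplier in (0, 1] applied to nitrification
#'   rates in light incubations.
#' @param dark_uptake_factor multiplier applied to uptake rates in dark
#'   incubations (uptake is light-driven).
#' @param tracer_atom_frac 15N atom fraction of the tracer (default 0.98).
#' @param depth_m nominal sample depth.
#' @return a list of class `incubation_truth`.
#' @export
incubation_truth <- function(process = c("nh4_oxidation", "nh4_uptake",
                                         "no3_uptake"),
                             vmax = 22, ks = 300,
                             ambient_substrate = 20,
                             ambient_product = 1000,
                             product_delta0 = 0,
                             light_inhibition = 0.5,
                             dark_uptake_factor = 0.3,
                             tracer_atom_frac = 0.98,
                             depth_m = 25) {
  process <- match.arg(process)
  stopifnot(vmax > 0, ks > 0, ambient_substrate >= 0, ambient_product > 0,
            light_inhibition >= 0, light_inhibition <= 1,
            dark_uptake_factor >= 0,
            tracer_atom_frac > 0, tracer_atom_frac < 1)
  structure(
    list(process = process, vmax = vmax, ks = ks,
         ambient_substrate = ambient_substrate,
         ambient_product = ambient_product,
         product_delta0 = product_delta0,
         light_inhibition = light_inhibition,
         dark_uptake_factor = dark_uptake_factor,
         tracer_atom_frac = tracer_atom_frac,
         depth_m = depth_m),
    class = "incubation_truth"
  )
}

#' Ground truth of a simulated incubation or station
#'
#' @param x a table produced by [simulate_incubation()],
#'   [simulate_kinetic_experiment()] or [simulate_station()].
#' @return the truth record attached by the generator.
#' @export
sim_truth <- function(x) attr(x, "truth")

# light/dark multiplier on the true rate
light_factor <- function(truth, light) {
  if (truth$process == "nh4_oxidation") {
    ifelse(light == "light", truth$light_inhibition, 1)
  } else {
    ifelse(light == "light", 1, truth$dark_uptake_factor)
  }
}

#' Simulate a 15N tracer incubation
#'
#' Forward model of one spiked bottle incubation. The substrate labelling
#' f15 follows from exact mass balance of the ambient pool (natural
#' abundance) with the tracer spike; the transformation proceeds at the
#' constant rate `mm_rate(vmax, ks, ambient + spike)` (times the light/dark
#' factor), appropriate for short incubations with negligible substrate
#' depletion and isotope dilution; product 15N and total N accumulate by
#' exact mass balance over the duration. Optional analytical noise:
#' multiplicative on concentrations (CV `conc_cv`, default 3.5%) and
#' additive on delta-15N (SD `delta_sd`, default 0.2 permil).
#'
#' @param truth an [incubation_truth()].
#' @param spike final tracer concentration, nmol N per litre; default 20
#'   for oxidation and 10 for uptake processes.
#' @param duration incubation length in hours; default 12 for oxidation and
#'   3 for uptake.
#' @param replicates bottles per light condition.
#' @param light character vector of conditions to simulate.
#' @param noise add analytical noise?
#' @param conc_cv coefficient of variation of concentration measurements.
#' @param delta_sd standard deviation of delta-15N measurements, permil.
#' @param seed optional seed; the caller's RNG stream is restored afterwards.
#' @return a tibble of incubation records (see [calculate_rates()]) with
#'   the truth — including the true ambient-substrate rate per light
#'   condition — in `sim_truth()`.
#' @export
simulate_incubation <- function(truth, spike = NULL, duration = NULL,
                                replicates = 2, light = c("light", "dark"),
                                noise = TRUE, conc_cv = 0.035,
                                delta_sd = 0.2, seed = NULL) {
  stopifnot(inherits(truth, "incubation_truth"))
  if (is.null(spike)) {
    spike <- if (truth$process == "nh4_oxidation") 20 else 10
  }
  if (is.null(duration)) {
    duration <- if (truth$process == "nh4_oxidation") 12 else 3
  }
  stopifnot(duration > 0, spike >= 0, replicates >= 1)
  light <- match.arg(light, c("light", "dark"), several.ok = TRUE)
  with_seed(seed, {
    n_nat <- natural_abundance()
    ci <- truth$ambient_substrate
    total <- ci + spike
    f15 <- if (spike > 0) {
      (ci * n_nat + spike * truth$tracer_atom_frac) / total
    } else {
      n_nat
    }
    n0 <- delta_to_atom_fraction(truth$product_delta0)
    c0 <- truth$ambient_product
    grid <- tidyr::expand_grid(light = light, replicate = seq_len(replicates))
    lf <- light_factor(truth, grid$light)
    rate <- mm_rate(truth$vmax, truth$ks, total) * lf
    ct <- c0 + rate * duration
    nt <- (c0 * n0 + rate * f15 * duration) / ct
    rec <- tibble::tibble(
      depth_m = truth$depth_m,
      process = truth$process,
      light = grid$light,
      replicate = grid$replicate,
      t_h = duration,
      c0_product = c0,
      n0_product = n0,
      ct_product = ct,
      nt_product = nt,
      ci_substrate = ci,
      ct_tracer = spike,
      n_substrate = f15
    )
    if (noise) {
      k <- nrow(rec)
      noisy_conc <- function(x) x * exp(stats::rnorm(k, 0, conc_cv))
      noisy_af <- function(n) {
        delta_to_atom_fraction(
          atom_fraction_to_delta(n) + stats::rnorm(k, 0, delta_sd))
      }
      rec$c0_product <- noisy_conc(rec$c0_product)
      rec$ct_product <- noisy_conc(rec$ct_product)
      rec$n0_product <- noisy_af(rec$n0_product)
      rec$nt_product <- noisy_af(rec$nt_product)
    }
    truth_tbl <- tibble::tibble(
      light = grid$light, replicate = grid$replicate,
      true_rate_bulk = rate,
      true_rate_ambient = mm_rate(truth$vmax, truth$ks, ci) * lf,
      true_rate_linearized = rate * ci / total,
      f15 = f15, spike = spike, duration = duration
    )
    structure(rec, truth = c(truth, list(records = truth_tbl)))
  })
}

#' Simulate a Michaelis-Menten kinetic experiment
#'
#' One tracer incubation per enrichment level and replicate, following the
#' standard design of four 15N additions spanning 10-2000 nmol N per litre
#' into duplicate bottles. Rates are assembled from the noise-free product
#' 15N mass balance (the sum of the 15N and 14N accumulation rates, i.e.
#' the rate at total substrate concentration); measurement error is then
#' applied to the assembled rates as multiplicative noise with CV
#' `rate_noise_cv`.
#'
#' @param truth an [incubation_truth()].
#' @param levels tracer addition levels, nmol N per litre.
#' @param replicates bottles per level.
#' @param duration incubation hours.
#' @param light condition of the incubations (single value).
#' @param noise add rate noise?
#' @param rate_noise_cv coefficient of variation of the rate noise.
#' @param seed optional seed.
#' @return a tibble (`s_total`, `rate`, `level`, `replicate`, `depth_m`,
#'   `process`) ready for [fit_mm()], with the generating truth in
#'   `sim_truth()`.
#' @export
simulate_kinetic_experiment <- function(truth,
                                        levels = c(10, 100, 500, 2000),
                                        replicates = 2, duration = NULL,
                                        light = "dark", noise = TRUE,
                                        rate_noise_cv = 0.05, seed = NULL) {
  stopifnot(inherits(truth, "incubation_truth"), length(levels) >= 3)
  with_seed(seed, {
    series <- purrr::map_dfr(levels, function(lv) {
      rec <- simulate_incubation(truth, spike = lv, duration = duration,
                                 replicates = replicates, light = light,
                                 noise = FALSE)
      r15 <- rate_r15(rec)
      rate <- r15$value + rate_r14(rec, r15)$value
      tibble::tibble(
        depth_m = truth$depth_m,
        process = truth$process,
        level = lv,
        replicate = rec$replicate,
        s_total = truth$ambient_substrate + lv,
        rate = rate
      )
    })
    if (noise) {
      series$rate <- series$rate *
        exp(stats::rnorm(nrow(series), 0, rate_noise_cv))
    }
    structure(series, truth = truth)
  })
}

#' Ground truth for a simulated station
#'
#' Parameters of a stratified oligotrophic station: an isothermal mixed
#' layer over a linear thermocline, exponential light attenuation, a
#' sigmoidal (logistic) nitracline, Gaussian nitrite and chlorophyll maxima,
#' low ammonium, and unimodal ammonium-uptake and nitrification profiles —
#' uptake peaking in the sunlit layer, nitrification below — whose crossover
#' sits at the nitracline by default. The nitrification amplitude is derived
#' from `crossover_depth`, so the generated profiles cross exactly there.
#'
#' @param grid sampling depths, metres (strictly increasing).
#' @param surface_temp surface temperature, degrees C.
#' @param mld mixed-layer depth: the depth where temperature has dropped
#'   `mld_delta_t` below the surface value.
#' @param mld_delta_t temperature offset defining `mld`.
#' @param thermocline_slope temperature decrease below the mixed layer,
#'   degrees C per metre.
#' @param k PAR attenuation coefficient, per metre.
#' @param no3_deep deep nitrate concentration, micromol per litre.
#' @param nitracline_center,nitracline_width logistic nitracline inflection
#'   depth and scale, metres.
#' @param nh4_mean ambient ammonium, nmol N per litre.
#' @param pnm_depth,pnm_amplitude,pnm_width Gaussian primary nitrite
#'   maximum (m, nmol per litre, m).
#' @param dcm_depth,dcm_amplitude,dcm_width Gaussian deep chlorophyll
#'   maximum (m, relative fluorescence, m).
#' @param uptake_peak_depth,uptake_peak_rate,uptake_width Gaussian ammonium
#'   uptake profile (m, nmol N per litre per hour, m).
#' @param nitrif_peak_depth,nitrif_width Gaussian nitrification profile
#'   shape (its amplitude is set by the crossover).
#' @param crossover_depth depth where nitrification overtakes uptake, m.
#' @param temp_sd,par_cv,no3_cv,no2_cv,nh4_sdlog,chl_cv,rate_cv noise
#'   levels (additive SD for temperature, multiplicative CV or log-SD
#'   otherwise).
#' @return a list of class `station_truth`, including the implied
#'   `euphotic_depth` (0.1% light level).
#' @export
station_truth <- function(grid = seq(0, 200, by = 5),
                          surface_temp = 29, mld = 40, mld_delta_t = 0.8,
                          thermocline_slope = 0.12,
                          k = 0.06, no3_deep = 30,
                          nitracline_center = 70, nitracline_width = 8,
                          nh4_mean = 15,
                          pnm_depth = 85, pnm_amplitude = 200, pnm_width = 12,
                          dcm_depth = 75, dcm_amplitude = 1, dcm_width = 15,
                          uptake_peak_depth = 30, uptake_peak_rate = 0.6,
                          uptake_width = 25,
                          nitrif_peak_depth = 110, nitrif_width = 30,
                          crossover_depth = 70,
                          temp_sd = 0.01, par_cv = 0.05, no3_cv = 0.01,
                          no2_cv = 0.05, nh4_sdlog = 0.6, chl_cv = 0.05,
                          rate_cv = 0.10) {
  stopifnot(!is.unsorted(grid, strictly = TRUE), all(grid >= 0),
            mld > min(grid), mld < max(grid),
            crossover_depth > min(grid), crossover_depth < max(grid),
            nitracline_width > 0, k > 0, thermocline_slope > 0)
  structure(
    list(grid = grid, surface_temp = surface_temp, mld = mld,
         mld_delta_t = mld_delta_t, thermocline_slope = thermocline_slope,
         k = k, no3_deep = no3_deep,
         nitracline_center = nitracline_center,
         nitracline_width = nitracline_width,
         nh4_mean = nh4_mean,
         pnm_depth = pnm_depth, pnm_amplitude = pnm_amplitude,
         pnm_width = pnm_width,
         dcm_depth = dcm_depth, dcm_amplitude = dcm_amplitude,
         dcm_width = dcm_width,
         uptake_peak_depth = uptake_peak_depth,
         uptake_peak_rate = uptake_peak_rate, uptake_width = uptake_width,
         nitrif_peak_depth = nitrif_peak_depth, nitrif_width = nitrif_width,
         crossover_depth = crossover_depth,
         euphotic_depth = log(1000) / k,
         temp_sd = temp_sd, par_cv = par_cv, no3_cv = no3_cv,
         no2_cv = no2_cv, nh4_sdlog = nh4_sdlog, chl_cv = chl_cv,
         rate_cv = rate_cv),
    class = "station_truth"
  )
}

gaussian_peak <- function(z, center, width, amplitude) {
  amplitude * exp(-(z - center)^2 / (2 * width^2))
}

#' Simulate a station profile
#'
#' Generates a bottle/CTD table from a [station_truth()]: piecewise-linear
#' temperature (mixed layer then thermocline), exponential PAR, logistic
#' nitrate, Gaussian nitrite and chlorophyll maxima, low noisy ammonium, a
#' deep silicate increase, and unimodal uptake and nitrification rate
#' profiles crossing at the truth's crossover depth. With `noise = TRUE`,
#' seeded analytical noise is added to every series (temperature gets
#' additive sensor noise; concentrations, PAR, fluorescence and rates get
#' multiplicative log-normal noise, which keeps them positive).
#'
#' @param truth a [station_truth()].
#' @param noise add noise?
#' @param seed optional seed.
#' @return a station-profile tibble (`depth_m`, `temp_C`, `par`, `no3`,
#'   `no2`, `nh4`, `sio4`, `chl_fluor`, `nh4_uptake`, `nitrification`) with
#'   the truth in `sim_truth()`. `par` is percent of surface.
#' @export
simulate_station <- function(truth, noise = TRUE, seed = NULL) {
  stopifnot(inherits(truth, "station_truth"))
  with_seed(seed, {
    z <- truth$grid
    # temperature: isothermal to the kink, then linear; the kink depth is
    # placed so the delta-T threshold is crossed exactly at the true MLD
    kink <- truth$mld - truth$mld_delta_t / truth$thermocline_slope
    temp <- truth$surface_temp - pmax(0, z - kink) * truth$thermocline_slope
    par <- 100 * exp(-truth$k * z)
    no3 <- truth$no3_deep /
      (1 + exp(-(z - truth$nitracline_center) / truth$nitracline_width))
    no2 <- 5 + gaussian_peak(z, truth$pnm_depth, truth$pnm_width,
                             truth$pnm_amplitude)
    chl <- 0.05 + gaussian_peak(z, truth$dcm_depth, truth$dcm_width,
                                truth$dcm_amplitude)
    nh4 <- rep(truth$nh4_mean, length(z))
    sio4 <- 1 + 28 / (1 + exp(-(z - 80) / 10))
    uptake <- gaussian_peak(z, truth$uptake_peak_depth, truth$uptake_width,
                            truth$uptake_peak_rate)
    # anchor the nitrification amplitude so the two curves cross exactly at
    # the prescribed crossover depth
    u_at_cross <- gaussian_peak(truth$crossover_depth,
                                truth$uptake_peak_depth, truth$uptake_width,
                                truth$uptake_peak_rate)
    nitrif_amp <- u_at_cross /
      exp(-(truth$crossover_depth - truth$nitrif_peak_depth)^2 /
            (2 * truth$nitrif_width^2))
    nitrif <- gaussian_peak(z, truth$nitrif_peak_depth, truth$nitrif_width,
                            nitrif_amp)
    if (noise) {
      m <- length(z)
      lnoise <- function(x, cv) x * exp(stats::rnorm(m, 0, cv))
      temp <- temp + stats::rnorm(m, 0, truth$temp_sd)
      par <- lnoise(par, truth$par_cv)
      no3 <- lnoise(no3, truth$no3_cv)
      no2 <- lnoise(no2, truth$no2_cv)
      chl <- lnoise(chl, truth$chl_cv)
      nh4 <- pmin(74, pmax(1, nh4 * exp(stats::rnorm(m, 0, truth$nh4_sdlog))))
      sio4 <- lnoise(sio4, truth$no3_cv)
      uptake <- lnoise(uptake, truth$rate_cv)
      nitrif <- lnoise(nitrif, truth$rate_cv)
    }
    profile <- tibble::tibble(
      depth_m = z, temp_C = temp, par = par, no3 = no3, no2 = no2,
      nh4 = nh4, sio4 = sio4, chl_fluor = chl,
      nh4_uptake = uptake, nitrification = nitrif
    )
    structure(profile, truth = c(truth, list(nitrif_amplitude = nitrif_amp)))
  })
}
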