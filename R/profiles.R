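# Water-column feature detection on depth-indexed station profiles.
#
# A station profile is a data frame with a strictly increasing `depth_m`
# column (metres, positive downward, shallowest first) plus any of:
# temp_C, par (absolute or % of surface), no3, no2, nh4, sio4, chl_fluor,
# and rate columns such as nh4_uptake / nitrification.

validate_profile <- function(profile) {
  if (!"depth_m" %in% names(profile)) {
    rlang::abort("Profile needs a `depth_m` column.",
                 class = "n15rates_schema_error")
  }
  d <- profile$depth_m
  if (anyNA(d) || is.unsorted(d, strictly = TRUE)) {
    rlang::abort("`depth_m` must be strictly increasing with no missing values.",
                 class = "n15rates_invalid_profile")
  }
  invisible(profile)
}

#' Mixed-layer depth by temperature threshold
#'
#' The shallowest depth at which temperature falls `delta_t` degrees C below
#' the surface (shallowest) value, linearly interpolated between the
#' bracketing samples.
#'
#' @param profile station profile with `depth_m` and `temp_C`.
#' @param delta_t temperature offset defining the mixed-layer base
#'   (default 0.8 degrees C).
#' @return depth in metres, or `NA` when the threshold is never crossed
#'   (e.g. a fully mixed water column).
#' @export
mixed_layer_depth <- function(profile, delta_t = 0.8) {
  validate_profile(profile)
  stopifnot("temp_C" %in% names(profile), delta_t > 0)
  ok <- !is.na(profile$temp_C)
  d <- profile$depth_m[ok]
  temp <- profile$temp_C[ok]
  if (length(d) < 2) {
    rlang::abort("Need at least 2 temperature samples.",
                 class = "n15rates_invalid_profile")
  }
  target <- temp[1] - delta_t
  below <- which(temp <= target)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (temp[i] == target || i == 1) return(d[i])
  # linear interpolation between the last warmer sample and the crossing one
  d[i - 1] + (d[i] - d[i - 1]) * (temp[i - 1] - target) / (temp[i - 1] - temp[i])
}

#' Nitracline range and depth
#'
#' The nitracline is located from the vertical nitrate gradient on raw
#' adjacent sample pairs (no smoothing). The "steepest range" is the longest
#' contiguous run of pairs whose gradients all reach at least `contiguity`
#' (default 90%) of the maximum gradient (ties broken toward the run holding
#' the maximum, then toward the shallower run); the nitracline depth is the
#' midpoint (mean) of the range endpoints. When the maximum gradient does
#' not exceed `flatness_floor` there is no nitracline (the
#' eutrophic-coastal case where nitrate is high at all depths).
#'
#' @param profile station profile with `depth_m` and `no3`.
#' @param contiguity fraction of the maximum gradient a pair must reach to
#'   belong to the steepest range.
#' @param flatness_floor minimum gradient (concentration units per metre)
#'   for a nitracline to be declared; the default 0.05 (micromolar nitrate
#'   per metre) sits well above nutrient-analyzer noise on typical bottle
#'   spacings and well below real nitracline gradients.
#' @return a one-row tibble: `nitracline_top`, `nitracline_bottom`,
#'   `nitracline_depth` (all `NA` when no nitracline is present).
#' @export
nitracline <- function(profile, contiguity = 0.9, flatness_floor = 0.05) {
  validate_profile(profile)
  stopifnot("no3" %in% names(profile))
  ok <- !is.na(profile$no3)
  d <- profile$depth_m[ok]
  no3 <- profile$no3[ok]
  if (length(d) < 3) {
    rlang::abort("Need at least 3 nitrate samples.",
                 class = "n15rates_invalid_profile")
  }
  grad <- diff(no3) / diff(d)
  gmax <- max(grad)
  none <- tibble::tibble(nitracline_top = NA_real_,
                         nitracline_bottom = NA_real_,
                         nitracline_depth = NA_real_)
  if (gmax <= flatness_floor) return(none)
  steep <- grad >= contiguity * gmax
  runs <- rle(steep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  # longest qualifying run; ties -> the run holding the maximum gradient,
  # then the shallower one
  imax <- which.max(grad)
  len <- runs$lengths[cand]
  best <- cand[len == max(len)]
  holds_max <- vapply(best, function(j) {
    starts[j] <= imax && imax <= ends[j]
  }, logical(1))
  pick <- if (any(holds_max)) best[holds_max][1] else best[1]
  top <- d[starts[pick]]
  bottom <- d[ends[pick] + 1L]
  tibble::tibble(nitracline_top = top, nitracline_bottom = bottom,
                 nitracline_depth = (top + bottom) / 2)
}

#' Euphotic depth from PAR attenuation
#'
#' Fits the exponential light model `PAR(z) = sPAR * exp(-k z)` by ordinary
#' least squares on `log(PAR)` versus depth, then solves for the depth
#' receiving `fraction` of surface PAR: `z = log(1 / fraction) / k`. A known
#' attenuation coefficient can be supplied directly instead of a profile.
#'
#' @param profile station profile with `depth_m` and `par` (absolute or
#'   percent of surface; only the slope matters). Ignored when `k` is given.
#' @param k attenuation coefficient (per metre), if already known.
#' @param fraction surface-PAR fraction defining the euphotic depth
#'   (default 0.001, i.e. the 0.1% light level).
#' @param par_floor instrument floor; PAR values at or below it are
#'   excluded from the fit.
#' @return a one-row tibble with `attenuation_k` and `euphotic_depth` (m).
#' @export
euphotic_depth <- function(profile = NULL, k = NULL, fraction = 0.001,
                           par_floor = 0) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(k)) {
    validate_profile(profile)
    stopifnot("par" %in% names(profile))
    ok <- !is.na(profile$par) & profile$par > par_floor
    d <- profile$depth_m[ok]
    par <- profile$par[ok]
    if (length(d) < 2) {
      rlang::abort("Need at least 2 positive PAR samples above the floor.",
                   class = "n15rates_invalid_profile")
    }
    slope <- stats::coef(stats::lm(log(par) ~ d))[["d"]]
    if (slope >= 0) {
      rlang::abort("PAR does not decrease with depth; cannot fit attenuation.",
                   class = "n15rates_invalid_optics")
    }
    k <- -slope
  }
  stopifnot(k > 0)
  tibble::tibble(attenuation_k = k, euphotic_depth = log(1 / fraction) / k)
}

# Depth of the global maximum of a series; ties broken shallow.
# Returns depth plus a flag when the maximum sits on a profile endpoint.
series_maximum <- function(depth, x) {
  ok <- !is.na(x)
  if (sum(ok) == 0 || diff(range(x[ok])) == 0) {
    return(list(depth = NA_real_, boundary = NA))
  }
  d <- depth[ok]
  x <- x[ok]
  i <- which.max(x)
  list(depth = d[i], boundary = i == 1L || i == length(x))
}

#' Subsurface extremum layers
#'
#' Depths of the primary nitrite maximum (PNM, global maximum of nitrite),
#' the deep chlorophyll maximum (DCM, maximum of chlorophyll fluorescence)
#' and the maximum of the pointwise nitrate/silicate ratio (an indicator of
#' preferential remineralization of nitrogen from sinking particles).
#' Ties are broken toward the shallower depth; maxima falling on the first
#' or last sample are flagged as boundary extrema.
#'
#' @param profile station profile; uses whichever of `no2`, `chl_fluor`,
#'   `no3` and `sio4` are present.
#' @return a one-row tibble: `pnm_depth`, `pnm_boundary`, `dcm_depth`,
#'   `dcm_boundary`, `no3_si_ratio_max_depth` (all `NA` for flat or absent
#'   series).
#' @export
extremum_layers <- function(profile) {
  validate_profile(profile)
  d <- profile$depth_m
  pnm <- if ("no2" %in% names(profile)) {
    series_maximum(d, profile$no2)
  } else {
    list(depth = NA_real_, boundary = NA)
  }
  dcm <- if ("chl_fluor" %in% names(profile)) {
    series_maximum(d, profile$chl_fluor)
  } else {
    list(depth = NA_real_, boundary = NA)
  }
  ratio_depth <- NA_real_
  if (all(c("no3", "sio4") %in% names(profile))) {
    ratio <- ifelse(!is.na(profile$sio4) & profile$sio4 > 0,
                    profile$no3 / profile$sio4, NA_real_)
    ratio_depth <- series_maximum(d, ratio)$depth
  }
  tibble::tibble(
    pnm_depth = pnm$depth, pnm_boundary = pnm$boundary,
    dcm_depth = dcm$depth, dcm_boundary = dcm$boundary,
    no3_si_ratio_max_depth = ratio_depth
  )
}

#' Uptake-to-nitrification transition depth
#'
#' Locates the shallowest depth at which nitrification overtakes ammonium
#' uptake and stays dominant: a crossover counts only when nitrification
#' exceeds uptake for at least `persistence` consecutive samples below it
#' (so single-sample sign flips in co-occurring, comparable rate profiles do
#' not register). The two series may be on different depth grids; the
#' coarser is linearly interpolated onto the finer over their common span.
#'
#' @param uptake data frame with `depth_m` and `rate` (ammonium uptake).
#' @param nitrification data frame with `depth_m` and `rate`.
#' @param persistence minimum number of consecutive nitrification-dominated
#'   samples required below the crossover (default 2).
#' @return a one-row tibble: `transition_depth` (m, `NA` when absent) and
#'   `transition_status`, one of `"transition"`, `"surface_dominated"`
#'   (nitrification already dominant at the shallowest sample) or
#'   `"co_occurring"` (no persistent crossover).
#' @export
transition_depth <- function(uptake, nitrification, persistence = 2) {
  for (x in list(uptake, nitrification)) {
    if (!all(c("depth_m", "rate") %in% names(x))) {
      rlang::abort("Rate profiles need `depth_m` and `rate` columns.",
                   class = "n15rates_schema_error")
    }
  }
  top <- max(min(uptake$depth_m), min(nitrification$depth_m))
  bot <- min(max(uptake$depth_m), max(nitrification$depth_m))
  # evaluate both series on the finer of the two grids, common span only
  grids <- list(uptake$depth_m, nitrification$depth_m)
  spacing <- vapply(grids, function(g) {
    if (length(g) < 2) Inf else min(diff(sort(g)))
  }, numeric(1))
  grid <- sort(unique(grids[[which.min(spacing)]]))
  grid <- grid[grid >= top & grid <= bot]
  if (length(grid) < 2) {
    rlang::abort("Fewer than 2 common depths between the two rate profiles.",
                 class = "n15rates_insufficient_overlap"
    )
  }
  u <- stats::approx(uptake$depth_m, uptake$rate, xout = grid)$y
  n <- stats::approx(nitrification$depth_m, nitrification$rate, xout = grid)$y
  excess <- n - u
  dom <- excess > 0
  run_len <- function(i) {
    len <- 0
    while (i + len <= length(dom) && dom[i + len]) len <- len + 1
    len
  }
  result <- function(depth, status) {
    tibble::tibble(transition_depth = depth, transition_status = status)
  }
  if (dom[1] && run_len(1) >= persistence) {
    return(result(NA_real_, "surface_dominated"))
  }
  starts <- which(!dom[-length(dom)] & dom[-1]) + 1L
  for (i in starts) {
    if (run_len(i) >= persistence) {
      z <- grid[i - 1] + (grid[i] - grid[i - 1]) *
        (0 - excess[i - 1]) / (excess[i] - excess[i - 1])
      return(result(z, "transition"))
    }
  }
  result(NA_real_, "co_occurring")
}

#' Compare light and dark incubation rates
#'
#' Student's t test on replicate rates from paired light and dark
#' incubations: paired across depths when `paired = TRUE` (rates matched
#' elementwise), otherwise a two-sample test with pooled variance.
#'
#' @param light,dark numeric vectors of replicate rates (at least 2 each).
#' @param paired match rates elementwise (e.g. by depth)?
#' @return a one-row tibble: `statistic`, `p.value`, `mean_difference`
#'   (light minus dark), `method`.
#' @export
paired_light_dark_test <- function(light, dark, paired = FALSE) {
  if (length(light) < 2 || length(dark) < 2) {
    rlang::abort("Need at least 2 replicates in each condition.",
                 class = "n15rates_insufficient_replicates")
  }
  res <- tryCatch(
    stats::t.test(light, dark, paired = paired, var.equal = !paired),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # degenerate case: both groups constant; equal means mean no evidence
    if (stats::var(light) == 0 && stats::var(dark) == 0 &&
        mean(light) == mean(dark)) {
      return(tibble::tibble(statistic = 0, p.value = 1,
                            mean_difference = 0,
                            method = "Student's t (degenerate)"))
    }
    rlang::abort("t test failed on the supplied rates.",
                 class = "n15rates_test_error")
  }
  tibble::tibble(
    statistic = unname(res$statistic),
    p.value = res$p.value,
    mean_difference = mean(light) - mean(dark),
    method = res$method
  )
}

#' Rate-covariate regression diagnostics
#'
#' Ordinary least-squares fits of a rate column against each covariate,
#' reporting slope, R-squared and the slope p-value — the standard first
#' look at what a rate profile co-varies with (nitrate, light, fluorescence).
#'
#' @param profile station profile.
#' @param rate_col name of the rate column.
#' @param covariates character vector of covariate column names.
#' @return a tibble with one row per covariate: `covariate`, `slope`,
#'   `r_squared`, `p_value`, `n`.
#' @export
rate_correlations <- function(profile, rate_col,
                              covariates = intersect(
                                c("no3", "par", "chl_fluor", "nh4"),
                                names(profile))) {
  validate_profile(profile)
  stopifnot(rate_col %in% names(profile), length(covariates) > 0)
  purrr::map_dfr(covariates, function(cv) {
    dat <- profile[stats::complete.cases(profile[c(rate_col, cv)]), ]
    fit <- stats::lm(stats::reformulate(cv, rate_col), data = dat)
    sm <- summary(fit)
    tibble::tibble(
      covariate = cv,
      slope = stats::coef(fit)[[cv]],
      r_squared = sm$r.squared,
      p_value = sm$coefficients[cv, "Pr(>|t|)"],
      n = nrow(dat)
    )
  })
}

#' All water-column features of a station profile
#'
#' Runs every feature detector the profile's columns support and returns a
#' one-row summary: mixed-layer depth, nitracline range and midpoint, PAR
#' attenuation and euphotic depth, PNM/DCM/nitrate-silicate-ratio maxima,
#' and the uptake-to-nitrification transition depth (when rate columns
#' `nh4_uptake` and `nitrification` are present).
#'
#' @param profile station profile data frame.
#' @param delta_t mixed-layer temperature offset (degrees C).
#' @param contiguity,flatness_floor see [nitracline()].
#' @param fraction,par_floor see [euphotic_depth()].
#' @param persistence see [transition_depth()].
#' @return a one-row tibble of features; absent inputs yield `NA` features.
#' @examples
#' st <- simulate_station(station_truth(), noise = FALSE)
#' profile_features(st)
#' @export
profile_features <- function(profile, delta_t = 0.8, contiguity = 0.9,
                             flatness_floor = 0.01, fraction = 0.001,
                             par_floor = 0, persistence = 2) {
  validate_profile(profile)
  feats <- tibble::tibble(
    mld = if ("temp_C" %in% names(profile)) {
      mixed_layer_depth(profile, delta_t)
    } else {
      NA_real_
    }
  )
  feats <- dplyr::bind_cols(
    feats,
    if ("no3" %in% names(profile)) {
      nitracline(profile, contiguity, flatness_floor)
    } else {
      tibble::tibble(nitracline_top = NA_real_, nitracline_bottom = NA_real_,
                     nitracline_depth = NA_real_)
    },
    if ("par" %in% names(profile)) {
      euphotic_depth(profile, fraction = fraction, par_floor = par_floor)
    } else {
      tibble::tibble(attenuation_k = NA_real_, euphotic_depth = NA_real_)
    },
    extremum_layers(profile),
    if (all(c("nh4_uptake", "nitrification") %in% names(profile))) {
      transition_depth(
        data.frame(depth_m = profile$depth_m, rate = profile$nh4_uptake),
        data.frame(depth_m = profile$depth_m, rate = profile$nitrification),
        persistence = persistence
      )
    } else {
      tibble::tibble(transition_depth = NA_real_,
                     transition_status = NA_character_)
    }
  )
  feats
}
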