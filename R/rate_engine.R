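# Rate computation from tracer incubations.
#
# An incubation record is one row of a data frame with columns:
#   c0_product, n0_product  - product pool at t0 (nmol N/L, atom fraction)
#   ct_product, nt_product  - product pool at t  (nmol N/L, atom fraction)
#   ci_substrate            - ambient substrate concentration (nmol N/L)
#   ct_tracer               - final tracer concentration (nmol N/L)
#   n_substrate             - substrate atom fraction f15 after the spike
#   t_h                     - incubation duration (h)
# plus any identifying columns (station, depth_m, light, replicate, process)
# which are carried through to the outputs.

REQUIRED_INCUBATION_COLS <- c(
  "c0_product", "n0_product", "ct_product", "nt_product",
  "ci_substrate", "ct_tracer", "n_substrate", "t_h"
)

validate_incubations <- function(records) {
  missing <- setdiff(REQUIRED_INCUBATION_COLS, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Incubation table is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "n15rates_schema_error"
    )
  }
  if (any(records$t_h <= 0)) {
    rlang::abort("Incubation duration `t_h` must be positive.",
                 class = "n15rates_invalid_record")
  }
  conc_cols <- c("c0_product", "ct_product", "ci_substrate", "ct_tracer")
  if (any(as.matrix(records[conc_cols]) < 0)) {
    rlang::abort("Concentrations must be non-negative.",
                 class = "n15rates_invalid_record")
  }
  invisible(records)
}

# Identifying columns carried through to rate outputs, when present.
id_cols <- function(records) {
  intersect(c("station", "depth_m", "light", "replicate", "process"),
            names(records))
}

rate_tbl <- function(records, value, method, units = "nmol N L-1 h-1") {
  out <- dplyr::select(tibble::as_tibble(records),
                       dplyr::all_of(id_cols(records)))
  out$method <- method
  out$value <- value
  out$units <- units
  out
}

#' Bulk transformation rate from a tracer incubation
#'
#' The bulk rate is the transformation rate at the full (ambient + tracer)
#' substrate concentration, from the 15N enrichment of the product pool:
#' `R_bulk = C0 * (n_t - n_0) / (t * f15)`, where `C0` is the initial
#' product concentration and `f15` the substrate atom fraction after the
#' spike. Because the tracer itself raises the substrate concentration,
#' `R_bulk` overestimates the in-situ rate whenever the ambient pool is
#' small relative to the spike.
#'
#' @param records incubation data frame (see package docs for columns).
#' @param r15_standard reference isotope ratio, used only for the
#'   labelling-informativeness check.
#' @return a tibble with the identifying columns plus `method`, `value`,
#'   `units`. Negative rates are retained, not clamped.
#' @export
rate_bulk <- function(records, r15_standard = r15n_air) {
  validate_incubations(records)
  if (any(records$n_substrate <= natural_abundance(r15_standard))) {
    rlang::abort(
      "Substrate atom fraction is at or below natural abundance; the labelling is uninformative.",
      class = "n15rates_uninformative_labelling"
    )
  }
  value <- records$c0_product * (records$nt_product - records$n0_product) /
    (records$t_h * records$n_substrate)
  rate_tbl(records, value, "bulk")
}

#' 15N and 14N accumulation rates in the product pool
#'
#' `rate_r15()` is the accumulation rate of 15N atoms,
#' `(C_t * n_t - C_0 * n_0) / t`; `rate_r14()` scales it to the 14N
#' accumulation rate via the substrate labelling,
#' `R14 = R15 * (1 - n_sub) / n_sub`. Their sum is the total product
#' accumulation rate at bulk substrate concentration.
#'
#' @inheritParams rate_bulk
#' @return a tibble of rate estimates (see [rate_bulk()]).
#' @export
rate_r15 <- function(records) {
  validate_incubations(records)
  value <- (records$ct_product * records$nt_product -
              records$c0_product * records$n0_product) / records$t_h
  rate_tbl(records, value, "r15")
}

#' @rdname rate_r15
#' @param r15_rates optional precomputed output of [rate_r15()]; computed
#'   from `records` when absent.
#' @export
rate_r14 <- function(records, r15_rates = NULL) {
  validate_incubations(records)
  n_sub <- records$n_substrate
  if (any(n_sub <= 0) || any(n_sub >= 1)) {
    rlang::abort("Substrate atom fraction must lie inside (0, 1).",
                 class = "n15rates_uninformative_labelling")
  }
  if (is.null(r15_rates)) r15_rates <- rate_r15(records)
  value <- r15_rates$value * (1 - n_sub) / n_sub
  rate_tbl(records, value, "r14")
}

#' In-situ rate calibrated for tracer enrichment
#'
#' Scales the total accumulation rate back to the ambient substrate
#' concentration by linear interpolation:
#' `R_in_situ = (R15 + R14) * Ci / (Ci + Ct)`, where `Ci` is the ambient
#' substrate and `Ct` the tracer addition. The correction assumes a
#' near-first-order kinetic response, valid while the total substrate stays
#' below the half-saturation concentration Ks; when a kinetic fit is
#' supplied the function warns if that regime is violated.
#'
#' @inheritParams rate_bulk
#' @param fit optional [fit_mm()] result used to check the first-order
#'   assumption (`Ci + Ct < Ks`).
#' @return a tibble of rate estimates; always `<= R15 + R14`, with equality
#'   only when no tracer was added.
#' @export
rate_in_situ <- function(records, fit = NULL) {
  validate_incubations(records)
  total <- records$ci_substrate + records$ct_tracer
  if (any(total <= 0)) {
    rlang::abort("Ambient substrate and tracer are both zero.",
                 class = "n15rates_no_substrate")
  }
  r15 <- rate_r15(records)
  r14 <- rate_r14(records, r15)
  if (!is.null(fit) && any(total >= fit$ks)) {
    rlang::warn(
      "Total substrate (ambient + tracer) is at or above Ks: the first-order assumption behind the in-situ calibration does not hold.",
      class = "n15rates_first_order_regime_warning"
    )
  }
  value <- (r15$value + r14$value) * records$ci_substrate / total
  rate_tbl(records, value, "in_situ")
}

#' Detection limit of a tracer-derived rate
#'
#' The smallest rate whose product-pool enrichment is distinguishable from
#' analytical noise. A reliable enrichment is taken as `k_sigma` times the
#' delta-15N standard deviation of the analysis (default 3 x 0.2 permil =
#' 0.6 permil); the corresponding atom-fraction increase `dn_min` is
#' computed by exact conversion at the pool's initial delta, and
#' `DL = C_product * dn_min / (t * f15)`. The limit therefore grows with
#' the product pool and shrinks with labelling strength and incubation
#' time, so it is computed per sample rather than as a global constant.
#'
#' @param product_conc product-pool concentration (nmol N per litre).
#' @param f15 substrate 15N atom fraction after the spike.
#' @param t_h incubation duration in hours.
#' @param delta_sd analytical standard deviation of delta-15N, permil.
#' @param k_sigma multiple of `delta_sd` regarded as a reliable enrichment.
#' @param initial_delta delta-15N of the product pool at t0, permil.
#' @inheritParams delta_to_atom_fraction
#' @return detection limit in nmol N per litre per hour (multiply by 24
#'   for daily units).
#' @export
detection_limit <- function(product_conc, f15, t_h,
                            delta_sd = 0.2, k_sigma = 3,
                            initial_delta = 0, r15_standard = r15n_air) {
  stopifnot(delta_sd > 0, k_sigma > 0, all(t_h > 0),
            all(f15 > 0), all(f15 < 1), all(product_conc >= 0))
  dn_min <- delta_to_atom_fraction(initial_delta + k_sigma * delta_sd,
                                   r15_standard) -
    delta_to_atom_fraction(initial_delta, r15_standard)
  product_conc * dn_min / (t_h * f15)
}

#' All rate estimates for a table of incubations
#'
#' Computes the bulk, 15N-accumulation, 14N-accumulation and calibrated
#' in-situ rates for every record, together with the per-sample detection
#' limit, and returns them as one tidy table (one row per record per
#' method).
#'
#' @inheritParams rate_in_situ
#' @inheritParams detection_limit
#' @return a tibble with the identifying columns plus `method`, `value`,
#'   `units`, `detection_limit` and `below_dl`.
#' @examples
#' truth <- incubation_truth(vmax = 2, ks = 500, ambient_substrate = 20)
#' rec <- simulate_incubation(truth, noise = FALSE)
#' calculate_rates(rec)
#' @export
calculate_rates <- function(records, fit = NULL, delta_sd = 0.2, k_sigma = 3,
                            r15_standard = r15n_air) {
  validate_incubations(records)
  dl <- detection_limit(
    product_conc = records$c0_product,
    f15 = records$n_substrate,
    t_h = records$t_h,
    delta_sd = delta_sd, k_sigma = k_sigma,
    initial_delta = atom_fraction_to_delta(records$n0_product, r15_standard),
    r15_standard = r15_standard
  )
  r15 <- rate_r15(records)
  out <- dplyr::bind_rows(
    rate_bulk(records, r15_standard),
    r15,
    rate_r14(records, r15),
    rate_in_situ(records, fit)
  )
  out$detection_limit <- rep(dl, 4)
  out$below_dl <- out$value < out$detection_limit
  out
}

#' Integrate paired hourly rates to a daily rate
#'
#' Nitrification (ammonium oxidation) daily rates assume equal day and night
#' periods: `12 * light + 12 * dark`. Nitrogen uptake is light-driven, and
#' the daily rate is estimated as 16 times the light hourly rate.
#'
#' @param light hourly rate from the light incubation (nmol N per litre per
#'   hour); vectorised.
#' @param dark hourly rate from the paired dark incubation; required for
#'   oxidation.
#' @param process `"oxidation"` or `"uptake"`.
#' @param light_hours,dark_hours oxidation multipliers (default 12 and 12).
#' @param uptake_hours uptake multiplier applied to the light rate
#'   (default 16).
#' @return daily rate(s), nmol N per litre per day.
#' @export
integrate_daily <- function(light, dark = NULL,
                            process = c("oxidation", "uptake"),
                            light_hours = 12, dark_hours = 12,
                            uptake_hours = 16) {
  process <- match.arg(process)
  stopifnot(is.numeric(light))
  if (process == "oxidation") {
    if (is.null(dark)) {
      rlang::abort(
        "Daily oxidation integration needs paired light and dark rates.",
        class = "n15rates_missing_pair"
      )
    }
    light_hours * light + dark_hours * dark
  } else {
    uptake_hours * light
  }
}
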