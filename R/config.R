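# Run configuration: the tunable constants of the whole pipeline in one
# validated list that round-trips losslessly through YAML.

#' Pipeline run configuration
#'
#' Collects every tunable constant of the rate pipeline with its default:
#' the isotope reference ratio, tracer labelling, detection-limit
#' parameters (3 x 0.2 permil), daily-integration multipliers (12 h light +
#' 12 h dark for oxidation, 16 h for uptake), nitracline detection rule,
#' euphotic light fraction (0.1%), and mixed-layer temperature offset
#' (0.8 degrees C). Values are validated against their documented domains.
#'
#' @param r15_standard reference 15N/14N ratio.
#' @param tracer_atom_frac tracer 15N atom fraction.
#' @param delta_sd analytical delta-15N standard deviation, permil.
#' @param k_sigma detection-limit multiple of `delta_sd`.
#' @param light_hours,dark_hours daily multipliers for oxidation.
#' @param uptake_hours daily multiplier for uptake.
#' @param mld_delta_t mixed-layer temperature offset, degrees C.
#' @param nitracline_contiguity gradient fraction defining the steepest
#'   range.
#' @param nitracline_flatness_floor minimum gradient for a nitracline.
#' @param euphotic_fraction surface-PAR fraction of the euphotic depth.
#' @param seed default RNG seed for simulations.
#' @return a named list of class `n15rates_config`.
#' @export
run_config <- function(r15_standard = r15n_air,
                       tracer_atom_frac = 0.98,
                       delta_sd = 0.2, k_sigma = 3,
                       light_hours = 12, dark_hours = 12, uptake_hours = 16,
                       mld_delta_t = 0.8,
                       nitracline_contiguity = 0.9,
                       nitracline_flatness_floor = 0.01,
                       euphotic_fraction = 0.001,
                       seed = 1L) {
  cfg <- list(
    r15_standard = r15_standard,
    tracer_atom_frac = tracer_atom_frac,
    delta_sd = delta_sd,
    k_sigma = k_sigma,
    light_hours = light_hours,
    dark_hours = dark_hours,
    uptake_hours = uptake_hours,
    mld_delta_t = mld_delta_t,
    nitracline_contiguity = nitracline_contiguity,
    nitracline_flatness_floor = nitracline_flatness_floor,
    euphotic_fraction = euphotic_fraction,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "n15rates_config")
}

validate_config <- function(cfg) {
  ok <- cfg$r15_standard > 0 &&
    cfg$tracer_atom_frac > 0 && cfg$tracer_atom_frac < 1 &&
    cfg$delta_sd > 0 && cfg$k_sigma > 0 &&
    cfg$light_hours >= 0 && cfg$dark_hours >= 0 && cfg$uptake_hours >= 0 &&
    cfg$mld_delta_t > 0 &&
    cfg$nitracline_contiguity > 0 && cfg$nitracline_contiguity <= 1 &&
    cfg$nitracline_flatness_floor >= 0 &&
    cfg$euphotic_fraction > 0 && cfg$euphotic_fraction <= 1
  if (!isTRUE(ok)) {
    rlang::abort("Configuration value outside its documented domain.",
                 class = "n15rates_invalid_config")
  }
  invisible(cfg)
}

#' Read / write a run configuration
#'
#' YAML serialization of [run_config()]; unknown keys are rejected and the
#' result is validated, so `read_config(write_config(cfg, f))` is the
#' identity.
#'
#' @param path YAML file path.
#' @return for `read_config`, an `n15rates_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "n15rates_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "n15rates_invalid_config")
  }
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param cfg an `n15rates_config` list.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
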