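# CSV readers/writers and run configuration.
#
# CSV dialect throughout: comma-separated, UTF-8, header row, empty string =
# missing. Headers are matched case-insensitively. Isotope columns carry an
# explicit unit suffix (_atom_pct or _delta_permil) and are converted to
# atom fractions at the boundary; depths are metres, positive downward.

# lower-case header lookup; returns the actual column name or NA
find_col <- function(df, name) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0) NA_character_ else names(df)[hit[1]]
}

# Resolve an isotope column "<stem>_atom_pct" or "<stem>_delta_permil" to an
# atom-fraction vector. Errors if both unit variants are present.
isotope_col <- function(df, stem, r15_standard) {
  pct <- find_col(df, paste0(stem, "_atom_pct"))
  del <- find_col(df, paste0(stem, "_delta_permil"))
  if (!is.na(pct) && !is.na(del)) {
    rlang::abort(
      sprintf("Both %s_atom_pct and %s_delta_permil are present; supply one.",
              stem, stem),
      class = "n15rates_ambiguity_error"
    )
  }
  if (!is.na(pct)) return(df[[pct]] / 100)
  if (!is.na(del)) return(delta_to_atom_fraction(df[[del]], r15_standard))
  NULL
}

require_cols <- function(df, cols, what) {
  actual <- vapply(cols, function(x) find_col(df, x), character(1))
  if (anyNA(actual)) {
    rlang::abort(
      sprintf("%s is missing mandatory column(s): %s",
              what, paste(cols[is.na(actual)], collapse = ", ")),
      class = "n15rates_schema_error"
    )
  }
  actual
}

# Drop invalid rows, warn with their file line numbers (header = line 1),
# and attach them as a "problems" attribute.
reject_rows <- function(df, bad, reason) {
  if (!any(bad)) return(df)
  lines <- which(bad) + 1L
  rlang::warn(
    sprintf("Rejected %d row(s) (%s) at line(s): %s",
            sum(bad), reason, paste(lines, collapse = ", ")),
    class = "n15rates_row_rejected"
  )
  problems <- tibble::tibble(line = lines, reason = reason)
  out <- df[!bad, , drop = FALSE]
  attr(out, "problems") <- dplyr::bind_rows(attr(df, "problems"), problems)
  out
}

#' Read an incubation table
#'
#' Expected columns (case-insensitive): `station` (optional), `depth_m`,
#' `light` (L/D or light/dark), `replicate`, `t_h`, `c0_product`,
#' `ct_product`, `ci_substrate`, `ct_tracer`, and isotope columns
#' `n0_product_*`, `nt_product_*` plus either `n_substrate_*` (post-spike
#' labelling) or `n_tracer_*` (tracer composition, from which the post-spike
#' labelling is computed by mass balance with an ambient pool at natural
#' abundance), where `*` is `atom_pct` or `delta_permil`. Rows failing basic
#' validity (non-positive duration, negative concentrations, missing
#' mandatory values) are rejected individually with their line numbers; the
#' remainder is returned.
#'
#' @param path CSV file path.
#' @inheritParams delta_to_atom_fraction
#' @return an incubation tibble (see [calculate_rates()]) with rejected
#'   rows in `attr(, "problems")`.
#' @export
read_incubations <- function(path, r15_standard = r15n_air) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path),
                 class = "n15rates_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  cols <- require_cols(raw, c("depth_m", "light", "t_h", "c0_product",
                              "ct_product", "ci_substrate", "ct_tracer"),
                       "Incubation table")
  n0 <- isotope_col(raw, "n0_product", r15_standard)
  nt <- isotope_col(raw, "nt_product", r15_standard)
  if (is.null(n0) || is.null(nt)) {
    rlang::abort(
      "Need n0_product and nt_product isotope columns (suffix _atom_pct or _delta_permil).",
      class = "n15rates_schema_error"
    )
  }
  n_sub <- isotope_col(raw, "n_substrate", r15_standard)
  if (is.null(n_sub)) {
    n_trc <- isotope_col(raw, "n_tracer", r15_standard)
    if (is.null(n_trc)) {
      rlang::abort(
        "Need either n_substrate_* or n_tracer_* isotope columns.",
        class = "n15rates_schema_error"
      )
    }
    ci <- raw[[cols["ci_substrate"]]]
    ct <- raw[[cols["ct_tracer"]]]
    n_sub <- (ci * natural_abundance(r15_standard) + ct * n_trc) /
      (ci + ct)
  }
  light <- tolower(as.character(raw[[cols["light"]]]))
  light <- dplyr::case_match(light, c("l", "light") ~ "light",
                             c("d", "dark") ~ "dark",
                             .default = NA_character_)
  station_col <- find_col(raw, "station")
  rep_col <- find_col(raw, "replicate")
  out <- tibble::tibble(
    station = if (is.na(station_col)) NA_character_ else
      as.character(raw[[station_col]]),
    depth_m = raw[[cols["depth_m"]]],
    light = light,
    replicate = if (is.na(rep_col)) 1L else raw[[rep_col]],
    t_h = raw[[cols["t_h"]]],
    c0_product = raw[[cols["c0_product"]]],
    n0_product = n0,
    ct_product = raw[[cols["ct_product"]]],
    nt_product = nt,
    ci_substrate = raw[[cols["ci_substrate"]]],
    ct_tracer = raw[[cols["ct_tracer"]]],
    n_substrate = n_sub
  )
  num <- c("t_h", "c0_product", "n0_product", "ct_product", "nt_product",
           "ci_substrate", "ct_tracer", "n_substrate")
  bad <- !stats::complete.cases(out[c("light", num)]) |
    out$t_h <= 0 |
    apply(out[c("c0_product", "ct_product", "ci_substrate", "ct_tracer")] < 0,
          1, any) |
    out$n_substrate <= 0 | out$n_substrate >= 1
  bad[is.na(bad)] <- TRUE
  reject_rows(out, bad, "invalid or missing values")
}

#' Read a station bottle/CTD table
#'
#' Expected columns (case-insensitive): `station` (optional), `depth_m`,
#' and any of `temp_C`, `par_pct_surface` or `par_abs` (exactly one,
#' returned as `par`), `no3`, `no2`, `nh4`, `sio4`, `chl_fluor`,
#' `nh4_uptake`, `nitrification`. Rows with missing or non-increasing
#' depths are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return a station-profile tibble sorted by depth (see
#'   [profile_features()]).
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path),
                 class = "n15rates_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  require_cols(raw, "depth_m", "Profile table")
  par_pct <- find_col(raw, "par_pct_surface")
  par_abs <- find_col(raw, "par_abs")
  if (!is.na(par_pct) && !is.na(par_abs)) {
    rlang::abort("Both par_pct_surface and par_abs present; supply one.",
                 class = "n15rates_ambiguity_error")
  }
  keep <- c("station", "depth_m", "temp_c", "no3", "no2", "nh4", "sio4",
            "chl_fluor", "nh4_uptake", "nitrification")
  out <- tibble::tibble(.rows = nrow(raw))
  for (nm in keep) {
    col <- find_col(raw, nm)
    if (!is.na(col)) {
      out[[if (nm == "temp_c") "temp_C" else nm]] <- raw[[col]]
    }
  }
  if (!is.na(par_pct)) out$par <- raw[[par_pct]]
  if (!is.na(par_abs)) out$par <- raw[[par_abs]]
  bad <- is.na(out$depth_m)
  out <- reject_rows(out, bad, "missing depth")
  dplyr::arrange(out, .data$depth_m)
}

#' Read a kinetic-series table
#'
#' Expected columns (case-insensitive): `depth_m`, `process`,
#' `s_total_nmol_L`, `rate_nmol_L_h`, `replicate` (optional).
#'
#' @param path CSV file path.
#' @return a tibble ready for [fit_mm()], one row per incubation.
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path),
                 class = "n15rates_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  cols <- require_cols(raw, c("depth_m", "process", "s_total_nmol_l",
                              "rate_nmol_l_h"), "Kinetic table")
  rep_col <- find_col(raw, "replicate")
  out <- tibble::tibble(
    depth_m = raw[[cols["depth_m"]]],
    process = as.character(raw[[cols["process"]]]),
    s_total = raw[[cols["s_total_nmol_l"]]],
    rate = raw[[cols["rate_nmol_l_h"]]],
    replicate = if (is.na(rep_col)) 1L else raw[[rep_col]]
  )
  bad <- !stats::complete.cases(out[c("s_total", "rate")]) | out$s_total <= 0
  reject_rows(out, bad, "invalid or missing values")
}

#' Write a result table atomically
#'
#' Writes CSV to a temporary file in the destination directory and renames
#' it into place, so a failed run never leaves a partial output.
#'
#' @param x a data frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("n15rates_", tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(x, tmp, progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
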