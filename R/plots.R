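# Diagnostic figures.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Michaelis-Menten fit
#'
#' Observed rates against total substrate concentration with the fitted
#' saturation curve; the half-saturation point (`ks`, `vmax / 2`) is marked.
#'
#' @param object an `mm_fit` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    s_total = seq(0, max(dat$s_total), length.out = 200)
  )
  grid$rate <- mm_rate(object$vmax, object$ks, grid$s_total)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_total, y = .data$rate)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = object$ks, y = object$vmax / 2,
                      shape = 4, size = 3, colour = "firebrick") +
    ggplot2::labs(
      x = "Total substrate (nmol N L-1)",
      y = "Rate (nmol N L-1 h-1)",
      title = sprintf("vmax = %.3g, ks = %.3g, alpha = %.3g",
                      object$vmax, object$ks, object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a station profile
#'
#' Depth profiles of the selected series, depth increasing downward, one
#' panel per variable. Detected features (from [profile_features()]) can be
#' overlaid as horizontal depth markers.
#'
#' @param profile station-profile data frame.
#' @param vars columns to plot (default: every known series present).
#' @param features optional one-row tibble from [profile_features()]; its
#'   depth-valued columns are drawn as dashed horizontal lines.
#' @return a ggplot.
#' @export
plot_profile <- function(profile, vars = NULL, features = NULL) {
  validate_profile(profile)
  known <- c("temp_C", "par", "no3", "no2", "nh4", "sio4", "chl_fluor",
             "nh4_uptake", "nitrification")
  if (is.null(vars)) vars <- intersect(known, names(profile))
  stopifnot(length(vars) > 0, all(vars %in% names(profile)))
  long <- tidyr::pivot_longer(
    profile[c("depth_m", vars)],
    cols = dplyr::all_of(vars),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(long$series, levels = vars)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$value, y = .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~series, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Depth (m)") +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    depth_cols <- intersect(
      c("mld", "nitracline_depth", "euphotic_depth", "pnm_depth",
        "dcm_depth", "transition_depth"),
      names(features)
    )
    marks <- tidyr::pivot_longer(features[depth_cols],
                                 cols = dplyr::everything(),
                                 names_to = "feature", values_to = "depth_m")
    marks <- marks[!is.na(marks$depth_m), ]
    if (nrow(marks) > 0) {
      p <- p + ggplot2::geom_hline(
        data = marks,
        ggplot2::aes(yintercept = .data$depth_m, colour = .data$feature),
        linetype = "dashed"
      ) +
        ggplot2::labs(colour = "Feature")
    }
  }
  p
}
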