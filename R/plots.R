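#' Plot a fitted chlorophyll profile
#'
#' Observations and the fitted shifted Gaussian, depth increasing
#' downward.
#'
#' @param object `scm_profile_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scm_profile_fit <- function(object, ...) {
  obs <- object$observations
  zz <- seq(min(obs$depth_m), max(obs$depth_m), length.out = 200)
  curve <- tibble(depth_m = zz,
                  chl_mg_m3 = evaluate_profile(object, zz))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$chl_mg_m3, y = .data$depth_m)) +
    ggplot2::geom_path(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(chlorophyll ~ (mg ~ m^-3)),
                  y = "depth (m)",
                  title = sprintf("Shifted-Gaussian fit [%s]", object$flag))
}

#' Plot a daily production profile
#'
#' @param object `scm_production` object.
#' @param ... Unused.
#' @return A ggplot with the photic depth marked.
#' @export
autoplot.scm_production <- function(object, ...) {
  d <- object$dpp_profile
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dpp, y = .data$depth_m)) +
    ggplot2::geom_path(colour = "darkgreen") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(DPP ~ (mg ~ C ~ m^-3 ~ d^-1)),
                  y = "depth (m)")
  if (!is.na(object$zp)) {
    g <- g + ggplot2::geom_hline(yintercept = object$zp, linetype = "dashed")
  }
  g
}

#' Plot a collection of chlorophyll profiles
#'
#' @param profiles Tibble of profile parameters (one row per station).
#' @param depths Depth grid for evaluation. Default 0--100 m.
#' @return A ggplot of chlorophyll vs depth, one line per station.
#' @export
plot_profiles <- function(profiles, depths = seq(0, 100, by = 0.5)) {
  d <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    tibble(station = profiles$station[i], depth_m = depths,
           chl_mg_m3 = evaluate_profile(profiles[i, ], depths))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chl_mg_m3, y = .data$depth_m,
                                  group = .data$station)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(chlorophyll ~ (mg ~ m^-3)), y = "depth (m)")
}

#' Plot a spectrum
#'
#' @param spec Spectrum tibble (`wavelength_nm`, `value`).
#' @return A ggplot.
#' @export
plot_spectrum <- function(spec) {
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorption",
                  subtitle = spectrum_kind(spec))
}

#' Plot sensitivity records against a shape index
#'
#' @param records Records tibble from a `run_*` experiment.
#' @param x Unquoted predictor column (e.g. `zm_over_sigma` or
#'   `zm_over_zp`).
#' @param colour Optional unquoted column mapped to colour (e.g. `sigma`
#'   or `treatment`).
#' @return A ggplot of percent difference vs the index.
#' @export
plot_sensitivity <- function(records, x, colour = NULL) {
  x_q <- enquo(x); c_q <- enquo(colour)
  d <- records[!records$flagged & is.finite(records$percent_difference), ]
  g <- ggplot2::ggplot(d, ggplot2::aes(x = !!x_q,
                                       y = .data$percent_difference))
  g <- if (quo_is_null(c_q)) g + ggplot2::geom_point() else {
    g + ggplot2::geom_point(ggplot2::aes(colour = !!c_q))
  }
  g + ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(y = "percent difference (%)")
}
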