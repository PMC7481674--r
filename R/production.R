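#' Photosynthesis--irradiance (PE) parameters
#'
#' @param PmB Assimilation number: chlorophyll-normalized photosynthetic
#'   rate at saturating light, mg C (mg chl)^-1 h^-1 (> 0).
#' @param alphaB Initial slope of the PE curve, mg C (mg chl)^-1 h^-1
#'   (umol quanta m^-2 s^-1)^-1 (> 0).
#' @param station Optional station label.
#' @return A tibble with `station`, `PmB`, `alphaB` and the derived light
#'   adaptation parameter `Ek = PmB / alphaB` (umol quanta m^-2 s^-1).
#' @export
pe_params <- function(PmB, alphaB, station = NA_character_) {
  assert_finite(PmB, "PmB"); assert_finite(alphaB, "alphaB")
  if (any(PmB <= 0)) stop_scmprod("PmB must be > 0", "invalid_parameter")
  if (any(alphaB <= 0)) stop_scmprod("alphaB must be > 0", "invalid_parameter")
  tibble(station = as.character(station), PmB = PmB, alphaB = alphaB,
         Ek = PmB / alphaB)
}

#' Spectrally resolved initial slope
#'
#' The normalized phytoplankton absorption shape serves as a proxy for the
#' action spectrum of light-limited photosynthesis. The broadband slope is
#' distributed over wavelength as `alphaB(lambda) = alphaB * shape(lambda)
#' / mean(shape)`, preserving the spectral mean over 400--700 nm; rescaling
#' the shape by any constant leaves the result unchanged.
#'
#' @param alphaB Broadband initial slope.
#' @param shape Normalized absorption shape on the model grid
#'   (tibble `wavelength_nm`, `value`).
#' @return Tibble with `wavelength_nm`, `alphaB_lambda`.
#' @export
spectral_alpha <- function(alphaB, shape) {
  m <- mean(shape$value)
  if (!isTRUE(m > 0)) stop_scmprod("shape has non-positive mean", "domain")
  tibble(wavelength_nm = shape$wavelength_nm,
         alphaB_lambda = alphaB * shape$value / m)
}

#' Light-saturation response of the PE curve
#'
#' Maps the spectrally integrated light-limited rate
#' \eqn{\Pi^B_\lambda = \int_{400}^{700} \alpha^B(\lambda) E(z,\lambda)
#' \,d\lambda} onto the chlorophyll-normalized photosynthetic rate. The
#' default is the saturating form
#' \deqn{P^B = \Pi^B_\lambda / \sqrt{1 + (\Pi^B_\lambda / P^B_m)^2},}
#' which increases monotonically toward the plateau `PmB`. An alternative
#' algebraic variant `Pi / (1 + (Pi/PmB)^2)` is available for comparison
#' (`form = "typeset"`); it is non-monotonic at high light and is not used
#' by default.
#'
#' @param pi_lambda Light-limited rate(s), mg C (mg chl)^-1 h^-1 (>= 0).
#' @param PmB Assimilation number.
#' @param form `"saturating"` (default) or `"typeset"`.
#' @return `P^B`, same units as `PmB`; always < `PmB` for the saturating
#'   form.
#' @export
pb_rate <- function(pi_lambda, PmB, form = c("saturating", "typeset")) {
  form <- match.arg(form)
  if (any(pi_lambda < 0)) stop_scmprod("pi_lambda must be >= 0", "domain")
  if (any(PmB <= 0)) stop_scmprod("PmB must be > 0", "domain")
  r <- pi_lambda / PmB
  switch(form,
    saturating = pi_lambda / sqrt(1 + r^2),
    typeset = pi_lambda / (1 + r^2)
  )
}

#' Uniform counterpart of a chlorophyll profile
#'
#' Returns the profile used in uniform-vs-non-uniform comparisons: the
#' surface chlorophyll concentration `B(0)` held constant over depth
#' (`h = 0`). A flat profile is its own counterpart.
#'
#' @param profile One-row profile parameters.
#' @return A one-row profile tibble.
#' @export
uniform_counterpart <- function(profile) {
  p <- as_param_list(profile, c("B0", "h", "zm", "sigma"))
  b0 <- evaluate_profile(p, 0)
  st <- if (is.data.frame(profile) && "station" %in% names(profile)) {
    as.character(profile$station[1])
  } else NA_character_
  gaussian_profile(B0 = b0, h = 0, zm = p$zm, sigma = p$sigma, station = st)
}

#' Daily depth-integrated primary production
#'
#' Volumetric production at depth and time is `B(z) * P^B(z, t)`, where
#' `P^B` follows from the spectral light-limited rate (trapezoid
#' quadrature of `alphaB(lambda) E(z, t, lambda)` over 400--700 nm) through
#' the saturating PE response. Rates are integrated over the daylight
#' window (trapezoid in time, hourly rates to daily) and then over depth
#' down to the photic depth `zp`.
#'
#' @param profile One-row profile parameters.
#' @param pe One-row PE parameters (`PmB`, `alphaB`).
#' @param field [propagate()] output for this profile.
#' @param zp Photic depth, m; computed from `field` when `NULL`. If the
#'   water column is dark (polar night) the result is zero production with
#'   `zp = NA`.
#' @param form PE response form, see [pb_rate()].
#' @return An object of class `scm_production`: `dpp_profile` (tibble
#'   `depth_m`, `dpp` in mg C m^-3 d^-1), `dpp_integrated`
#'   (mg C m^-2 d^-1 over `[0, zp]`), `zp`, and the inputs used.
#' @export
daily_production <- function(profile, pe, field, zp = NULL,
                             form = c("saturating", "typeset")) {
  form <- match.arg(form)
  pe1 <- as_param_list(pe, c("PmB", "alphaB"))
  if (is.null(zp)) {
    zp <- withCallingHandlers(
      photic_depth(field),
      scmprod_warning_no_photic_depth = function(w) invokeRestart("muffleWarning")
    )
  }
  if (!is.na(zp) && zp > max(field$depths)) {
    stop_scmprod("zp exceeds the depth grid", "configuration")
  }

  shape <- tibble(wavelength_nm = field$wavelengths,
                  value = field$model$shape)
  al <- spectral_alpha(pe1$alphaB, shape)
  wl_w <- trapz_weights(field$wavelengths) * al$alphaB_lambda

  depths <- field$depths
  chl <- evaluate_profile(profile, depths)
  nt <- length(field$times)
  vol <- matrix(0, length(depths), nt)        # mg C m^-3 h^-1
  for (i in seq_len(nt)) {
    pi_l <- as.numeric(field$E[, i, ] %*% wl_w)
    vol[, i] <- chl * pb_rate(pi_l, pe1$PmB, form = form)
  }
  # time integral over the daylight window: hourly rates -> daily
  tw <- trapz_weights(field$times)
  dpp_z <- as.numeric(vol %*% tw)             # mg C m^-3 d^-1

  dpp_int <- if (is.na(zp)) 0 else integrate_to_depth(depths, dpp_z, zp)

  structure(
    list(
      dpp_profile = tibble(depth_m = depths, dpp = dpp_z),
      dpp_integrated = dpp_int, zp = zp,
      daylength_h = diff(range(field$times)),
      profile = as_tibble(profile), pe = as_tibble(pe), form = form,
      rates = vol, times = field$times
    ),
    class = "scm_production"
  )
}

# trapezoid integral of y(z) over [0, z_top], z_top not necessarily a node
integrate_to_depth <- function(z, y, z_top) {
  if (z_top <= 0) return(0)
  inside <- z <= z_top
  zi <- z[inside]; yi <- y[inside]
  total <- trapz(zi, yi)
  k <- sum(inside)
  if (k < length(z) && z[k] < z_top) {
    y_top <- approx(z, y, xout = z_top)$y
    total <- total + (z_top - z[k]) * (yi[k] + y_top) / 2
  }
  total
}

#' @export
print.scm_production <- function(x, ...) {
  cat("Daily primary production\n")
  cat(sprintf("  integrated to zp = %.1f m: %.2f mg C m^-2 d^-1\n",
              x$zp, x$dpp_integrated))
  cat(sprintf("  daylight window: %.1f h; PE form: %s\n",
              x$daylength_h, x$form))
  invisible(x)
}
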