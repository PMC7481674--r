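#' Construct an absorption spectrum
#'
#' @param wavelength_nm Wavelengths, nm, strictly increasing, within
#'   350--750 nm.
#' @param value Absorption coefficients, m^-1 (or m^2 (mg chl)^-1 for
#'   chlorophyll-specific spectra; dimensionless for normalized shapes).
#' @param kind One of `"water"`, `"phytoplankton_specific"`, `"cdom"`,
#'   `"normalized_shape"`. A normalized shape must equal 1 at 440 nm.
#' @return A tibble with columns `wavelength_nm`, `value` and a `kind`
#'   attribute.
#' @export
absorption_spectrum <- function(wavelength_nm, value,
                                kind = c("water", "phytoplankton_specific",
                                         "cdom", "normalized_shape")) {
  kind <- match.arg(kind)
  assert_finite(wavelength_nm, "wavelength_nm")
  assert_finite(value, "value")
  if (length(wavelength_nm) != length(value)) {
    stop_scmprod("wavelengths and values must have equal length",
                 "invalid_parameter")
  }
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    stop_scmprod("wavelengths must be strictly increasing", "invalid_parameter")
  }
  if (any(wavelength_nm < 350 | wavelength_nm > 750)) {
    stop_scmprod("wavelengths must lie within [350, 750] nm",
                 "invalid_parameter")
  }
  if (any(value < 0)) stop_scmprod("values must be >= 0", "invalid_parameter")
  if (kind == "normalized_shape") {
    v440 <- approx(wavelength_nm, value, xout = 440)$y
    if (!isTRUE(abs(v440 - 1) < 1e-6)) {
      stop_scmprod("normalized shape must equal 1.0 at 440 nm",
                   "invalid_parameter")
    }
  }
  out <- tibble(wavelength_nm = wavelength_nm, value = value)
  attr(out, "kind") <- kind
  out
}

spectrum_kind <- function(spec) {
  k <- attr(spec, "kind")
  if (is.null(k)) "unknown" else k
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; the target grid must lie within the spectrum's
#' coverage.
#'
#' @param spec Spectrum tibble (`wavelength_nm`, `value`).
#' @param wavelengths Target grid, nm.
#' @return Resampled spectrum tibble (same `kind`).
#' @export
resample_spectrum <- function(spec, wavelengths) {
  if (min(wavelengths) < min(spec$wavelength_nm) - 1e-9 ||
      max(wavelengths) > max(spec$wavelength_nm) + 1e-9) {
    stop_scmprod("target grid extends beyond spectrum coverage",
                 "configuration")
  }
  v <- approx(spec$wavelength_nm, spec$value, xout = wavelengths)$y
  out <- tibble(wavelength_nm = wavelengths, value = v)
  attr(out, "kind") <- spectrum_kind(spec)
  out
}

#' Bundled pure-water absorption spectrum
#'
#' A published-style tabulation of pure-water absorption over 400--700 nm
#' (m^-1), used as the default water component of the absorption budget.
#' Any two-column file (`wavelength_nm`, `value`) can be supplied instead.
#'
#' @param path Optional path to a replacement table.
#' @return Spectrum tibble of kind `"water"`.
#' @export
water_absorption <- function(path = NULL) {
  if (is.null(path)) path <- scmprod_extdata("water_absorption.csv")
  d <- readr::read_csv(path, show_col_types = FALSE)
  absorption_spectrum(d$wavelength_nm, d$value, kind = "water")
}

#' CDOM absorption parameters
#'
#' Coloured dissolved organic matter (yellow substances) absorbs with a
#' decreasing exponential, `a_y(lambda) = a_y(440) * exp(-slope *
#' (lambda - 440))`. The magnitude `a_y(440)` is either scaled to the sum of
#' phytoplankton and water absorption at 440 nm (`ratio440`, default 0.30)
#' or fixed at `background440` (m^-1); the two modes are mutually
#' exclusive.
#'
#' @param slope Spectral slope, nm^-1 (> 0). Default 0.014.
#' @param ratio440 Scaling ratio a_y(440) / (a_ph(440) + a_w(440)).
#'   Default 0.30.
#' @param background440 Optional fixed a_y(440), m^-1 (the extreme
#'   terrigenous-influence experiment uses 0.07).
#' @return A list of class `scm_cdom_params`.
#' @export
cdom_params <- function(slope = 0.014, ratio440 = 0.30, background440 = NULL) {
  if (!is.null(background440) && !missing(ratio440)) {
    stop_scmprod("set either ratio440 or background440, not both",
                 "configuration")
  }
  if (slope <= 0) stop_scmprod("slope must be > 0", "invalid_parameter")
  if (ratio440 < 0) stop_scmprod("ratio440 must be >= 0", "invalid_parameter")
  structure(
    list(slope = slope, ratio440 = ratio440, background440 = background440),
    class = "scm_cdom_params"
  )
}

#' CDOM absorption spectrum
#'
#' @param cdom Parameters from [cdom_params()].
#' @param aph440 Phytoplankton absorption at 440 nm, m^-1 (ignored in
#'   background mode).
#' @param aw440 Pure-water absorption at 440 nm, m^-1.
#' @param wavelengths Wavelength grid, nm.
#' @return Spectrum tibble of kind `"cdom"`.
#' @export
cdom_absorption <- function(cdom, aph440, aw440, wavelengths) {
  ay440 <- if (!is.null(cdom$background440)) {
    cdom$background440
  } else {
    cdom$ratio440 * (aph440 + aw440)
  }
  v <- ay440 * exp(-cdom$slope * (wavelengths - 440))
  out <- tibble(wavelength_nm = wavelengths, value = v)
  attr(out, "kind") <- "cdom"
  out
}

#' Mean 440-nm-normalized absorption shape
#'
#' Each input spectrum is divided by its (interpolated) value at 440 nm,
#' the normalized spectra are averaged pointwise on a common grid, and the
#' mean is re-normalized to exactly 1.0 at 440 nm. This is how a single
#' regional mean shape is built from per-assemblage phytoplankton spectra.
#'
#' @param spectra A list of spectrum tibbles (`wavelength_nm`, `value`).
#' @param wavelengths Common grid; defaults to the first spectrum's grid.
#' @return Spectrum tibble of kind `"normalized_shape"`.
#' @export
mean_normalized_spectrum <- function(spectra, wavelengths = NULL) {
  if (length(spectra) == 0L) {
    stop_scmprod("need at least one spectrum", "configuration")
  }
  if (is.null(wavelengths)) wavelengths <- spectra[[1]]$wavelength_nm
  normed <- lapply(spectra, function(s) {
    v440 <- approx(s$wavelength_nm, s$value, xout = 440)$y
    if (!isTRUE(v440 > 0)) {
      stop_scmprod("spectrum is zero (or undefined) at 440 nm", "domain")
    }
    approx(s$wavelength_nm, s$value / v440, xout = wavelengths)$y
  })
  m <- Reduce(`+`, normed) / length(normed)
  m440 <- approx(wavelengths, m, xout = 440)$y
  out <- tibble(wavelength_nm = wavelengths, value = m / m440)
  attr(out, "kind") <- "normalized_shape"
  out
}

#' Assemble the bio-optical absorption model
#'
#' Collects the absorbing components that drive attenuation: pure water,
#' a chlorophyll-specific phytoplankton term (normalized spectral shape
#' scaled by `aph_star_440`, m^2 (mg chl)^-1) and CDOM. All spectra are
#' resampled onto the common wavelength grid at construction.
#'
#' @param water Water spectrum; default [water_absorption()].
#' @param phyto_shape 440-nm-normalized phytoplankton shape; default
#'   [synth_spectrum()].
#' @param aph_star_440 Chlorophyll-specific phytoplankton absorption at
#'   440 nm, m^2 (mg chl)^-1. Default 0.05.
#' @param cdom [cdom_params()].
#' @param wavelengths Model grid, nm. Default 400--700 at 5 nm.
#' @return An object of class `scm_optical_model`.
#' @export
optical_model <- function(water = water_absorption(),
                          phyto_shape = synth_spectrum(),
                          aph_star_440 = 0.05,
                          cdom = cdom_params(),
                          wavelengths = seq(400, 700, by = 5)) {
  if (aph_star_440 < 0) {
    stop_scmprod("aph_star_440 must be >= 0", "invalid_parameter")
  }
  aw <- resample_spectrum(water, wavelengths)$value
  shp <- resample_spectrum(phyto_shape, wavelengths)$value
  i440 <- which.min(abs(wavelengths - 440))
  structure(
    list(
      wavelengths = wavelengths,
      aw = aw,
      shape = shp,
      aw440 = approx(wavelengths, aw, xout = 440)$y,
      shape440 = approx(wavelengths, shp, xout = 440)$y,
      aph_star_440 = aph_star_440,
      cdom = cdom,
      i440 = i440
    ),
    class = "scm_optical_model"
  )
}

# a_y(440) for a given reference (surface) chlorophyll, m^-1
ay440_value <- function(model, chl_ref) {
  if (!is.null(model$cdom$background440)) return(model$cdom$background440)
  aph440 <- chl_ref * model$aph_star_440 * model$shape440
  model$cdom$ratio440 * (aph440 + model$aw440)
}

# total absorption matrix over depth x wavelength for a chlorophyll vector;
# the CDOM magnitude is set by the reference (surface) chlorophyll and is
# constant over depth
absorption_matrix <- function(model, chl, chl_ref = chl[1]) {
  ay <- ay440_value(model, chl_ref) *
    exp(-model$cdom$slope * (model$wavelengths - 440))
  base <- model$aw + ay                              # wavelength vector
  outer(chl, model$aph_star_440 * model$shape) +
    matrix(base, nrow = length(chl), ncol = length(base), byrow = TRUE)
}

#' Total spectral absorption at one chlorophyll concentration
#'
#' `a_total(lambda) = a_w + chl * aph_star_440 * shape(lambda) +
#' a_y(lambda)`.
#'
#' @param model [optical_model()].
#' @param chl Chlorophyll concentration, mg m^-3 (>= 0).
#' @param chl_for_cdom Reference chlorophyll setting the CDOM magnitude
#'   (defaults to `chl`).
#' @return Spectrum tibble, m^-1.
#' @export
total_absorption <- function(model, chl, chl_for_cdom = chl) {
  if (chl < 0) stop_scmprod("chl must be >= 0", "domain")
  a <- absorption_matrix(model, chl, chl_ref = chl_for_cdom)[1, ]
  tibble(wavelength_nm = model$wavelengths, value = a)
}
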