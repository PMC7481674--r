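#' Sky and run conditions
#'
#' @param latitude Degrees north (|lat| <= 90).
#' @param day_of_year 1--366.
#' @param cloud_fraction Fractional daily cloud cover, 0 (clear sky) to 1.
#' @param time_step Nominal time step, hours (the surface model uses
#'   `n_times` nodes over the daylight window; this records the requested
#'   resolution).
#' @return A list of class `scm_sky`.
#' @export
sky_conditions <- function(latitude, day_of_year, cloud_fraction = 0,
                           time_step = 1) {
  if (abs(latitude) > 90) stop_scmprod("|latitude| must be <= 90", "domain")
  if (day_of_year < 1 || day_of_year > 366) {
    stop_scmprod("day_of_year must be in 1..366", "domain")
  }
  if (cloud_fraction < 0 || cloud_fraction > 1) {
    stop_scmprod("cloud_fraction must be in [0, 1]", "domain")
  }
  structure(
    list(latitude = latitude, day_of_year = day_of_year,
         cloud_fraction = cloud_fraction, time_step = time_step),
    class = "scm_sky"
  )
}

# Cooper's formula for solar declination, degrees
solar_declination <- function(day_of_year) {
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Solar geometry for a station day
#'
#' Solar zenith angles from standard astronomical formulae (declination
#' from day of year, hour angle from local solar time). Handles polar day
#' (24 h daylight window) and polar night (empty window).
#'
#' @param sky [sky_conditions()].
#' @param times Hours from local midnight; default hourly 0..24.
#' @return A tibble with `time_h`, `zenith_deg`, `daylight` (logical),
#'   carrying `declination_deg`, `sunrise_h`, `sunset_h`, `daylength_h` as
#'   attributes. For polar night `daylength_h` is 0; for midnight sun 24.
#' @export
solar_geometry <- function(sky, times = seq(0, 24, by = 1)) {
  lat <- sky$latitude * pi / 180
  dec <- solar_declination(sky$day_of_year) * pi / 180
  hour_angle <- (times - 12) * 15 * pi / 180
  cosz <- sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(hour_angle)
  zen <- acos(pmin(pmax(cosz, -1), 1)) * 180 / pi

  cos_h0 <- -tan(lat) * tan(dec)
  if (cos_h0 <= -1) {            # midnight sun
    sunrise <- 0; sunset <- 24
  } else if (cos_h0 >= 1) {      # polar night
    sunrise <- NA_real_; sunset <- NA_real_
  } else {
    h0 <- acos(cos_h0) * 180 / pi / 15
    sunrise <- 12 - h0; sunset <- 12 + h0
  }
  daylength <- if (is.na(sunrise)) 0 else sunset - sunrise

  out <- tibble(time_h = times, zenith_deg = zen, daylight = zen < 90)
  attr(out, "declination_deg") <- dec * 180 / pi
  attr(out, "sunrise_h") <- sunrise
  attr(out, "sunset_h") <- sunset
  attr(out, "daylength_h") <- daylength
  out
}

#' Bundled extraterrestrial solar spectrum
#'
#' Mean exoatmospheric solar spectral irradiance over 400--700 nm
#' (W m^-2 nm^-1), used by the clear-sky model. Replaceable via `path`.
#'
#' @param path Optional two-column CSV (`wavelength_nm`,
#'   `irradiance_w_m2_nm`).
#' @return Tibble with `wavelength_nm`, `irradiance_w_m2_nm`.
#' @export
solar_spectrum <- function(path = NULL) {
  if (is.null(path)) path <- scmprod_extdata("solar_spectrum.csv")
  readr::read_csv(path, show_col_types = FALSE)
}

# W m^-2 nm^-1 -> umol quanta m^-2 s^-1 nm^-1 at wavelength lambda (nm)
watts_to_quanta <- function(lambda_nm) lambda_nm * 0.0083593

# Kasten & Young relative optical air mass
air_mass <- function(zenith_deg) {
  1 / (cos(zenith_deg * pi / 180) +
         0.50572 * (96.07995 - zenith_deg)^(-1.6364))
}

#' Clear-sky spectral surface irradiance
#'
#' A two-stream direct/diffuse parameterization: Rayleigh, aerosol and
#' ozone (Chappuis band) transmittances applied to the bundled
#' extraterrestrial spectrum, with half of the Rayleigh-scattered and most
#' of the aerosol-scattered light recovered as downwelling diffuse
#' irradiance. Output is in umol quanta m^-2 s^-1 nm^-1 just above the sea
#' surface. Any externally supplied surface spectrum can be used instead by
#' constructing the same object with [surface_irradiance()].
#'
#' @param sky [sky_conditions()].
#' @param times Hours from local midnight; default 25 nodes spanning the
#'   daylight window (all 24 h under midnight sun).
#' @param wavelengths Grid, nm. Default 400--700 at 5 nm.
#' @param aerosol_beta Angstrom turbidity coefficient. Default 0.05
#'   (clean marine Arctic).
#' @param aerosol_alpha Angstrom exponent. Default 1.3.
#' @param ozone_atm_cm Ozone column, atm cm. Default 0.35.
#' @return An object of class `scm_surface_irradiance`: times, wavelengths,
#'   `direct` and `diffuse` matrices (time x wavelength), zenith angles.
#' @export
clear_sky_spectrum <- function(sky, times = NULL,
                               wavelengths = seq(400, 700, by = 5),
                               aerosol_beta = 0.05, aerosol_alpha = 1.3,
                               ozone_atm_cm = 0.35) {
  geom_day <- solar_geometry(sky, times = seq(0, 24, by = 0.25))
  if (is.null(times)) {
    sr <- attr(geom_day, "sunrise_h"); ss <- attr(geom_day, "sunset_h")
    if (is.na(sr)) {
      times <- seq(0, 24, length.out = 25)   # polar night: all dark
    } else {
      times <- seq(sr, ss, length.out = 25)
    }
  }
  geom <- solar_geometry(sky, times = times)

  e0 <- solar_spectrum()
  e0v <- approx(e0$wavelength_nm, e0$irradiance_w_m2_nm,
                xout = wavelengths)$y * watts_to_quanta(wavelengths)

  lam_um <- wavelengths / 1000
  tau_r <- 0.008735 * lam_um^(-4.08)
  tau_a <- aerosol_beta * lam_um^(-aerosol_alpha)
  k_oz <- 0.12 * exp(-((wavelengths - 602) / 80)^2)   # Chappuis band, atm-cm^-1

  nt <- length(times); nl <- length(wavelengths)
  direct <- matrix(0, nt, nl)
  diffuse <- matrix(0, nt, nl)
  up <- geom$zenith_deg < 90
  for (i in which(up)) {
    m <- air_mass(geom$zenith_deg[i])
    cz <- cos(geom$zenith_deg[i] * pi / 180)
    t_r <- exp(-tau_r * m)
    t_a <- exp(-tau_a * m)
    t_o <- exp(-k_oz * ozone_atm_cm * m)
    direct[i, ] <- e0v * cz * t_r * t_a * t_o
    diffuse[i, ] <- e0v * cz * t_o *
      (0.5 * (1 - t_r) * t_a + 0.85 * t_r * (1 - t_a))
  }
  surface_irradiance(times, wavelengths, direct, diffuse,
                     zenith_deg = geom$zenith_deg,
                     cloud_fraction = 0)
}

#' Construct a surface irradiance object
#'
#' Container for spectral downwelling irradiance just above the sea
#' surface, split into direct and diffuse streams. Use this to supply a
#' measured or externally modelled surface light field.
#'
#' @param times Hours from local midnight.
#' @param wavelengths nm.
#' @param direct,diffuse Matrices (time x wavelength), umol quanta
#'   m^-2 s^-1 nm^-1, zero when the sun is below the horizon.
#' @param zenith_deg Solar zenith angle per time, degrees.
#' @param cloud_fraction Cloud fraction the field corresponds to.
#' @return An object of class `scm_surface_irradiance`.
#' @export
surface_irradiance <- function(times, wavelengths, direct, diffuse,
                               zenith_deg, cloud_fraction = 0) {
  if (any(direct < 0) || any(diffuse < 0)) {
    stop_scmprod("irradiance must be >= 0", "invalid_parameter")
  }
  structure(
    list(times = times, wavelengths = wavelengths,
         direct = direct, diffuse = diffuse,
         zenith_deg = zenith_deg, cloud_fraction = cloud_fraction),
    class = "scm_surface_irradiance"
  )
}

#' Total surface PAR time series
#'
#' @param surface [surface_irradiance()] object.
#' @return Tibble with `time_h`, `par` (umol quanta m^-2 s^-1, 400--700 nm).
#' @export
surface_par <- function(surface) {
  w <- trapz_weights(surface$wavelengths)
  tibble(
    time_h = surface$times,
    par = as.numeric((surface$direct + surface$diffuse) %*% w)
  )
}

#' Apply cloud cover to a clear-sky surface field
#'
#' Total irradiance is multiplied by a monotone cloud factor, by default
#' the classic linear ocean-surface attenuation `f(C) = 1 - 0.62 * C`
#' (so `f(0) = 1`), and the diffuse fraction is blended linearly toward 1
#' with cloud fraction, reaching all-diffuse at full overcast. The factor
#' is a configurable strategy (any monotone decreasing `f` with
#' `f(0) = 1` can be supplied).
#'
#' @param surface Clear-sky [surface_irradiance()].
#' @param cloud_fraction 0--1.
#' @param cloud_factor Function of `C` giving the total-irradiance factor.
#' @return A new `scm_surface_irradiance`.
#' @export
apply_cloud <- function(surface, cloud_fraction,
                        cloud_factor = function(C) 1 - 0.62 * C) {
  if (cloud_fraction < 0 || cloud_fraction > 1) {
    stop_scmprod("cloud_fraction must be in [0, 1]", "domain")
  }
  f <- cloud_factor(cloud_fraction)
  total <- (surface$direct + surface$diffuse) * f
  # pointwise clear-sky diffuse fraction, blended linearly toward 1
  denom <- surface$direct + surface$diffuse
  d0 <- ifelse(denom > 0, surface$diffuse / denom, 1)
  dc <- d0 + (1 - d0) * cloud_fraction
  surface_irradiance(
    surface$times, surface$wavelengths,
    direct = total * (1 - dc), diffuse = total * dc,
    zenith_deg = surface$zenith_deg, cloud_fraction = cloud_fraction
  )
}

# unpolarized Fresnel transmittance across air -> water
fresnel_transmittance <- function(zenith_deg, n_water = 1.34) {
  th_i <- zenith_deg * pi / 180
  if (th_i < 1e-9) {
    r <- ((n_water - 1) / (n_water + 1))^2
    return(1 - r)
  }
  th_t <- asin(sin(th_i) / n_water)
  rs <- (sin(th_i - th_t) / sin(th_i + th_t))^2
  rp <- (tan(th_i - th_t) / tan(th_i + th_t))^2
  1 - (rs + rp) / 2
}

#' Propagate surface irradiance through the water column
#'
#' The direct beam is refracted across the air--sea interface (Snell's law,
#' refractive index `n_water`), loses a zenith-dependent Fresnel
#' reflectance, and is attenuated along its slant path:
#' `dE/dz = -a_total(z, lambda) E / cos(theta_w)`. The diffuse stream loses
#' a fixed near-normal-incidence 4% at the interface and is attenuated with
#' mean cosine `mu_d`. Attenuation is absorption-driven and depth-varying:
#' `a_total` uses the local chlorophyll `B(z)` of the profile, with the
#' CDOM magnitude scaled from the surface chlorophyll.
#'
#' @param surface [surface_irradiance()] (above-water).
#' @param profile Gaussian profile parameters (one row).
#' @param model [optical_model()].
#' @param depths Depth grid, m, starting at 0, increasing. Default 0--200
#'   at 0.5 m.
#' @param mu_d Mean cosine of the diffuse stream in water. Default 0.83.
#' @param n_water Refractive index of seawater. Default 1.34.
#' @param diffuse_loss Air--sea transmission loss of the diffuse stream.
#'   Default 0.04.
#' @return An object of class `scm_light_field`: `E` array
#'   (depth x time x wavelength, umol quanta m^-2 s^-1 nm^-1), `par` matrix
#'   (depth x time), grids, and the optical model and profile used.
#' @export
propagate <- function(surface, profile, model,
                      depths = seq(0, 200, by = 0.5),
                      mu_d = 0.83, n_water = 1.34, diffuse_loss = 0.04) {
  if (length(depths) < 2L || depths[1] != 0 || is.unsorted(depths, strictly = TRUE)) {
    stop_scmprod("depth grid must start at 0 and increase", "configuration")
  }
  if (any(!is.finite(depths))) {
    stop_scmprod("depth grid must be finite", "configuration")
  }
  wl <- surface$wavelengths
  if (!isTRUE(all.equal(wl, model$wavelengths))) {
    stop_scmprod("surface and optical model wavelength grids differ",
                 "internal_consistency")
  }
  chl <- evaluate_profile(profile, depths)
  a <- absorption_matrix(model, chl)            # depth x wavelength
  # cumulative optical depth per wavelength (vertical path)
  Cz <- apply(a, 2, function(col) cumtrapz(depths, col))

  nt <- length(surface$times); nz <- length(depths); nl <- length(wl)
  E <- array(0, dim = c(nz, nt, nl))
  t_dif <- exp(-Cz / mu_d)                       # time-independent
  for (i in seq_len(nt)) {
    zen <- surface$zenith_deg[i]
    if (zen >= 90) next
    tf <- fresnel_transmittance(zen, n_water)
    th_w <- asin(sin(zen * pi / 180) / n_water)
    t_dir <- exp(-Cz / cos(th_w))
    Ei <- t_dir * matrix(surface$direct[i, ] * tf, nz, nl, byrow = TRUE) +
      t_dif * matrix(surface$diffuse[i, ] * (1 - diffuse_loss), nz, nl,
                     byrow = TRUE)
    E[, i, ] <- Ei
  }
  w <- trapz_weights(wl)
  par <- matrix(0, nz, nt)
  for (i in seq_len(nt)) par[, i] <- E[, i, ] %*% w

  structure(
    list(depths = depths, times = surface$times, wavelengths = wl,
         E = E, par = par, surface = surface, model = model,
         profile = as_tibble(profile)),
    class = "scm_light_field"
  )
}

#' Photic depth (1% PAR level)
#'
#' The depth at which PAR (irradiance integrated 400--700 nm) falls to 1%
#' of its just-below-surface value, located by log-linear interpolation
#' between the bracketing grid nodes (exact for exponential decay).
#' Evaluated at local solar noon (the time of maximum surface PAR) unless
#' `t_ref` is given.
#'
#' @param field [propagate()] output.
#' @param t_ref Optional reference time, hours; defaults to the time of
#'   maximum sub-surface PAR.
#' @param fraction Light level defining the photic depth. Default 0.01.
#' @return Photic depth, m. `NA` (with a warning) when surface PAR is zero
#'   (polar night).
#' @export
photic_depth <- function(field, t_ref = NULL, fraction = 0.01) {
  i <- if (is.null(t_ref)) {
    which.max(field$par[1, ])
  } else {
    which.min(abs(field$times - t_ref))
  }
  p <- field$par[, i]
  if (p[1] <= 0) {
    warn("surface PAR is zero (polar night); no photic depth",
         class = "scmprod_warning_no_photic_depth")
    return(NA_real_)
  }
  target <- fraction * p[1]
  below <- which(p <= target)
  if (length(below) == 0L) {
    stop_scmprod(
      sprintf("PAR does not reach %.3g%% of surface within the depth grid (max %.1f m); extend the grid",
              100 * fraction, max(field$depths)),
      "configuration"
    )
  }
  j <- below[1]
  if (j == 1L) return(0)
  z1 <- field$depths[j - 1L]; z2 <- field$depths[j]
  l1 <- log(p[j - 1L]); l2 <- log(max(p[j], .Machine$double.xmin))
  z1 + (log(target) - l1) * (z2 - z1) / (l2 - l1)
}
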