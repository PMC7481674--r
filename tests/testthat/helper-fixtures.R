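# shared fixtures: coarse grids keep unit tests fast; acceptance tests use
# the package defaults

tiny_config <- function(...) {
  run_config(wavelengths = seq(400, 700, by = 10),
             depths = seq(0, 300, by = 1), ...)
}

# flat (wavelength-independent) optical model: pure absorber `a`, no
# phytoplankton, no CDOM
flat_model <- function(a = 0.1, wavelengths = seq(400, 700, by = 10)) {
  water <- absorption_spectrum(c(400, 700), c(a, a), kind = "water")
  shape <- absorption_spectrum(c(400, 700), c(1, 1), kind = "normalized_shape")
  optical_model(water = water, phyto_shape = shape, aph_star_440 = 0,
                cdom = cdom_params(ratio440 = 0),
                wavelengths = wavelengths)
}

# single-time surface field: sun at given zenith, direct and/or diffuse,
# flat unit spectrum scaled by `magnitude`
single_time_surface <- function(zenith = 0, magnitude = 1000,
                                diffuse_frac = 0,
                                wavelengths = seq(400, 700, by = 10),
                                times = c(0, 12, 24)) {
  nt <- length(times); nl <- length(wavelengths)
  direct <- matrix(magnitude * (1 - diffuse_frac) / 300, nt, nl)
  diffuse <- matrix(magnitude * diffuse_frac / 300, nt, nl)
  surface_irradiance(times, wavelengths, direct, diffuse,
                     zenith_deg = rep(zenith, nt), cloud_fraction = 0)
}

mean_field_profile <- function(station = "mean") {
  gaussian_profile(B0 = 0.19, h = 4.91 * 12.42, zm = 24.7, sigma = 12.42,
                   station = station)
}
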