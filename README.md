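# scmprod

Vertically and spectrally resolved modelling of water-column primary
production over subsurface chlorophyll maxima (SCMs) in stratified Arctic
seas.

Stratified, ice-melt-freshened Arctic water columns routinely hold a
subsurface chlorophyll peak between the nutrient-poor surface layer and the
dark interior. Whether that peak matters for depth-integrated carbon
fixation depends on the shape of the chlorophyll profile, the
photophysiology of the cells, and how much light survives down to the
layer. `scmprod` is for biological oceanographers who want to fit observed
profiles, run a spectral production model over them, and quantify the error
committed by common simplifications (uniform profiles, mis-assigned PE
parameters, clear-sky assumptions, ignored CDOM).

## The model in brief

* **Profile**: chlorophyll is a four-parameter shifted Gaussian
  `B(z) = B0 + h/(σ√(2π)) · exp(−(z−zm)²/(2σ²))`, fitted to bottle or
  (quenching-corrected) fluorescence data by bounded nonlinear least
  squares.
* **Optics**: absorption by pure water, phytoplankton
  (440-nm-normalized mean spectral shape × local `B(z)`) and CDOM
  (`a_y(440)·e^(−0.014(λ−440))`, scaled to 0.30 of phytoplankton + water
  absorption at 440 nm, or a fixed background).
* **Light**: a two-stream clear-sky spectrum (with a linear cloud factor
  `1 − 0.62C`) is refracted across the interface and attenuated along
  angular paths; the photic depth `z_p` is the 1% PAR level.
* **Production**: the spectral light-limited rate
  `Π = ∫ α^B(λ) E(z,λ) dλ` saturates as `P^B = Π/√(1+(Π/Pm^B)²)` toward the
  assimilation number; volumetric rates `B(z)·P^B` are integrated over the
  daylight window and down to `z_p`, in mg C m⁻² d⁻¹.
* **Sensitivity**: paired runs per station — non-uniform vs uniform
  profile, PE parameters ±1 s.d., CDOM raised to a 0.07 m⁻¹ background,
  cloud cover 0–100% — with OLS regressions of the percent error against
  the shape indices `z_m/σ` and `z_m/z_p`.

A synthetic-station generator (truncated lognormal/normal parameter draws
matching Atlantic Arctic field statistics, noisy bottle casts, quenched
fluorescence traces, pigment-band absorption shapes) makes the whole
pipeline runnable and testable without any external data.

## Worked example

Daily production for the field-mean profile (`B0 = 0.19` mg m⁻³,
`z_m = 24.7` m, `σ = 12.42` m, `h/σ = 4.91`) with mean PE parameters
(`Pm^B = 1.73`, `α^B = 0.034`) on a clear July day at 75°N:

```r
library(scmprod)

profile <- gaussian_profile(B0 = 0.19, h = 4.91 * 12.42, zm = 24.7,
                            sigma = 12.42, station = "mean")
pe <- pe_params(PmB = 1.73, alphaB = 0.034)
station_dpp(profile, pe, run_config())
#>   station dpp_integrated    zp zm_over_zp zm_over_sigma dpp_surface
#> 1    mean           1580 47.87      0.516         1.989       18.48
```

The water column fixes about 1580 mg C m⁻² d⁻¹ down to a photic depth of
47.9 m; the peak sits halfway down the photic zone (`z_m/z_p = 0.52`) with
shape index `z_m/σ = 1.99`, and the surface rate is 18.5 mg C m⁻³ d⁻¹.

How much of that would a uniform-profile assumption miss? On a small
synthetic ensemble:

```r
cfg <- generator_config(n_stations = 12, seed = 1)
profiles <- sample_profiles(cfg)
uvn <- run_uniform_vs_nonuniform(profiles, pe, run_config())
summary(uvn$percent_difference)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -41.77   15.99   37.36   63.34   92.19  229.27
glance(regress(uvn, x = zm_over_sigma, subset = zm_over_sigma < 4.6))
#>   slope intercept r.squared p.value n         subset_rule
#> 1  40.9     -20.1     0.483  0.0377 9 zm_over_sigma < 4.6
```

Positive percent differences are production the uniform run misses
(deep/narrow peaks, here up to +229%); negative ones are surface-intense
profiles the uniform run overestimates. Below the `z_m/σ = 4.6` breakdown
the error scales with the shape index. `plot_sensitivity(uvn,
x = zm_over_sigma, colour = sigma)` draws the relation; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`.

See the vignette (`vignettes/scm-production-model.Rmd`) for the full model
description, parameter table and design rationale.

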