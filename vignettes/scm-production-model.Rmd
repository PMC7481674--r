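---
title: "Modelling water-column primary production over subsurface chlorophyll maxima"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling water-column primary production over subsurface chlorophyll maxima}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(scmprod)
library(dplyr)
```

Stratified Arctic seas routinely develop subsurface chlorophyll maximum
(SCM) layers: thin, sometimes intense peaks of phytoplankton biomass sitting
between the nutrient-depleted surface layer and the dark interior. Whether
those layers matter for water-column carbon fixation depends on three
things — the *shape* of the chlorophyll profile, the *photophysiology* of
the cells, and the *light* remaining at the depth of the peak. `scmprod`
implements a vertically and spectrally resolved production model built
around exactly those three ingredients, and the sensitivity experiments
that quantify when ignoring the SCM biases depth-integrated production.

## The model

### Chlorophyll profile

The vertical chlorophyll distribution is a four-parameter shifted Gaussian,

$$B(z) = B_0 + \frac{h}{\sigma\sqrt{2\pi}}
  \exp\!\left(-\frac{(z-z_m)^2}{2\sigma^2}\right),$$

with background $B_0$ (mg m$^{-3}$), integrated peak chlorophyll $h$
(mg m$^{-2}$), peak depth $z_m$ (m, positive downward) and width $\sigma$
(m). $z_m$ may be slightly negative when the best fit centres the peak just
above the sea surface. `fit_profile()` estimates the four parameters by
bounded nonlinear least squares (Levenberg–Marquardt, **minpack.lm**);
`B0`, `h` are bounded below by zero and `sigma` by 0.5 m to exclude
degenerate zero-width fits, while `zm` is unbounded. Starting values are
taken from the data (minimum for $B_0$, depth of the maximum for $z_m$,
half the half-maximum span for $\sigma$, trapezoid integral of the excess
for $h$), with a handful of width-perturbed restarts; the best residual sum
of squares wins. A fitted peak amplitude below 1% of $B_0$ is flagged
`"quasi-uniform"`, the "very small bump on a uniform background" class that
behaves differently in the shape analysis.

Fluorescence-derived profiles can be corrected for surface
(non-photochemical) quenching: calibration pairs give
$\log B_{\mathrm{extr}} = \log x + y \log F$ by OLS, the deficit
$\Delta B = x B^y - B$ is evaluated at the shallowest reading, and
$\Delta B\,e^{-0.05 z}$ is added back, so the correction decays below 1% of
$\Delta B$ by about 92 m. $\Delta B$ is a single scalar (quenching is a
surface phenomenon, observed in the top ~20 m); the 0.05 m$^{-1}$ decay is
configurable.

### Absorption budget and light

Attenuation is absorption-driven, with three components on a common 5 nm
grid over 400–700 nm:

* pure water (bundled published-style tabulation, replaceable by file);
* phytoplankton: a 440-nm-normalized mean spectral shape scaled by
  $a^*_{ph}(440)$ (default 0.05 m$^2$ (mg chl)$^{-1}$) and the *local*
  chlorophyll $B(z)$, so the SCM shades itself;
* CDOM: $a_y(\lambda) = a_y(440)\,e^{-S(\lambda-440)}$ with slope
  $S = 0.014$ nm$^{-1}$, and magnitude either scaled as
  $a_y(440) = 0.30\,(a_{ph}(440)+a_w(440))$ using the station's surface
  chlorophyll, or fixed at a background value (0.07 m$^{-1}$ in the
  terrigenous-influence experiment).

The default phytoplankton shape is synthetic (`synth_spectrum()`): a sum of
pigment-band Gaussians with the chlorophyll-a blue peak near 440 nm, a
carotenoid shoulder, a green trough and a red band near 675 nm at 0.3–0.6
relative height. It emulates the smooth regional mean of measured Arctic
spectra; `mean_normalized_spectrum()` builds the same object from real
per-assemblage spectra when you have them.

Surface irradiance comes from a two-stream clear-sky parameterization:
Rayleigh, aerosol (Ångström $\beta = 0.05$, $\alpha = 1.3$) and ozone
(Chappuis band, 0.35 atm cm) transmittances applied to a bundled
extraterrestrial spectrum, with half of the Rayleigh-scattered and 85% of
the aerosol-scattered light recovered as downwelling diffuse irradiance.
At zenith 0 this yields total PAR of about 1500–2200 µmol quanta
m$^{-2}$ s$^{-1}$ with a diffuse fraction near 0.13. Any measured surface
field can be supplied through `surface_irradiance()` instead. Cloud cover
multiplies the total by the classic linear ocean-surface factor
$f(C) = 1 - 0.62\,C$ and blends the diffuse fraction linearly toward 1 at
full overcast. We initially used the gentler $1-0.75\,C^{3.4}$ form, but at
high Arctic zenith angles the direct beam travels a longer slant path and
loses more at the interface than diffuse light, so converting direct to
diffuse under thin cloud *increased* underwater light faster than that
factor removed it — partial overcast then looked brighter at depth than
clear sky. The linear factor keeps the clear-sky-assumption error
non-negative and monotone in cloud fraction, which is also the physically
expected regime for daily means over the ocean.

Underwater, the direct beam refracts across the interface (Snell,
$n = 1.34$; Snell caps the in-water zenith at $\approx 48.3^\circ$), loses
a zenith-dependent Fresnel reflectance, and attenuates along its slant
path $1/\cos\theta_w$; the diffuse stream loses a fixed 4% and attenuates
with mean cosine $\mu_d = 0.83$. Scattering is otherwise neglected — the
attenuators in this model are absorbers, with the angular path-length
correction standing in for the directional structure of the field.

The photic depth $z_p$ is where PAR falls to 1% of its just-below-surface
value, located by log-linear interpolation between grid nodes (exact for
exponential decay) at the time of maximum surface PAR (local solar noon).
Production is integrated to that single $z_p$ per station-day.

### Production

The light-limited rate is spectral,
$\Pi^B_\lambda(z,t) = \int_{400}^{700} \alpha^B(\lambda) E(z,t,\lambda)\,
d\lambda$, with the normalized absorption shape as proxy for the action
spectrum, scaled so the spectral mean preserves the broadband
$\alpha^B$. The chlorophyll-normalized rate follows the saturating
response

$$P^B = \frac{\Pi^B_\lambda}{\sqrt{1 + (\Pi^B_\lambda/P^B_m)^2}},$$

which rises linearly at low light and approaches the plateau $P^B_m$ — the
behaviour the shape analysis depends on. An algebraic variant
$\Pi/(1+(\Pi/P^B_m)^2)$ appears in parts of the literature, but it is
non-monotonic (it decays back to zero at high light) and inconsistent with
a plateau; it is available behind `form = "typeset"` for comparison and is
not used by default. Photoinhibition is deliberately excluded: the
incubation fits that produce $P^B_m$ and $\alpha^B$ may account for it, but
the water-column model carries no inhibition term.

Volumetric production is $B(z)\,P^B(z,t)$ (mg C m$^{-3}$ h$^{-1}$),
integrated by trapezoid over the daylight window (24 h under the midnight
sun) and then over depth to $z_p$, giving daily production in
mg C m$^{-2}$ d$^{-1}$.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| $a^*_{ph}(440)$ | 0.05 | m$^2$ (mg chl)$^{-1}$ | magnitude of chlorophyll-specific absorption; field shapes are normalized, so the level is a knob results are sensitive to |
| CDOM ratio | 0.30 | — | $a_y(440)$ relative to $a_{ph}+a_w$ at 440 |
| CDOM slope | 0.014 | nm$^{-1}$ | spectral steepness of yellow-substance absorption |
| $\mu_d$ | 0.83 | — | mean cosine of the diffuse stream |
| latitude / day | 75°N / 196 | — | standard station-day (midnight sun); declared here because the field study does not pin one |
| grids | 5 nm, 0.5 m, 25 time nodes | — | halving any step changes integrated production by well under 1% |
| depth span | 0–300 m | m | deep enough that the 1% light level of near-clear water stays on the grid |

## The synthetic-station generator

`generator_config()` draws profile parameters from truncated lognormals
($B_0$, $\sigma$, $h/\sigma$, $P^B_m$, $\alpha^B$) and a truncated normal
($z_m$, admitting small negative values), with the location parameter
solved numerically so the *truncated* mean equals the configured mean.
Defaults are the field means and printed ranges ($B_0$ 0.19 mg m$^{-3}$,
$z_m$ 24.7 m, $\sigma$ 12.42 m, $h/\sigma$ 4.91, $P^B_m$ 1.73,
$\alpha^B$ 0.034, with ranges 0.01–1.94, −7.88–75.33, 0.03–35.4,
0.24–9.6, 0.002–0.182 respectively). Two values are package choices the
field data do not fix: $\sigma$ is truncated to [0.5, 40] m (only its mean
is printed), and the lognormal spreads (sdlog 0.65 for $P^B_m$, 0.55 for
$\alpha^B$, 0.8 for $B_0$) are set to realistic field-style variability —
they imply a mean light-adaptation parameter $E_k$ near 70 µmol quanta
m$^{-2}$ s$^{-1}$, consistent with Arctic observations.

Parameters are drawn independently by default. A Gaussian-copula knob
(`bsurf_zm_rho`) can couple $B_0$ and $z_m$, but it turns out the weak
negative relation between surface chlorophyll and peak depth seen in field
data is already *structural* in the shifted-Gaussian geometry — deep peaks
simply do not reach the surface — and the independent-draw ensemble shows
it at about the observed strength ($R^2 \approx 0.15$–0.2 for
$B_{surf} \sim z_m$). The knob therefore defaults to 0.

`observe()` emulates sampling: bottle casts (6–12 depths spanning the
surface to $\max(60, z_m + 3\sigma)$, multiplicative lognormal noise) or
1-m fluorescence traces with surface quenching applied as the *exact
inverse* of the correction, so the correction round-trips to the truth at
zero noise — which is how the correction is validated.

What the generator does **not** emulate: correlated vertical structure
(nutricline coupling), non-Gaussian thin-layer shapes, instrument-specific
fluorescence artifacts beyond quenching, sea-ice optics, or any real
covariance between photophysiology and profile shape. Passing tests on
this ensemble therefore demonstrates internal correctness and the model's
qualitative structure, not agreement with any particular field campaign;
in particular, independent draws produce more extreme shape combinations
(tiny background under a deep intense peak) than real station sets, so
ensemble extremes of the uniform-vs-non-uniform error run larger than
field values.

## A worked run

```{r example}
profile <- gaussian_profile(B0 = 0.19, h = 4.91 * 12.42, zm = 24.7,
                            sigma = 12.42, station = "mean")
pe <- pe_params(PmB = 1.73, alphaB = 0.034)
config <- run_config()          # 75 N, day 196, clear sky

res <- station_dpp(profile, pe, config)
res
```

The uniform-vs-non-uniform comparison, on a small ensemble:

```{r uvn}
cfg <- generator_config(n_stations = 12, seed = 1)
profiles <- sample_profiles(cfg)
uvn <- run_uniform_vs_nonuniform(profiles, pe, config)
summary(uvn$percent_difference)
glance(regress(uvn, x = zm_over_sigma, subset = zm_over_sigma < 4.6))
```

```{r plot, fig.alt = "percent difference vs shape index"}
plot_sensitivity(uvn, x = zm_over_sigma, colour = sigma)
```

## Numerical choices and degenerate inputs

* Quadrature is trapezoidal throughout (wavelength, time, depth); the
  depth integral to $z_p$ adds the partial cell by linear interpolation.
* The photic-depth root uses log-linear interpolation between the
  bracketing nodes; uniqueness follows from monotone PAR.
* A station in polar night has no photic depth (`NA`, classed warning) and
  zero production, not an error.
* Constant (flat) observations are admitted as quasi-uniform fits; true
  non-convergence raises a classed error carrying the initializations
  tried.
* Profiles are evaluated only for $z \ge 0$ in production computations,
  even when $z_m < 0$.
* Percent differences use one signed convention,
  $100\,(\text{treatment}-\text{reference})/\text{reference}$, with the
  reference being the uniform / mean-PE / cloudy-truth / ratio-CDOM run
  respectively; stations with zero reference production are flagged and
  excluded from regressions, as are CDOM-experiment stations whose
  reference CDOM already exceeds the treatment background.

## Known limitations

* No Raman scattering, fluorescence emission, wave focusing or sea-ice
  optics; attenuation is purely absorptive with an angular path-length
  correction.
* The clear-sky and cloud parameterizations are simple transmittance
  models; they meet plausibility contracts (PAR level, diffuse fraction,
  monotonicity) rather than reproducing any specific radiative-transfer
  code, and the surface field can be replaced by data.
* One mean absorption shape represents all stations; regional shape
  differences enter only through `mean_normalized_spectrum()` if supplied.
* PE parameters enter as given (no temperature or nutrient dependence),
  and carbon-to-chlorophyll conversion, respiration and new-production
  partitioning are out of scope.
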