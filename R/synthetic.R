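# --- truncated distributions with a prescribed (truncated) mean ---------------

# mean of a lognormal truncated to [l, u]
trunc_lnorm_mean <- function(mu, s, l, u) {
  a <- (log(l) - mu) / s; b <- (log(u) - mu) / s
  denom <- pnorm(b) - pnorm(a)
  # far outside the window the mass piles up at the nearer bound
  if (denom < 1e-12) return(if (mu < log(l)) l else u)
  exp(mu + s^2 / 2) * (pnorm(b - s) - pnorm(a - s)) / denom
}

# mean of a normal truncated to [l, u]
trunc_norm_mean <- function(mu, s, l, u) {
  a <- (l - mu) / s; b <- (u - mu) / s
  denom <- pnorm(b) - pnorm(a)
  if (denom < 1e-12) return(if (mu < l) l else u)
  mu + s * (dnorm(a) - dnorm(b)) / denom
}

# solve the location parameter so the truncated mean equals `mean`
solve_lnorm_mu <- function(mean, s, l, u) {
  if (mean <= l || mean >= u) {
    stop_scmprod("target mean must lie inside the truncation range",
                 "configuration")
  }
  uniroot(function(m) trunc_lnorm_mean(m, s, l, u) - mean,
          lower = log(l) - 5, upper = log(u) + 5, tol = 1e-10)$root
}

solve_norm_mu <- function(mean, s, l, u) {
  if (mean <= l || mean >= u) {
    stop_scmprod("target mean must lie inside the truncation range",
                 "configuration")
  }
  uniroot(function(m) trunc_norm_mean(m, s, l, u) - mean,
          lower = l - 10 * s, upper = u + 10 * s, tol = 1e-10)$root
}

# inverse-CDF draws from the truncated laws, driven by uniforms so a Gaussian
# copula can impose correlation between parameters
q_trunc_lnorm <- function(p, mean, s, l, u) {
  if (s <= 0) return(rep(mean, length(p)))
  mu <- solve_lnorm_mu(mean, s, l, u)
  pl <- stats::plnorm(l, mu, s); pu <- stats::plnorm(u, mu, s)
  stats::qlnorm(pl + p * (pu - pl), mu, s)
}

q_trunc_norm <- function(p, mean, s, l, u) {
  if (s <= 0) return(rep(mean, length(p)))
  mu <- solve_norm_mu(mean, s, l, u)
  pl <- pnorm(l, mu, s); pu <- pnorm(u, mu, s)
  qnorm(pl + p * (pu - pl), mu, s)
}

#' Synthetic-station generator configuration
#'
#' Parameter distributions emulating the statistical structure of Atlantic
#' Arctic field data: truncated lognormals for the positive profile and PE
#' parameters (location solved so the truncated mean equals the configured
#' mean) and a truncated normal for the peak depth `zm`, which admits small
#' negative values. Defaults are the field means and printed ranges:
#' `B0` mean 0.19 (0.01--1.94 mg m^-3), `zm` mean 24.7 (-7.88--75.33 m),
#' `sigma` mean 12.42 m, `h/sigma` mean 4.91 (0.03--35.4 mg m^-3),
#' `PmB` mean 1.73 (0.24--9.6), `alphaB` mean 0.034 (0.002--0.182).
#' The width `sigma` has no printed range; truncation [0.5, 40] m is a
#' package default covering the observed spread of shapes.
#'
#' @param n_stations Number of stations to draw.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @param B0,zm,sigma,h_over_sigma,PmB,alphaB Lists with `mean`, spread
#'   (`sdlog` for lognormal, `sd` for `zm`) and `range`. A zero spread
#'   gives a point mass at the mean.
#' @param n_bottle_depths Range (min, max) of bottle depths per station.
#' @param bottle_noise Multiplicative lognormal noise sdlog for bottle
#'   samples. Default 0.05.
#' @param fluor_noise Same for fluorescence traces. Default 0.02.
#' @param quench_x,quench_y Quenching calibration coefficients used when
#'   generating surface-quenched fluorescence (x = 1, y = 1 disables
#'   quenching).
#' @param bsurf_zm_rho Optional Gaussian-copula correlation between `B0`
#'   and `zm` (negative values emulate the weak negative surface
#'   chlorophyll vs peak depth dependence). Default 0 (independent).
#' @return A list of class `scm_generator_config`.
#' @export
generator_config <- function(
    n_stations = 50, seed = 1,
    B0 = list(mean = 0.19, sdlog = 0.8, range = c(0.01, 1.94)),
    zm = list(mean = 24.7, sd = 15, range = c(-7.88, 75.33)),
    sigma = list(mean = 12.42, sdlog = 0.5, range = c(0.5, 40)),
    h_over_sigma = list(mean = 4.91, sdlog = 1.0, range = c(0.03, 35.4)),
    PmB = list(mean = 1.73, sdlog = 0.65, range = c(0.24, 9.6)),
    alphaB = list(mean = 0.034, sdlog = 0.55, range = c(0.002, 0.182)),
    n_bottle_depths = c(8, 12),
    bottle_noise = 0.05, fluor_noise = 0.02,
    quench_x = 1.3, quench_y = 1.0,
    bsurf_zm_rho = 0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_scmprod("a seed is mandatory for reproducibility", "configuration")
  }
  structure(
    list(n_stations = n_stations, seed = as.integer(seed),
         B0 = B0, zm = zm, sigma = sigma, h_over_sigma = h_over_sigma,
         PmB = PmB, alphaB = alphaB,
         n_bottle_depths = n_bottle_depths,
         bottle_noise = bottle_noise, fluor_noise = fluor_noise,
         quench_x = quench_x, quench_y = quench_y,
         bsurf_zm_rho = bsurf_zm_rho),
    class = "scm_generator_config"
  )
}

station_ids <- function(n) sprintf("st%03d", seq_len(n))

#' Draw synthetic Gaussian profile parameters
#'
#' @param cfg [generator_config()].
#' @return Tibble with `station`, `B0`, `h`, `zm`, `sigma` (and
#'   `h_over_sigma`); `h = (h/sigma) * sigma`.
#' @export
sample_profiles <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_stations
  rho <- cfg$bsurf_zm_rho
  z1 <- rnorm(n); z2 <- rnorm(n)
  u_b0 <- pnorm(z1)
  u_zm <- pnorm(rho * z1 + sqrt(1 - rho^2) * z2)
  u_sig <- runif(n); u_hs <- runif(n)

  b0 <- q_trunc_lnorm(u_b0, cfg$B0$mean, cfg$B0$sdlog, cfg$B0$range[1],
                      cfg$B0$range[2])
  zm <- q_trunc_norm(u_zm, cfg$zm$mean, cfg$zm$sd, cfg$zm$range[1],
                     cfg$zm$range[2])
  sg <- q_trunc_lnorm(u_sig, cfg$sigma$mean, cfg$sigma$sdlog,
                      cfg$sigma$range[1], cfg$sigma$range[2])
  hs <- q_trunc_lnorm(u_hs, cfg$h_over_sigma$mean, cfg$h_over_sigma$sdlog,
                      cfg$h_over_sigma$range[1], cfg$h_over_sigma$range[2])
  tibble(station = station_ids(n), B0 = b0, h = hs * sg, zm = zm, sigma = sg,
         h_over_sigma = hs)
}

#' Draw synthetic PE parameters
#'
#' @param cfg [generator_config()].
#' @return Tibble with `station`, `PmB`, `alphaB`, `Ek`.
#' @export
sample_pe <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_stations
  pmb <- q_trunc_lnorm(runif(n), cfg$PmB$mean, cfg$PmB$sdlog,
                       cfg$PmB$range[1], cfg$PmB$range[2])
  alb <- q_trunc_lnorm(runif(n), cfg$alphaB$mean, cfg$alphaB$sdlog,
                       cfg$alphaB$range[1], cfg$alphaB$range[2])
  pe_params(PmB = pmb, alphaB = alb, station = station_ids(n))
}

# quench offset solving delta = x*(B(0)-delta)^y - (B(0)-delta) at z = 0,
# so that the standard correction recovers the unquenched surface value
solve_quench_delta <- function(b_surface, x, y) {
  if (x == 1 && y == 1) return(0)
  g <- function(d) x * (b_surface - d)^y - (b_surface - d) - d
  uniroot(g, lower = 0, upper = b_surface * (1 - 1e-9), tol = 1e-14)$root
}

#' Observe a synthetic station
#'
#' Emulates field sampling of a known truth profile. Bottle mode samples
#' 6--12 discrete depths spanning `[0, max(60, zm + 3 sigma)]` (always
#' including the surface and bracketing the peak) with multiplicative
#' lognormal noise. Fluorescence mode produces a 1-m-resolution trace with
#' surface quenching applied as the exact inverse of the standard
#' correction, so that [quenching_correction()] with the true calibration
#' recovers the truth; the matching calibration pairs are attached as the
#' `"calibration"` attribute.
#'
#' @param profile One-row truth profile.
#' @param cfg [generator_config()].
#' @param mode `"bottle"` or `"fluorescence"`.
#' @param station_index Integer used (with the seed) to give each station
#'   its own reproducible noise stream.
#' @return Observations tibble (`depth_m`, `chl_mg_m3`, `source`).
#' @export
observe <- function(profile, cfg, mode = c("bottle", "fluorescence"),
                    station_index = 1L) {
  mode <- match.arg(mode)
  set.seed(cfg$seed + 10000L + as.integer(station_index))
  p <- as_param_list(profile, c("B0", "h", "zm", "sigma"))
  zmax <- max(60, p$zm + 3 * p$sigma)

  if (mode == "bottle") {
    k <- if (cfg$n_bottle_depths[2] > cfg$n_bottle_depths[1]) {
      sample(seq(cfg$n_bottle_depths[1], cfg$n_bottle_depths[2]), 1)
    } else cfg$n_bottle_depths[1]
    depths <- seq(0, zmax, length.out = k)
    chl <- evaluate_profile(p, depths)
    if (cfg$bottle_noise > 0) {
      chl <- chl * exp(rnorm(k, 0, cfg$bottle_noise))
    }
    return(tibble(depth_m = depths, chl_mg_m3 = chl, source = "bottle"))
  }

  depths <- seq(0, floor(zmax), by = 1)
  truth <- evaluate_profile(p, depths)
  delta <- solve_quench_delta(truth[1], cfg$quench_x, cfg$quench_y)
  quenched <- truth - delta * exp(-0.05 * depths)
  if (cfg$fluor_noise > 0) {
    quenched <- quenched * exp(rnorm(length(depths), 0, cfg$fluor_noise))
  }
  out <- tibble(depth_m = depths, chl_mg_m3 = quenched,
                source = "fluorescence")
  f <- seq(0.5 * min(truth), 1.5 * max(truth), length.out = 20)
  attr(out, "calibration") <- tibble(
    fluorescence = f,
    chl_extracted = cfg$quench_x * f^cfg$quench_y
  )
  out
}

#' Synthetic mean phytoplankton absorption shape
#'
#' A smooth positive 440-nm-normalized absorption spectrum built from
#' pigment-band Gaussians: the chlorophyll-a blue (Soret) peak near 440 nm
#' with a broad carotenoid shoulder, a green trough and the chlorophyll-a
#' red band near 675 nm with relative height in 0.3--0.6. It stands in for
#' a regional mean measured shape and is the default spectral proxy for the
#' action spectrum of light-limited photosynthesis.
#'
#' @param wavelengths Grid, nm. Default 400--700 at 5 nm.
#' @param red_height Amplitude of the 675 nm band before normalization.
#' @return Spectrum tibble of kind `"normalized_shape"` (value 1.0 at
#'   440 nm).
#' @export
synth_spectrum <- function(wavelengths = seq(400, 700, by = 5),
                           red_height = 0.42) {
  s <- exp(-0.5 * ((wavelengths - 438) / 28)^2) +
    0.25 * exp(-0.5 * ((wavelengths - 490) / 24)^2) +
    0.35 * exp(-0.5 * ((wavelengths - 470) / 60)^2) +
    red_height * exp(-0.5 * ((wavelengths - 675) / 11)^2) +
    0.04
  s440 <- approx(wavelengths, s, xout = 440)$y
  out <- tibble(wavelength_nm = wavelengths, value = s / s440)
  attr(out, "kind") <- "normalized_shape"
  out
}

#' Generate a full set of synthetic stations
#'
#' Draws profiles and PE parameters and attaches observations per station,
#' so the whole pipeline (observe, fit, propagate, produce) runs without
#' external files.
#'
#' @param cfg [generator_config()].
#' @param mode Observation mode passed to [observe()].
#' @return Tibble with truth parameters (`B0`, `h`, `zm`, `sigma`), PE
#'   parameters (`PmB`, `alphaB`, `Ek`) and an `obs` list-column.
#' @export
synth_stations <- function(cfg, mode = "bottle") {
  profiles <- sample_profiles(cfg)
  pe <- sample_pe(cfg)
  obs <- purrr::map(seq_len(nrow(profiles)), function(i) {
    observe(profiles[i, ], cfg, mode = mode, station_index = i)
  })
  out <- left_join(profiles, pe, by = "station")
  out$obs <- obs
  out
}
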