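#' Run configuration for production computations
#'
#' Collects the environmental and numerical settings shared by a model run:
#' sky (latitude, day of year, cloud), optical constants and grids.
#' Defaults describe an open-water Atlantic Arctic station day in July
#' under the midnight sun; grids are chosen so halving any step changes
#' integrated production by well under 1%.
#'
#' @param latitude Degrees north. Default 75.
#' @param day_of_year Default 196 (mid July).
#' @param cloud_fraction Daily cloud cover 0--1. Default 0 (clear sky).
#' @param wavelengths Spectral grid, nm. Default 400--700 at 5 nm.
#' @param depths Depth grid, m. Default 0--300 at 0.5 m (deep enough to
#'   contain the 1% light level even in near-clear water).
#' @param aph_star_440 Chlorophyll-specific phytoplankton absorption at
#'   440 nm, m^2 (mg chl)^-1. Default 0.05.
#' @param cdom [cdom_params()].
#' @param water Optional water spectrum (default bundled table).
#' @param phyto_shape Optional normalized absorption shape (default
#'   [synth_spectrum()]).
#' @param mu_d Mean cosine for diffuse light. Default 0.83.
#' @param n_water In-water refractive index. Default 1.34.
#' @param pe_form PE response form, see [pb_rate()].
#' @return A list of class `scm_config`.
#' @export
run_config <- function(latitude = 75, day_of_year = 196, cloud_fraction = 0,
                       wavelengths = seq(400, 700, by = 5),
                       depths = seq(0, 300, by = 0.5),
                       aph_star_440 = 0.05,
                       cdom = cdom_params(),
                       water = NULL, phyto_shape = NULL,
                       mu_d = 0.83, n_water = 1.34,
                       pe_form = "saturating") {
  structure(
    list(latitude = latitude, day_of_year = day_of_year,
         cloud_fraction = cloud_fraction,
         wavelengths = wavelengths, depths = depths,
         aph_star_440 = aph_star_440, cdom = cdom,
         water = water, phyto_shape = phyto_shape,
         mu_d = mu_d, n_water = n_water, pe_form = pe_form),
    class = "scm_config"
  )
}

build_optics <- function(config, cdom = config$cdom) {
  water <- if (is.null(config$water)) water_absorption() else config$water
  shape <- if (is.null(config$phyto_shape)) {
    synth_spectrum(wavelengths = config$wavelengths)
  } else config$phyto_shape
  optical_model(water = water, phyto_shape = shape,
                aph_star_440 = config$aph_star_440, cdom = cdom,
                wavelengths = config$wavelengths)
}

build_surface <- function(config, cloud_fraction = config$cloud_fraction) {
  sky <- sky_conditions(config$latitude, config$day_of_year, cloud_fraction)
  surf <- clear_sky_spectrum(sky, wavelengths = config$wavelengths)
  if (cloud_fraction > 0) surf <- apply_cloud(surf, cloud_fraction)
  surf
}

run_one <- function(profile, pe, config, model, surface) {
  field <- propagate(surface, profile, model, depths = config$depths,
                     mu_d = config$mu_d, n_water = config$n_water)
  daily_production(profile, pe, field, form = config$pe_form)
}

#' Daily production for a table of stations
#'
#' The `run-dpp` pipeline: for each fitted profile, build the light field,
#' locate the photic depth and integrate daily production, under one PE
#' parameter set (or one per station).
#'
#' @param profiles Tibble of profile parameters (`station`, `B0`, `h`,
#'   `zm`, `sigma`).
#' @param pe PE parameters: one row (recycled) or one per station.
#' @param config [run_config()].
#' @return Tibble with `station`, `dpp_integrated`, `zp`, `zm_over_zp`,
#'   `zm_over_sigma`, `dpp_surface`.
#' @export
station_dpp <- function(profiles, pe, config = run_config()) {
  model <- build_optics(config)
  surface <- build_surface(config)
  pe <- recycle_pe(pe, nrow(profiles))
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    prod <- run_one(profiles[i, ], pe[i, ], config, model, surface)
    tibble(
      station = profiles$station[i],
      dpp_integrated = prod$dpp_integrated, zp = prod$zp,
      zm_over_zp = profiles$zm[i] / prod$zp,
      zm_over_sigma = profiles$zm[i] / profiles$sigma[i],
      dpp_surface = prod$dpp_profile$dpp[1]
    )
  })
}

recycle_pe <- function(pe, n) {
  if (nrow(pe) == 1L) pe[rep(1L, n), ] else {
    if (nrow(pe) != n) {
      stop_scmprod("pe must have 1 row or one per station", "configuration")
    }
    pe
  }
}

sensitivity_record <- function(station, ref, trt, profile, zp) {
  flagged <- !(ref > 0)
  tibble(
    station = station,
    dpp_reference = ref, dpp_treatment = trt,
    percent_difference = if (flagged) NA_real_ else 100 * (trt - ref) / ref,
    zm = profile$zm, sigma = profile$sigma,
    zm_over_sigma = profile$zm / profile$sigma,
    zm_over_zp = profile$zm / zp, zp = zp,
    flagged = flagged
  )
}

#' Uniform vs non-uniform profile experiment
#'
#' For each station, integrated daily production is computed twice: with
#' the fitted non-uniform profile (treatment) and with its uniform
#' counterpart, the surface chlorophyll held constant over depth
#' (reference). The light field is recomputed for each profile, so
#' self-shading is consistent; surface production is identical in the two
#' runs by construction. `percent_difference = 100 * (nonuniform -
#' uniform) / uniform`: positive when ignoring the SCM underestimates
#' water-column production.
#'
#' @param profiles Profile parameter tibble; a `flag` column (from
#'   [fit_profiles()]) is carried through when present.
#' @param pe PE parameters (one row, or one per station).
#' @param config [run_config()].
#' @return Tibble of sensitivity records (one per station) with shape
#'   indices from the non-uniform run; stations with zero reference
#'   production are flagged and carry `NA` percent difference. Includes
#'   `dpp_surface_reference` / `dpp_surface_treatment`.
#' @export
run_uniform_vs_nonuniform <- function(profiles, pe, config = run_config()) {
  model <- build_optics(config)
  surface <- build_surface(config)
  pe <- recycle_pe(pe, nrow(profiles))
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    uni <- uniform_counterpart(p)
    prod_u <- run_one(uni, pe[i, ], config, model, surface)
    prod_n <- run_one(p, pe[i, ], config, model, surface)
    rec <- sensitivity_record(p$station, prod_u$dpp_integrated,
                              prod_n$dpp_integrated, p, prod_n$zp)
    rec$dpp_surface_reference <- prod_u$dpp_profile$dpp[1]
    rec$dpp_surface_treatment <- prod_n$dpp_profile$dpp[1]
    rec$flag <- if ("flag" %in% names(p)) p$flag else NA_character_
    rec
  })
}

#' PE-parameter perturbation experiment
#'
#' Integrated production with each PE parameter adjusted by +/- 1 standard
#' deviation, against the reference run using the mean parameters. The
#' light field does not depend on the PE parameters, so it is computed
#' once per station. Errors from perturbing `PmB` are largest when the
#' biomass sits in saturating light (low `zm/zp`); errors from `alphaB`
#' are largest when it sits in the light-limited region (high `zm/zp`).
#'
#' @param profiles Profile parameter tibble.
#' @param pe PE table; the reference uses its mean `PmB` and `alphaB`, and
#'   the standard deviations are computed from it when it has more than
#'   one row.
#' @param config [run_config()].
#' @param sd Optional named list/vector with elements `PmB` and `alphaB`
#'   overriding the table-derived standard deviations.
#' @return Records tibble with a `treatment` column
#'   (`PmB+1sd`, `PmB-1sd`, `alphaB+1sd`, `alphaB-1sd`).
#' @export
run_pe_perturbation <- function(profiles, pe, config = run_config(),
                                sd = NULL) {
  if (is.null(sd)) {
    if (nrow(pe) < 2L) {
      stop_scmprod("supply `sd` or a PE table with > 1 row", "configuration")
    }
    sd <- list(PmB = stats::sd(pe$PmB), alphaB = stats::sd(pe$alphaB))
  }
  sd <- as.list(sd)
  if (sd$PmB <= 0 || sd$alphaB <= 0) {
    stop_scmprod("standard deviations must be > 0", "domain")
  }
  mean_pe <- pe_params(PmB = mean(pe$PmB), alphaB = mean(pe$alphaB))
  variants <- list(
    `PmB+1sd` = pe_params(mean_pe$PmB + sd$PmB, mean_pe$alphaB),
    `PmB-1sd` = pe_params(max(mean_pe$PmB - sd$PmB, 1e-6), mean_pe$alphaB),
    `alphaB+1sd` = pe_params(mean_pe$PmB, mean_pe$alphaB + sd$alphaB),
    `alphaB-1sd` = pe_params(mean_pe$PmB, max(mean_pe$alphaB - sd$alphaB, 1e-9))
  )

  model <- build_optics(config)
  surface <- build_surface(config)
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    field <- propagate(surface, p, model, depths = config$depths,
                       mu_d = config$mu_d, n_water = config$n_water)
    ref <- daily_production(p, mean_pe, field, form = config$pe_form)
    purrr::map_dfr(names(variants), function(nm) {
      trt <- daily_production(p, variants[[nm]], field, zp = ref$zp,
                              form = config$pe_form)
      rec <- sensitivity_record(p$station, ref$dpp_integrated,
                                trt$dpp_integrated, p, ref$zp)
      rec$treatment <- nm
      rec
    })
  })
}

#' CDOM background experiment
#'
#' Integrated production when the CDOM absorption at 440 nm is raised to a
#' uniform background value (default 0.07 m^-1, an extreme
#' terrigenous-influence case), relative to the reference run where CDOM
#' scales with phytoplankton and water absorption. Added absorber can only
#' remove light, so percent differences are never positive, and deeper
#' peaks lose more.
#'
#' @param profiles Profile parameter tibble.
#' @param pe PE parameters (one row, or one per station).
#' @param config [run_config()].
#' @param background440 Treatment a_y(440), m^-1. Stations whose reference
#'   CDOM level already exceeds the background are flagged and excluded
#'   (the treatment would remove absorber there); if no station qualifies
#'   the run is refused.
#' @return Records tibble (percent difference vs `zm`).
#' @export
run_cdom_experiment <- function(profiles, pe, config = run_config(),
                                background440 = 0.07) {
  model_ref <- build_optics(config)
  ay_ref <- vapply(seq_len(nrow(profiles)), function(i) {
    ay440_value(model_ref, surface_chl(profiles[i, c("B0", "h", "zm", "sigma")]))
  }, numeric(1))
  if (all(ay_ref > background440)) {
    stop_scmprod("background440 must exceed the reference CDOM level",
                 "domain")
  }
  cdom_bg <- cdom_params(slope = config$cdom$slope,
                         background440 = background440)
  model_bg <- build_optics(config, cdom = cdom_bg)
  surface <- build_surface(config)
  pe <- recycle_pe(pe, nrow(profiles))
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    ref <- run_one(p, pe[i, ], config, model_ref, surface)
    if (ay_ref[i] > background440) {
      rec <- sensitivity_record(p$station, ref$dpp_integrated, NA_real_,
                                p, ref$zp)
      rec$percent_difference <- NA_real_
      rec$flagged <- TRUE
      return(rec)
    }
    trt <- run_one(p, pe[i, ], config, model_bg, surface)
    sensitivity_record(p$station, ref$dpp_integrated, trt$dpp_integrated,
                       p, ref$zp)
  })
}

#' Cloud-cover experiment
#'
#' Error committed by assuming clear sky when the true sky is cloudy: for
#' each cloud fraction, the reference is production under the
#' cloud-modified surface field and the treatment is the clear-sky run.
#' The error is non-negative and non-decreasing in cloud fraction;
#' stations whose biomass sits in saturating light are buffered by the
#' plateau of the PE curve.
#'
#' @param profiles Profile parameter tibble.
#' @param pe PE parameters (one row, or one per station).
#' @param config [run_config()].
#' @param cloud_fractions Fractions to evaluate. Default 0, 0.25, 0.5,
#'   0.75, 1.
#' @return Records tibble with a `cloud_fraction` column;
#'   `percent_difference = 100 * (clear - cloudy) / cloudy`.
#' @export
run_cloud_experiment <- function(profiles, pe, config = run_config(),
                                 cloud_fractions = c(0, 0.25, 0.5, 0.75, 1)) {
  if (any(cloud_fractions < 0 | cloud_fractions > 1)) {
    stop_scmprod("cloud fractions must lie in [0, 1]", "domain")
  }
  model <- build_optics(config)
  clear <- build_surface(config, cloud_fraction = 0)
  surfaces <- lapply(cloud_fractions, function(C) {
    if (C == 0) clear else apply_cloud(clear, C)
  })
  pe <- recycle_pe(pe, nrow(profiles))
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    prod_clear <- run_one(p, pe[i, ], config, model, clear)
    purrr::map_dfr(seq_along(cloud_fractions), function(k) {
      prod_cloudy <- run_one(p, pe[i, ], config, model, surfaces[[k]])
      rec <- sensitivity_record(p$station, prod_cloudy$dpp_integrated,
                                prod_clear$dpp_integrated, p, prod_cloudy$zp)
      rec$cloud_fraction <- cloud_fractions[k]
      rec
    })
  })
}

#' Ordinary least-squares regression on sensitivity records
#'
#' Relates percent differences to a profile-shape index, optionally on a
#' subset (e.g. `zm_over_sigma < 4.6`). Flagged records and non-finite
#' responses are dropped.
#'
#' @param records Records tibble from one of the `run_*` experiments.
#' @param x Unquoted name of the predictor column (e.g. `zm_over_sigma`).
#' @param y Unquoted name of the response. Default `percent_difference`.
#' @param subset Optional unquoted logical expression evaluated in
#'   `records` selecting the rows to fit.
#' @return An object of class `scm_regression`; see [tidy()] and
#'   [glance()]. `glance()` reports slope, intercept, `r.squared`, the
#'   two-sided slope p-value, `n` and the subset rule applied.
#' @export
regress <- function(records, x, y = percent_difference, subset = NULL) {
  x_q <- enquo(x); y_q <- enquo(y); s_q <- enquo(subset)
  d <- records
  if ("flagged" %in% names(d)) d <- d[!d$flagged, , drop = FALSE]
  subset_rule <- "none"
  if (!quo_is_null(s_q)) {
    keep <- eval_tidy(s_q, data = d)
    d <- d[keep & !is.na(keep), , drop = FALSE]
    subset_rule <- as_label(s_q)
  }
  xv <- eval_tidy(x_q, data = d)
  yv <- eval_tidy(y_q, data = d)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) {
    stop_scmprod("need at least 3 records after subsetting",
                 "insufficient_data")
  }
  if (stats::var(xv) <= 0) {
    stop_scmprod("predictor has zero variance; regression undefined",
                 "regression_undefined")
  }
  fit <- lm(yv ~ xv)
  structure(
    list(model = fit, n = length(xv), subset_rule = subset_rule,
         x_name = as_label(x_q), y_name = as_label(y_q)),
    class = "scm_regression"
  )
}

#' @export
print.scm_regression <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("OLS: %s ~ %s (subset: %s)\n", x$y_name, x$x_name,
              x$subset_rule))
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              g$slope, g$intercept, g$r.squared, g$p.value, g$n))
  invisible(x)
}
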