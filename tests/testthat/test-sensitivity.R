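ens_config <- tiny_config()
mean_pe <- pe_params(1.73, 0.034)

test_that("uniform-vs-nonuniform comparison has the expected sign structure", {
  profiles <- dplyr::bind_rows(
    gaussian_profile(0.3, 0, 10, 5, station = "flat"),
    gaussian_profile(0.1, 40, 30, 3, station = "deep_narrow"),
    gaussian_profile(0.1, 60, -2, 20, station = "surface_intense")
  )
  rec <- run_uniform_vs_nonuniform(profiles, mean_pe, ens_config)
  expect_equal(nrow(rec), 3)
  # a flat profile is its own counterpart: exactly zero difference
  expect_equal(rec$percent_difference[rec$station == "flat"], 0,
               tolerance = 1e-9)
  # a deep narrow SCM adds production the uniform run misses
  expect_gt(rec$percent_difference[rec$station == "deep_narrow"], 0)
  # a surface-intensified profile is overestimated by the uniform run
  expect_lt(rec$percent_difference[rec$station == "surface_intense"], 0)
  # surface production identical in the two runs (identical surface light)
  expect_equal(rec$dpp_surface_reference, rec$dpp_surface_treatment,
               tolerance = 1e-12)
})

test_that("PE perturbations are signed and shaped by the light environment", {
  profiles <- dplyr::bind_rows(
    gaussian_profile(0.5, 30, 2, 6, station = "shallow"),
    gaussian_profile(0.05, 30, 55, 5, station = "deep")
  )
  pe_tbl <- pe_params(PmB = c(1.2, 1.7, 2.3), alphaB = c(0.02, 0.034, 0.05))
  rec <- run_pe_perturbation(profiles, pe_tbl, ens_config)
  expect_equal(nrow(rec), 8)
  plus <- rec[rec$treatment == "PmB+1sd", ]
  minus <- rec[rec$treatment == "PmB-1sd", ]
  expect_true(all(plus$percent_difference >= -1e-9))
  expect_true(all(minus$percent_difference <= 1e-9))

  # saturating near-surface biomass: PmB errors near the full 100*sd/PmB,
  # alphaB errors near zero; the deep station reverses the ranking
  sd_pm <- sd(pe_tbl$PmB); mean_pm <- mean(pe_tbl$PmB)
  shallow_pm <- plus$percent_difference[plus$station == "shallow"]
  expect_gt(shallow_pm, 0.5 * 100 * sd_pm / mean_pm)
  shallow_al <- abs(rec$percent_difference[rec$treatment == "alphaB+1sd" &
                                             rec$station == "shallow"])
  deep_al <- abs(rec$percent_difference[rec$treatment == "alphaB+1sd" &
                                          rec$station == "deep"])
  expect_lt(shallow_al, shallow_pm)
  expect_gt(deep_al, shallow_al)

  expect_error(run_pe_perturbation(profiles, mean_pe, ens_config),
               class = "scmprod_error_configuration")
  expect_error(run_pe_perturbation(profiles, pe_tbl, ens_config,
                                   sd = list(PmB = 0, alphaB = 0.01)),
               class = "scmprod_error_domain")
})

test_that("raising CDOM to a background can only lose production, more so for deep peaks", {
  profiles <- dplyr::bind_rows(
    gaussian_profile(0.2, 25, 10, 6, station = "shallow"),
    gaussian_profile(0.2, 25, 40, 6, station = "deep")
  )
  rec <- run_cdom_experiment(profiles, mean_pe, ens_config,
                             background440 = 0.07)
  expect_true(all(rec$percent_difference <= 1e-9))
  expect_gt(abs(rec$percent_difference[rec$station == "deep"]),
            abs(rec$percent_difference[rec$station == "shallow"]))

  # a background equal to the reference level changes nothing
  model <- scmprod:::build_optics(ens_config)
  ay_ref <- scmprod:::ay440_value(model, surface_chl(profiles[1, ]))
  rec_id <- run_cdom_experiment(profiles[1, ], mean_pe, ens_config,
                                background440 = ay_ref)
  expect_equal(rec_id$percent_difference, 0, tolerance = 1e-9)

  # treatment below the reference level is rejected
  expect_error(
    run_cdom_experiment(profiles, mean_pe, ens_config, background440 = 1e-4),
    class = "scmprod_error_domain"
  )
})

test_that("assuming clear sky overestimates production, monotonically in cloud", {
  profiles <- dplyr::bind_rows(
    gaussian_profile(0.5, 30, 2, 6, station = "saturated"),
    gaussian_profile(0.05, 30, 55, 5, station = "limited")
  )
  rec <- run_cloud_experiment(profiles, mean_pe, ens_config,
                              cloud_fractions = c(0, 0.5, 1))
  expect_true(all(rec$percent_difference >= -1e-9))
  expect_equal(rec$percent_difference[rec$cloud_fraction == 0], c(0, 0),
               tolerance = 1e-12)
  for (st in unique(rec$station)) {
    err <- rec$percent_difference[rec$station == st]
    expect_true(all(diff(err) >= -1e-9))
  }
  # the PE plateau buffers stations whose biomass sits in saturating light
  e_sat <- rec$percent_difference[rec$station == "saturated" &
                                    rec$cloud_fraction == 1]
  e_lim <- rec$percent_difference[rec$station == "limited" &
                                    rec$cloud_fraction == 1]
  expect_lt(e_sat, e_lim)
  # DPP under full overcast is strictly below clear-sky DPP
  expect_true(all(rec$dpp_reference[rec$cloud_fraction == 1] <
                    rec$dpp_treatment[rec$cloud_fraction == 1]))
})

test_that("OLS on records reports slope, R^2 and honest subsetting", {
  rec <- tibble::tibble(
    station = sprintf("s%02d", 1:10),
    percent_difference = seq(-40, 50, length.out = 10),
    zm_over_sigma = seq(0, 9, length.out = 10),
    flagged = FALSE
  )
  r <- regress(rec, x = zm_over_sigma)
  g <- glance(r)
  expect_equal(g$r.squared, 1, tolerance = 1e-12)
  expect_equal(g$slope, 10, tolerance = 1e-9)
  expect_equal(g$n, 10)

  # the subset rule keeps strictly-below-threshold rows only
  r2 <- regress(rec, x = zm_over_sigma, subset = zm_over_sigma < 4.6)
  expect_equal(glance(r2)$n, sum(rec$zm_over_sigma < 4.6))
  expect_match(glance(r2)$subset_rule, "4.6")

  # shuffled predictor carries no signal
  set.seed(99)
  big <- tibble::tibble(
    percent_difference = rnorm(200),
    zm_over_sigma = sample(rnorm(200)),
    flagged = FALSE
  )
  expect_lt(glance(regress(big, x = zm_over_sigma))$r.squared, 0.1)

  # degenerate designs are refused
  rec0 <- dplyr::mutate(rec, zm_over_sigma = 1)
  expect_error(regress(rec0, x = zm_over_sigma),
               class = "scmprod_error_regression_undefined")
  expect_error(regress(rec[1:2, ], x = zm_over_sigma),
               class = "scmprod_error_insufficient_data")
})

test_that("tidiers expose fits and productions as tibbles", {
  depths <- seq(0, 80, length.out = 10)
  p <- gaussian_profile(0.2, 30, 25, 8)
  obs <- tibble::tibble(depth_m = depths,
                        chl_mg_m3 = evaluate_profile(p, depths))
  fit <- fit_profile(obs)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "zm"], 25, tolerance = 1e-5)
  expect_named(glance(fit), c("B0", "h", "zm", "sigma", "rss", "n", "flag"))

  cfg <- tiny_config()
  model <- scmprod:::build_optics(cfg)
  surf <- scmprod:::build_surface(cfg)
  field <- propagate(surf, p, model, depths = cfg$depths)
  prod <- daily_production(p, pe_params(1.73, 0.034), field)
  expect_named(tidy(prod), c("depth_m", "dpp"))
  expect_equal(glance(prod)$dpp_integrated, prod$dpp_integrated)
})
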