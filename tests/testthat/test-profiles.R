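test_that("shifted Gaussian evaluates correctly, including closed-form anchors", {
  # zero-peak profile is the constant background
  p0 <- gaussian_profile(B0 = 0.5, h = 0, zm = 20, sigma = 5)
  expect_equal(evaluate_profile(p0, c(-5, 0, 20, 100)), rep(0.5, 4))

  # field-mean parameters: peak value B0 + (h/sigma)/sqrt(2*pi)
  p <- mean_field_profile()
  expect_equal(evaluate_profile(p, 24.7), 0.19 + 4.91 / sqrt(2 * pi),
               tolerance = 1e-12)

  # unit Gaussian matches the standard normal density, symmetrically
  pg <- gaussian_profile(B0 = 0, h = 1, zm = 0, sigma = 1)
  expect_equal(evaluate_profile(pg, 1), dnorm(1), tolerance = 1e-12)
  expect_equal(evaluate_profile(pg, -1), evaluate_profile(pg, 1))
})

test_that("profile bounds: infimum is B0 and supremum is B0 + h/(sigma sqrt(2 pi))", {
  set.seed(11)
  z <- seq(-50, 300, by = 0.25)
  for (i in 1:20) {
    p <- gaussian_profile(B0 = runif(1, 0, 2), h = runif(1, 0, 200),
                          zm = runif(1, -8, 80), sigma = runif(1, 0.5, 40))
    v <- evaluate_profile(p, z)
    expect_gte(min(v), p$B0 - 1e-12)
    expect_lte(max(v), p$B0 + p$h / (p$sigma * sqrt(2 * pi)) + 1e-12)
    # the supremum is attained exactly at zm
    expect_equal(evaluate_profile(p, p$zm),
                 p$B0 + p$h / (p$sigma * sqrt(2 * pi)), tolerance = 1e-12)
  }
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(gaussian_profile(-0.1, 1, 10, 5), class = "scmprod_error_invalid_parameter")
  expect_error(gaussian_profile(0.1, 1, 10, 0), class = "scmprod_error_invalid_parameter")
  expect_error(gaussian_profile(0.1, -1, 10, 5), class = "scmprod_error_invalid_parameter")
  expect_error(evaluate_profile(list(B0 = 0.1, h = 1, zm = NaN, sigma = 5), 0),
               class = "scmprod_error_invalid_parameter")
  # negative zm is legitimate (peak centred above the sea surface)
  expect_silent(gaussian_profile(0.1, 10, -3, 5))
})

test_that("fit recovers noiseless parameters to 1e-6 relative", {
  truth <- gaussian_profile(B0 = 0.2, h = 30, zm = 25, sigma = 8)
  depths <- seq(0, 80, length.out = 12)
  obs <- tibble::tibble(depth_m = depths,
                        chl_mg_m3 = evaluate_profile(truth, depths))
  fit <- fit_profile(obs)
  expect_equal(fit$B0, 0.2, tolerance = 1e-6)
  expect_equal(fit$h, 30, tolerance = 1e-6)
  expect_equal(fit$zm, 25, tolerance = 1e-6)
  expect_equal(fit$sigma, 8, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_identical(fit$flag, "scm")
})

test_that("fit under 5% multiplicative noise recovers zm and sigma", {
  cfg <- generator_config(n_stations = 30, seed = 303, bottle_noise = 0.05,
                          n_bottle_depths = c(10, 10))
  profiles <- sample_profiles(cfg)
  err_zm <- err_sig <- numeric(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    obs <- observe(profiles[i, ], cfg, mode = "bottle", station_index = i)
    fit <- fit_profile(obs[, c("depth_m", "chl_mg_m3")])
    err_zm[i] <- fit$zm - profiles$zm[i]
    err_sig[i] <- fit$sigma / profiles$sigma[i] - 1
  }
  expect_lte(median(abs(err_zm)), 2)
  expect_lte(median(abs(err_sig)), 0.2)
})

test_that("constant observations fit as a quasi-uniform profile", {
  obs <- tibble::tibble(depth_m = seq(0, 60, by = 10),
                        chl_mg_m3 = rep(0.4, 7))
  fit <- fit_profile(obs)
  expect_equal(fit$B0, 0.4, tolerance = 1e-3)
  amp <- fit$h / (fit$sigma * sqrt(2 * pi))
  expect_lt(amp, 0.01 * fit$B0 + 1e-8)
  expect_identical(fit$flag, "quasi-uniform")
})

test_that("bottle profiles with too few depths are rejected", {
  obs <- tibble::tibble(depth_m = c(0, 10, 20, 30, 40),
                        chl_mg_m3 = c(0.5, 0.9, 1.5, 0.8, 0.4))
  expect_error(fit_profile(obs, source = "bottle"),
               class = "scmprod_error_insufficient_data")
  # the same data are admissible as a fluorescence trace
  expect_s3_class(fit_profile(obs, source = "fluorescence"),
                  "scm_profile_fit")
})

test_that("fit_profiles maps over stations and returns one row each", {
  truth <- dplyr::bind_rows(
    gaussian_profile(0.1, 20, 20, 5, station = "a"),
    gaussian_profile(0.3, 50, 35, 10, station = "b")
  )
  depths <- seq(0, 90, length.out = 14)
  data <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(station = truth$station[i], depth_m = depths,
                   chl_mg_m3 = evaluate_profile(truth[i, ], depths))
  })
  fits <- fit_profiles(data)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$zm, truth$zm, tolerance = 1e-5)
  expect_equal(fits$h, truth$h, tolerance = 1e-5)
})

test_that("quenching correction follows the exponential-decay model", {
  depth <- seq(0, 120, by = 2)
  p <- gaussian_profile(0.2, 25, 30, 8)
  chl <- evaluate_profile(p, depth)
  obs <- tibble::tibble(depth_m = depth, chl_mg_m3 = chl)

  # identity calibration: x = 1, y = 1 leaves the profile unchanged
  f <- seq(0.1, 3, length.out = 10)
  cal_id <- tibble::tibble(fluorescence = f, chl_extracted = f)
  out <- quenching_correction(obs, cal_id)
  expect_equal(out$chl_mg_m3, chl, tolerance = 1e-12)
  expect_equal(attr(out, "quenching")$delta_b, 0, tolerance = 1e-12)

  # x = 2, y = 1 with surface reading 0.5: delta_b = 0.5,
  # added term at 20 m = 0.5 * exp(-1)
  obs2 <- tibble::tibble(depth_m = c(0, 20, 100), chl_mg_m3 = c(0.5, 0.5, 0.5))
  cal2 <- tibble::tibble(fluorescence = f, chl_extracted = 2 * f)
  out2 <- quenching_correction(obs2, cal2)
  q <- attr(out2, "quenching")
  expect_equal(q$delta_b, 0.5, tolerance = 1e-10)
  expect_equal(out2$chl_mg_m3[2] - 0.5, 0.5 * exp(-1), tolerance = 1e-10)
  # correction at z = 0 equals delta_b exactly; < 1% of delta_b at 100 m
  expect_equal(out2$chl_mg_m3[1] - 0.5, q$delta_b, tolerance = 1e-12)
  expect_lt(out2$chl_mg_m3[3] - 0.5, 0.01 * q$delta_b)

  # domain errors
  cal_bad <- tibble::tibble(fluorescence = c(1, -1), chl_extracted = c(1, 2))
  expect_error(quenching_correction(obs2, cal_bad), class = "scmprod_error_domain")
  expect_error(quenching_correction(obs2, NULL), class = "scmprod_error_configuration")
})

test_that("shape indices match closed forms", {
  p <- mean_field_profile()
  si <- shape_indices(p, zp = 50)
  expect_equal(si$zm_over_sigma, 24.7 / 12.42, tolerance = 1e-12)
  expect_equal(si$zm_over_zp, 24.7 / 50, tolerance = 1e-12)
  expect_equal(si$peak_amplitude, p$h / (p$sigma * sqrt(2 * pi)))
  # quadrature of the profile vs the Gaussian-CDF closed form
  closed <- p$B0 * 50 + p$h * (pnorm((50 - p$zm) / p$sigma) -
                                 pnorm(-p$zm / p$sigma))
  expect_equal(si$column_chl, closed, tolerance = 1e-6)

  # the whole-axis peak integral equals h (Gaussian normalization)
  pg <- gaussian_profile(B0 = 0, h = 10, zm = 0, sigma = 5)
  whole <- integrate(function(z) evaluate_profile(pg, z), -Inf, Inf)$value
  expect_equal(whole, 10, tolerance = 1e-6)

  expect_equal(shape_indices(gaussian_profile(0, 1, 50, 5), zp = 50)$zm_over_zp, 1)
  expect_error(shape_indices(p, zp = -1), class = "scmprod_error_domain")
})

test_that("profile summaries average parameters and surface chlorophyll", {
  p1 <- gaussian_profile(0.1, 10, 10, 5, station = "a")
  s1 <- summarize_profiles(p1)
  expect_equal(s1$mean[s1$parameter == "B0"], 0.1)
  expect_equal(s1$min, s1$max)

  p2 <- dplyr::bind_rows(p1, gaussian_profile(0.3, 10, 30, 5, station = "b"))
  s2 <- summarize_profiles(p2)
  expect_equal(s2$mean[s2$parameter == "zm"], 20)
  expect_true(all(s2$min <= s2$mean & s2$mean <= s2$max))

  expect_error(summarize_profiles(p2[0, ]), class = "scmprod_error_configuration")
})
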