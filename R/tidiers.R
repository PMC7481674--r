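#' Tidy a profile fit
#'
#' @param x `scm_profile_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.scm_profile_fit <- function(x, ...) {
  tibble(term = c("B0", "h", "zm", "sigma"),
         estimate = c(x$B0, x$h, x$zm, x$sigma))
}

#' One-row summary of a profile fit
#'
#' @param x `scm_profile_fit` object.
#' @param ... Unused.
#' @return Tibble with `B0`, `h`, `zm`, `sigma`, `rss`, `n`, `flag`.
#' @export
glance.scm_profile_fit <- function(x, ...) {
  tibble(B0 = x$B0, h = x$h, zm = x$zm, sigma = x$sigma,
         rss = x$rss, n = x$n, flag = x$flag)
}

#' Tidy a sensitivity regression
#'
#' @param x `scm_regression` object.
#' @param ... Unused.
#' @return Broom-style coefficient table.
#' @export
tidy.scm_regression <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("(Intercept)", x$x_name),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' One-row summary of a sensitivity regression
#'
#' @param x `scm_regression` object.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r.squared`, `p.value`
#'   (two-sided, slope), `n`, `subset_rule`.
#' @export
glance.scm_regression <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    slope = unname(coef(x$model)[2]),
    intercept = unname(coef(x$model)[1]),
    r.squared = s$r.squared,
    p.value = s$coefficients[2, 4],
    n = x$n,
    subset_rule = x$subset_rule
  )
}

#' Tidy a production result
#'
#' @param x `scm_production` object.
#' @param ... Unused.
#' @return The volumetric daily production profile (`depth_m`, `dpp` in
#'   mg C m^-3 d^-1).
#' @export
tidy.scm_production <- function(x, ...) x$dpp_profile

#' One-row summary of a production result
#'
#' @param x `scm_production` object.
#' @param ... Unused.
#' @return Tibble with `dpp_integrated`, `zp`, `daylength_h`, `form`.
#' @export
glance.scm_production <- function(x, ...) {
  tibble(dpp_integrated = x$dpp_integrated, zp = x$zp,
         daylength_h = x$daylength_h, form = x$form)
}
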