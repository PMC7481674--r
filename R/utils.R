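# trapezoid quadrature on an irregular grid
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# cumulative trapezoid, same length as x, starting at 0
cumtrapz <- function(x, y) {
  if (length(x) < 2L) return(rep(0, length(x)))
  c(0, cumsum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2))
}

# trapezoid weights w such that sum(w * y) == trapz(x, y)
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

stop_scmprod <- function(message, class) {
  abort(message, class = c(paste0("scmprod_error_", class), "scmprod_error"))
}

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_scmprod(paste0("`", name, "` must be finite numeric"), "invalid_parameter")
  }
  invisible(x)
}

# coerce a one-row data frame / named list / named vector to a named list of
# scalars with the requested fields
as_param_list <- function(x, fields) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop_scmprod("expected a single profile (one row)", "invalid_parameter")
    }
    x <- as.list(x)
  }
  x <- as.list(x)
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0L) {
    stop_scmprod(
      paste0("missing field(s): ", paste(missing, collapse = ", ")),
      "invalid_parameter"
    )
  }
  lapply(x[fields], function(v) as.numeric(v)[1])
}

scmprod_extdata <- function(file) {
  path <- system.file("extdata", file, package = "scmprod")
  if (!nzchar(path)) {
    stop_scmprod(paste0("bundled data file not found: ", file), "configuration")
  }
  path
}
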