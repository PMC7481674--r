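#' Read chlorophyll profile observations
#'
#' Delimited text with columns `depth_m`, `chl_mg_m3` and optionally
#' `station` and `source` (long format, one or many stations).
#'
#' @param path CSV file path.
#' @return Tibble of observations.
#' @export
read_profile_obs <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("depth_m", "chl_mg_m3") %in% names(d))) {
    stop_scmprod("file needs columns depth_m and chl_mg_m3", "configuration")
  }
  if (!"station" %in% names(d)) d$station <- "station_1"
  d
}

#' Read a PE parameter table
#'
#' Columns `PmB` and `alphaB` (required), `station` and `latitude`
#' (optional). When `min_latitude` is given, only rows with
#' `latitude > min_latitude` are kept — the standard Arctic subset uses
#' latitudes above 60 degrees N. The derived `Ek` is appended.
#'
#' @param path CSV file path.
#' @param min_latitude Optional latitude filter (strictly greater than).
#' @return Tibble with `station`, `PmB`, `alphaB`, `Ek` (and `latitude`
#'   if present).
#' @export
read_pe_table <- function(path, min_latitude = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("PmB", "alphaB") %in% names(d))) {
    stop_scmprod("file needs columns PmB and alphaB", "configuration")
  }
  if (!is.null(min_latitude)) {
    if (!"latitude" %in% names(d)) {
      stop_scmprod("latitude filter requested but no latitude column",
                   "configuration")
    }
    d <- d[d$latitude > min_latitude, , drop = FALSE]
  }
  if (!"station" %in% names(d)) d$station <- station_ids(nrow(d))
  d$Ek <- d$PmB / d$alphaB
  as_tibble(d)
}

#' Summary statistics of a PE table
#'
#' Arithmetic means and ranges of the assimilation number, initial slope
#' and light adaptation parameter.
#'
#' @param pe Tibble with `PmB`, `alphaB` (and `Ek`, recomputed if absent).
#' @return Tibble with columns `parameter`, `mean`, `min`, `max`, `sd`,
#'   `n`.
#' @export
summarize_pe <- function(pe) {
  if (nrow(pe) == 0L) stop_scmprod("PE table is empty", "configuration")
  if (!"Ek" %in% names(pe)) pe$Ek <- pe$PmB / pe$alphaB
  vals <- list(PmB = pe$PmB, alphaB = pe$alphaB, Ek = pe$Ek)
  purrr::map_dfr(names(vals), function(nm) {
    v <- vals[[nm]]
    tibble(parameter = nm, mean = mean(v), min = min(v), max = max(v),
           sd = stats::sd(v), n = length(v))
  })
}

#' Read a two-column spectrum file
#'
#' @param path CSV with columns `wavelength_nm`, `value`.
#' @param kind Spectrum kind, see [absorption_spectrum()].
#' @return Spectrum tibble.
#' @export
read_spectrum <- function(path, kind = "water") {
  d <- readr::read_csv(path, show_col_types = FALSE)
  absorption_spectrum(d$wavelength_nm, d$value, kind = kind)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` (e.g.
#'   `"pe_params_synthetic.csv"`, a synthetic stand-in PE table whose
#'   latitude > 60 N subset emulates the Atlantic Arctic statistics);
#'   `NULL` lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
scmprod_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "scmprod")))
  }
  scmprod_extdata(file)
}

#' Write a fitted-parameter (or records) table to CSV
#'
#' Thin wrapper over [readr::write_csv()] so pipeline outputs share one
#' canonical schema.
#'
#' @param x Tibble (fitted parameters, sensitivity records, ...).
#' @param path Output file.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}
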