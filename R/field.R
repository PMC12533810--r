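#' Gridded daily-mean PM2.5 concentration field
#'
#' A `conc_field` holds daily-mean surface PM2.5 (ug m-3) for one model
#' scenario on a regular grid: a numeric array indexed `(day, row, col)`,
#' the calendar dates of the days, uniformly spaced cell-center coordinates,
#' and a scenario label identifying the wildfire-emissions and meteorology
#' inputs of the run that produced it.
#'
#' @param values Numeric array with dimensions `(day, row, col)`. All values
#'   must be finite and non-negative.
#' @param days Vector of calendar dates (`Date` or coercible), one per day
#'   slice, strictly increasing.
#' @param scenario A [scenario_label()].
#' @param row_centers,col_centers Cell-center coordinates (projected x/y or
#'   lon/lat) along the row and column axes. Must be uniformly spaced.
#'   Defaults to unit spacing starting at 0.5.
#'
#' @return An object of class `conc_field`.
#' @examples
#' f <- conc_field(array(5, c(2, 3, 4)), days = as.Date("2023-06-06") + 0:1,
#'                 scenario = scenario_label("CAMS", "FNL"))
#' f
#' @export
conc_field <- function(values, days, scenario = scenario_label("NONE", "FNL"),
                       row_centers = NULL, col_centers = NULL) {
  values <- unclass(values)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort_field("`values` must be a 3-d array indexed (day, row, col)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort_field("`values` contains missing or non-finite concentrations")
  }
  if (any(values < 0)) {
    abort_field("`values` contains negative concentrations")
  }
  days <- as.Date(days)
  dim(days) <- NULL
  if (length(days) != dim(values)[1L]) {
    abort_field("length of `days` does not match the day dimension of `values`")
  }
  if (length(days) > 1L && any(diff(days) <= 0)) {
    abort_field("`days` must be strictly increasing")
  }
  nr <- dim(values)[2L]
  nc <- dim(values)[3L]
  if (is.null(row_centers)) row_centers <- seq_len(nr) - 0.5
  if (is.null(col_centers)) col_centers <- seq_len(nc) - 0.5
  check_uniform(row_centers, nr, "row_centers")
  check_uniform(col_centers, nc, "col_centers")
  stopifnot(inherits(scenario, "scenario_label"))
  structure(
    list(values = values, days = days, scenario = scenario,
         row_centers = as.numeric(row_centers),
         col_centers = as.numeric(col_centers)),
    class = "conc_field"
  )
}

abort_field <- function(msg) rlang::abort(msg, class = "smokewave_field_error")

check_uniform <- function(x, n, what) {
  if (length(x) != n) abort_field(paste0("`", what, "` has wrong length"))
  if (n > 1L) {
    d <- diff(x)
    if (any(abs(d - d[1L]) > 1e-8 * max(abs(d[1L]), 1)) || d[1L] <= 0) {
      abort_field(paste0("`", what, "` is not uniformly increasing"))
    }
  }
  invisible(x)
}

#' Label a model scenario by its emissions and meteorology inputs
#'
#' Scenarios are the members of the 2x2 factorial wildfire ensemble
#' (emissions dataset crossed with meteorological driver) plus the
#' no-wildfire controls. `emissions = "NONE"` marks a control run;
#' `emissions = "AVERAGE"` labels derived ensemble means.
#'
#' @param emissions One of `"CAMS"`, `"QFED"`, `"NONE"`, `"AVERAGE"`.
#' @param meteorology One of `"FNL"`, `"NAM"`, `"AVERAGE"`.
#' @return A `scenario_label` object.
#' @examples
#' scenario_label("QFED", "NAM")
#' @export
scenario_label <- function(emissions, meteorology) {
  emissions <- match.arg(emissions, c("CAMS", "QFED", "NONE", "AVERAGE"))
  meteorology <- match.arg(meteorology, c("FNL", "NAM", "AVERAGE"))
  structure(list(emissions = emissions, meteorology = meteorology),
            class = "scenario_label")
}

#' @export
format.scenario_label <- function(x, ...) {
  paste(x$emissions, x$meteorology, sep = "-")
}

#' @export
print.scenario_label <- function(x, ...) {
  cat("<scenario>", format(x), "\n")
  invisible(x)
}

#' @export
format.conc_field <- function(x, ...) {
  d <- dim(x$values)
  sprintf("<conc_field %s: %d day(s) x %d x %d, range [%.2f, %.2f] ug/m3>",
          format(x$scenario), d[1L], d[2L], d[3L],
          min(x$values), max(x$values))
}

#' @export
print.conc_field <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
dim.conc_field <- function(x) dim(x$values)

#' Convert a concentration field to a long tibble
#'
#' One row per (day, row, col) cell with the cell-center coordinates and the
#' PM2.5 value, ready for dplyr/ggplot2 work.
#'
#' @param x A `conc_field`.
#' @param ... Unused.
#' @return A tibble with columns `day`, `row`, `col`, `x`, `y`, `pm25`,
#'   `scenario`.
#' @method as_tibble conc_field
#' @export
as_tibble.conc_field <- function(x, ...) {
  d <- dim(x$values)
  grid <- tidyr::expand_grid(day = x$days, row = seq_len(d[2L]),
                             col = seq_len(d[3L]))
  grid <- dplyr::arrange(grid, .data$day, .data$row, .data$col)
  ycoord <- x$row_centers[grid$row]
  xcoord <- x$col_centers[grid$col]
  pm25 <- x$values[cbind(match(grid$day, x$days), grid$row, grid$col)]
  scen <- format(x$scenario)
  tibble::tibble(
    day = grid$day, row = grid$row, col = grid$col,
    y = ycoord, x = xcoord, pm25 = pm25, scenario = scen
  )
}

same_grid <- function(a, b) {
  identical(dim(a$values)[2:3], dim(b$values)[2:3]) &&
    max(abs(a$row_centers - b$row_centers)) < 1e-8 &&
    max(abs(a$col_centers - b$col_centers)) < 1e-8
}

same_days <- function(a, b) identical(a$days, b$days)

#' Average a field over an episode window
#'
#' Per-cell mean of the daily slices inside `days`, e.g. the 3-day smoke-wave
#' average used as the exposure metric for health impact assessment. Returns
#' a single-day field stamped with the first day of the window.
#'
#' @param field A `conc_field`.
#' @param days Dates to average over; defaults to all days in the field.
#' @return A single-day `conc_field`.
#' @export
episode_mean <- function(field, days = field$days) {
  days <- as.Date(days)
  idx <- match(days, field$days)
  if (length(idx) == 0L) abort_field("empty day selection")
  if (anyNA(idx)) {
    abort_field(paste0("requested day(s) not in field: ",
                       paste(format(days[is.na(idx)]), collapse = ", ")))
  }
  d <- dim(field$values)
  m <- apply(field$values[idx, , , drop = FALSE], c(2, 3), mean)
  conc_field(array(m, c(1L, d[2L], d[3L])), days = days[1L],
             scenario = field$scenario,
             row_centers = field$row_centers, col_centers = field$col_centers)
}

#' Write a concentration field to a CF-style NetCDF file
#'
#' Stores variable `pm25(day, row, col)` with units `"ug m-3"`, coordinate
#' variables for the day axis (days since 1970-01-01) and the row/column
#' cell centers, and the scenario label as global attributes.
#'
#' @param field A `conc_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path) {
  dim_day <- ncdf4::ncdim_def("day", "days since 1970-01-01",
                              as.numeric(field$days))
  dim_row <- ncdf4::ncdim_def("row", "cell center y", field$row_centers)
  dim_col <- ncdf4::ncdim_def("col", "cell center x", field$col_centers)
  var <- ncdf4::ncvar_def("pm25", "ug m-3", list(dim_day, dim_row, dim_col),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, field$values)
  ncdf4::ncatt_put(nc, 0, "emissions", field$scenario$emissions)
  ncdf4::ncatt_put(nc, 0, "meteorology", field$scenario$meteorology)
  invisible(path)
}

#' Read a concentration field from a CF-style NetCDF file
#'
#' Expects the layout written by [write_field()]: a `pm25(day, row, col)`
#' variable in ug m-3 (mg m-3 is converted) on a uniformly spaced grid. The
#' field invariants (finite, non-negative, uniform spacing) are validated on
#' load and violations raise an error naming the offending attribute.
#'
#' @param path NetCDF file path.
#' @param scenario Optional [scenario_label()] overriding the file's global
#'   attributes.
#' @return A `conc_field`.
#' @export
read_field <- function(path, scenario = NULL) {
  if (!file.exists(path)) abort_field(paste0("no such file: ", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!"pm25" %in% names(nc$var)) {
    abort_field(paste0("variable `pm25` missing from ", path))
  }
  vals <- ncdf4::ncvar_get(nc, "pm25", collapse_degen = FALSE)
  units <- ncdf4::ncatt_get(nc, "pm25", "units")$value
  if (identical(units, "mg m-3")) {
    vals <- vals * 1000
  } else if (!identical(units, "ug m-3")) {
    abort_field(paste0("unsupported pm25 units attribute: ", units))
  }
  days <- as.Date(as.vector(ncdf4::ncvar_get(nc, "day")),
                  origin = "1970-01-01")
  rows <- as.numeric(ncdf4::ncvar_get(nc, "row"))
  cols <- as.numeric(ncdf4::ncvar_get(nc, "col"))
  if (is.null(scenario)) {
    emis <- ncdf4::ncatt_get(nc, 0, "emissions")
    met <- ncdf4::ncatt_get(nc, 0, "meteorology")
    if (!emis$hasatt || !met$hasatt) {
      abort_field("scenario attributes (emissions, meteorology) missing")
    }
    scenario <- scenario_label(emis$value, met$value)
  }
  conc_field(vals, days = days, scenario = scenario,
             row_centers = rows, col_centers = cols)
}
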