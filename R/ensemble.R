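#' Bundle factorial ensemble members and controls
#'
#' A `scenario_ensemble` holds the four wildfire-inclusive members of the
#' 2x2 factorial design (emissions dataset CAMS/QFED crossed with
#' meteorological driver FNL/NAM) plus any no-wildfire control fields. All
#' members must share the same grid and day axis.
#'
#' @param ... `conc_field` objects (or a single list of them). Members are
#'   keyed by their scenario labels; duplicates are an error.
#' @return A `scenario_ensemble`.
#' @examples
#' ens <- make_ensemble(synthetic_config(seed = 1))
#' is_complete_factorial(ens)
#' @export
scenario_ensemble <- function(...) {
  fields <- rlang::list2(...)
  if (length(fields) == 1L && !inherits(fields[[1L]], "conc_field")) {
    fields <- fields[[1L]]
  }
  stopifnot(all(vapply(fields, inherits, logical(1), "conc_field")))
  keys <- vapply(fields, function(f) format(f$scenario), character(1))
  if (anyDuplicated(keys)) {
    rlang::abort(paste0("duplicate scenario: ", keys[duplicated(keys)][1L]),
                 class = "smokewave_ensemble_error")
  }
  names(fields) <- keys
  ref <- fields[[1L]]
  ok <- vapply(fields, function(f) same_grid(ref, f) && same_days(ref, f),
               logical(1))
  if (!all(ok)) {
    rlang::abort(paste0("member(s) on a different grid or day axis: ",
                        paste(keys[!ok], collapse = ", ")),
                 class = "smokewave_ensemble_error")
  }
  structure(list(members = fields), class = "scenario_ensemble")
}

factorial_keys <- function() {
  c("CAMS-FNL", "CAMS-NAM", "QFED-FNL", "QFED-NAM")
}

#' @rdname scenario_ensemble
#' @param ens A `scenario_ensemble`.
#' @export
is_complete_factorial <- function(ens) {
  all(factorial_keys() %in% names(ens$members))
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat("<scenario_ensemble>", length(x$members), "member(s):",
      paste(names(x$members), collapse = ", "), "\n")
  cat(if (is_complete_factorial(x)) "complete" else "incomplete",
      "2x2 wildfire factorial\n")
  invisible(x)
}

member <- function(ens, key) {
  if (!key %in% names(ens$members)) {
    rlang::abort(paste0("ensemble is missing member ", key),
                 class = "smokewave_ensemble_error")
  }
  ens$members[[key]]
}

require_factorial <- function(ens) {
  missing <- setdiff(factorial_keys(), names(ens$members))
  if (length(missing) > 0L) {
    rlang::abort(paste0("incomplete factorial; missing member(s): ",
                        paste(missing, collapse = ", ")),
                 class = "smokewave_ensemble_error")
  }
  invisible(ens)
}

#' Cell-wise mean of the four wildfire ensemble members
#'
#' The "ensemble average" field — the mean of the CAMS/QFED x FNL/NAM
#' members — serves as the best-estimate concentration field and as the
#' baseline for relative uncertainty.
#'
#' @param ens A complete-factorial `scenario_ensemble`.
#' @return A `conc_field` labeled `AVERAGE-AVERAGE`.
#' @export
ensemble_average <- function(ens) {
  require_factorial(ens)
  m <- ens$members[factorial_keys()]
  vals <- (m[[1L]]$values + m[[2L]]$values + m[[3L]]$values + m[[4L]]$values) / 4
  ref <- m[[1L]]
  conc_field(vals, days = ref$days,
             scenario = scenario_label("AVERAGE", "AVERAGE"),
             row_centers = ref$row_centers, col_centers = ref$col_centers)
}

#' Mean of the no-wildfire control members
#'
#' @param ens A `scenario_ensemble` containing one or two `NONE-*` controls.
#' @return A `conc_field` labeled `NONE-AVERAGE`.
#' @export
control_average <- function(ens) {
  keys <- grep("^NONE-", names(ens$members), value = TRUE)
  if (length(keys) == 0L) {
    rlang::abort("ensemble has no no-wildfire control members",
                 class = "smokewave_ensemble_error")
  }
  vals <- Reduce(`+`, lapply(ens$members[keys], `[[`, "values")) / length(keys)
  ref <- ens$members[[keys[1L]]]
  conc_field(vals, days = ref$days,
             scenario = scenario_label("NONE", "AVERAGE"),
             row_centers = ref$row_centers, col_centers = ref$col_centers)
}

#' Decompose ensemble spread into one factor's uncertainty field
#'
#' For the 2x2 factorial ensemble the uncertainty attributable to the
#' wildfire-emissions input is the signed half-sum of the two paired member
#' differences holding meteorology fixed,
#' `1/2 * ((QFED_FNL - CAMS_FNL) + (QFED_NAM - CAMS_NAM))`,
#' and the meteorology analogue holds emissions fixed,
#' `1/2 * ((CAMS_FNL - CAMS_NAM) + (QFED_FNL - QFED_NAM))`.
#' The sign convention is fixed: QFED minus CAMS, FNL minus NAM; reversing
#' either order would flip the sign of the corresponding field.
#'
#' The relative field is the absolute field as a percentage of the ensemble
#' average. Cells whose ensemble average falls below `floor` are masked
#' (`NA`) rather than reported, to avoid unbounded percentages.
#'
#' @param ens A complete-factorial `scenario_ensemble`.
#' @param factor `"emissions"` or `"meteorology"`.
#' @param floor Minimum ensemble-average concentration (ug m-3) for a cell's
#'   relative value to be defined. Default 1.
#' @return An `uncertainty_field` with components `absolute` (signed
#'   ug m-3 array), `relative` (signed percent, `NA` where masked),
#'   `factor`, and `baseline` (the ensemble-average `conc_field`).
#' @export
factor_uncertainty <- function(ens, factor = c("emissions", "meteorology"),
                               floor = 1) {
  factor <- match.arg(factor)
  require_factorial(ens)
  v <- lapply(ens$members[factorial_keys()], `[[`, "values")
  absolute <- if (factor == "emissions") {
    ((v[["QFED-FNL"]] - v[["CAMS-FNL"]]) +
       (v[["QFED-NAM"]] - v[["CAMS-NAM"]])) / 2
  } else {
    ((v[["CAMS-FNL"]] - v[["CAMS-NAM"]]) +
       (v[["QFED-FNL"]] - v[["QFED-NAM"]])) / 2
  }
  baseline <- ensemble_average(ens)
  relative <- relative_change(absolute, baseline$values, floor = floor)
  structure(
    list(absolute = absolute, relative = relative, factor = factor,
         baseline = baseline, floor = floor),
    class = "uncertainty_field"
  )
}

#' @export
print.uncertainty_field <- function(x, ...) {
  cat(sprintf("<uncertainty_field %s: absolute range [%.2f, %.2f] ug/m3, %d masked cell(s)>\n",
              x$factor, min(x$absolute), max(x$absolute), sum(is.na(x$relative))))
  invisible(x)
}

#' Convert an uncertainty field to a long tibble
#'
#' @param x An `uncertainty_field`.
#' @param ... Unused.
#' @return A tibble with columns `day`, `row`, `col`, `factor`, `absolute`,
#'   `relative`, `average` (masked relative cells are `NA`).
#' @method as_tibble uncertainty_field
#' @export
as_tibble.uncertainty_field <- function(x, ...) {
  base <- as_tibble(x$baseline)
  idx <- cbind(match(base$day, x$baseline$days), base$row, base$col)
  tibble::tibble(
    day = base$day, row = base$row, col = base$col, factor = x$factor,
    absolute = x$absolute[idx], relative = x$relative[idx],
    average = base$pm25
  )
}

#' Relative change with respect to a baseline concentration
#'
#' `100 * absolute / average`, sign preserved. Cells where the average is
#' at or below `floor` are undefined and returned as `NA`, never silently
#' zeroed.
#'
#' @param absolute Signed change (ug m-3); scalar or array.
#' @param average Baseline concentration (ug m-3), same shape.
#' @param floor Averages at or below this are masked. Default 0 here (pure
#'   arithmetic); [factor_uncertainty()] applies its own floor.
#' @return Signed percentage, `NA` where undefined.
#' @examples
#' relative_change(40.7, 99.3) # 40.98...
#' @export
relative_change <- function(absolute, average, floor = 0) {
  out <- 100 * absolute / average
  out[average <= floor] <- NA_real_
  out
}

#' Round half away from zero
#'
#' Tabular reports round half-up (0.05 -> 0.1, -0.05 -> -0.1) to match the
#' usual presentation of signed uncertainty percentages; base R's
#' [round()] rounds half to even. Internal arithmetic is full precision.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @examples
#' round_half_up(0.25, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tabulate per-day uncertainty at selected grid cells
#'
#' Reporting helper mirroring city-by-day uncertainty tables: for each named
#' location (grid cell) and day it lists the ensemble-average concentration
#' and both factors' absolute and relative (half-up rounded, 1 decimal)
#' uncertainties.
#'
#' @param ens A complete-factorial `scenario_ensemble`.
#' @param cells A data frame with columns `name`, `row`, `col`.
#' @param floor Passed to [factor_uncertainty()].
#' @return A tibble with one row per location x day.
#' @export
uncertainty_report <- function(ens, cells, floor = 1) {
  stopifnot(is.data.frame(cells), all(c("name", "row", "col") %in% names(cells)))
  emis <- factor_uncertainty(ens, "emissions", floor = floor)
  met <- factor_uncertainty(ens, "meteorology", floor = floor)
  avg <- emis$baseline
  purrr::pmap_dfr(cells, function(name, row, col, ...) {
    average <- avg$values[, row, col]
    emis_abs <- emis$absolute[, row, col]
    emis_rel <- round_half_up(emis$relative[, row, col], 1)
    met_abs <- met$absolute[, row, col]
    met_rel <- round_half_up(met$relative[, row, col], 1)
    tibble::tibble(
      name = name, day = avg$days, row = row, col = col,
      average = average, emis_abs = emis_abs, emis_rel = emis_rel,
      met_abs = met_abs, met_rel = met_rel
    )
  })
}
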