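#' Pair monitor observations with co-located model values
#'
#' Each monitor-day record is joined to the model value of the grid cell
#' whose center is nearest the monitor location (Euclidean distance in the
#' grid's coordinate system). Monitors outside the grid bounding box are
#' skipped with a message; monitor days absent from the field, or records
#' with missing observations, are dropped and counted.
#'
#' @param field A `conc_field`.
#' @param monitors Data frame with columns `site_id`, `x`, `y`, `date`,
#'   `pm25` (missing observations as `NA`).
#' @return A tibble of pairs: `site_id`, `date`, `row`, `col`, `obs`,
#'   `model`, with attributes `n_dropped` (missing obs or day) and
#'   `skipped_sites` (out-of-domain site ids).
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' ens <- make_ensemble(cfg)
#' truth <- ensemble_average(ens)
#' mon <- make_monitors(cfg, truth)
#' pairs <- pair_monitors(truth, mon)
#' glance(evaluate_pairs(pairs))
#' @export
pair_monitors <- function(field, monitors) {
  stopifnot(is.data.frame(monitors),
            all(c("site_id", "x", "y", "date", "pm25") %in% names(monitors)))
  monitors <- tibble::as_tibble(monitors)
  monitors$date <- as.Date(monitors$date)

  rc <- field$row_centers
  cc <- field$col_centers
  dy <- if (length(rc) > 1L) rc[2L] - rc[1L] else 1
  dx <- if (length(cc) > 1L) cc[2L] - cc[1L] else 1
  in_dom <- monitors$y >= rc[1L] - dy / 2 & monitors$y <= rc[length(rc)] + dy / 2 &
    monitors$x >= cc[1L] - dx / 2 & monitors$x <= cc[length(cc)] + dx / 2
  skipped <- unique(monitors$site_id[!in_dom])
  if (length(skipped) > 0L) {
    rlang::inform(paste0("skipping ", length(skipped),
                         " out-of-domain site(s): ",
                         paste(skipped, collapse = ", ")))
  }
  mon <- monitors[in_dom, , drop = FALSE]

  # nearest cell center; uniform spacing makes this an index computation
  row <- pmin(pmax(round((mon$y - rc[1L]) / dy) + 1L, 1L), length(rc))
  col <- pmin(pmax(round((mon$x - cc[1L]) / dx) + 1L, 1L), length(cc))
  day_idx <- match(mon$date, field$days)

  keep <- !is.na(day_idx) & !is.na(mon$pm25)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    rlang::inform(paste0("dropping ", n_dropped,
                         " record(s) with missing observation or model day"))
  }
  out <- tibble::tibble(
    site_id = mon$site_id[keep], date = mon$date[keep],
    row = row[keep], col = col[keep],
    obs = mon$pm25[keep],
    model = field$values[cbind(day_idx[keep], row[keep], col[keep])]
  )
  if (nrow(out) == 0L) {
    rlang::abort("no overlapping site-days between monitors and field",
                 class = "smokewave_eval_error")
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "skipped_sites") <- skipped
  out
}

#' Model-evaluation statistic battery for paired observations
#'
#' Computes the standard air-quality evaluation statistics over pooled
#' obs-model pairs: mean bias `MB = mean(model - obs)` (ug m-3), normalized
#' mean error `NME = 100 * sum(|model - obs|) / sum(obs)` (%), normalized
#' mean bias `NMB = 100 * sum(model - obs) / sum(obs)` (%), root mean
#' square error `RMSE = sqrt(mean((model - obs)^2))` (ug m-3), and the
#' slope, intercept and R-squared of the ordinary least squares regression
#' of model on observation (model as ordinate).
#'
#' If the observations sum to zero the normalized metrics are undefined and
#' returned as `NA` with a warning.
#'
#' @param pairs Data frame with columns `obs` and `model`; at least 3 rows.
#' @param by Optional column name to group by (e.g. `"site_id"`) for a
#'   per-group breakdown; default pools all pairs.
#' @return A `smoke_eval` object (or a tibble of [glance()] rows when `by`
#'   is given). Use [tidy()] / [glance()] to extract the statistics.
#' @export
evaluate_pairs <- function(pairs, by = NULL) {
  stopifnot(is.data.frame(pairs), all(c("obs", "model") %in% names(pairs)))
  if (!is.null(by)) {
    grouped <- dplyr::group_split(dplyr::group_by(pairs, .data[[by]]))
    return(purrr::map_dfr(grouped, function(g) {
      dplyr::bind_cols(tibble::tibble("{by}" := g[[by]][1L]),
                       glance(evaluate_pairs(g)))
    }))
  }
  if (nrow(pairs) < 3L) {
    rlang::abort("need at least 3 obs-model pairs",
                 class = "smokewave_eval_error")
  }
  obs <- pairs$obs
  model <- pairs$model
  diff <- model - obs
  sum_obs <- sum(obs)
  if (sum_obs <= 0) {
    rlang::warn("sum of observations is zero; normalized metrics undefined")
    nme <- nmb <- NA_real_
  } else {
    nme <- 100 * sum(abs(diff)) / sum_obs
    nmb <- 100 * sum(diff) / sum_obs
  }
  fit <- stats::lm(model ~ obs)
  ss_tot <- sum((model - mean(model))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r2 = r2,
      mb = mean(diff),
      nme = nme,
      nmb = nmb,
      rmse = sqrt(mean(diff^2)),
      n_pairs = nrow(pairs)
    ),
    class = "smoke_eval"
  )
}

#' @export
print.smoke_eval <- function(x, ...) {
  cat("<smoke_eval>", x$n_pairs, "pairs\n")
  print(glance(x))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of evaluation statistics
#'
#' @param x A `smoke_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `mb`, `nme`, `nmb`,
#'   `rmse`, `n_pairs`.
#' @method glance smoke_eval
#' @export
glance.smoke_eval <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 mb = x$mb, nme = x$nme, nmb = x$nmb, rmse = x$rmse,
                 n_pairs = x$n_pairs)
}

#' Long-format evaluation statistics
#'
#' @param x A `smoke_eval` object.
#' @param ... Unused.
#' @return A tibble with columns `statistic`, `value`, `unit`.
#' @method tidy smoke_eval
#' @export
tidy.smoke_eval <- function(x, ...) {
  tibble::tibble(
    statistic = c("slope", "intercept", "r2", "mb", "nme", "nmb", "rmse"),
    value = c(x$slope, x$intercept, x$r2, x$mb, x$nme, x$nmb, x$rmse),
    unit = c("1", "ug m-3", "1", "ug m-3", "%", "%", "ug m-3")
  )
}

#' Evaluate every ensemble member (and derived averages) against monitors
#'
#' Runs [pair_monitors()] and [evaluate_pairs()] for each wildfire member,
#' the ensemble average, each control and the control average, over an
#' episode window.
#'
#' @param ens A `scenario_ensemble`.
#' @param monitors Monitor data frame (see [pair_monitors()]).
#' @param days Optional date vector restricting the evaluation window.
#' @return A tibble with a `scenario` column followed by the [glance()]
#'   statistics, one row per evaluated field.
#' @export
evaluate_ensemble <- function(ens, monitors, days = NULL) {
  fields <- ens$members
  if (is_complete_factorial(ens)) {
    fields <- c(fields, list("CMAQ-Average" = ensemble_average(ens)))
  }
  if (any(grepl("^NONE-", names(ens$members)))) {
    fields <- c(fields, list("noWildfire-Average" = control_average(ens)))
  }
  monitors <- tibble::as_tibble(monitors)
  if (!is.null(days)) {
    monitors <- dplyr::filter(monitors, as.Date(.data$date) %in% as.Date(days))
  }
  purrr::imap_dfr(fields, function(f, key) {
    dplyr::bind_cols(tibble::tibble(scenario = key),
                     glance(evaluate_pairs(pair_monitors(f, monitors))))
  })
}
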