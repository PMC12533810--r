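#' Define a log-linear concentration-response health impact function
#'
#' A health impact function (HIF) links a change in pollutant exposure
#' `delta_x` (ug m-3) to a change in health events through a log-linear
#' concentration-response relation with coefficient `beta` (per ug m-3):
#' `delta_Y = y0 * Pop * (1 - exp(-beta * delta_x))` per exposed day.
#'
#' @param endpoint Endpoint name, e.g. `"asthma_ed_visits"`.
#' @param beta Concentration-response coefficient, per ug m-3.
#' @param beta_se Standard error of `beta` (>= 0).
#' @param baseline_rate Optional endpoint-level baseline incidence rate
#'   (events per person per day) overriding county-specific rates.
#' @return A `health_impact_function` object.
#' @examples
#' health_impact_function("asthma_ed_visits", beta = 5.108e-3, beta_se = 5e-4)
#' @export
health_impact_function <- function(endpoint, beta, beta_se,
                                   baseline_rate = NULL) {
  stopifnot(is.character(endpoint), length(endpoint) == 1L,
            is.finite(beta), beta_se >= 0)
  structure(list(endpoint = endpoint, beta = beta, beta_se = beta_se,
                 baseline_rate = baseline_rate),
            class = "health_impact_function")
}

#' @export
print.health_impact_function <- function(x, ...) {
  cat(sprintf("<health_impact_function %s: beta = %.4g (se %.2g) per ug/m3>\n",
              x$endpoint, x$beta, x$beta_se))
  invisible(x)
}

#' Registry of synthetic endpoint definitions
#'
#' Four short-term PM2.5 morbidity endpoints with synthetic coefficients.
#' The betas are back-computed so that a sustained exposure change of
#' 100 ug m-3 produces rate increases of roughly 40% (asthma ED visits),
#' 8% (respiratory ED visits), 15% (cardiovascular hospital admissions)
#' and 50% (work-loss days) — realistic relative magnitudes for a severe
#' smoke episode. They are stand-ins, not published epidemiological
#' coefficients; supply your own [health_impact_function()]s for real work.
#'
#' @param endpoints Optional character vector selecting a subset.
#' @return A named list of `health_impact_function` objects.
#' @export
default_endpoints <- function(endpoints = NULL) {
  reg <- list(
    asthma_ed_visits = health_impact_function(
      "asthma_ed_visits", beta = -log(1 - 0.40) / 100, beta_se = 5e-4),
    respiratory_ed_visits = health_impact_function(
      "respiratory_ed_visits", beta = -log(1 - 0.08) / 100, beta_se = 1.5e-4),
    cardiovascular_ha = health_impact_function(
      "cardiovascular_ha", beta = -log(1 - 0.15) / 100, beta_se = 3e-4),
    work_loss_days = health_impact_function(
      "work_loss_days", beta = -log(1 - 0.50) / 100, beta_se = 9e-4)
  )
  if (!is.null(endpoints)) reg <- reg[endpoints]
  reg
}

#' Population-weighted county exposure change
#'
#' Aggregates the cell-wise difference between a scenario field and the
#' no-wildfire control to counties through a crosswalk of cell weights:
#' `delta_x(county) = sum_cells weight * (scenario - control)`. Both inputs
#' are single-day fields (use [episode_mean()] first for multi-day windows).
#'
#' @param scenario_mean Single-day `conc_field` for the wildfire scenario.
#' @param control_mean Single-day `conc_field` for the control.
#' @param xwalk Crosswalk data frame with columns `county_id`, `row`,
#'   `col`, `weight` (weights sum to 1 per county).
#' @return A tibble with columns `county_id`, `delta_x` (ug m-3).
#' @export
county_exposure <- function(scenario_mean, control_mean, xwalk) {
  stopifnot(same_grid(scenario_mean, control_mean))
  if (dim(scenario_mean$values)[1L] != 1L || dim(control_mean$values)[1L] != 1L) {
    rlang::abort("fields must be single-day episode means",
                 class = "smokewave_health_error")
  }
  validate_crosswalk(xwalk, dim(scenario_mean$values)[2:3])
  diff <- scenario_mean$values[1L, , ] - control_mean$values[1L, , ]
  xwalk |>
    dplyr::mutate(cell_diff = diff[cbind(.data$row, .data$col)]) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(delta_x = sum(.data$weight * .data$cell_diff),
                     .groups = "drop")
}

#' Validate a grid-cell-to-county crosswalk
#'
#' Checks that per-county weights are non-negative and sum to 1 within
#' 1e-9 and that every referenced cell lies inside the grid.
#'
#' @param xwalk Data frame with `county_id`, `row`, `col`, `weight`.
#' @param grid_dim Integer `(rows, cols)` of the target grid.
#' @return The crosswalk as a tibble, invisibly; errors name offending
#'   counties.
#' @export
validate_crosswalk <- function(xwalk, grid_dim) {
  stopifnot(is.data.frame(xwalk),
            all(c("county_id", "row", "col", "weight") %in% names(xwalk)))
  if (any(xwalk$weight < 0)) {
    rlang::abort("crosswalk weights must be non-negative",
                 class = "smokewave_health_error")
  }
  bad_cell <- xwalk$row < 1 | xwalk$row > grid_dim[1L] |
    xwalk$col < 1 | xwalk$col > grid_dim[2L]
  if (any(bad_cell)) {
    rlang::abort(paste0("crosswalk cells outside grid for county: ",
                        paste(unique(xwalk$county_id[bad_cell]), collapse = ", ")),
                 class = "smokewave_health_error")
  }
  sums <- dplyr::summarise(dplyr::group_by(xwalk, .data$county_id),
                           s = sum(.data$weight), .groups = "drop")
  bad <- sums$county_id[abs(sums$s - 1) > 1e-9]
  if (length(bad) > 0L) {
    rlang::abort(paste0("crosswalk weights do not sum to 1 for county: ",
                        paste(bad, collapse = ", ")),
                 class = "smokewave_health_error")
  }
  invisible(tibble::as_tibble(xwalk))
}

#' Attributable health events and their variance for one county
#'
#' The change in events over an `n_days` episode with a daily baseline
#' incidence rate `y0` (events per person per day) is
#' `delta_Y = y0 * Pop * (1 - exp(-beta * delta_x)) * n_days`.
#' Uncertainty in `beta` is propagated by the delta method,
#' `Var(delta_Y) = (y0 * Pop * delta_x * exp(-beta * delta_x) * n_days)^2 * se^2`,
#' or by seeded Monte-Carlo sampling of `beta ~ Normal(beta, se)`; the two
#' agree closely whenever `se * delta_x` is small.
#'
#' @param hif A [health_impact_function()].
#' @param population Exposed population (persons, >= 0).
#' @param baseline_rate Baseline incidence rate, events per person per day.
#' @param delta_x Exposure change, ug m-3 (vectorized).
#' @param n_days Number of episode days (>= 1).
#' @param method `"delta"` (default) or `"montecarlo"`.
#' @param n_draws,seed Monte-Carlo draws and RNG seed.
#' @return A tibble with columns `delta_events`, `variance`.
#' @examples
#' hif <- health_impact_function("asthma_ed_visits", 6.7e-3, 6.7e-4)
#' delta_events(hif, population = 1e5, baseline_rate = 2.2e-5,
#'              delta_x = 100, n_days = 3)
#' @export
delta_events <- function(hif, population, baseline_rate, delta_x, n_days = 1L,
                         method = c("delta", "montecarlo"),
                         n_draws = 2000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(hif, "health_impact_function"), n_days >= 1)
  if (any(population < 0)) {
    rlang::abort("population must be non-negative",
                 class = "smokewave_health_error")
  }
  scale <- baseline_rate * population * n_days
  dy <- scale * (1 - exp(-hif$beta * delta_x))
  if (method == "delta") {
    v <- (scale * delta_x * exp(-hif$beta * delta_x))^2 * hif$beta_se^2
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    betas <- stats::rnorm(n_draws, hif$beta, hif$beta_se)
    scale_v <- rep_len(scale, length(delta_x))
    v <- vapply(seq_along(delta_x), function(i) {
      stats::var(scale_v[i] * (1 - exp(-betas * delta_x[i])))
    }, numeric(1))
  }
  # delta_x = 0 contributes no events and no beta sensitivity
  v[delta_x == 0] <- 0
  tibble::tibble(delta_events = dy, variance = v)
}

#' County burden table for one endpoint and one scenario
#'
#' Combines county exposure changes with county profiles and a health
#' impact function into the per-county burden: attributable events, their
#' variance, baseline events (`y0 * Pop * n_days`), and the county
#' incidence rate ratio with its 95% CI.
#'
#' @param exposure Tibble from [county_exposure()] (`county_id`, `delta_x`).
#' @param profiles Data frame with `county_id`, `population`,
#'   `baseline_rate` (per person-day) and optional `region_id`.
#' @param hif A [health_impact_function()]; its `baseline_rate`, if set,
#'   overrides the county rates.
#' @param n_days Episode length in days.
#' @return A `county_burden` tibble: `county_id`, `region_id`, `delta_x`,
#'   `delta_events`, `variance`, `baseline_events`, `irr`, `ci_low`,
#'   `ci_high`.
#' @export
county_burden <- function(exposure, profiles, hif, n_days = 1L) {
  stopifnot(is.data.frame(profiles),
            all(c("county_id", "population", "baseline_rate") %in% names(profiles)))
  missing <- setdiff(exposure$county_id, profiles$county_id)
  if (length(missing) > 0L) {
    rlang::abort(paste0("no profile for county: ",
                        paste(missing, collapse = ", ")),
                 class = "smokewave_health_error")
  }
  profiles <- tibble::as_tibble(profiles)
  if (!"region_id" %in% names(profiles)) profiles$region_id <- NA_character_
  tab <- dplyr::inner_join(exposure, profiles, by = "county_id")
  rate <- if (!is.null(hif$baseline_rate)) hif$baseline_rate else tab$baseline_rate
  de <- delta_events(hif, tab$population, rate, tab$delta_x, n_days = n_days)
  out <- tibble::tibble(
    county_id = tab$county_id, region_id = tab$region_id,
    delta_x = tab$delta_x,
    delta_events = de$delta_events, variance = de$variance,
    baseline_events = rate * tab$population * n_days
  )
  ci <- purrr::pmap_dfr(
    out[c("delta_events", "variance", "baseline_events")],
    function(delta_events, variance, baseline_events) {
      r <- irr(tibble::tibble(delta_events = delta_events,
                              variance = variance,
                              baseline_events = baseline_events))
      r[c("irr", "ci_low", "ci_high")]
    }
  )
  out <- dplyr::bind_cols(out, ci)
  class(out) <- c("county_burden", class(out))
  out
}

#' Incidence rate ratio from aggregated health burdens
#'
#' Aggregates attributable events over any grouping of counties and forms
#' the incidence rate ratio
#' `IRR = sum(delta_events) / sum(baseline_events) + 1`
#' with a normal-theory 95% CI on the attributable events,
#' `CI95 = sum(delta_events) +/- 1.96 * sqrt(sum(variance))`, mapped to the
#' ratio scale by dividing by the baseline events and adding 1.
#'
#' @param burdens Data frame with columns `delta_events`, `variance`,
#'   `baseline_events` (e.g. a [county_burden()] table or any subset).
#' @param by Optional grouping column name (e.g. `"region_id"`).
#' @return A tibble with `irr`, `ci_low`, `ci_high` (plus the grouping
#'   column and `delta_events`, `baseline_events` sums when `by` is given).
#' @examples
#' irr(tibble::tibble(delta_events = 40, variance = 25, baseline_events = 100))
#' @export
irr <- function(burdens, by = NULL) {
  stopifnot(is.data.frame(burdens),
            all(c("delta_events", "variance", "baseline_events") %in% names(burdens)))
  if (!is.null(by)) {
    return(
      burdens |>
        dplyr::group_by(.data[[by]]) |>
        dplyr::group_modify(function(g, key) {
          dplyr::bind_cols(
            tibble::tibble(delta_events = sum(g$delta_events),
                           baseline_events = sum(g$baseline_events)),
            irr(g)
          )
        }) |>
        dplyr::ungroup()
    )
  }
  sum_d <- sum(burdens$delta_events)
  sum_b <- sum(burdens$baseline_events)
  sum_v <- sum(burdens$variance)
  if (sum_b <= 0) {
    rlang::abort("baseline events must be positive to form an IRR",
                 class = "smokewave_health_error")
  }
  half <- 1.96 * sqrt(sum_v)
  tibble::tibble(
    irr = sum_d / sum_b + 1,
    ci_low = (sum_d - half) / sum_b + 1,
    ci_high = (sum_d + half) / sum_b + 1
  )
}

#' Run the full health chain for every scenario and endpoint
#'
#' For each wildfire ensemble member and the ensemble average, computes the
#' episode-mean exposure change against the control average and applies
#' each endpoint's health impact function, yielding one county burden table
#' per scenario x endpoint.
#'
#' @param ens A `scenario_ensemble` containing the four wildfire members
#'   and at least one `NONE-*` control.
#' @param xwalk County crosswalk (see [validate_crosswalk()]).
#' @param profiles County profile table (see [county_burden()]).
#' @param hifs A list of [health_impact_function()]s (default
#'   [default_endpoints()]).
#' @param days Episode days to average over; default all days.
#' @param control Either `"average"` (mean of both controls, default) or a
#'   specific control key such as `"NONE-FNL"`.
#' @return A tibble with columns `scenario`, `endpoint`, `burden`
#'   (list-column of [county_burden()] tables).
#' @export
run_endpoints <- function(ens, xwalk, profiles, hifs = default_endpoints(),
                          days = NULL, control = "average") {
  require_factorial(ens)
  ctrl_field <- if (identical(control, "average")) {
    control_average(ens)
  } else {
    member(ens, control)
  }
  if (is.null(days)) days <- ctrl_field$days
  n_days <- length(days)
  ctrl_mean <- episode_mean(ctrl_field, days)
  scenarios <- c(as.list(ens$members[factorial_keys()]),
                 list("CMAQ-Average" = ensemble_average(ens)))
  tidyr::expand_grid(scenario = names(scenarios),
                     endpoint = vapply(hifs, `[[`, character(1), "endpoint")) |>
    dplyr::mutate(burden = purrr::map2(
      .data$scenario, .data$endpoint,
      function(sc, ep) {
        exposure <- county_exposure(episode_mean(scenarios[[sc]], days),
                                    ctrl_mean, xwalk)
        hif <- hifs[[which(vapply(hifs, `[[`, character(1), "endpoint") == ep)]]
        county_burden(exposure, profiles, hif, n_days = n_days)
      }
    ))
}
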