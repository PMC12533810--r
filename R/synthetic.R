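#' Configuration for the synthetic smoke-episode generator
#'
#' Defines a complete synthetic study: a regular grid, a smooth low
#' background PM2.5 field, and a high-concentration Gaussian plume (daily
#' means on the order of 100-200 ug m-3) advecting across the domain over
#' the episode days. The 2x2 factorial structure mirrors a wildfire
#' modeling ensemble: the two emissions variants scale the plume amplitude
#' (systematic offsets), the two meteorology variants shift its trajectory
#' (transport-path offsets). Monitors sample the ensemble-average field
#' with Gaussian noise; counties tile the grid in rectangular blocks; ED
#' visit counts are Poisson draws consistent with the log-linear health
#' model.
#'
#' @param rows,cols Grid dimensions (default 20 x 30).
#' @param spacing Cell size in the grid coordinate unit (default 12, km).
#' @param n_days Episode length in days (default 3).
#' @param start_date First episode day (default 2023-06-06).
#' @param background Background PM2.5 level, ug m-3 (default 5).
#' @param amplitude Plume peak amplitude before emissions scaling, ug m-3
#'   (default 180, giving daily maxima well above 100 in every member).
#' @param width Plume Gaussian standard deviation in cells (default 3).
#' @param start_cell Plume center `(row, col)` on day 1 (default `c(10, 6)`).
#' @param drift Per-day plume displacement `(rows, cols)` (default
#'   `c(0, 9)`: eastward advection across the domain).
#' @param emissions_scale Named amplitude multipliers for the two emissions
#'   variants (default `c(CAMS = 0.9, QFED = 1.25)`, a ~30% systematic
#'   difference).
#' @param met_shift Named list of trajectory offsets in cells for the two
#'   meteorology variants (default FNL `c(0, 0)`, NAM `c(1, -1)`: a small
#'   transport-path difference).
#' @param n_monitors Number of monitor sites (default 30).
#' @param noise_sd Monitor observation noise standard deviation, ug m-3
#'   (default 5).
#' @param county_blocks Number of county blocks `(row blocks, col blocks)`
#'   tiling the grid (default `c(4, 5)`, 20 counties of 5 x 6 cells).
#' @param population_range County populations are drawn log-uniformly from
#'   this range (default `c(1e5, 1e6)` persons).
#' @param baseline_rate Baseline incidence rate, events per person per day
#'   (default 2.2e-5, a plausible asthma ED-visit rate).
#' @param beta,beta_se Concentration-response coefficient and its SE used
#'   both to simulate visits and as the modeling default
#'   (default `-log(0.6)/100` per ug m-3, i.e. a 40% rate increase at a
#'   100 ug m-3 exposure change, and SE 5e-4).
#' @param baseline_len,buffer_days Baseline visit window: `baseline_len`
#'   days on each side of the episode, separated from it by `buffer_days`
#'   (defaults 7 and 3).
#' @param seed Master RNG seed recorded in all outputs (default 42).
#' @return A validated `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' ens <- make_ensemble(cfg)
#' ensemble_average(ens)
#' @export
synthetic_config <- function(rows = 20L, cols = 30L, spacing = 12,
                             n_days = 3L, start_date = as.Date("2023-06-06"),
                             background = 5, amplitude = 180, width = 3,
                             start_cell = c(10, 6), drift = c(0, 9),
                             emissions_scale = c(CAMS = 0.9, QFED = 1.25),
                             met_shift = list(FNL = c(0, 0), NAM = c(1, -1)),
                             n_monitors = 30L, noise_sd = 5,
                             county_blocks = c(4L, 5L),
                             population_range = c(1e5, 1e6),
                             baseline_rate = 2.2e-5,
                             beta = -log(0.6) / 100, beta_se = 5e-4,
                             baseline_len = 7L, buffer_days = 3L,
                             seed = 42L) {
  cfg <- list(
    rows = as.integer(rows), cols = as.integer(cols), spacing = spacing,
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    background = background, amplitude = amplitude, width = width,
    start_cell = start_cell, drift = drift,
    emissions_scale = emissions_scale, met_shift = met_shift,
    n_monitors = as.integer(n_monitors), noise_sd = noise_sd,
    county_blocks = as.integer(county_blocks),
    population_range = population_range, baseline_rate = baseline_rate,
    beta = beta, beta_se = beta_se,
    baseline_len = as.integer(baseline_len),
    buffer_days = as.integer(buffer_days),
    seed = as.integer(seed)
  )
  stopifnot(cfg$rows >= 1, cfg$cols >= 1, cfg$n_days >= 1,
            cfg$amplitude >= 0, cfg$width > 0, cfg$noise_sd >= 0,
            all(cfg$emissions_scale >= 0), cfg$baseline_rate >= 0,
            all(cfg$population_range > 0),
            all(c("CAMS", "QFED") %in% names(cfg$emissions_scale)),
            all(c("FNL", "NAM") %in% names(cfg$met_shift)),
            cfg$rows %% cfg$county_blocks[1L] == 0,
            cfg$cols %% cfg$county_blocks[2L] == 0)
  # the plume center must stay on the grid for every day and met variant
  for (met in c("FNL", "NAM")) {
    for (d in seq_len(cfg$n_days) - 1L) {
      ctr <- cfg$start_cell + d * cfg$drift + cfg$met_shift[[met]]
      if (ctr[1L] < 1 || ctr[1L] > cfg$rows || ctr[2L] < 1 || ctr[2L] > cfg$cols) {
        rlang::abort(sprintf(
          "plume center leaves the grid on day %d under %s shift", d + 1L, met),
          class = "smokewave_config_error")
      }
    }
  }
  structure(cfg, class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

background_field <- function(cfg) {
  r <- matrix(seq_len(cfg$rows), cfg$rows, cfg$cols)
  c_ <- matrix(seq_len(cfg$cols), cfg$rows, cfg$cols, byrow = TRUE)
  cfg$background * (1 + 0.3 * sin(pi * r / cfg$rows) * sin(pi * c_ / cfg$cols))
}

gaussian_plume <- function(cfg, center) {
  r <- matrix(seq_len(cfg$rows), cfg$rows, cfg$cols)
  c_ <- matrix(seq_len(cfg$cols), cfg$rows, cfg$cols, byrow = TRUE)
  exp(-((r - center[1L])^2 + (c_ - center[2L])^2) / (2 * cfg$width^2))
}

#' Generate the factorial plume ensemble and controls
#'
#' Each wildfire member is `background + emissions_scale[e] * amplitude *
#' plume(day)` with the plume trajectory shifted by the meteorology
#' variant's offset; the additive construction means the injected factor
#' differences are exactly recoverable by the uncertainty decomposition
#' when the other factor is held fixed. Controls carry the background only.
#' The construction is fully deterministic given the configuration.
#'
#' @param cfg A [synthetic_config()].
#' @return A `scenario_ensemble` holding the four wildfire members and the
#'   two no-wildfire controls.
#' @export
make_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  days <- cfg$start_date + seq_len(cfg$n_days) - 1L
  coords <- grid_centers(cfg)
  bg <- background_field(cfg)
  build <- function(emis, met) {
    vals <- array(0, c(cfg$n_days, cfg$rows, cfg$cols))
    for (d in seq_len(cfg$n_days)) {
      ctr <- cfg$start_cell + (d - 1L) * cfg$drift + cfg$met_shift[[met]]
      plume <- if (emis == "NONE") 0 else {
        cfg$emissions_scale[[emis]] * cfg$amplitude * gaussian_plume(cfg, ctr)
      }
      vals[d, , ] <- bg + plume
    }
    conc_field(vals, days = days, scenario = scenario_label(emis, met),
               row_centers = coords$row, col_centers = coords$col)
  }
  members <- purrr::map(
    list(c("CAMS", "FNL"), c("CAMS", "NAM"), c("QFED", "FNL"),
         c("QFED", "NAM"), c("NONE", "FNL"), c("NONE", "NAM")),
    function(p) build(p[1L], p[2L])
  )
  scenario_ensemble(members)
}

grid_centers <- function(cfg) {
  list(row = (seq_len(cfg$rows) - 0.5) * cfg$spacing,
       col = (seq_len(cfg$cols) - 0.5) * cfg$spacing)
}

#' Generate synthetic monitor observations of a field
#'
#' Places `n_monitors` sites at distinct random cell centers and observes
#' the supplied field with additive Gaussian noise, truncated at zero.
#' Deterministic per seed.
#'
#' @param cfg A [synthetic_config()].
#' @param truth A `conc_field` to observe (e.g. the ensemble average).
#' @param seed RNG seed (default `cfg$seed`).
#' @return A monitor tibble: `site_id`, `x`, `y`, `date`, `pm25`.
#' @export
make_monitors <- function(cfg, truth, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "conc_field"))
  n_cells <- cfg$rows * cfg$cols
  if (cfg$n_monitors > n_cells) {
    rlang::abort("more monitors than grid cells",
                 class = "smokewave_config_error")
  }
  with_seed(seed, {
    cells <- sample.int(n_cells, cfg$n_monitors)
    row <- ((cells - 1L) %% cfg$rows) + 1L
    col <- ((cells - 1L) %/% cfg$rows) + 1L
    grid <- tidyr::expand_grid(
      site = seq_len(cfg$n_monitors),
      day_idx = seq_along(truth$days)
    )
    noise <- stats::rnorm(nrow(grid), 0, cfg$noise_sd)
    tibble::tibble(
      site_id = sprintf("S%03d", grid$site),
      x = truth$col_centers[col[grid$site]],
      y = truth$row_centers[row[grid$site]],
      date = truth$days[grid$day_idx],
      pm25 = pmax(0, truth$values[cbind(grid$day_idx, row[grid$site],
                                        col[grid$site])] + noise)
    )
  })
}

#' Generate county profiles and the grid-to-county crosswalk
#'
#' Counties are rectangular blocks tiling the grid with equal within-county
#' cell weights; populations are drawn log-uniformly from
#' `cfg$population_range` (seeded). Counties are grouped into regions by
#' block row (`R1`, `R2`, ...), the grouping used for validation
#' aggregation.
#'
#' @param cfg A [synthetic_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return A list with `profiles` (county_id, region_id, population,
#'   baseline_rate) and `crosswalk` (county_id, row, col, weight).
#' @export
make_counties <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  bl_r <- cfg$rows / cfg$county_blocks[1L]
  bl_c <- cfg$cols / cfg$county_blocks[2L]
  xwalk <- tidyr::expand_grid(row = seq_len(cfg$rows), col = seq_len(cfg$cols)) |>
    dplyr::mutate(
      block_row = ceiling(.data$row / bl_r),
      block_col = ceiling(.data$col / bl_c),
      county_id = sprintf("C%02d", (.data$block_row - 1L) *
                            cfg$county_blocks[2L] + .data$block_col),
      weight = 1 / (bl_r * bl_c)
    )
  n_counties <- prod(cfg$county_blocks)
  pops <- with_seed(seed, {
    exp(stats::runif(n_counties, log(cfg$population_range[1L]),
                     log(cfg$population_range[2L])))
  })
  profiles <- xwalk |>
    dplyr::distinct(.data$county_id, .data$block_row) |>
    dplyr::arrange(.data$county_id) |>
    dplyr::transmute(
      county_id = .data$county_id,
      region_id = sprintf("R%d", .data$block_row),
      population = pops[dplyr::row_number()],
      baseline_rate = cfg$baseline_rate
    )
  list(profiles = profiles,
       crosswalk = dplyr::select(xwalk, "county_id", "row", "col", "weight"))
}

#' Simulate ED visit count series consistent with the health model
#'
#' Daily counts per region are Poisson draws with rate
#' `sum_counties y0 * Pop * exp(beta * delta_x(county, day))` on episode
#' days and `sum_counties y0 * Pop` on baseline days (no exposure change).
#' The baseline window is `cfg$baseline_len` days on each side of the
#' episode, separated from it by `cfg$buffer_days`.
#'
#' @param cfg A [synthetic_config()].
#' @param exposure_by_day Tibble `county_id`, `date`, `delta_x` for the
#'   episode days (see [simulate_inputs()]).
#' @param counties Optional county set from [make_counties()]; regenerated
#'   from `cfg` when omitted.
#' @param seed RNG seed for the Poisson draws (default `cfg$seed`).
#' @return A visit tibble `region_id`, `date`, `count` with the smoke and
#'   baseline day windows attached as attributes `smoke_days` and
#'   `baseline_days`.
#' @export
make_visits <- function(cfg, exposure_by_day, counties = NULL,
                        seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("county_id", "date", "delta_x") %in% names(exposure_by_day)))
  if (is.null(counties)) counties <- make_counties(cfg)
  prof <- counties$profiles
  smoke_days <- sort(unique(as.Date(exposure_by_day$date)))
  baseline_days <- c(
    min(smoke_days) - cfg$buffer_days - seq_len(cfg$baseline_len),
    max(smoke_days) + cfg$buffer_days + seq_len(cfg$baseline_len)
  )
  smoke_rates <- exposure_by_day |>
    dplyr::inner_join(prof, by = "county_id") |>
    dplyr::group_by(region_id = .data$region_id, date = as.Date(.data$date)) |>
    dplyr::summarise(rate = sum(.data$baseline_rate * .data$population *
                                  exp(cfg$beta * .data$delta_x)),
                     .groups = "drop")
  base_rates <- prof |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(rate = sum(.data$baseline_rate * .data$population),
                     .groups = "drop") |>
    tidyr::expand_grid(date = baseline_days) |>
    dplyr::select("region_id", "date", "rate")
  all_rates <- dplyr::arrange(dplyr::bind_rows(smoke_rates, base_rates),
                              .data$region_id, .data$date)
  counts <- with_seed(seed, stats::rpois(nrow(all_rates), all_rates$rate))
  out <- tibble::tibble(region_id = all_rates$region_id,
                        date = all_rates$date, count = counts)
  attr(out, "smoke_days") <- smoke_days
  attr(out, "baseline_days") <- sort(baseline_days)
  out
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper producing everything the pipeline consumes:
#' the factorial ensemble with controls, the ensemble-average "truth"
#' field, monitors observing it, county profiles and crosswalk, per
#' county-day exposure changes of the ensemble average over the control
#' average, and one realization of ED visit counts.
#'
#' @param cfg A [synthetic_config()].
#' @return A named list: `ensemble`, `truth`, `monitors`, `counties`,
#'   `crosswalk`, `exposure_by_day`, `visits`, `config`.
#' @export
simulate_inputs <- function(cfg) {
  ens <- make_ensemble(cfg)
  truth <- ensemble_average(ens)
  ctrl <- control_average(ens)
  counties <- make_counties(cfg)
  exposure_by_day <- purrr::map_dfr(seq_along(truth$days), function(d) {
    county_exposure(episode_mean(truth, truth$days[d]),
                    episode_mean(ctrl, ctrl$days[d]),
                    counties$crosswalk) |>
      dplyr::mutate(date = truth$days[d])
  })
  visits <- make_visits(cfg, exposure_by_day, counties)
  list(ensemble = ens, truth = truth,
       monitors = make_monitors(cfg, truth),
       counties = counties$profiles, crosswalk = counties$crosswalk,
       exposure_by_day = exposure_by_day, visits = visits, config = cfg)
}
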