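#' Run the full episodic smoke-analysis workflow
#'
#' Executes the pipeline stages in dependency order — `simulate` (or ingest
#' of existing files), `evaluate`, `uncertainty`, `health`, `validate` —
#' writing each stage's outputs to a named subdirectory of `out_dir` and a
#' JSON run manifest recording the configuration hash, input checksums,
#' stages executed, seed and package version. Stages whose outputs already
#' exist are skipped unless listed in `redo`, so deleting one stage's
#' directory and rerunning regenerates only that stage (and nothing
#' upstream).
#'
#' @param config A [synthetic_config()], a YAML file path of
#'   `synthetic_config()` arguments, or a named list of them.
#' @param out_dir Output directory (created if missing).
#' @param stages Stages to run, in order; default all.
#' @param redo Stages to force-rerun even if their outputs exist.
#' @param quiet Suppress progress messages.
#' @return The manifest (a list), invisibly; side effect: files under
#'   `out_dir`.
#' @examples
#' \donttest{
#' out <- run_all(synthetic_config(seed = 1), out_dir = tempfile())
#' out$stages
#' }
#' @export
run_all <- function(config, out_dir,
                    stages = c("simulate", "evaluate", "uncertainty",
                               "health", "validate"),
                    redo = character(), quiet = FALSE) {
  cfg <- load_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) rlang::inform(paste0(...))

  manifest <- list(
    tool = "smokewave",
    version = as.character(utils::packageVersion("smokewave")),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list()
  )

  done <- function(stage) {
    marker <- file.path(out_dir, stage, ".complete")
    file.exists(marker) && !stage %in% redo
  }
  finish <- function(stage, files) {
    writeLines(format(Sys.time()), file.path(out_dir, stage, ".complete"))
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }
  stage_dir <- function(stage) {
    d <- file.path(out_dir, stage)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }

  sim <- NULL
  get_sim <- function() {
    if (is.null(sim)) sim <<- simulate_inputs(cfg)
    sim
  }

  if ("simulate" %in% stages) {
    d <- stage_dir("simulate")
    if (done("simulate")) {
      say("simulate: outputs present, skipping")
    } else {
      say("simulate: generating synthetic inputs")
      s <- get_sim()
      files <- character()
      for (key in names(s$ensemble$members)) {
        f <- file.path(d, paste0(tolower(gsub("-", "_", key)), ".nc"))
        write_field(s$ensemble$members[[key]], f)
        files <- c(files, f)
      }
      readr::write_csv(s$monitors, file.path(d, "monitors.csv"))
      readr::write_csv(s$counties, file.path(d, "counties.csv"))
      readr::write_csv(s$crosswalk, file.path(d, "crosswalk.csv"))
      readr::write_csv(s$visits, file.path(d, "visits.csv"))
      readr::write_csv(s$exposure_by_day, file.path(d, "exposure_by_day.csv"))
      finish("simulate", c(files, file.path(d, c(
        "monitors.csv", "counties.csv", "crosswalk.csv", "visits.csv",
        "exposure_by_day.csv"
      ))))
    }
  }

  read_stage_inputs <- function() {
    d <- file.path(out_dir, "simulate")
    fields <- lapply(list.files(d, pattern = "\\.nc$", full.names = TRUE),
                     read_field)
    list(
      ensemble = scenario_ensemble(fields),
      monitors = readr::read_csv(file.path(d, "monitors.csv"),
                                 show_col_types = FALSE),
      counties = readr::read_csv(file.path(d, "counties.csv"),
                                 show_col_types = FALSE),
      crosswalk = readr::read_csv(file.path(d, "crosswalk.csv"),
                                  show_col_types = FALSE),
      visits = readr::read_csv(file.path(d, "visits.csv"),
                               show_col_types = FALSE),
      exposure_by_day = readr::read_csv(file.path(d, "exposure_by_day.csv"),
                                        show_col_types = FALSE)
    )
  }

  inputs <- NULL
  get_inputs <- function() {
    if (is.null(inputs)) inputs <<- read_stage_inputs()
    inputs
  }

  if ("evaluate" %in% stages) {
    d <- stage_dir("evaluate")
    if (done("evaluate")) {
      say("evaluate: outputs present, skipping")
    } else {
      say("evaluate: monitor-based model evaluation")
      inp <- get_inputs()
      stats <- evaluate_ensemble(inp$ensemble, inp$monitors)
      readr::write_csv(stats, file.path(d, "stats.csv"))
      finish("evaluate", file.path(d, "stats.csv"))
    }
  }

  if ("uncertainty" %in% stages) {
    d <- stage_dir("uncertainty")
    if (done("uncertainty")) {
      say("uncertainty: outputs present, skipping")
    } else {
      say("uncertainty: factorial decomposition")
      inp <- get_inputs()
      for (fac in c("emissions", "meteorology")) {
        u <- factor_uncertainty(inp$ensemble, fac)
        readr::write_csv(as_tibble(u), file.path(d, paste0(fac, ".csv")))
      }
      avg <- ensemble_average(inp$ensemble)
      write_field(avg, file.path(d, "ensemble_average.nc"))
      finish("uncertainty", file.path(d, c("emissions.csv",
                                           "meteorology.csv",
                                           "ensemble_average.nc")))
    }
  }

  if ("health" %in% stages) {
    d <- stage_dir("health")
    if (done("health")) {
      say("health: outputs present, skipping")
    } else {
      say("health: county burden and IRR per endpoint")
      inp <- get_inputs()
      hifs <- default_endpoints()
      hifs[["asthma_ed_visits"]] <- health_impact_function(
        "asthma_ed_visits", cfg$beta, cfg$beta_se)
      tables <- run_endpoints(inp$ensemble, inp$crosswalk, inp$counties,
                              hifs = hifs)
      files <- character()
      for (i in seq_len(nrow(tables))) {
        f <- file.path(d, sprintf("%s_%s.csv",
                                  tables$endpoint[i],
                                  tolower(gsub("-", "_", tables$scenario[i]))))
        readr::write_csv(tables$burden[[i]], f)
        files <- c(files, f)
      }
      finish("health", files)
    }
  }

  if ("validate" %in% stages) {
    d <- stage_dir("validate")
    if (done("validate")) {
      say("validate: outputs present, skipping")
    } else {
      say("validate: observed vs modeled IRR")
      inp <- get_inputs()
      hif <- health_impact_function("asthma_ed_visits", cfg$beta, cfg$beta_se)
      burden <- run_endpoints(inp$ensemble, inp$crosswalk, inp$counties,
                              hifs = list(hif)) |>
        dplyr::filter(.data$scenario == "CMAQ-Average") |>
        dplyr::pull("burden")
      modeled <- irr(burden[[1L]], by = "region_id")
      smoke_days <- sort(unique(as.Date(inp$exposure_by_day$date)))
      baseline_days <- setdiff(unique(as.Date(inp$visits$date)), smoke_days)
      obs <- observed_irr(inp$visits, smoke_days,
                          as.Date(baseline_days, origin = "1970-01-01"))
      cmp <- compare_irr(obs, modeled)
      readr::write_csv(cmp, file.path(d, "comparison.csv"))
      finish("validate", file.path(d, "comparison.csv"))
    }
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

load_config <- function(config) {
  if (inherits(config, "synthetic_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      rlang::abort(paste0("config file not found: ", config),
                   class = "smokewave_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    rlang::abort("config must be a synthetic_config, a YAML path, or a list",
                 class = "smokewave_config_error")
  }
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "smokewave_config_error")
  }
  do.call(synthetic_config, config)
}
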