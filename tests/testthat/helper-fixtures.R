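# Shared fixtures: tiny deterministic fields and random ensembles.

tiny_field <- function(vals, days = as.Date("2023-06-06"),
                       emissions = "CAMS", meteorology = "FNL") {
  vals <- as.matrix(vals)
  if (length(dim(vals)) == 2L) {
    vals <- array(vals, c(1L, nrow(vals), ncol(vals)))
  }
  conc_field(vals, days = days,
             scenario = scenario_label(emissions, meteorology))
}

# random positive fields on a shared small grid, one per factorial member
random_ensemble <- function(seed = 1, n_days = 2L, rows = 5L, cols = 6L,
                            controls = FALSE) {
  set.seed(seed)
  labels <- list(c("CAMS", "FNL"), c("CAMS", "NAM"),
                 c("QFED", "FNL"), c("QFED", "NAM"))
  if (controls) labels <- c(labels, list(c("NONE", "FNL"), c("NONE", "NAM")))
  fields <- lapply(labels, function(l) {
    conc_field(array(runif(n_days * rows * cols, 0, 100),
                     c(n_days, rows, cols)),
               days = as.Date("2023-06-06") + seq_len(n_days) - 1L,
               scenario = scenario_label(l[1L], l[2L]))
  })
  scenario_ensemble(fields)
}

# ensemble built additively: base + e(emissions) + m(meteorology), so the
# factor decomposition must recover the injected differences exactly
additive_ensemble <- function(seed = 2, n_days = 2L, rows = 4L, cols = 5L,
                              e = c(CAMS = 10, QFED = 25),
                              m = c(FNL = 3, NAM = 8)) {
  set.seed(seed)
  base <- array(runif(n_days * rows * cols, 20, 60), c(n_days, rows, cols))
  fields <- list()
  for (emis in c("CAMS", "QFED")) {
    for (met in c("FNL", "NAM")) {
      fields <- c(fields, list(conc_field(
        base + e[[emis]] + m[[met]],
        days = as.Date("2023-06-06") + seq_len(n_days) - 1L,
        scenario = scenario_label(emis, met)
      )))
    }
  }
  list(ensemble = scenario_ensemble(fields), base = base, e = e, m = m)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(rows = 10L, cols = 12L, n_days = 3L, start_cell = c(5, 3),
         drift = c(0, 3), county_blocks = c(2L, 3L), n_monitors = 12L,
         seed = 7L),
    list(...)
  )
  do.call(synthetic_config, args)
}
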