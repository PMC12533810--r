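hif_test <- health_impact_function("asthma_ed_visits", beta = 6.7e-3,
                                   beta_se = 6.7e-4)

test_that("crosswalk validation catches bad weights and stray cells", {
  ok <- tibble::tibble(county_id = c("A", "A", "B"),
                       row = c(1, 2, 1), col = c(1, 1, 2),
                       weight = c(0.5, 0.5, 1))
  expect_silent(validate_crosswalk(ok, c(2, 2)))
  bad_sum <- dplyr::mutate(ok, weight = c(0.5, 0.4, 1))
  expect_error(validate_crosswalk(bad_sum, c(2, 2)), "A",
               class = "smokewave_health_error")
  stray <- dplyr::mutate(ok, row = c(1, 9, 1))
  expect_error(validate_crosswalk(stray, c(2, 2)), "outside grid",
               class = "smokewave_health_error")
  neg <- dplyr::mutate(ok, weight = c(1.5, -0.5, 1))
  expect_error(validate_crosswalk(neg, c(2, 2)),
               class = "smokewave_health_error")
})

test_that("county_exposure matches an explicit weighted-sum oracle", {
  set.seed(41)
  rows <- 4L; cols <- 6L
  day <- as.Date("2023-06-06")
  sc <- conc_field(array(runif(rows * cols, 10, 120), c(1, rows, cols)), day)
  ct <- conc_field(array(runif(rows * cols, 0, 10), c(1, rows, cols)), day)
  xw <- tidyr::expand_grid(row = 1:rows, col = 1:cols) |>
    dplyr::mutate(county_id = rep(c("A", "B", "C"), length.out = rows * cols),
                  weight = runif(rows * cols))
  xw <- xw |>
    dplyr::group_by(county_id) |>
    dplyr::mutate(weight = weight / sum(weight)) |>
    dplyr::ungroup()
  got <- county_exposure(sc, ct, xw)
  for (cid in c("A", "B", "C")) {
    rowscid <- xw[xw$county_id == cid, ]
    acc <- 0
    for (i in seq_len(nrow(rowscid))) {
      acc <- acc + rowscid$weight[i] *
        (sc$values[1, rowscid$row[i], rowscid$col[i]] -
           ct$values[1, rowscid$row[i], rowscid$col[i]])
    }
    expect_equal(got$delta_x[got$county_id == cid], acc, tolerance = 1e-12)
  }

  # scenario == control gives zero exposure change everywhere
  zero <- county_exposure(sc, sc, xw)
  expect_true(all(abs(zero$delta_x) < 1e-12))

  # single-cell county with difference 80
  sc2 <- ct
  sc2$values[1, 2, 3] <- ct$values[1, 2, 3] + 80
  one <- tibble::tibble(county_id = "X", row = 2, col = 3, weight = 1)
  expect_equal(county_exposure(sc2, ct, one)$delta_x, 80)
})

test_that("delta_events reproduces the closed form and its limits", {
  # frozen from an independent 40-digit evaluation of
  # y0*Pop*(1-exp(-beta*dx))*n and (y0*Pop*dx*exp(-beta*dx)*n)^2*se^2
  de <- delta_events(hif_test, population = 1e5, baseline_rate = 2.2e-5,
                     delta_x = 100, n_days = 3)
  expect_equal(de$delta_events, 3.2227233866088196, tolerance = 1e-12)
  expect_equal(de$variance, 0.051201521984558552, tolerance = 1e-12)

  # delta_x = 0 -> no events, no variance
  z <- delta_events(hif_test, 1e5, 2.2e-5, 0, n_days = 3)
  expect_equal(z$delta_events, 0)
  expect_equal(z$variance, 0)

  # linearization: dY/(y0*Pop*beta*dx*n) -> 1 for beta*dx < 0.01
  dx <- 0.01 / hif_test$beta * 0.99
  lin <- delta_events(hif_test, 1e5, 2.2e-5, dx, n_days = 3)
  expect_equal(lin$delta_events / (2.2e-5 * 1e5 * hif_test$beta * dx * 3), 1,
               tolerance = 0.01)

  expect_error(delta_events(hif_test, -5, 2.2e-5, 10),
               class = "smokewave_health_error")
})

test_that("Monte-Carlo variance agrees with the delta method for small SE", {
  dxs <- c(5, 20, 60)
  stopifnot(all(hif_test$beta_se * dxs < 0.05))
  dm <- delta_events(hif_test, 2e5, 3e-5, dxs, n_days = 3)
  mc <- delta_events(hif_test, 2e5, 3e-5, dxs, n_days = 3,
                     method = "montecarlo", n_draws = 20000, seed = 99)
  expect_equal(mc$variance, dm$variance, tolerance = 0.05)
  # seeded draws are reproducible
  mc2 <- delta_events(hif_test, 2e5, 3e-5, dxs, n_days = 3,
                      method = "montecarlo", n_draws = 20000, seed = 99)
  expect_identical(mc$variance, mc2$variance)
})

test_that("delta_events saturates at the baseline events for huge exposure", {
  huge <- delta_events(hif_test, 1e5, 2.2e-5, 1e6, n_days = 3)
  cap <- 2.2e-5 * 1e5 * 3
  expect_lte(huge$delta_events, cap)
  expect_equal(huge$delta_events, cap, tolerance = 1e-6)
})

test_that("irr implements the aggregate formulas exactly", {
  # hand arithmetic: 40/100 + 1 = 1.40; CI 40 +/- 1.96*sqrt(25)
  r <- irr(tibble::tibble(delta_events = 40, variance = 25,
                          baseline_events = 100))
  expect_equal(r$irr, 1.40)
  expect_equal(r$ci_low, 1.302)
  expect_equal(r$ci_high, 1.498)

  # no change, no variance -> IRR exactly 1 with degenerate CI
  r0 <- irr(tibble::tibble(delta_events = 0, variance = 0,
                           baseline_events = 50))
  expect_equal(r0$irr, 1)
  expect_equal(r0$ci_low, 1)
  expect_equal(r0$ci_high, 1)

  expect_error(irr(tibble::tibble(delta_events = 1, variance = 0,
                                  baseline_events = 0)),
               class = "smokewave_health_error")
})

test_that("irr is invariant to how counties are partitioned into groups", {
  set.seed(43)
  tab <- tibble::tibble(
    delta_events = runif(12, 0, 30), variance = runif(12, 0, 4),
    baseline_events = runif(12, 50, 200),
    region_id = rep(c("R1", "R2", "R3"), each = 4)
  )
  whole <- irr(tab)
  by_region <- irr(tab, by = "region_id")
  pooled <- irr(tibble::tibble(
    delta_events = by_region$delta_events,
    variance = tapply(tab$variance, tab$region_id, sum)[by_region$region_id],
    baseline_events = by_region$baseline_events
  ))
  expect_equal(pooled$irr, whole$irr, tolerance = 1e-12)
  expect_equal(pooled$ci_low, whole$ci_low, tolerance = 1e-12)
})

test_that("IRR exceeds 1 for positive exposure and increases with it", {
  prof <- tibble::tibble(county_id = "A", population = 1e5,
                         baseline_rate = 2.2e-5)
  dxs <- c(0.5, 5, 20, 80, 150)
  irrs <- vapply(dxs, function(dx) {
    b <- county_burden(tibble::tibble(county_id = "A", delta_x = dx),
                       prof, hif_test, n_days = 3)
    b$irr
  }, numeric(1))
  expect_true(all(irrs > 1))
  expect_true(all(diff(irrs) > 0))
})

test_that("county IRR ranking is invariant to uniform population scaling", {
  cfg <- small_config()
  sim <- simulate_inputs(cfg)
  exposure <- county_exposure(
    episode_mean(sim$truth), episode_mean(control_average(sim$ensemble)),
    sim$crosswalk
  )
  b1 <- county_burden(exposure, sim$counties, hif_test, n_days = 3)
  scaled <- dplyr::mutate(sim$counties, population = population * 10)
  b2 <- county_burden(exposure, scaled, hif_test, n_days = 3)
  expect_identical(order(b1$irr), order(b2$irr))
  expect_equal(b1$irr, b2$irr, tolerance = 1e-12)
})

test_that("run_endpoints emits one burden table per scenario and endpoint", {
  cfg <- small_config()
  sim <- simulate_inputs(cfg)
  hifs <- default_endpoints(c("asthma_ed_visits", "work_loss_days"))
  tabs <- run_endpoints(sim$ensemble, sim$crosswalk, sim$counties, hifs)
  expect_equal(nrow(tabs), 5 * 2) # 4 members + average, 2 endpoints
  expect_setequal(unique(tabs$scenario),
                  c("CAMS-FNL", "CAMS-NAM", "QFED-FNL", "QFED-NAM",
                    "CMAQ-Average"))
  expect_true(all(vapply(tabs$burden, nrow, integer(1)) ==
                    nrow(sim$counties)))

  # identical endpoint definitions give identical tables
  twin <- list(health_impact_function("a", 2e-3, 1e-4),
               health_impact_function("b", 2e-3, 1e-4))
  tt <- run_endpoints(sim$ensemble, sim$crosswalk, sim$counties, twin)
  ta <- tt$burden[[which(tt$scenario == "CMAQ-Average" & tt$endpoint == "a")]]
  tb <- tt$burden[[which(tt$scenario == "CMAQ-Average" & tt$endpoint == "b")]]
  expect_equal(ta$irr, tb$irr)
})

test_that("plume-core counties outrank far-field counties in every member", {
  cfg <- synthetic_config(seed = 5)
  sim <- simulate_inputs(cfg)
  tabs <- run_endpoints(sim$ensemble, sim$crosswalk, sim$counties,
                        default_endpoints("asthma_ed_visits"))
  # core: counties crossed by the plume trajectory (its row band);
  # background: counties in the row band farthest from it
  core <- unique(dplyr::pull(
    dplyr::filter(sim$crosswalk, row == cfg$start_cell[1]), county_id))
  far_row <- if (cfg$start_cell[1] <= cfg$rows / 2) cfg$rows else 1L
  background <- unique(dplyr::pull(
    dplyr::filter(sim$crosswalk, row == far_row), county_id))
  for (i in seq_len(nrow(tabs))) {
    b <- tabs$burden[[i]]
    expect_gt(min(b$irr[b$county_id %in% core]),
              max(b$irr[b$county_id %in% background]))
  }
})
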