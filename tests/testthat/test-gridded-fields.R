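test_that("conc_field enforces its invariants", {
  vals <- array(1, c(2, 3, 4))
  f <- conc_field(vals, days = as.Date("2023-06-06") + 0:1)
  expect_s3_class(f, "conc_field")
  expect_equal(dim(f), c(2L, 3L, 4L))

  bad <- vals; bad[1, 1, 1] <- -2
  expect_error(conc_field(bad, days = as.Date("2023-06-06") + 0:1),
               class = "smokewave_field_error")
  nav <- vals; nav[2, 1, 1] <- NA
  expect_error(conc_field(nav, days = as.Date("2023-06-06") + 0:1),
               class = "smokewave_field_error")
  expect_error(conc_field(vals, days = as.Date("2023-06-06") + c(1, 0)),
               class = "smokewave_field_error")
  expect_error(conc_field(vals, days = as.Date("2023-06-06") + 0:1,
                          col_centers = c(0, 1, 3, 7)),
               class = "smokewave_field_error")
})

test_that("NetCDF write/read round-trips a field bit-identically", {
  cfg <- small_config()
  f <- make_ensemble(cfg)$members[["QFED-NAM"]]
  path <- withr::local_tempfile(fileext = ".nc")
  write_field(f, path)
  g <- read_field(path)
  expect_identical(g$values, f$values)
  expect_identical(g$days, f$days)
  expect_equal(g$row_centers, f$row_centers)
  expect_equal(g$col_centers, f$col_centers)
  expect_identical(format(g$scenario), "QFED-NAM")
})

test_that("reading rejects files without a pm25 variable and converts units", {
  path <- withr::local_tempfile(fileext = ".nc")
  d <- ncdf4::ncdim_def("day", "days since 1970-01-01", 19514)
  v <- ncdf4::ncvar_def("ozone", "ppb", list(d), prec = "double")
  nc <- ncdf4::nc_create(path, v)
  ncdf4::ncvar_put(nc, v, 42)
  ncdf4::nc_close(nc)
  expect_error(read_field(path), "pm25", class = "smokewave_field_error")

  # mg m-3 is converted to ug m-3 on load
  f <- tiny_field(matrix(0.005, 2, 2))
  path2 <- withr::local_tempfile(fileext = ".nc")
  write_field(f, path2)
  nc <- ncdf4::nc_open(path2, write = TRUE)
  ncdf4::ncvar_put(nc, "pm25", matrix(0.005 / 1000, 2, 2))
  ncdf4::ncatt_put(nc, "pm25", "units", "mg m-3")
  ncdf4::nc_close(nc)
  expect_equal(read_field(path2)$values, f$values)
})

test_that("synthetic plume file has the configured shape", {
  cfg <- synthetic_config(seed = 1)
  ens <- make_ensemble(cfg)
  path <- withr::local_tempfile(fileext = ".nc")
  write_field(ens$members[["CAMS-FNL"]], path)
  expect_equal(dim(read_field(path)), c(3L, 20L, 30L))
})

test_that("ensemble_average matches a brute-force member mean", {
  ens <- random_ensemble(seed = 11)
  avg <- ensemble_average(ens)
  # independent loop-based oracle
  oracle <- array(0, dim(ens$members[[1]]$values))
  for (k in c("CAMS-FNL", "CAMS-NAM", "QFED-FNL", "QFED-NAM")) {
    oracle <- oracle + ens$members[[k]]$values
  }
  oracle <- oracle / 4
  expect_equal(avg$values, oracle, tolerance = 1e-15)

  # four identical fields average to themselves; 1,2,3,4 -> 2.5
  f <- tiny_field(matrix(7, 2, 2))
  same <- scenario_ensemble(lapply(list(c("CAMS", "FNL"), c("CAMS", "NAM"),
                                        c("QFED", "FNL"), c("QFED", "NAM")),
                                   function(l) tiny_field(matrix(7, 2, 2),
                                                          emissions = l[1],
                                                          meteorology = l[2])))
  expect_equal(ensemble_average(same)$values, f$values)
  vals <- list(1, 2, 3, 4)
  mixed <- scenario_ensemble(purrr::map2(
    vals, list(c("CAMS", "FNL"), c("CAMS", "NAM"),
               c("QFED", "FNL"), c("QFED", "NAM")),
    function(v, l) tiny_field(matrix(v, 2, 2), emissions = l[1],
                              meteorology = l[2])
  ))
  expect_equal(unique(as.vector(ensemble_average(mixed)$values)), 2.5)
})

test_that("ensemble_average lies between the member min and max cell-wise", {
  for (seed in 1:5) {
    ens <- random_ensemble(seed = seed)
    avg <- ensemble_average(ens)$values
    vals <- lapply(ens$members, `[[`, "values")
    lo <- pmin(vals[[1]], vals[[2]], vals[[3]], vals[[4]])
    hi <- pmax(vals[[1]], vals[[2]], vals[[3]], vals[[4]])
    expect_true(all(avg >= lo - 1e-12) && all(avg <= hi + 1e-12))
  }
})

test_that("incomplete factorials are rejected with the missing members named", {
  ens <- random_ensemble(seed = 3)
  ens$members[["QFED-NAM"]] <- NULL
  expect_error(ensemble_average(ens), "QFED-NAM",
               class = "smokewave_ensemble_error")
  expect_error(factor_uncertainty(ens, "emissions"), "QFED-NAM",
               class = "smokewave_ensemble_error")
  expect_false(is_complete_factorial(ens))
})

test_that("factor_uncertainty is zero for a degenerate ensemble", {
  f <- function(e, m) tiny_field(matrix(50, 3, 3), emissions = e,
                                 meteorology = m)
  ens <- scenario_ensemble(list(f("CAMS", "FNL"), f("CAMS", "NAM"),
                                f("QFED", "FNL"), f("QFED", "NAM")))
  for (fac in c("emissions", "meteorology")) {
    u <- factor_uncertainty(ens, fac)
    expect_true(all(u$absolute == 0))
    expect_true(all(u$relative == 0))
  }
})

test_that("additive ensembles recover the injected factor differences exactly", {
  ae <- additive_ensemble(seed = 4)
  ue <- factor_uncertainty(ae$ensemble, "emissions")
  um <- factor_uncertainty(ae$ensemble, "meteorology")
  expect_equal(unique(as.vector(ue$absolute)),
               ae$e[["QFED"]] - ae$e[["CAMS"]])
  expect_equal(unique(as.vector(um$absolute)),
               ae$m[["FNL"]] - ae$m[["NAM"]])

  # invariance to the other factor's injected difference
  ae2 <- additive_ensemble(seed = 4, m = c(FNL = 0, NAM = 30))
  ue2 <- factor_uncertainty(ae2$ensemble, "emissions")
  expect_equal(ue2$absolute, ue$absolute)
})

test_that("swapping a factor's two levels flips the sign of its field", {
  ens <- random_ensemble(seed = 9)
  u <- factor_uncertainty(ens, "emissions")
  swapped <- ens
  a <- swapped$members[["CAMS-FNL"]]$values
  swapped$members[["CAMS-FNL"]]$values <- swapped$members[["QFED-FNL"]]$values
  swapped$members[["QFED-FNL"]]$values <- a
  b <- swapped$members[["CAMS-NAM"]]$values
  swapped$members[["CAMS-NAM"]]$values <- swapped$members[["QFED-NAM"]]$values
  swapped$members[["QFED-NAM"]]$values <- b
  u_swapped <- factor_uncertainty(swapped, "emissions")
  expect_equal(u_swapped$absolute, -u$absolute, tolerance = 1e-15)
})

test_that("factor_uncertainty is linear in the ensemble", {
  e1 <- random_ensemble(seed = 21)
  e2 <- random_ensemble(seed = 22)
  mix <- e1
  for (k in names(mix$members)) {
    mix$members[[k]]$values <-
      0.3 * e1$members[[k]]$values + 0.7 * e2$members[[k]]$values
  }
  u_mix <- factor_uncertainty(mix, "meteorology")$absolute
  u_lin <- 0.3 * factor_uncertainty(e1, "meteorology")$absolute +
    0.7 * factor_uncertainty(e2, "meteorology")$absolute
  expect_equal(u_mix, u_lin, tolerance = 1e-12)
})

test_that("relative_change preserves sign and masks non-positive averages", {
  expect_equal(relative_change(0, 50), 0)
  expect_equal(relative_change(-10, 50), -20)
  expect_true(is.na(relative_change(5, 0)))
  expect_true(is.na(relative_change(5, 0.5, floor = 1)))
  u <- factor_uncertainty(random_ensemble(seed = 5), "emissions", floor = 1e9)
  expect_true(all(is.na(u$relative)))
})

test_that("round_half_up rounds ties away from zero at one decimal", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(1.04, 1), 1.0)
  expect_equal(round_half_up(c(15.88, 40.987), 1), c(15.9, 41.0))
})

test_that("episode_mean matches a loop-based oracle and handles edge cases", {
  set.seed(31)
  vals <- array(runif(3 * 4 * 5, 0, 80), c(3, 4, 5))
  days <- as.Date("2023-06-06") + 0:2
  f <- conc_field(vals, days = days)

  m <- episode_mean(f, days)
  oracle <- matrix(0, 4, 5)
  for (d in 1:3) oracle <- oracle + vals[d, , ]
  oracle <- oracle / 3
  expect_equal(m$values[1, , ], oracle, tolerance = 1e-15)

  one <- episode_mean(f, days[2])
  expect_equal(one$values[1, , ], vals[2, , ])

  cst <- conc_field(array(9, c(3, 2, 2)), days = days)
  expect_equal(unique(as.vector(episode_mean(cst)$values)), 9)

  expect_error(episode_mean(f, as.Date("2020-01-01")),
               class = "smokewave_field_error")
  expect_error(episode_mean(f, as.Date(character())),
               class = "smokewave_field_error")
})

test_that("uncertainty_report tabulates per-cell per-day values", {
  ens <- random_ensemble(seed = 6, n_days = 2)
  cells <- tibble::tibble(name = c("A", "B"), row = c(2, 4), col = c(3, 1))
  rep <- uncertainty_report(ens, cells)
  expect_equal(nrow(rep), 4)
  u <- factor_uncertainty(ens, "emissions")
  expect_equal(rep$emis_abs[rep$name == "A"], u$absolute[, 2, 3])
  expect_equal(rep$emis_rel,
               round_half_up(100 * rep$emis_abs / rep$average, 1))
})
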