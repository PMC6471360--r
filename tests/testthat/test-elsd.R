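test_that("power calibration round-trips exact power-law points", {
  x <- c(0.2, 0.4, 0.6, 0.8, 1.0) / 0.05
  fit <- fit_power_calibration(x, 0.4568 * x^1.4353)
  expect_equal(fit$a, 0.4568, tolerance = 1e-6 / 0.4568)
  expect_equal(fit$b, 1.4353, tolerance = 1e-6 / 1.4353)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # identity curve
  id <- fit_power_calibration(c(0.5, 1, 2), c(0.5, 1, 2))
  expect_equal(unname(coef(id)), c(1, 1), tolerance = 1e-12)
})

test_that("log-log fit matches the closed-form OLS oracle on noisy data", {
  set.seed(11)
  for (i in 1:10) {
    x <- exp(runif(8, -1, 3))
    y <- 0.7 * x^1.3 * exp(rnorm(8, sd = 0.05))
    fit <- fit_power_calibration(x, y)
    lx <- log(x); ly <- log(y)
    b_hat <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
    a_hat <- exp(mean(ly) - b_hat * mean(lx))
    expect_equal(fit$b, b_hat, tolerance = 1e-9)
    expect_equal(fit$a, a_hat, tolerance = 1e-9)
  }
})

test_that("direct nonlinear refinement reproduces exact coefficients", {
  x <- c(4, 8, 12, 16, 20)
  fit <- fit_power_calibration(x, 0.9241 * x^1.4759, method = "direct")
  expect_equal(fit$a, 0.9241, tolerance = 1e-6)
  expect_equal(fit$b, 1.4759, tolerance = 1e-6)
  expect_identical(fit$fit_scale, "direct")
})

test_that("calibration fitting validates its inputs", {
  expect_error(fit_power_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_calibration(c(1, 2, -3), c(1, 2, 3)),
               "strictly positive")
  expect_error(fit_power_calibration(c(1, 2, 3), c(1, 0, 3)),
               "strictly positive")
})

test_that("invert_calibration is the inverse map", {
  expect_equal(invert_calibration(power_calibration(1, 1), 0.5), 0.5)
  expect_equal(invert_calibration(power_calibration(0.4568, 1.4353), 0.4568),
               1.0, tolerance = 1e-12)
  expect_equal(invert_calibration(power_calibration(2, 1.7), 0), 0)
  expect_error(invert_calibration(power_calibration(1, 1), -0.1), ">= 0")
  set.seed(7)
  for (i in 1:25) {
    cv <- power_calibration(runif(1, 0.1, 500), runif(1, 0.8, 2))
    x <- runif(1, 0.01, 30)
    expect_equal(invert_calibration(cv, predict(cv, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("ttgs_mass implements the normalized mass equation", {
  cv <- power_calibration(0.4568, 1.4353)
  # area ratio equal to a -> concentration ratio 1 -> C_IS * m_LP / C_S
  obs <- flat_peak_table(0.4568 * 1000, "TTGS", is_area = 1000, m_lp = 120,
                         m_a = 150)
  expect_equal(ttgs_mass(obs, cv), 0.05 * 120 / 1 * 150 / 150,
               tolerance = 1e-12)
  # zero area -> zero mass
  expect_equal(ttgs_mass(obs, cv, area = 0), 0)
  # doubling m_a halves the normalized mass
  obs2 <- flat_peak_table(0.4568 * 1000, "TTGS", is_area = 1000, m_lp = 120,
                          m_a = 300)
  expect_equal(ttgs_mass(obs2, cv), ttgs_mass(obs, cv) / 2,
               tolerance = 1e-12)
})

test_that("lipolysis_rate handles degenerate and boundary inputs", {
  cv <- power_calibration(0.9241, 1.4759)
  obs0 <- flat_peak_table(c(500, 300), c("A", "B"), time_point = 0)
  # identical observations -> 0%
  obst <- flat_peak_table(c(500, 300), c("A", "B"), time_point = 30)
  expect_equal(as.numeric(lipolysis_rate(obs0, obst, cv)), 0,
               tolerance = 1e-12)
  # total area zero at t -> 100%
  gone <- flat_peak_table(c(0, 0), c("A", "B"), time_point = 30)
  expect_equal(as.numeric(lipolysis_rate(obs0, gone, cv)), 100)
  # time-0 table required first
  expect_error(lipolysis_rate(obst, obst, cv), "0-min")
  # larger area at t than 0 -> negative rate, flagged not clamped
  more <- flat_peak_table(c(800, 500), c("A", "B"), time_point = 30)
  expect_warning(r <- lipolysis_rate(obs0, more, cv), "outside")
  expect_lt(as.numeric(r), 0)
  expect_identical(attr(r, "quality"), "out_of_range")
})

test_that("zero-noise forward simulation recovers the designed total rates", {
  for (oil in c("SBO", "PGO", "PHY", "IO")) {
    cfg <- default_simulation_config(oil, seed = 5)
    tabs <- simulate_peak_tables(cfg)
    r <- lipolysis_rate(tabs$t0, tabs$tt, cfg$targets$TTGS$curve, "total")
    expect_equal(as.numeric(r), cfg$targets$TTGS$rate, tolerance = 1e-9,
                 label = sprintf("total rate (%s)", oil))
  }
})

test_that("per-species rates use each species' own exponent", {
  cfg <- default_simulation_config("PGO", seed = 5, level = "species")
  tabs <- simulate_peak_tables(cfg)
  curves <- lapply(cfg$targets, `[[`, "curve")
  rates <- species_lipolysis_rates(tabs$t0, tabs$tt, curves)
  for (sp in names(cfg$targets))
    expect_equal(rates[[sp]], cfg$targets[[sp]]$rate, tolerance = 1e-9)
  # with b = 1, halving one species' area at equal bookkeeping gives 50%
  b1 <- list(X = power_calibration(3, 1))
  obs0 <- flat_peak_table(c(400, 100), c("X", "Y"))
  obst <- flat_peak_table(c(200, 100), c("X", "Y"), time_point = 30)
  expect_equal(unname(species_lipolysis_rates(obs0, obst, b1, "X")), 50,
               tolerance = 1e-12)
  # all species unchanged -> all zero
  same <- species_lipolysis_rates(
    obs0, flat_peak_table(c(400, 100), c("X", "Y"), time_point = 30),
    list(X = power_calibration(3, 1.4), Y = power_calibration(1, 1.1)))
  expect_equal(unname(same), c(0, 0), tolerance = 1e-12)
})

test_that("species absent at time 0 are skipped; missing curves are fatal", {
  obs0 <- flat_peak_table(400, "X")
  obst <- flat_peak_table(c(200, 50), c("X", "Z"), time_point = 30)
  curves <- list(X = power_calibration(1, 1.4), Z = power_calibration(1, 1))
  expect_warning(r <- species_lipolysis_rates(obs0, obst, curves),
                 "missing at 0 min")
  expect_named(r, "X")
  expect_error(
    suppressWarnings(species_lipolysis_rates(
      obs0, obst, list(Z = power_calibration(1, 1)), species = "X")),
    "no calibration curve")
})

test_that("the coefficient a cancels from the rate", {
  set.seed(21)
  cfg <- default_simulation_config("PGO", seed = 21)
  tabs <- simulate_peak_tables(cfg)
  b <- cfg$targets$TTGS$curve$b
  ref <- as.numeric(lipolysis_rate(tabs$t0, tabs$tt,
                                   power_calibration(1, b), "total"))
  for (a in exp(runif(50, log(1e-3), log(1e3)))) {
    r <- as.numeric(lipolysis_rate(tabs$t0, tabs$tt,
                                   power_calibration(a, b), "total"))
    expect_equal(r, ref, tolerance = 1e-12)
  }
})

test_that("rates are invariant to rescaling all areas at one time point", {
  cfg <- default_simulation_config("SBO", seed = 9, level = "species")
  tabs <- simulate_peak_tables(cfg)
  curves <- lapply(cfg$targets, `[[`, "curve")
  ref <- species_lipolysis_rates(tabs$t0, tabs$tt, curves)
  scaled <- tabs$tt
  scaled$peaks$area <- scaled$peaks$area * 7.3
  scaled$is_area <- scaled$is_area * 7.3
  expect_equal(species_lipolysis_rates(tabs$t0, scaled, curves), ref,
               tolerance = 1e-12)
})

test_that("rate strictly increases as the t-min area decreases", {
  cv <- power_calibration(0.4568, 1.4353)
  obs0 <- flat_peak_table(600, "TTGS")
  areas <- seq(550, 50, by = -100)
  rates <- vapply(areas, function(a)
    as.numeric(lipolysis_rate(obs0,
                              flat_peak_table(a, "TTGS", time_point = 30),
                              cv)), 0)
  expect_true(all(diff(rates) > 0))
})

test_that("1% area noise keeps the mean absolute rate error within 1 point", {
  errs <- vapply(1:200, function(i) {
    cfg <- default_simulation_config("PGO", seed = 1000 + i, noise_cv = 0.01)
    tabs <- simulate_peak_tables(cfg)
    r <- suppressWarnings(
      lipolysis_rate(tabs$t0, tabs$tt, cfg$targets$TTGS$curve, "total"))
    abs(as.numeric(r) - cfg$targets$TTGS$rate)
  }, 0)
  expect_lte(mean(errs), 1)
})
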