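# Synthetic input generators: determinism, calibration, round trips.

test_that("casualty generator is deterministic and noise-free when asked", {
  cfg <- synth_config(seed = 11)
  a <- gen_casualty_series(cfg, "fatality")
  b <- gen_casualty_series(cfg, "fatality")
  expect_identical(a, b)
  other_seed <- gen_casualty_series(synth_config(seed = 12), "fatality")
  expect_false(isTRUE(all.equal(a$count, other_seed$count)))
  other_kind <- gen_casualty_series(cfg, "severe_injury")
  expect_false(isTRUE(all.equal(a$count / a$count[1],
                                other_kind$count / other_kind$count[1])))

  clean <- gen_casualty_series(synth_config(seed = 11, noise_cv = 0),
                               "fatality")
  expect_equal(clean$count, 63000 * 0.97^(0:9))
  expect_lt(max(abs(tidy(fit_gm11(clean))$relative_error)), 1e-9)
})

test_that("grey fit recovers the generating decay from a noisy draw", {
  cfg <- synth_config(seed = 42, casualty_base = c(fatality = 73000,
                                                   severe_injury = 210000),
                      annual_decay = 0.03, noise_cv = 0.01)
  fit <- fit_gm11(gen_casualty_series(cfg, "fatality"))
  expect_lt(abs(exp(-fit$a) - 0.97), 0.005)
})

test_that("fleet fixture is internally consistent and round-trips the stock", {
  cfg <- synth_config(seed = 3)
  fx <- gen_fleet_fixture(cfg)
  expect_true(all(diff(fx$survival$fraction) <= 0))
  expect_true(all(fx$survival$fraction >= 0 & fx$survival$fraction <= 1))
  expect_identical(nrow(fx$historical_sales), 18L)
  expect_identical(gen_fleet_fixture(cfg), fx)

  # forward stock-balance solve, then cohort reconstruction of the stock
  years <- 2019:2035
  gdp <- project_gdp(fx$gdp_growth_anchors, fx$pgdp_base_year,
                     fx$pgdp_base_value, years)
  stock <- tibble::tibble(
    year = years,
    stock = gompertz_ownership(gdp$pgdp, fx$vos, fx$alpha, fx$beta) *
      fx$population$persons[match(years, fx$population$year)] / 1000)
  nv <- sales_from_stock(stock, fx$historical_sales, fx$survival)
  all_sales <- dplyr::bind_rows(fx$historical_sales, nv)
  sr <- c(1, fx$survival$fraction)
  rebuilt <- vapply(years, function(y) {
    sum(vapply(0:18, function(t) {
      v <- all_sales$nv[all_sales$year == y - t]
      if (length(v) == 0) 0 else v * sr[t + 1]
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rebuilt, stock$stock, tolerance = 0.001)
  expect_true(all(nv$nv > 0))
})

test_that("condition log converges to its generating shares", {
  big <- gen_condition_log(synth_config(seed = 8, n_collisions = 1e6))
  ps <- speed_factor(big$distributions, "fatality")
  expect_equal(100 * ps, 63.0, tolerance = 0.5 / 63.0)
  small <- gen_condition_log(synth_config(seed = 8, n_collisions = 1000))
  ps_small <- speed_factor(small$distributions, "fatality")
  expect_lt(abs(ps_small - speed_factor(small$probs, "fatality")), 0.05)
  expect_identical(
    gen_condition_log(synth_config(seed = 8, n_collisions = 1000))$log,
    small$log)
  expect_error(gen_condition_log(synth_config(n_collisions = 10)),
               class = "aeb_validation_error")
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(annual_decay = 1.2), class = "aeb_validation_error")
  expect_error(synth_config(noise_cv = -1))
  expect_error(synth_config(n_years = 2))
})
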