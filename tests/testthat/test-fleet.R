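# Gompertz ownership, GDP projection, stock turnover, penetration.

test_that("Gompertz ownership has the right limits and monotonicity", {
  expect_equal(gompertz_ownership(1e9), 376, tolerance = 1e-6)
  expect_equal(gompertz_ownership(0), 376 * exp(-3.3546), tolerance = 1e-12)
  expect_equal(gompertz_ownership(0), 13.12, tolerance = 1e-3)
  expect_gte(gompertz_ownership(60000), gompertz_ownership(50000))
  pgdp <- seq(0, 1e5, length.out = 200)
  expect_true(all(diff(gompertz_ownership(pgdp)) >= 0))
  expect_true(all(gompertz_ownership(pgdp) <= 376))
})

test_that("two-point Gompertz fit round-trips its generating constants", {
  cases <- list(c(alpha = -3.3546, beta = -0.00013),
                c(alpha = -2, beta = -0.0002))
  for (cs in cases) {
    pts <- tibble::tibble(
      pgdp = c(9000, 12000),
      ownership = gompertz_ownership(c(9000, 12000), 376, cs["alpha"], cs["beta"]))
    fit <- fit_gompertz(pts, vos = 376)
    expect_equal(fit$alpha, unname(cs["alpha"]), tolerance = 1e-6)
    expect_equal(fit$beta, unname(cs["beta"]), tolerance = 1e-6)
  }
  bad <- tibble::tibble(pgdp = c(9000, 12000), ownership = c(100, 376))
  expect_error(fit_gompertz(bad), class = "aeb_domain_error")
})

test_that("GDP growth interpolates between anchors and compounds", {
  anchors <- tibble::tibble(year = c(2020, 2030), growth = c(0.06, 0.03))
  out <- project_gdp(anchors, 2020, 10000, 2020:2030)
  expect_equal(out$growth[out$year == 2025], 0.045)
  # hand compounding: growth 5.7% in 2021, 5.4% in 2022
  expect_equal(out$pgdp[out$year == 2022], 10000 * 1.057 * 1.054,
               tolerance = 1e-12)
  flat <- project_gdp(tibble::tibble(year = c(2020, 2030), growth = c(0, 0)),
                      2020, 10000, 2020:2030)
  expect_true(all(flat$pgdp == 10000))
  expect_error(project_gdp(anchors, 2020, 10000, 2020:2040),
               class = "aeb_extrapolation_error")
})

test_that("the policy schedule interpolates and clamps", {
  sched <- npr_schedule(c(2017, 2030, 2040))
  expect_equal(sched$npr, c(0.2, 1, 1))
  expect_equal(npr_schedule(2010)$npr, 0)
})

test_that("stock balance reduces to known closed forms", {
  hist <- tibble::tibble(year = 2001:2018, nv = rep(5, 18))
  stock1 <- tibble::tibble(year = 2019, stock = 200)
  # immediate retirement: sales replace the whole stock
  expect_equal(sales_from_stock(stock1, hist, flat_survival(0))$nv, 200)
  # no retirement for 18 years: sales are the stock increment over survivors
  expect_equal(sales_from_stock(stock1, hist, flat_survival(1))$nv, 200 - 18 * 5)
  # shrinking stock: floored at zero, with a warning
  big_hist <- tibble::tibble(year = 2001:2018, nv = rep(20, 18))
  expect_warning(
    out <- sales_from_stock(tibble::tibble(year = 2019, stock = 100),
                            big_hist, flat_survival(1)),
    "floored")
  expect_equal(out$nv, 0)
  expect_error(sales_from_stock(stock1, hist[-1, ], flat_survival(1)),
               class = "aeb_validation_error")
})

test_that("market penetration follows hand stock accounting", {
  surv <- tibble::tibble(age = 1:18, fraction = c(0.5, rep(0, 17)))
  sales <- tibble::tibble(year = c(2001, 2002), nv = c(100, 100))
  stock <- tibble::tibble(year = 2002, stock = 150)
  npr <- tibble::tibble(year = c(2001, 2002), npr = c(0, 1))
  pr <- market_penetration(sales, npr, surv, stock, 2002)
  expect_equal(pr$pr, 2 / 3)
  # no equipped sales ever -> zero penetration
  none <- market_penetration(sales, dplyr::mutate(npr, npr = 0), surv, stock, 2002)
  expect_equal(none$pr, 0)
  # everything equipped -> full penetration (clamped against rounding)
  all_on <- market_penetration(sales, dplyr::mutate(npr, npr = 1), surv, stock, 2002)
  expect_equal(all_on$pr, 1)
  expect_error(market_penetration(sales, npr, surv,
                                  tibble::tibble(year = 2002, stock = 0), 2002),
               class = "aeb_domain_error")
})

test_that("fixture-driven projection matches the published penetration shape", {
  fleet <- project_fleet(gen_fleet_fixture(synth_config(seed = 1)))
  expect_true(all(fleet$pr >= 0 & fleet$pr <= 1))
  expect_true(all(diff(fleet$pr) >= -1e-12))
  expect_true(all(diff(fleet$vo) >= 0))
  # loose neighbourhood of the published fleet-share trajectory
  expect_equal(fleet$pr[fleet$year == 2020], 0.104, tolerance = 0.05 / 0.104)
  expect_equal(fleet$pr[fleet$year == 2025], 0.340, tolerance = 0.05 / 0.340)
  expect_equal(fleet$pr[fleet$year == 2030], 0.603, tolerance = 0.05 / 0.603)
})
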