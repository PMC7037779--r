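# Scenario arithmetic, percent reductions, sensitivity, report assembly.

endpoint_inputs <- function() {
  list(
    cas = tibble::tibble(year = 2030,
                         kind = c("fatality", "severe_injury"),
                         casualties = c(47484, 143163)),
    pr = tibble::tibble(year = 2030, pr = 0.603)
  )
}

test_that("scenario multipliers follow their definitions", {
  fx <- endpoint_inputs()
  base <- run_scenario(fx$cas, fx$pr, scenario = "baseline")
  expect_true(all(base$avoided == 0))
  zero_pr <- run_scenario(fx$cas, dplyr::mutate(fx$pr, pr = 0),
                          scenario = "optimistic")
  expect_true(all(zero_pr$avoided == 0))
  opt <- run_scenario(fx$cas, fx$pr, scenario = "optimistic")
  pes <- run_scenario(fx$cas, fx$pr, scenario = "pessimistic")
  adj <- adjustment_factors()
  expect_equal(pes$avoided,
               opt$avoided * adj$combined[match(opt$kind, adj$kind)])
  expect_true(all(opt$avoided <= opt$casualties_no_aeb))
})

test_that("percent reductions are penetration times effectiveness", {
  fx <- endpoint_inputs()
  opt <- percent_reduction(run_scenario(fx$cas, fx$pr, scenario = "optimistic"))
  expect_equal(opt$pct[opt$kind == "fatality"], 7.98, tolerance = 0.011 / 7.98)
  expect_equal(opt$pct[opt$kind == "severe_injury"], 5.47,
               tolerance = 0.011 / 5.47)
  pes <- percent_reduction(run_scenario(fx$cas, fx$pr, scenario = "pessimistic"))
  expect_equal(pes$pct[pes$kind == "fatality"], 3.12, tolerance = 0.011 / 3.12)
  expect_equal(pes$pct[pes$kind == "severe_injury"], 2.72,
               tolerance = 0.011 / 2.72)
  # full penetration with no limiting factors hits the effectiveness ceiling
  ceiling <- run_scenario(fx$cas, dplyr::mutate(fx$pr, pr = 1),
                          scenario = "optimistic")
  ec <- aeb_effectiveness()
  expect_equal(ceiling$pct_reduction, abs(ec$ec[match(ceiling$kind, ec$kind)]))
})

test_that("factor overrides reproduce the single-factor sensitivity gains", {
  fx <- endpoint_inputs()
  pes <- run_scenario(fx$cas, fx$pr, scenario = "pessimistic")
  full_speed <- run_scenario(fx$cas, fx$pr, scenario = "pessimistic",
                             factor_overrides = list(ps = 1))
  gains <- sensitivity_single_factor(adjustment_factors(), "speed")
  expect_equal(full_speed$avoided / pes$avoided - 1,
               gains$gain[match(full_speed$kind, gains$kind)])
  expect_error(run_scenario(fx$cas, fx$pr, scenario = "pessimistic",
                            factor_overrides = list(banana = 1)),
               class = "aeb_validation_error")
})

test_that("sensitivity gains are 1/factor - 1 and multiply back to the ratio", {
  adj <- adjustment_factors()
  tab <- sensitivity_table(adj)
  expect_identical(nrow(tab), 8L)
  expect_equal(tab$gain, 1 / tab$value - 1)
  one <- sensitivity_single_factor(
    tibble::tibble(kind = "fatality", ps = 1, pw = 1, pl = 1, po = 1,
                   combined = 1), "speed")
  expect_equal(one$gain, 0)
  expect_error(sensitivity_single_factor(
    tibble::tibble(kind = "fatality", ps = 0, pw = 1, pl = 1, po = 1), "speed"),
    class = "aeb_domain_error")
  # joint relaxation of all four factors recovers the optimistic ratio
  for (kind in c("fatality", "severe_injury")) {
    sub <- tab[tab$kind == kind, ]
    expect_equal(prod(1 + sub$gain),
                 1 / adj$combined[adj$kind == kind])
  }
})

test_that("report assembly is deterministic and complete", {
  years <- 2018:2030
  cas <- tidyr::expand_grid(year = years,
                            kind = c("fatality", "severe_injury")) |>
    dplyr::mutate(casualties = 50000)
  pr <- tibble::tibble(year = years, pr = seq(0.05, 0.65, length.out = 13))
  opt <- run_scenario(cas, pr, scenario = "optimistic")
  pes <- run_scenario(cas, pr, scenario = "pessimistic")
  rep <- build_report(list(opt, pes), sensitivity_table())
  expect_identical(nrow(rep$scenarios), 52L)
  expect_identical(rep$scenarios$scenario[1], "optimistic")
  # identity: pessimistic = combined x optimistic, every year
  adj <- adjustment_factors()
  wide <- tidyr::pivot_wider(rep$scenarios,
                             id_cols = c("year", "kind"),
                             names_from = "scenario", values_from = "avoided")
  expect_equal(wide$pessimistic,
               wide$optimistic * adj$combined[match(wide$kind, adj$kind)])
  expect_error(build_report(list()), class = "aeb_validation_error")
  expect_error(run_scenario(cas, pr[-1, ], scenario = "optimistic"),
               class = "aeb_validation_error")
})
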