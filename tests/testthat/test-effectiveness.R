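# Collision-type proportions and mechanism composition.

test_that("packaged collision table reproduces the printed proportions", {
  tab <- china_collision_types()
  expect_identical(nrow(tab), 9L)
  expect_equal(attr(tab, "totals")[["fatalities"]], 63772)
  expect_equal(tab$prop_fatalities[tab$type == "rear_end"], 6111 / 63772)
  expect_equal(100 * tab$prop_fatalities[tab$type == "rear_end"], 9.58,
               tolerance = 0.01 / 9.58)
  expect_equal(100 * tab$prop_injuries[tab$type == "pedestrian_single_vehicle"],
               9.03, tolerance = 0.01 / 9.03)
})

test_that("table validation catches bad proportions and empty input", {
  raw <- readr::read_csv(system.file("extdata", "collision_types_cn2017.csv",
                                     package = "aebimpact"),
                         show_col_types = FALSE)
  raw$pct_fatalities[raw$type == "rear_end"] <- 11
  expect_error(collision_type_table(raw), "rear_end",
               class = "aeb_validation_error")
  expect_error(collision_type_table(raw[0, ]), class = "aeb_validation_error")
  neg <- raw |> dplyr::mutate(pct_fatalities = NULL,
                              fatalities = replace(fatalities, 1, -5))
  expect_error(collision_type_table(neg), class = "aeb_validation_error")
})

test_that("mechanism-1 weighting matches hand arithmetic", {
  m1 <- mechanism1_effect(china_collision_types(), effectiveness_spec(),
                          "fatality")
  # 0.1342*0.44 + 0.0299*0.44 + 0.0794*0.27 + 0.0958*0.43, as a reduction
  expect_equal(m1, -0.1348, tolerance = 0.0005 / 0.1348)
  zero_spec <- effectiveness_spec(
    dplyr::mutate(default_effectiveness_types(), ec_fat = 0, ec_inj = 0),
    ec_m3 = 0)
  expect_equal(mechanism1_effect(china_collision_types(), zero_spec, "fatality"), 0)
  # a single type holding all casualties, fully avoided
  solo <- collision_type_table(
    tibble::tibble(type = "rear_end", accidents = 10, fatalities = 10,
                   injuries = 10))
  solo_spec <- effectiveness_spec(
    tibble::tibble(type = "rear_end", ec_fat = -1, ec_inj = -1), ec_m3 = 0)
  expect_equal(mechanism1_effect(solo, solo_spec, "fatality"), -1)
  bad_spec <- effectiveness_spec(
    tibble::tibble(type = "hovercraft", ec_fat = -0.1, ec_inj = -0.1))
  expect_error(mechanism1_effect(china_collision_types(), bad_spec, "fatality"),
               "hovercraft", class = "aeb_validation_error")
})

test_that("mechanism composition is multiplicative with known identities", {
  expect_equal(combined_effect(0, 0), 0)
  m1 <- -0.134832
  expect_equal(1 + combined_effect(m1, 0.003), (1 + m1) * 1.003)
  # behavioural term switched off changes the composed value by exactly 1.003
  expect_equal((1 + combined_effect(m1, 0.003)) / (1 + combined_effect(m1, 0)),
               1.003)
})

test_that("effect magnitude is bounded and monotone in per-type effectiveness", {
  tab <- china_collision_types()
  set.seed(31)
  for (i in 1:10) {
    spec_tbl <- dplyr::mutate(default_effectiveness_types(),
                              ec_fat = -runif(4), ec_inj = -runif(4))
    ec_m3 <- runif(1, -0.01, 0.01)
    m1 <- mechanism1_effect(tab, effectiveness_spec(spec_tbl, ec_m3), "fatality")
    ec <- combined_effect(m1, ec_m3)
    bound <- sum(abs(spec_tbl$ec_fat) *
                   tab$prop_fatalities[match(spec_tbl$type, tab$type)]) +
      abs(ec_m3)
    expect_lte(abs(ec), bound + 1e-12)
    # deepening one type's effectiveness deepens the total effect
    deeper <- spec_tbl
    deeper$ec_fat[1] <- deeper$ec_fat[1] - 0.1
    m1_deeper <- mechanism1_effect(tab, effectiveness_spec(deeper, ec_m3),
                                   "fatality")
    expect_lt(combined_effect(m1_deeper, ec_m3), ec)
  }
})

test_that("full-penetration pipeline lands on the headline percentages", {
  ec <- aeb_effectiveness()
  expect_equal(ec$pct_reduction[ec$kind == "fatality"], 13.22,
               tolerance = 0.01 / 13.22)
  expect_equal(ec$pct_reduction[ec$kind == "severe_injury"], 9.07,
               tolerance = 0.01 / 9.07)
})
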