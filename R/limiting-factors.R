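#' Condition distributions of collisions (gear, light, weather)
#'
#' Validates the long-format distribution table underlying the technical
#' limiting factors: one row per `(block, category)` with the proportion of
#' fatalities and of severe injuries occurring in that category. Within each
#' block, each casualty kind's proportions must sum to 1 within 0.005
#' (printed columns carry rounding).
#'
#' @param data Data frame with columns `block` (`gear`, `light`, `weather`),
#'   `category`, `prop_fatalities`, `prop_injuries`.
#' @return A tibble of class `condition_distributions`.
#' @export
condition_distributions <- function(data) {
  check_columns(data, c("block", "category", "prop_fatalities", "prop_injuries"),
                "condition distributions")
  data <- as_tibble(data)
  check_fraction(data$prop_fatalities, "prop_fatalities")
  check_fraction(data$prop_injuries, "prop_injuries")
  for (b in unique(data$block)) {
    for (col in c("prop_fatalities", "prop_injuries")) {
      s <- sum(data[[col]][data$block == b])
      if (abs(s - 1) > 0.005) {
        abort(sprintf("%s proportions in block `%s` sum to %.4f, not 1 (tol 0.005)",
                      col, b, s),
              class = "aeb_validation_error")
      }
    }
  }
  structure(data, class = c("condition_distributions", class(data)))
}

#' Packaged 2017 Chinese gear/light/weather distributions
#'
#' The distribution of transmission gear, light condition and weather among
#' Chinese road-collision fatalities and severe injuries in 2017, as
#' distributed with the package.
#'
#' @return A validated [condition_distributions()] tibble.
#' @export
china_condition_distributions <- function() {
  path <- system.file("extdata", "condition_distributions_cn2017.csv",
                      package = "aebimpact", mustWork = TRUE)
  condition_distributions(readr::read_csv(path, show_col_types = FALSE))
}

prop_col_for <- function(kind) {
  if (match_kind(kind) == "fatality") "prop_fatalities" else "prop_injuries"
}

block_props <- function(dist, block, kind) {
  sub <- dist[dist$block == block, ]
  if (nrow(sub) == 0) {
    abort(sprintf("distribution block `%s` is missing", block),
          class = "aeb_validation_error")
  }
  setNames(sub[[prop_col_for(kind)]], sub$category)
}

#' Speed applicability factor PS
#'
#' AEB is taken to be effective only below 60 km/h, proxied by the engaged
#' transmission gear: among manual-transmission collisions with a known,
#' engaged gear, the share in gears 1-4 or reverse. Automatic-transmission,
#' unclear-gear, and neutral collisions are excluded from numerator and
#' denominator alike (speed unobservable there):
#' \deqn{PS = \frac{g_1 + g_2 + g_3 + g_4 + reverse}
#'                 {1 - automatic - unclear - neutral}.}
#'
#' @param dist A [condition_distributions()] table.
#' @param kind `"fatality"` or `"severe_injury"`.
#' @return Fraction in `(0, 1]`.
#' @export
speed_factor <- function(dist, kind = c("fatality", "severe_injury")) {
  g <- block_props(dist, "gear", kind)
  num <- sum(g[c("gear1", "gear2", "gear3", "gear4", "reverse")], na.rm = TRUE)
  den <- 1 - sum(g[c("automatic", "unclear", "neutral")], na.rm = TRUE)
  if (den <= 0) {
    abort("speed factor denominator non-positive: no manual in-gear collisions",
          class = "aeb_domain_error")
  }
  num / den
}

#' Light applicability factor PL
#'
#' Collisions on unlit roads at night are taken as outside AEB's sensing
#' envelope; everything else (day, lit night, dusk, dawn) counts:
#' `PL = 1 - night_unlit`.
#'
#' @inheritParams speed_factor
#' @return Fraction in `(0, 1]`.
#' @export
light_factor <- function(dist, kind = c("fatality", "severe_injury")) {
  l <- block_props(dist, "light", kind)
  1 - unname(l["night_unlit"] %||% 0)
}

#' Weather applicability factor PW
#'
#' Good weather means sunny or cloudy; rain, snow, fog and the rarer
#' categories are outside the operating envelope: `PW = sunny + cloudy`.
#'
#' @inheritParams speed_factor
#' @return Fraction in `(0, 1]`.
#' @export
weather_factor <- function(dist, kind = c("fatality", "severe_injury")) {
  w <- block_props(dist, "weather", kind)
  unname(sum(w[c("sunny", "cloudy")], na.rm = TRUE))
}

#' Combine limiting factors into a single adjustment
#'
#' The realistic-scenario multiplier is the product of the speed, weather,
#' light and activation factors. Each must lie in `(0, 1]`.
#'
#' @param ps,pw,pl Speed, weather, light factors.
#' @param po Activation rate: share of drivers with the system switched on
#'   (default 0.93, from field observation of forward-collision-warning/AEB
#'   usage).
#' @return A one-row tibble with columns `ps`, `pw`, `pl`, `po`, `combined`.
#' @export
combined_adjustment <- function(ps, pw, pl, po = 0.93) {
  for (nm in c("ps", "pw", "pl", "po")) {
    check_fraction(get(nm), nm, 0, 1, open_lower = TRUE)
  }
  tibble(ps = ps, pw = pw, pl = pl, po = po, combined = ps * pw * pl * po)
}

#' Limiting-factor adjustments for both casualty kinds
#'
#' Computes the speed, weather and light factors from a condition
#' distribution table for fatalities and severe injuries separately and
#' multiplies in the activation rate.
#'
#' @param dist A [condition_distributions()] table (defaults to the
#'   packaged 2017 Chinese table).
#' @param activation_rate Share of drivers with AEB switched on.
#' @return A tibble of class `adjustment_factors` with one row per kind and
#'   columns `kind`, `ps`, `pw`, `pl`, `po`, `combined`.
#' @examples
#' adjustment_factors()
#' @export
adjustment_factors <- function(dist = china_condition_distributions(),
                               activation_rate = 0.93) {
  out <- purrr::map_dfr(aeb_kinds(), function(kind) {
    combined_adjustment(ps = speed_factor(dist, kind),
                        pw = weather_factor(dist, kind),
                        pl = light_factor(dist, kind),
                        po = activation_rate) |>
      mutate(kind = kind, .before = 1)
  })
  structure(out, class = c("adjustment_factors", class(out)))
}
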