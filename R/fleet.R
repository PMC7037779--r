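#' Gompertz vehicle-ownership curve
#'
#' Country-level vehicle ownership per 1000 people as a saturating function
#' of per-capita GDP: \eqn{VO = VOS \exp(\alpha \exp(\beta \cdot PGDP))}.
#' With both constants negative the curve rises monotonically from
#' \eqn{VOS e^{\alpha}} at zero income toward the saturation level `vos`.
#'
#' @param pgdp Per-capita GDP (same currency unit the constants were fitted
#'   in); vectorised.
#' @param vos Saturation ownership per 1000 people (default 376, the China
#'   Society of Automotive Engineers projection).
#' @param alpha,beta Gompertz constants (defaults -3.3546 and -0.00013,
#'   fitted to 2017-2018 Chinese data).
#' @return Vehicles per 1000 people, same length as `pgdp`.
#' @export
gompertz_ownership <- function(pgdp, vos = 376, alpha = -3.3546, beta = -0.00013) {
  stopifnot(vos > 0)
  check_fraction(pgdp, "pgdp", lower = 0, upper = Inf)
  vos * exp(alpha * exp(beta * pgdp))
}

#' Fit Gompertz constants from two ownership observations
#'
#' Exact two-point solve via the double-log linearisation
#' \eqn{\ln(-\ln(VO/VOS)) = \ln(-\alpha) + \beta \cdot PGDP}.
#'
#' @param data A data frame with exactly two rows and columns `pgdp`
#'   (distinct values) and `ownership` (each in `(0, vos)`).
#' @param vos Saturation ownership per 1000 people.
#' @return A list with elements `alpha` and `beta`.
#' @examples
#' pts <- tibble::tibble(pgdp = c(9000, 10000),
#'                       ownership = gompertz_ownership(c(9000, 10000)))
#' fit_gompertz(pts)
#' @export
fit_gompertz <- function(data, vos = 376) {
  check_columns(data, c("pgdp", "ownership"), "gompertz observations")
  if (nrow(data) != 2 || data$pgdp[1] == data$pgdp[2]) {
    abort("fit_gompertz needs exactly two observations at distinct pgdp values",
          class = "aeb_validation_error")
  }
  if (any(data$ownership <= 0 | data$ownership >= vos)) {
    abort("ownership must lie strictly between 0 and the saturation level",
          class = "aeb_domain_error")
  }
  z <- log(-log(data$ownership / vos))
  beta <- (z[2] - z[1]) / (data$pgdp[2] - data$pgdp[1])
  alpha <- -exp(z[1] - beta * data$pgdp[1])
  list(alpha = alpha, beta = beta)
}

#' Project per-capita GDP from growth-rate anchors
#'
#' Annual growth rates are linearly interpolated between anchor years and
#' compounded multiplicatively from the base-year value: the projected
#' value for year `y` applies the interpolated growth rate of year `y`
#' itself to the previous year's value.
#'
#' @param anchors Data frame with columns `year` and `growth` (fractional
#'   annual growth rates at anchor years, sorted by year).
#' @param base_year,base_value Per-capita GDP level anchoring the
#'   projection.
#' @param years Calendar years to return (must lie in
#'   `base_year..max(anchors$year)`; growth anchors must cover every
#'   compounding year - no extrapolation).
#' @return A tibble with columns `year`, `growth`, `pgdp`.
#' @export
project_gdp <- function(anchors, base_year, base_value, years) {
  check_columns(anchors, c("year", "growth"), "growth anchors")
  stopifnot(base_value > 0)
  anchors <- dplyr::arrange(as_tibble(anchors), .data$year)
  span <- base_year:max(years)
  need <- span[-1]
  if (any(need < min(anchors$year)) || any(need > max(anchors$year)) ||
      any(years < base_year)) {
    abort(sprintf("growth anchors cover %d-%d; cannot extrapolate for %d-%d",
                  min(anchors$year), max(anchors$year), min(c(need, years)),
                  max(c(need, years))),
          class = "aeb_extrapolation_error")
  }
  growth <- c(NA_real_, approx(anchors$year, anchors$growth, xout = need)$y)
  pgdp <- base_value * cumprod(c(1, 1 + growth[-1]))
  tibble(year = span, growth = growth, pgdp = pgdp) |>
    filter(.data$year %in% years)
}

#' New-vehicle penetration schedule from policy anchors
#'
#' Piecewise-linear interpolation of the share of new vehicles equipped
#' with AEB through policy anchor years; clamped to the first anchor value
#' before the first anchor and to the last value afterwards. The default
#' anchors follow the Chinese intelligent-vehicle policy plan: 0% of new
#' vehicles in 2015, 50% in 2020, 80% in 2025, 100% in 2030.
#'
#' @param years Calendar years to evaluate.
#' @param anchors Data frame with columns `year` and `npr` (fractions in
#'   `[0,1]`).
#' @return A tibble with columns `year` and `npr`.
#' @export
npr_schedule <- function(years, anchors = npr_anchors_default()) {
  check_columns(anchors, c("year", "npr"), "npr anchors")
  check_fraction(anchors$npr, "npr")
  tibble(year = years,
         npr = approx(anchors$year, anchors$npr, xout = years, rule = 2)$y)
}

#' @rdname npr_schedule
#' @export
npr_anchors_default <- function() {
  tibble(year = c(2015, 2020, 2025, 2030), npr = c(0, 0.5, 0.8, 1))
}

# Survival fractions SR_1..SR_18 from a survival table (age, fraction).
survival_vector <- function(survival, max_age = 18) {
  check_columns(survival, c("age", "fraction"), "survival curve")
  check_fraction(survival$fraction, "survival fraction")
  if (any(diff(survival$fraction[order(survival$age)]) > 1e-12)) {
    abort("survival fractions must be non-increasing in age",
          class = "aeb_validation_error")
  }
  sr <- setNames(rep(0, max_age), seq_len(max_age))
  keep <- survival$age >= 1 & survival$age <= max_age
  sr[as.character(survival$age[keep])] <- survival$fraction[keep]
  unname(sr)
}

#' New-vehicle sales from a stock balance
#'
#' Solves the fleet stock-turnover balance year by year: sales in year `y`
#' equal the target total stock minus the vehicles surviving from the 18
#' previous sales cohorts, \eqn{NV_y = VO_y Pop_y / 1000 - \sum_{t=1}^{18}
#' SR_t NV_{y-t}}. A negative balance (stock shrinking faster than
#' retirements) is floored at zero with a warning.
#'
#' @param stock Data frame with columns `year` and `stock` (total vehicles
#'   in use) for consecutive projection years.
#' @param history Data frame with columns `year` and `nv`: sales for the 18
#'   years preceding the first projection year.
#' @param survival Data frame with columns `age` (1..18) and `fraction`.
#' @return A tibble with columns `year` and `nv` over the projection years.
#' @export
sales_from_stock <- function(stock, history, survival) {
  check_columns(stock, c("year", "stock"), "stock path")
  check_columns(history, c("year", "nv"), "sales history")
  sr <- survival_vector(survival)
  years <- sort(stock$year)
  need <- setdiff((min(years) - 18):(min(years) - 1), history$year)
  if (length(need) > 0) {
    abort(sprintf("sales history missing year(s): %s",
                  paste(need, collapse = ", ")),
          class = "aeb_validation_error")
  }
  nv <- setNames(history$nv, history$year)
  floored <- integer(0)
  for (y in years) {
    surv_stock <- sum(sr * vapply(1:18, function(t) {
      v <- nv[as.character(y - t)]
      if (is.na(v)) 0 else v
    }, numeric(1)))
    bal <- stock$stock[stock$year == y] - surv_stock
    if (bal < 0) {
      floored <- c(floored, y)
      bal <- 0
    }
    nv[as.character(y)] <- bal
  }
  if (length(floored) > 0) {
    warn(sprintf("stock balance negative in %s; sales floored at 0",
                 paste(floored, collapse = ", ")))
  }
  tibble(year = years, nv = unname(nv[as.character(years)]))
}

#' AEB fleet market penetration from surviving equipped cohorts
#'
#' The fleet share equipped with AEB in year `y` is the cumulative
#' surviving equipped stock over the total stock:
#' \eqn{PR_y = \sum_{t=0}^{18} NPR_{y-t} NV_{y-t} SR_t / (VO_y Pop_y /
#' 1000)}, with \eqn{SR_0 = 1}. Sale years missing from `sales` contribute
#' zero only if their scheduled new-vehicle penetration is zero; otherwise
#' an error names them. The result is clamped to `[0, 1]`.
#'
#' @param sales Data frame with columns `year` and `nv` covering every year
#'   that contributes surviving equipped vehicles.
#' @param npr Data frame with columns `year` and `npr` (see
#'   [npr_schedule()]); years absent from it take the schedule value 0.
#' @param survival Data frame with columns `age` and `fraction`.
#' @param stock Data frame with columns `year` and `stock`.
#' @param years Years at which to evaluate the penetration rate.
#' @return A tibble with columns `year` and `pr`.
#' @export
market_penetration <- function(sales, npr, survival, stock, years) {
  check_columns(sales, c("year", "nv"), "sales")
  check_columns(npr, c("year", "npr"), "npr schedule")
  check_columns(stock, c("year", "stock"), "stock path")
  sr <- c(1, survival_vector(survival))      # SR_0 = 1
  nv <- setNames(sales$nv, sales$year)
  np <- setNames(npr$npr, npr$year)
  pr <- vapply(years, function(y) {
    den <- stock$stock[stock$year == y]
    if (length(den) != 1 || is.na(den) || den <= 0) {
      abort(sprintf("total stock missing or non-positive in %d", y),
            class = "aeb_domain_error")
    }
    equipped <- sum(vapply(0:18, function(t) {
      p <- np[as.character(y - t)]
      if (is.na(p)) p <- 0
      v <- nv[as.character(y - t)]
      if (is.na(v)) {
        if (p > 0) {
          abort(sprintf("sales missing for contributing year %d", y - t),
                class = "aeb_validation_error")
        }
        v <- 0
      }
      p * v * sr[t + 1]
    }, numeric(1)))
    equipped / den
  }, numeric(1))
  tibble(year = years, pr = pmin(pmax(pr, 0), 1))
}

#' Project the AEB fleet over a span of years
#'
#' Chains the fleet sub-models: per-capita GDP from growth anchors, vehicle
#' ownership from the Gompertz curve, total stock from ownership and
#' population, new-vehicle sales from the stock balance, the policy
#' new-vehicle penetration schedule, and finally the fleet penetration rate
#' from surviving equipped cohorts.
#'
#' @param params Fleet parameters as produced by [gen_fleet_fixture()] or
#'   assembled by hand: a list with `vos`, `alpha`, `beta`, `pgdp_base_year`,
#'   `pgdp_base_value`, `gdp_growth_anchors` (year, growth), `population`
#'   (year, persons), `survival` (age, fraction), `historical_sales`
#'   (year, nv), and optionally `npr_anchors`.
#' @param years Years to report (default 2018-2030).
#' @return A tibble with columns `year`, `pgdp`, `vo` (per 1000 people),
#'   `population`, `stock`, `nv`, `npr`, `pr`.
#' @examples
#' fleet <- gen_fleet_fixture(synth_config(seed = 7))
#' project_fleet(fleet)
#' @export
project_fleet <- function(params, years = 2018:2030) {
  req <- c("vos", "alpha", "beta", "pgdp_base_year", "pgdp_base_value",
           "gdp_growth_anchors", "population", "survival", "historical_sales")
  missing <- setdiff(req, names(params))
  if (length(missing) > 0) {
    abort(sprintf("fleet params missing: %s", paste(missing, collapse = ", ")),
          class = "aeb_validation_error")
  }
  anchors <- params$npr_anchors %||% npr_anchors_default()

  gdp <- project_gdp(params$gdp_growth_anchors, params$pgdp_base_year,
                     params$pgdp_base_value, years)
  pop <- setNames(params$population$persons, params$population$year)
  if (anyNA(pop[as.character(years)])) {
    abort("population path does not cover the requested years",
          class = "aeb_validation_error")
  }
  fleet <- gdp |>
    mutate(
      vo = gompertz_ownership(.data$pgdp, params$vos, params$alpha, params$beta),
      population = unname(pop[as.character(.data$year)]),
      stock = .data$vo * .data$population / 1000
    )

  first_proj <- max(params$historical_sales$year) + 1
  proj_years <- years[years >= first_proj]
  sales <- params$historical_sales
  if (length(proj_years) > 0) {
    sales <- bind_rows(
      sales,
      sales_from_stock(fleet |> filter(.data$year %in% proj_years) |>
                         select("year", "stock"),
                       params$historical_sales, params$survival)
    )
  }
  sched <- npr_schedule(sort(unique(c(sales$year, years))), anchors)
  pr <- market_penetration(sales, sched, params$survival,
                           fleet |> select("year", "stock"), years)

  fleet |>
    left_join(sales, by = "year") |>
    left_join(sched, by = "year") |>
    left_join(pr, by = "year") |>
    select("year", "pgdp", "vo", "population", "stock", "nv", "npr", "pr")
}

#' @rdname project_fleet
#' @param object A fleet projection tibble from `project_fleet()`.
#' @param ... Unused.
#' @export
plot_penetration <- function(object, ...) {
  check_columns(object, c("year", "npr", "pr"), "fleet projection")
  long <- object |>
    select("year", "npr", "pr") |>
    tidyr::pivot_longer(c("npr", "pr"), names_to = "series", values_to = "share")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$share,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "year", y = "share of fleet / of new sales",
                  colour = NULL, title = "AEB penetration") +
    ggplot2::theme_minimal()
}
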