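#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the offline input generator. The defaults emulate
#' the study conditions the analysis assumes: a quasi-exponentially
#' declining national casualty series starting near 63,000 annual
#' fatalities and 210,000 severe injuries in 2008, declining 3% a year with
#' 1% multiplicative noise; a Gompertz ownership path with the published
#' constants; a population plateauing at 1.463 billion in 2030; a logistic
#' vehicle survival curve truncated at 18 years; and gear/light/weather
#' condition shares equal to the packaged 2017 Chinese distribution table.
#'
#' @param seed Integer seed; every generator draw is reproducible from it.
#' @param start_year First year of the casualty series.
#' @param n_years Length of the casualty series.
#' @param casualty_base Named vector: series value at `start_year` for
#'   `fatality` and `severe_injury`.
#' @param annual_decay Fractional annual decline of the noise-free trend.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise.
#' @param vos,alpha,beta Gompertz ownership parameters.
#' @param pgdp_base_year,pgdp_base_value Per-capita GDP anchor.
#' @param gdp_growth_anchors Data frame (`year`, `growth`) of annual GDP
#'   growth-rate anchors, linearly interpolated between.
#' @param pop_ceiling Population plateau (persons) reached at
#'   `pop_ceiling_year`.
#' @param pop_ceiling_year Year the population plateau is reached.
#' @param pop_gap Population shortfall below the ceiling 12 years before
#'   the plateau year.
#' @param survival_midpoint,survival_steepness Logistic survival-curve
#'   shape: `S(t) = 1/(1 + exp(steepness * (t - midpoint)))`, truncated at
#'   `survival_max_age`.
#' @param survival_max_age Maximum vehicle age (years).
#' @param history_growth Annual growth factor of the historical sales
#'   series.
#' @param history_noise_cv Multiplicative noise on historical sales.
#' @param condition_shares Generating probabilities for the condition log:
#'   a [condition_distributions()]-shaped data frame, or `NULL` for the
#'   packaged 2017 table.
#' @param n_collisions Sample size per casualty kind for the condition log.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         start_year = 2008,
                         n_years = 10,
                         casualty_base = c(fatality = 63000,
                                           severe_injury = 210000),
                         annual_decay = 0.03,
                         noise_cv = 0.01,
                         vos = 376,
                         alpha = -3.3546,
                         beta = -0.00013,
                         pgdp_base_year = 2018,
                         pgdp_base_value = 9770,
                         gdp_growth_anchors = tibble(
                           year = c(2018, 2020, 2030, 2040, 2050),
                           growth = c(0.066, 0.06, 0.03, 0.024, 0.02)),
                         pop_ceiling = 1.463e9,
                         pop_ceiling_year = 2030,
                         pop_gap = 70.2e6,
                         survival_midpoint = 16,
                         survival_steepness = 0.6,
                         survival_max_age = 18,
                         history_growth = 1.08,
                         history_noise_cv = 0.01,
                         condition_shares = NULL,
                         n_collisions = 100000) {
  stopifnot(seed == as.integer(seed))
  check_fraction(annual_decay, "annual_decay", 0, 1, TRUE, TRUE)
  stopifnot(noise_cv >= 0, n_years >= 4, all(casualty_base > 0))
  structure(as.list(environment()), class = "synth_config")
}

# Kind-specific substream so fatality and injury draws are independent.
kind_seed <- function(cfg, kind, salt = 0L) {
  (cfg$seed + 1009L * match(match_kind(kind), aeb_kinds()) + salt) %% .Machine$integer.max
}

#' Generate a synthetic annual casualty series
#'
#' Draws \eqn{x_k = base (1 - decay)^k (1 + \varepsilon_k)} with
#' \eqn{\varepsilon_k \sim N(0, cv^2)}, resampling any draw that would make
#' the count non-positive (grey modelling requires a positive series).
#'
#' @param cfg A [synth_config()].
#' @param kind `"fatality"` or `"severe_injury"`.
#' @return A casualty series tibble (`year`, `count`).
#' @examples
#' gen_casualty_series(synth_config(seed = 42), "fatality")
#' @export
gen_casualty_series <- function(cfg, kind = c("fatality", "severe_injury")) {
  kind <- match_kind(kind)
  base <- cfg$casualty_base[[kind]]
  k <- seq_len(cfg$n_years) - 1
  trend <- base * (1 - cfg$annual_decay)^k
  eps <- withr::with_seed(kind_seed(cfg, kind), {
    e <- stats::rnorm(cfg$n_years, 0, cfg$noise_cv)
    while (any(e <= -1)) {
      bad <- e <= -1
      e[bad] <- stats::rnorm(sum(bad), 0, cfg$noise_cv)
    }
    e
  })
  tibble(year = cfg$start_year + k, count = trend * (1 + eps))
}

# Logistic survival curve, truncated at max_age.
synth_survival <- function(cfg) {
  age <- seq_len(cfg$survival_max_age)
  tibble(age = age,
         fraction = 1 / (1 + exp(cfg$survival_steepness *
                                   (age - cfg$survival_midpoint))))
}

# Population path: rises to the ceiling at the plateau year, flat after.
synth_population <- function(cfg, years) {
  horizon <- cfg$pop_ceiling_year
  persons <- ifelse(
    years >= horizon, cfg$pop_ceiling,
    cfg$pop_ceiling - cfg$pop_gap * ((horizon - years) / 12)^1.3)
  tibble(year = years, persons = persons)
}

#' Generate a synthetic fleet-parameter fixture
#'
#' Builds a complete, internally consistent set of fleet inputs: the
#' Gompertz ownership constants, a compounding GDP path, a plateauing
#' population, the logistic survival curve, and an 18-year historical sales
#' series scaled so the stock-balance equation continues smoothly into the
#' projection (first projected sales approximately extend the historical
#' growth). If the stock balance would still go negative, progressively
#' flatter history ramps are tried, with a warning.
#'
#' @param cfg A [synth_config()].
#' @param projection_start First projected sales year (history covers the
#'   18 preceding years).
#' @return A fleet-parameter list accepted by [project_fleet()].
#' @export
gen_fleet_fixture <- function(cfg, projection_start = 2019) {
  years <- cfg$pgdp_base_year:2050
  gdp <- project_gdp(cfg$gdp_growth_anchors, cfg$pgdp_base_year,
                     cfg$pgdp_base_value, years)
  pop <- synth_population(cfg, years)
  stock <- tibble(
    year = years,
    stock = gompertz_ownership(gdp$pgdp, cfg$vos, cfg$alpha, cfg$beta) *
      pop$persons / 1000
  )
  survival <- synth_survival(cfg)
  sr <- survival$fraction
  s_first <- stock$stock[stock$year == projection_start]

  jitter <- withr::with_seed(cfg$seed, {
    e <- stats::rnorm(cfg$survival_max_age, 0, cfg$history_noise_cv)
    pmax(1 + e, 0.5)
  })
  hist_years <- (projection_start - cfg$survival_max_age):(projection_start - 1)
  history <- NULL
  for (g in c(cfg$history_growth, 1.04, 1.0)) {
    A <- sum(sr * g^(-(seq_along(sr) - 1)))
    h_last <- s_first / (A + g)
    cand <- tibble(year = hist_years,
                   nv = h_last * g^(hist_years - max(hist_years)) * jitter)
    proj <- stock |> filter(.data$year >= projection_start)
    nv <- withCallingHandlers(
      sales_from_stock(proj, cand, survival),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (all(nv$nv > 0)) {
      history <- cand
      if (g != cfg$history_growth) {
        warn(sprintf("history ramp flattened to %.2f to keep the stock balance feasible", g))
      }
      break
    }
  }
  if (is.null(history)) {
    warn("stock balance infeasible for all history ramps; using flat history with floored sales")
    history <- tibble(year = hist_years, nv = s_first / (sum(sr) + 1) * jitter)
  }

  list(
    vos = cfg$vos, alpha = cfg$alpha, beta = cfg$beta,
    pgdp_base_year = cfg$pgdp_base_year,
    pgdp_base_value = cfg$pgdp_base_value,
    gdp_growth_anchors = cfg$gdp_growth_anchors,
    population = pop,
    survival = survival,
    historical_sales = history,
    npr_anchors = npr_anchors_default()
  )
}

#' Generate a synthetic collision condition log
#'
#' Draws `n_collisions` casualty records per kind, each with a gear, light
#' and weather category sampled independently from the generating shares,
#' and returns both the raw log and the empirical distribution table it
#' implies.
#'
#' @param cfg A [synth_config()]; `cfg$condition_shares` supplies the
#'   generating probabilities (`NULL` means the packaged 2017 Chinese
#'   table).
#' @return A list with elements `log` (tibble: `kind`, `gear`, `light`,
#'   `weather`), `distributions` (empirical [condition_distributions()]),
#'   and `probs` (the generating table).
#' @export
gen_condition_log <- function(cfg) {
  if (cfg$n_collisions < 1000) {
    abort("n_collisions must be at least 1000", class = "aeb_validation_error")
  }
  probs <- cfg$condition_shares
  if (is.null(probs)) probs <- china_condition_distributions()
  check_columns(probs, c("block", "category", "prop_fatalities", "prop_injuries"),
                "condition shares")

  draw_kind <- function(kind) {
    col <- prop_col_for(kind)
    withr::with_seed(kind_seed(cfg, kind, salt = 7L), {
      cols <- lapply(c("gear", "light", "weather"), function(b) {
        sub <- probs[probs$block == b, ]
        sample(sub$category, cfg$n_collisions, replace = TRUE,
               prob = sub[[col]] / sum(sub[[col]]))
      })
      tibble(kind = kind, gear = cols[[1]], light = cols[[2]],
             weather = cols[[3]])
    })
  }
  log <- bind_rows(lapply(aeb_kinds(), draw_kind))

  emp <- purrr::map_dfr(c("gear", "light", "weather"), function(b) {
    purrr::map_dfr(split(log, log$kind), function(sub) {
      tab <- table(factor(sub[[b]],
                          levels = probs$category[probs$block == b]))
      tibble(block = b, category = names(tab), kind = sub$kind[1],
             prop = as.numeric(tab) / nrow(sub))
    })
  }) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "prop") |>
    dplyr::rename(prop_fatalities = "fatality",
                  prop_injuries = "severe_injury")

  list(log = log, distributions = condition_distributions(emp), probs = probs)
}
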