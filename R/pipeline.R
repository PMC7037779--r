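#' Run the full AEB safety-impact study
#'
#' End-to-end pipeline: Grey-Markov forecast of fatalities and severe
#' injuries to the horizon year, fleet penetration projection, the
#' full-penetration effectiveness from the collision-type table, the
#' limiting-factor adjustment from the condition distributions, the three
#' scenarios (baseline, optimistic, pessimistic) over the forecast span,
#' and the single-factor sensitivity decomposition.
#'
#' @param casualties Wide annual casualty table (`year`, `fatalities`,
#'   `severe_injuries`). Defaults to a synthetic series emulating the
#'   2008-2017 national statistics.
#' @param fleet_params Fleet-parameter list for [project_fleet()]; defaults
#'   to the synthetic fixture.
#' @param collision_table A [collision_type_table()]; defaults to the
#'   packaged 2017 Chinese table.
#' @param conditions A [condition_distributions()] table; defaults to the
#'   packaged 2017 Chinese table.
#' @param effectiveness An [effectiveness_spec()].
#' @param activation_rate Share of drivers with AEB switched on.
#' @param npr_anchors Policy anchors for the new-vehicle penetration
#'   schedule.
#' @param horizon_year Final forecast year (default 2030).
#' @param n_states Markov residual states for the forecast.
#' @param synth A [synth_config()] used when `casualties` or `fleet_params`
#'   are left `NULL`.
#' @return An object of class `aeb_study`: list with `report` (an
#'   [build_report()] object), `forecasts` (per-kind
#'   `grey_markov_forecast`s), `fleet` (projection tibble),
#'   `effectiveness`, `adjustment`, and `years` (the scenario span).
#' @examples
#' study <- run_aeb_study(synth = synth_config(seed = 3))
#' study$report
#' @export
run_aeb_study <- function(casualties = NULL,
                          fleet_params = NULL,
                          collision_table = china_collision_types(),
                          conditions = china_condition_distributions(),
                          effectiveness = effectiveness_spec(),
                          activation_rate = 0.93,
                          npr_anchors = npr_anchors_default(),
                          horizon_year = 2030,
                          n_states = 3,
                          synth = synth_config()) {
  if (is.null(casualties)) {
    fat <- gen_casualty_series(synth, "fatality")
    inj <- gen_casualty_series(synth, "severe_injury")
    casualties <- tibble(year = fat$year, fatalities = fat$count,
                         severe_injuries = inj$count)
  }
  if (is.null(fleet_params)) fleet_params <- gen_fleet_fixture(synth)
  check_columns(casualties, c("year", "fatalities", "severe_injuries"),
                "casualty table")
  last_obs <- max(casualties$year)
  if (horizon_year <= last_obs) {
    abort(sprintf("horizon year %d does not extend the observed span (ends %d)",
                  horizon_year, last_obs),
          class = "aeb_validation_error")
  }
  years <- (last_obs + 1):horizon_year

  forecasts <- lapply(setNames(aeb_kinds(), aeb_kinds()), function(kind) {
    forecast_grey_markov(casualty_series(casualties, kind),
                         horizon = horizon_year - last_obs,
                         n_states = n_states)
  })
  cn <- purrr::imap_dfr(forecasts, function(fc, kind) {
    fc$table |>
      filter(.data$type == "forecast") |>
      dplyr::transmute(year = .data$year, kind = kind,
                       casualties = .data$value)
  })

  fleet <- project_fleet(fleet_params, years = years)
  ec <- aeb_effectiveness(collision_table, effectiveness)
  adj <- adjustment_factors(conditions, activation_rate)
  pr <- fleet |> select("year", "pr")

  scenarios <- lapply(c("baseline", "optimistic", "pessimistic"),
                      function(sc) run_scenario(cn, pr, ec, adj, sc))
  report <- build_report(scenarios, sensitivity_table(adj))

  structure(
    list(report = report, forecasts = forecasts, fleet = fleet,
         effectiveness = ec, adjustment = adj, years = years),
    class = "aeb_study"
  )
}

#' @export
print.aeb_study <- function(x, ...) {
  cat(sprintf("AEB safety-impact study, %d-%d\n",
              min(x$years), max(x$years)))
  cat(sprintf("  full-penetration reduction: fatalities %.2f%%, injuries %.2f%%\n",
              x$effectiveness$pct_reduction[x$effectiveness$kind == "fatality"],
              x$effectiveness$pct_reduction[x$effectiveness$kind == "severe_injury"]))
  cat(sprintf("  fleet penetration at %d: %.1f%%\n", max(x$years),
              100 * x$fleet$pr[x$fleet$year == max(x$years)]))
  print(x$report)
  invisible(x)
}

#' Write every report table of a study to a directory
#'
#' Emits `forecast_fatality.csv`, `forecast_severe_injury.csv`,
#' `fleet.csv`, `effectiveness.csv`, `adjustment.csv`, `scenarios.csv`,
#' and `sensitivity.csv`. Avoided-casualty counts are rounded half-up to
#' integers at this point only.
#'
#' @param study An [run_aeb_study()] result.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in aeb_kinds()) {
    write_forecast_csv(study$forecasts[[kind]],
                       file.path(dir, sprintf("forecast_%s.csv", kind)))
  }
  write_fleet_csv(study$fleet, file.path(dir, "fleet.csv"))
  readr::write_csv(study$effectiveness, file.path(dir, "effectiveness.csv"))
  readr::write_csv(as_tibble(study$adjustment), file.path(dir, "adjustment.csv"))
  readr::write_csv(
    study$report$scenarios |>
      mutate(avoided = round_half_up(.data$avoided)),
    file.path(dir, "scenarios.csv"))
  readr::write_csv(study$report$sensitivity, file.path(dir, "sensitivity.csv"))
  invisible(dir)
}
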