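#' Run an AEB impact scenario
#'
#' Combines the no-AEB casualty forecast, the fleet penetration path, the
#' full-penetration effectiveness and the limiting-factor adjustment into
#' per-year avoided casualties:
#' \deqn{SI_y = CN_y \cdot |EC| \cdot PR_y \cdot (PS \cdot PW \cdot PL
#' \cdot PO)}
#' where the bracketed product applies only in the pessimistic (realistic)
#' scenario, is replaced by 1 in the optimistic scenario, and the whole
#' AEB effect is switched off in the baseline scenario.
#'
#' @param casualties No-AEB forecast: data frame with columns `year`,
#'   `kind`, `casualties` (e.g. assembled from [forecast_grey_markov()]
#'   results).
#' @param penetration Data frame with columns `year` and `pr` covering
#'   every forecast year.
#' @param effectiveness Output of [aeb_effectiveness()] (columns `kind`,
#'   `ec`).
#' @param adjustment Output of [adjustment_factors()] (columns `kind`,
#'   `ps`, `pw`, `pl`, `po`, `combined`); used by the pessimistic scenario.
#' @param scenario `"baseline"`, `"optimistic"`, or `"pessimistic"`.
#' @param factor_overrides Optional named list overriding individual
#'   factors (`ps`, `pw`, `pl`, `po`) in the pessimistic scenario, e.g.
#'   `list(ps = 1)` to model full-speed-range applicability; the combined
#'   product is recomputed.
#' @return A tibble of class `scenario_result` with columns `scenario`,
#'   `year`, `kind`, `casualties_no_aeb`, `avoided`, `pct_reduction`
#'   (fraction avoided of the no-AEB forecast).
#' @examples
#' cas <- tibble::tibble(year = 2030, kind = c("fatality", "severe_injury"),
#'                       casualties = c(47484, 143163))
#' pr <- tibble::tibble(year = 2030, pr = 0.603)
#' run_scenario(cas, pr, scenario = "optimistic")
#' @export
run_scenario <- function(casualties, penetration,
                         effectiveness = aeb_effectiveness(),
                         adjustment = adjustment_factors(),
                         scenario = c("baseline", "optimistic", "pessimistic"),
                         factor_overrides = NULL) {
  scenario <- match.arg(scenario)
  check_columns(casualties, c("year", "kind", "casualties"), "casualty forecast")
  check_columns(penetration, c("year", "pr"), "penetration path")
  check_columns(effectiveness, c("kind", "ec"), "effectiveness")
  missing_years <- setdiff(unique(casualties$year), penetration$year)
  if (length(missing_years) > 0) {
    abort(sprintf("penetration path missing forecast year(s): %s",
                  paste(sort(missing_years), collapse = ", ")),
          class = "aeb_validation_error")
  }

  adj <- as_tibble(adjustment)
  if (!is.null(factor_overrides)) {
    bad <- setdiff(names(factor_overrides), c("ps", "pw", "pl", "po"))
    if (length(bad) > 0) {
      abort(sprintf("unknown factor override(s): %s", paste(bad, collapse = ", ")),
            class = "aeb_validation_error")
    }
    for (nm in names(factor_overrides)) {
      check_fraction(factor_overrides[[nm]], nm, 0, 1, open_lower = TRUE)
      adj[[nm]] <- factor_overrides[[nm]]
    }
    adj$combined <- adj$ps * adj$pw * adj$pl * adj$po
  }

  out <- casualties |>
    as_tibble() |>
    left_join(penetration, by = "year") |>
    left_join(effectiveness |> select("kind", "ec"), by = "kind") |>
    left_join(adj |> select("kind", "combined"), by = "kind") |>
    mutate(
      multiplier = switch(scenario,
                          baseline = 0,
                          optimistic = 1,
                          pessimistic = .data$combined),
      avoided = .data$casualties * abs(.data$ec) * .data$pr * .data$multiplier,
      pct_reduction = abs(.data$ec) * .data$pr * .data$multiplier,
      scenario = scenario
    ) |>
    select("scenario", "year", "kind",
           casualties_no_aeb = "casualties", "avoided", "pct_reduction") |>
    arrange(.data$kind, .data$year)
  structure(out, class = c("scenario_result", class(out)))
}

#' Percentage casualty reduction of a scenario
#'
#' The percent reduction is algebraically independent of the casualty
#' forecast: \eqn{|EC| \cdot PR_y} in the optimistic scenario, additionally
#' times the combined adjustment in the pessimistic one.
#'
#' @param result A [run_scenario()] result.
#' @return A tibble with columns `year`, `kind`, `pct` (percent).
#' @export
percent_reduction <- function(result) {
  check_columns(result, c("year", "kind", "pct_reduction"), "scenario result")
  result |>
    as_tibble() |>
    dplyr::transmute(year = .data$year, kind = .data$kind,
                     pct = 100 * .data$pct_reduction)
}

#' Single-factor sensitivity of the realistic scenario
#'
#' Relative gain in avoided casualties from lifting one limiting factor to
#' 1 while the others stay at their computed values: because the factors
#' enter multiplicatively, the gain is `1/factor - 1`, per casualty kind.
#'
#' @param adjustment An [adjustment_factors()] tibble.
#' @param factor One of `"speed"`, `"light"`, `"weather"`, `"activation"`.
#' @return A tibble with columns `factor`, `kind`, `value` (the factor),
#'   `gain` (fractional uplift).
#' @examples
#' sensitivity_single_factor(adjustment_factors(), "speed")
#' @export
sensitivity_single_factor <- function(adjustment,
                                      factor = c("speed", "light", "weather",
                                                 "activation")) {
  factor <- match.arg(factor)
  col <- c(speed = "ps", light = "pl", weather = "pw", activation = "po")[[factor]]
  check_columns(adjustment, c("kind", col), "adjustment factors")
  value <- adjustment[[col]]
  if (any(value <= 0)) {
    abort("cannot compute sensitivity for a zero factor",
          class = "aeb_domain_error")
  }
  tibble(factor = factor, kind = adjustment$kind, value = value,
         gain = 1 / value - 1)
}

#' @rdname sensitivity_single_factor
#' @export
sensitivity_table <- function(adjustment = adjustment_factors()) {
  purrr::map_dfr(c("speed", "light", "weather", "activation"),
                 function(f) sensitivity_single_factor(adjustment, f))
}

#' Assemble the scenario and sensitivity report
#'
#' Binds scenario results into one tidy table (deterministic row order:
#' scenario, then casualty kind, then year) and attaches the single-factor
#' sensitivity table.
#'
#' @param scenarios A non-empty list of [run_scenario()] results.
#' @param sensitivities A sensitivity table from [sensitivity_table()]
#'   (optional).
#' @return An object of class `aeb_report`: list with elements `scenarios`
#'   and `sensitivity`.
#' @export
build_report <- function(scenarios, sensitivities = NULL) {
  if (length(scenarios) == 0) {
    abort("no scenarios supplied", class = "aeb_validation_error")
  }
  tbl <- bind_rows(lapply(scenarios, as_tibble)) |>
    arrange(factor(.data$scenario,
                   levels = c("baseline", "optimistic", "pessimistic")),
            .data$kind, .data$year)
  structure(list(scenarios = tbl, sensitivity = sensitivities),
            class = "aeb_report")
}

#' @export
print.aeb_report <- function(x, ...) {
  cat("AEB safety-impact report\n")
  last <- x$scenarios |>
    group_by(.data$scenario, .data$kind) |>
    filter(.data$year == max(.data$year)) |>
    ungroup() |>
    mutate(avoided = round_half_up(.data$avoided),
           pct = sprintf("%.2f%%", 100 * .data$pct_reduction))
  cat(sprintf("  final year (%d) avoided casualties:\n", max(last$year)))
  for (i in seq_len(nrow(last))) {
    cat(sprintf("    %-11s %-13s %8s  (%s of no-AEB forecast)\n",
                last$scenario[i], last$kind[i],
                format(last$avoided[i], big.mark = ","), last$pct[i]))
  }
  if (!is.null(x$sensitivity)) {
    cat("  single-factor uplifts (pessimistic scenario):\n")
    s <- x$sensitivity
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-10s %-13s +%.1f%%\n", s$factor[i], s$kind[i],
                  100 * s$gain[i]))
    }
  }
  invisible(x)
}

#' @rdname build_report
#' @param object An `aeb_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.aeb_report <- function(object, ...) {
  ggplot2::ggplot(object$scenarios,
                  ggplot2::aes(.data$year, .data$avoided,
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_y") +
    ggplot2::labs(x = "year", y = "avoided casualties", colour = NULL,
                  title = "Avoided casualties by scenario") +
    ggplot2::theme_minimal()
}
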