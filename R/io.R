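#' Read a validated CSV table
#'
#' Thin wrapper over [readr::read_csv()] that enforces a header schema and
#' numeric columns, strips thousands separators defensively ("55,686"
#' style), and reports validation failures with row/column coordinates.
#'
#' @param path CSV file path (UTF-8, comma separated, `.` decimal).
#' @param columns Character vector of required column names.
#' @param numeric_columns Columns that must parse as numbers (default: all
#'   required columns except obviously categorical ones is up to the
#'   caller; pass explicitly).
#' @return A tibble with the required columns.
#' @export
read_table_csv <- function(path, columns, numeric_columns = columns) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "aeb_validation_error")
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) {
      abort(sprintf("cannot read %s: %s", path, conditionMessage(e)),
            class = "aeb_validation_error")
    })
  if (nrow(data) == 0) {
    abort(sprintf("%s contains no data rows", path),
          class = "aeb_validation_error")
  }
  check_columns(data, columns, path)
  for (col in intersect(numeric_columns, names(data))) {
    raw <- gsub(",", "", data[[col]], fixed = TRUE)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "")
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric value `%s` at row %d, column `%s`",
                    path, raw[bad[1]], bad[1], col),
            class = "aeb_validation_error")
    }
    data[[col]] <- val
  }
  data
}

#' Read an annual casualty CSV
#'
#' Expects columns `year`, `fatalities`, `severe_injuries`.
#'
#' @param path CSV file path.
#' @return A tibble with those three numeric columns.
#' @export
read_casualty_csv <- function(path) {
  read_table_csv(path, c("year", "fatalities", "severe_injuries"))
}

#' Extract one kind's series from a wide casualty table
#'
#' @param data Wide table with columns `year`, `fatalities`,
#'   `severe_injuries`.
#' @param kind `"fatality"` or `"severe_injury"`.
#' @return A casualty series tibble (`year`, `count`).
#' @export
casualty_series <- function(data, kind = c("fatality", "severe_injury")) {
  kind <- match_kind(kind)
  check_columns(data, c("year", "fatalities", "severe_injuries"),
                "casualty table")
  col <- if (kind == "fatality") "fatalities" else "severe_injuries"
  validate_casualty_series(tibble(year = data$year, count = data[[col]]))
}

#' Write a Grey-Markov forecast to CSV
#'
#' Columns `year`, `fitted`, `forecast`, `relative_error`; fitted and
#' forecast values occupy disjoint year ranges.
#'
#' @param forecast A [forecast_grey_markov()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_forecast_csv <- function(forecast, path) {
  tbl <- forecast$table |>
    mutate(fitted = ifelse(.data$type == "fitted", .data$value, NA_real_),
           forecast = ifelse(.data$type == "forecast", .data$value, NA_real_)) |>
    select("year", "fitted", "forecast", "relative_error")
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Write a fleet projection to CSV
#'
#' Columns `year`, `vo`, `nv`, `npr`, `pr`.
#'
#' @param fleet A [project_fleet()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fleet_csv <- function(fleet, path) {
  readr::write_csv(fleet |> select("year", "vo", "nv", "npr", "pr"), path)
  invisible(path)
}

#' Default run configuration
#'
#' The packaged parameterization: 3 Markov states, horizon 2030, the
#' literature effectiveness constants, mechanism-3 +0.3%, activation rate
#' 0.93, and the policy new-vehicle penetration anchors. File paths are
#' unset; the packaged tables and the synthetic fleet fixture stand in.
#'
#' @return A nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    forecast = list(n_states = 3, horizon_year = 2030),
    activation_rate = 0.93,
    ec_m3 = 0.003,
    effectiveness = list(
      pedestrian_single_vehicle = list(ec_fat = -0.44, ec_inj = -0.33),
      obstacle_single_vehicle = list(ec_fat = -0.44, ec_inj = -0.33),
      rear_end = list(ec_fat = -0.43, ec_inj = -0.43),
      head_on = list(ec_fat = -0.27, ec_inj = -0.27)
    ),
    npr_anchors = list(year = c(2015, 2020, 2025, 2030),
                       npr = c(0, 0.5, 0.8, 1)),
    fleet = list(vos = 376, alpha = -3.3546, beta = -0.00013,
                 pgdp_base_year = 2018, pgdp_base_value = 9770,
                 gdp_growth_anchors = list(
                   year = c(2018, 2020, 2030, 2040, 2050),
                   growth = c(0.066, 0.06, 0.03, 0.024, 0.02))),
    files = list(casualties = NULL, collision_table = NULL,
                 conditions = NULL, population = NULL, survival = NULL,
                 historical_sales = NULL),
    scenario = "all",
    out_dir = NULL
  )
}

merge_config <- function(base, override, path = character(0)) {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key: %s",
                    paste(c(path, key), collapse = ".")),
            class = "aeb_validation_error")
    }
    if (is.list(base[[key]]) && is.list(override[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
      message(sprintf("config: %s overridden",
                      paste(c(path, key), collapse = ".")))
    }
  }
  base
}

#' Load a layered run configuration
#'
#' Layering order: packaged defaults, then an optional YAML file, then
#' programmatic overrides (e.g. parsed CLI flags) - later layers win, and
#' each overridden key is logged. Unknown keys are rejected.
#'
#' @param file Optional YAML configuration file.
#' @param overrides Optional named list applied last.
#' @return The merged configuration list.
#' @export
load_config <- function(file = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      abort(sprintf("config file not found: %s", file),
            class = "aeb_validation_error")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  cfg <- merge_config(cfg, overrides)
  check_fraction(cfg$activation_rate, "activation_rate", 0, 1, open_lower = TRUE)
  for (nm in names(cfg$files)) {
    p <- cfg$files[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("configured file `%s` does not exist: %s", nm, p),
            class = "aeb_validation_error")
    }
  }
  cfg
}

# Materialise the effectiveness spec described by a configuration.
config_effectiveness_spec <- function(cfg) {
  per_type <- purrr::imap_dfr(cfg$effectiveness, function(v, type) {
    tibble(type = type, ec_fat = v$ec_fat, ec_inj = v$ec_inj)
  })
  effectiveness_spec(per_type, ec_m3 = cfg$ec_m3)
}

# Materialise the npr anchors described by a configuration.
config_npr_anchors <- function(cfg) {
  tibble(year = cfg$npr_anchors$year, npr = cfg$npr_anchors$npr)
}

#' Write the complete synthetic fixture set to a directory
#'
#' Emits `casualties.csv`, `conditions.csv`, `population.csv`,
#' `survival.csv`, and `historical_sales.csv`, generated from a
#' [synth_config()]; together with the packaged collision-type table these
#' are every input the pipeline needs.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_fixture_set <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fat <- gen_casualty_series(cfg, "fatality")
  inj <- gen_casualty_series(cfg, "severe_injury")
  readr::write_csv(
    tibble(year = fat$year, fatalities = fat$count,
           severe_injuries = inj$count),
    file.path(dir, "casualties.csv"))
  cond <- gen_condition_log(cfg)
  readr::write_csv(as_tibble(cond$distributions),
                   file.path(dir, "conditions.csv"))
  fleet <- gen_fleet_fixture(cfg)
  readr::write_csv(fleet$population |> rename(persons = "persons"),
                   file.path(dir, "population.csv"))
  readr::write_csv(fleet$survival, file.path(dir, "survival.csv"))
  readr::write_csv(fleet$historical_sales,
                   file.path(dir, "historical_sales.csv"))
  invisible(dir)
}
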