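#' Collision-type table with recomputed proportions
#'
#' Validates a table of accident, fatality and injury counts by collision
#' type and derives the per-kind proportions used to weight per-type AEB
#' effectiveness. When printed percentage columns (`pct_accidents`,
#' `pct_fatalities`, `pct_injuries`) are present, the recomputed
#' proportions are cross-checked against them to 0.01 percentage points
#' and a mismatch names the offending row.
#'
#' @param data Data frame with columns `type`, `accidents`, `fatalities`,
#'   `injuries` (one row per collision type, optionally a `"total"` row)
#'   and optional printed percentage columns.
#' @return A tibble of class `collision_table` with added columns
#'   `prop_accidents`, `prop_fatalities`, `prop_injuries`; column totals are
#'   stored in the `totals` attribute. Proportions are computed against the
#'   `"total"` row when present (national statistical yearbooks denominate
#'   per-type shares on the full casualty total, which the listed types need
#'   not exhaust), otherwise against the column sums.
#' @examples
#' tab <- china_collision_types()
#' dplyr::filter(tab, type == "rear_end")
#' @export
collision_type_table <- function(data) {
  check_columns(data, c("type", "accidents", "fatalities", "injuries"),
                "collision table")
  data <- as_tibble(data)
  counts <- c("accidents", "fatalities", "injuries")
  is_total <- tolower(data$type) == "total"
  total_row <- data[is_total, ]
  data <- data[!is_total, ]
  if (nrow(data) == 0) {
    abort("collision table is empty", class = "aeb_validation_error")
  }
  for (col in counts) {
    if (any(!is.finite(data[[col]]) | data[[col]] < 0)) {
      abort(sprintf("column `%s` must be non-negative", col),
            class = "aeb_validation_error")
    }
  }
  totals <- vapply(counts, function(col) {
    if (nrow(total_row) == 1) total_row[[col]] else sum(data[[col]])
  }, numeric(1))
  for (col in counts) {
    prop <- data[[col]] / totals[[col]]
    printed <- data[[paste0("pct_", col)]]
    if (!is.null(printed)) {
      off <- abs(100 * prop - printed) > 0.01
      if (any(off)) {
        abort(sprintf(
          "recomputed %s proportion for `%s` (%.4f%%) disagrees with the printed %.2f%% by more than 0.01pp",
          col, data$type[which(off)[1]], 100 * prop[which(off)[1]],
          printed[which(off)[1]]),
          class = "aeb_validation_error")
      }
    }
    data[[paste0("prop_", col)]] <- prop
  }
  structure(data, class = c("collision_table", class(data)), totals = totals)
}

#' Packaged 2017 Chinese collision-type table
#'
#' Counts and printed proportions of accidents, fatalities and severe
#' injuries by collision type in China in 2017 (203,049 accidents, 63,772
#' fatalities, 209,645 severe injuries), as distributed with the package.
#'
#' @return A validated [collision_type_table()].
#' @export
china_collision_types <- function() {
  path <- system.file("extdata", "collision_types_cn2017.csv",
                      package = "aebimpact", mustWork = TRUE)
  collision_type_table(readr::read_csv(path, show_col_types = FALSE))
}

#' Per-collision-type AEB effectiveness specification
#'
#' Signed fractional casualty changes attributable to AEB for the four
#' collision types it addresses, plus the behavioural-adaptation
#' (mechanism 3) term. Reductions are negative, so the combined effect
#' composes multiplicatively as \eqn{(1 + EC_{m1})(1 + EC_{m3}) - 1}.
#'
#' Defaults carry the literature values: pedestrian and road-obstacle
#' collisions -44% (fatalities) / -33% (injuries), rear-end -43%, head-on
#' (front-impact) -27%, and a +0.3% behavioural-compensation increase.
#'
#' @param per_type Data frame with columns `type`, `ec_fat`, `ec_inj`
#'   (values in `[-1, 1]`).
#' @param ec_m3 Mechanism-3 signed fractional change (default `+0.003`).
#' @return A list of class `effectiveness_spec`.
#' @export
effectiveness_spec <- function(per_type = default_effectiveness_types(),
                               ec_m3 = 0.003) {
  check_columns(per_type, c("type", "ec_fat", "ec_inj"), "effectiveness spec")
  check_fraction(per_type$ec_fat, "ec_fat", -1, 1)
  check_fraction(per_type$ec_inj, "ec_inj", -1, 1)
  check_fraction(ec_m3, "ec_m3", -1, 1)
  structure(list(per_type = as_tibble(per_type), ec_m3 = ec_m3),
            class = "effectiveness_spec")
}

#' @rdname effectiveness_spec
#' @export
default_effectiveness_types <- function() {
  tibble(
    type = c("pedestrian_single_vehicle", "obstacle_single_vehicle",
             "rear_end", "head_on"),
    ec_fat = c(-0.44, -0.44, -0.43, -0.27),
    ec_inj = c(-0.33, -0.33, -0.43, -0.27)
  )
}

#' Mechanism-1 effect: proportion-weighted per-type effectiveness
#'
#' The direct driving-task effect \eqn{EC_{m1} = \sum_i EC_i PC_i}, where
#' `PC_i` is the share of the chosen casualty kind occurring in collision
#' type `i` and `EC_i` the per-type effectiveness. Types absent from the
#' spec contribute zero; a spec type missing from the table is an error.
#'
#' @param table A [collision_type_table()].
#' @param spec An [effectiveness_spec()].
#' @param kind `"fatality"` or `"severe_injury"`.
#' @return Signed fraction (negative for a net reduction).
#' @export
mechanism1_effect <- function(table, spec, kind = c("fatality", "severe_injury")) {
  kind <- match_kind(kind)
  stopifnot(inherits(spec, "effectiveness_spec"))
  if (!inherits(table, "collision_table")) table <- collision_type_table(table)
  unknown <- setdiff(spec$per_type$type, table$type)
  if (length(unknown) > 0) {
    abort(sprintf("effectiveness spec names unknown collision type(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "aeb_validation_error")
  }
  prop_col <- if (kind == "fatality") "prop_fatalities" else "prop_injuries"
  ec_col <- if (kind == "fatality") "ec_fat" else "ec_inj"
  joined <- dplyr::inner_join(spec$per_type, as_tibble(table), by = "type")
  sum(joined[[ec_col]] * joined[[prop_col]])
}

#' Compose mechanism effects multiplicatively
#'
#' \eqn{EC = (1 + EC_{m1})(1 + EC_{m3}) - 1}; the magnitude `|EC|` is the
#' headline full-penetration percentage reduction.
#'
#' @param ec_m1,ec_m3 Signed fractional effects in `(-1, 1]`.
#' @return Signed fraction.
#' @export
combined_effect <- function(ec_m1, ec_m3) {
  check_fraction(ec_m1, "ec_m1", -1, 1, open_lower = TRUE)
  check_fraction(ec_m3, "ec_m3", -1, 1, open_lower = TRUE)
  (1 + ec_m1) * (1 + ec_m3) - 1
}

#' Full-penetration AEB effectiveness for both casualty kinds
#'
#' Runs the mechanism-1 weighting and mechanism-3 composition end to end
#' on a collision-type table.
#'
#' @inheritParams mechanism1_effect
#' @return A tibble with one row per casualty kind and columns `kind`,
#'   `ec_m1`, `ec_m3`, `ec` (signed), and `pct_reduction` (`100 * |ec|`,
#'   the headline percentage).
#' @examples
#' aeb_effectiveness(china_collision_types())
#' @export
aeb_effectiveness <- function(table = china_collision_types(),
                              spec = effectiveness_spec()) {
  purrr::map_dfr(aeb_kinds(), function(kind) {
    m1 <- mechanism1_effect(table, spec, kind)
    ec <- combined_effect(m1, spec$ec_m3)
    tibble(kind = kind, ec_m1 = m1, ec_m3 = spec$ec_m3, ec = ec,
           pct_reduction = 100 * abs(ec))
  })
}
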