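#' Fit a Markov residual correction for a grey model
#'
#' Partitions the relative residuals of a grey fit into `n_states`
#' equal-width states spanning the residual range and estimates a
#' row-stochastic transition matrix from the observed state sequence.
#' Residuals here are \eqn{\varepsilon_k = (x_k - \hat x_k)/\hat x_k}, the
#' signed fraction by which the observation exceeds the fit, so that a
#' corrected value \eqn{\hat x_k (1 + c)} with `c` a state centre moves the
#' fit toward the data.
#'
#' Rows of the transition matrix with no observed outgoing transition are
#' set to the uniform distribution. When all residuals coincide (a perfect
#' fit of a geometric series, say) the partition collapses to a single
#' state whose centre is that common residual.
#'
#' @param data Observed casualty series (columns `year`, `count`).
#' @param fitted Grey-model fitted values: a data frame with columns `year`
#'   and `value` covering at least observed years 2..n (as returned by
#'   [predict.gm11()]).
#' @param n_states Number of residual states (positive integer; default 3).
#' @return An object of class `markov_correction`: `n_states` (effective
#'   count after degeneracy collapse), `state_bounds`, `state_centres`,
#'   `transition_matrix`, `last_state`, and `states` (per-year residual and
#'   state index).
#' @examples
#' geo <- tibble::tibble(year = 2001:2006, count = 100 * 0.9^(0:5))
#' fit <- fit_gm11(geo)
#' fit_markov_correction(geo, predict(fit), n_states = 2)
#' @export
fit_markov_correction <- function(data, fitted, n_states = 3) {
  data <- validate_casualty_series(data)
  check_columns(fitted, c("year", "value"), "fitted values")
  stopifnot(length(n_states) == 1, n_states >= 1,
            n_states == as.integer(n_states))

  # Residuals on observed years 2..n: year 1 is reproduced by construction.
  obs <- data[-1, ]
  joined <- dplyr::left_join(obs, fitted, by = "year")
  if (anyNA(joined$value)) {
    abort("fitted values do not cover observed years 2..n",
          class = "aeb_validation_error")
  }
  eps <- (joined$count - joined$value) / joined$value

  lo <- min(eps); hi <- max(eps)
  if (hi - lo < 1e-12) {
    # Degenerate: every residual identical; correction is that constant.
    n_states <- 1L
    bounds <- c(lo, hi)
    centres <- lo
    state <- rep(1L, length(eps))
  } else {
    bounds <- seq(lo, hi, length.out = n_states + 1)
    width <- (hi - lo) / n_states
    state <- pmin(floor((eps - lo) / width), n_states - 1) + 1L
    centres <- (bounds[-1] + bounds[-(n_states + 1)]) / 2
  }

  trans <- matrix(0, n_states, n_states)
  if (length(state) > 1) {
    for (i in seq_len(length(state) - 1)) {
      trans[state[i], state[i + 1]] <- trans[state[i], state[i + 1]] + 1
    }
  }
  rs <- rowSums(trans)
  for (i in seq_len(n_states)) {
    trans[i, ] <- if (rs[i] > 0) trans[i, ] / rs[i] else rep(1 / n_states, n_states)
  }

  structure(
    list(
      n_states = as.integer(n_states),
      state_bounds = bounds,
      state_centres = centres,
      transition_matrix = trans,
      last_state = state[length(state)],
      states = tibble(year = joined$year, residual = eps, state = state)
    ),
    class = "markov_correction"
  )
}

#' @export
print.markov_correction <- function(x, ...) {
  cat(sprintf("Markov residual correction: %d state(s)\n", x$n_states))
  cat("  centres:", paste(sprintf("%+.4f", x$state_centres), collapse = " "), "\n")
  cat("  transition matrix:\n")
  print(round(x$transition_matrix, 4))
  invisible(x)
}

# h-step state distribution from the last observed state.
propagate_state <- function(correction, h) {
  p <- replace(numeric(correction$n_states), correction$last_state, 1)
  P <- correction$transition_matrix
  for (i in seq_len(h)) p <- as.numeric(p %*% P)
  p
}

#' Grey-Markov forecast of an annual casualty series
#'
#' Fits a GM(1,1) grey model, then a Markov chain on the fit's relative
#' residuals, and corrects both the in-sample fit and the out-of-sample
#' forecast. In sample, each year's fitted value is scaled by
#' \eqn{(1 + c_{s_k})} where \eqn{c_{s_k}} is the centre of the state its
#' own residual falls in (by construction this cannot increase the absolute
#' relative error). Out of sample, the step-`h` forecast is the grey
#' forecast times \eqn{(1 + c_h)}, where \eqn{c_h} is the
#' probability-weighted mean of state centres after propagating the last
#' observed state `h` steps through the transition matrix.
#'
#' @param data Observed casualty series (columns `year`, `count`).
#' @param horizon Years to forecast beyond the observed span.
#' @param n_states Number of Markov residual states (default 3).
#' @return An object of class `grey_markov_forecast`: `table` (tibble with
#'   `year`, `observed`, `gm_value`, `value`, `type`, `relative_error`),
#'   `model` (the `gm11` fit), `correction` (the `markov_correction`),
#'   `mean_abs_relative_error`, `max_relative_error` (signed, worst year),
#'   and the same two diagnostics for the uncorrected grey fit.
#' @examples
#' set.seed(1)
#' s <- gen_casualty_series(synth_config(seed = 1), kind = "fatality")
#' fc <- forecast_grey_markov(s, horizon = 5)
#' glance(fc)
#' @export
forecast_grey_markov <- function(data, horizon = 0, n_states = 3) {
  data <- validate_casualty_series(data)
  model <- fit_gm11(data)
  gm <- predict(model, horizon = horizon)
  corr <- fit_markov_correction(data, gm[gm$type == "fitted", ], n_states = n_states)

  value <- gm$value
  n <- model$n
  # In-sample correction: scale by own-state centre (years 2..n).
  idx <- match(corr$states$year, gm$year)
  value[idx] <- gm$value[idx] * (1 + corr$state_centres[corr$states$state])
  # Out-of-sample: probability-weighted centre after h-step propagation.
  if (horizon > 0) {
    for (h in seq_len(horizon)) {
      p <- propagate_state(corr, h)
      value[n + h] <- gm$value[n + h] * (1 + sum(p * corr$state_centres))
    }
  }

  tbl <- gm |>
    dplyr::rename(gm_value = "value") |>
    mutate(
      value = value,
      observed = c(data$count, rep(NA_real_, horizon)),
      relative_error = ifelse(.data$type == "fitted" & .data$year > data$year[1],
                              (value - .data$observed) / .data$observed, NA_real_)
    ) |>
    select("year", "observed", "gm_value", "value", "type", "relative_error")

  re <- tbl$relative_error[!is.na(tbl$relative_error)]
  gm_re <- (gm$value[idx] - data$count[-1]) / data$count[-1]
  structure(
    list(
      table = tbl, model = model, correction = corr,
      mean_abs_relative_error = mean(abs(re)),
      max_relative_error = re[which.max(abs(re))],
      gm_mean_abs_relative_error = mean(abs(gm_re)),
      gm_max_relative_error = gm_re[which.max(abs(gm_re))]
    ),
    class = "grey_markov_forecast"
  )
}

#' @export
print.grey_markov_forecast <- function(x, ...) {
  cat("Grey-Markov forecast\n")
  print(x$model)
  cat(sprintf("  Markov states: %d; mean |relative error| %.2f%% (grey alone %.2f%%)\n",
              x$correction$n_states,
              100 * x$mean_abs_relative_error,
              100 * x$gm_mean_abs_relative_error))
  fc <- x$table[x$table$type == "forecast", ]
  if (nrow(fc) > 0) {
    cat(sprintf("  forecast %d-%d: %s\n", min(fc$year), max(fc$year),
                paste(format(round_half_up(fc$value), big.mark = ","),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grey_markov_forecast <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.grey_markov_forecast <- function(x, ...) {
  tibble(
    a = x$model$a, b = x$model$b, n = x$model$n,
    n_states = x$correction$n_states,
    mean_abs_relative_error = x$mean_abs_relative_error,
    max_relative_error = x$max_relative_error,
    gm_mean_abs_relative_error = x$gm_mean_abs_relative_error,
    gm_max_relative_error = x$gm_max_relative_error
  )
}

#' @rdname forecast_grey_markov
#' @param object A `grey_markov_forecast`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.grey_markov_forecast <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value, linetype = .data$type)) +
    ggplot2::labs(x = "year", y = "annual casualties",
                  linetype = NULL,
                  title = "Grey-Markov fit and forecast") +
    ggplot2::theme_minimal()
}
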