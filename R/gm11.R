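#' Fit a GM(1,1) grey model to an annual casualty series
#'
#' The first-order one-variable grey model fits a quasi-exponential trend to
#' a short positive time series. The raw series \eqn{x^{(0)}} is accumulated
#' into \eqn{x^{(1)}(k) = \sum_{i \le k} x^{(0)}(i)} (the accumulated
#' generating operation), the background value is the mean of consecutive
#' accumulated values \eqn{z^{(1)}(k) = 0.5 (x^{(1)}(k) + x^{(1)}(k-1))},
#' and the development coefficient `a` and grey input `b` solve the whitened
#' equation \eqn{x^{(0)}(k) + a z^{(1)}(k) = b} by least squares over
#' \eqn{k = 2..n}.
#'
#' @param data A casualty series: data frame with columns `year` and `count`
#'   (strictly positive, consecutive years, length at least 4).
#' @return An object of class `gm11` with elements `a` (development
#'   coefficient, 1/year), `b` (grey input), `x0_first`, `n`, `years`, and
#'   `data` (the series the model was fitted to).
#' @examples
#' geo <- tibble::tibble(year = 2001:2004, count = 100 * 0.9^(0:3))
#' fit <- fit_gm11(geo)
#' predict(fit, horizon = 1)
#' @seealso [predict.gm11()], [forecast_grey_markov()]
#' @export
fit_gm11 <- function(data) {
  data <- validate_casualty_series(data)
  x0 <- data$count
  n <- length(x0)
  x1 <- cumsum(x0)
  z1 <- 0.5 * (x1[-1] + x1[-n])
  # Whitened equation x0(k) = b - a * z1(k), least squares over k = 2..n
  X <- cbind(-z1, 1)
  y <- x0[-1]
  fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                  error = function(e) {
                    abort("GM(1,1) normal equations are singular; series admits no grey fit",
                          class = "aeb_degenerate_fit_error")
                  })
  a <- fit[1]
  b <- fit[2]
  if (!is.finite(a) || !is.finite(b) || abs(a) < .Machine$double.eps) {
    abort("GM(1,1) fit degenerate: development coefficient is zero",
          class = "aeb_degenerate_fit_error")
  }
  structure(
    list(a = unname(a), b = unname(b), x0_first = x0[1], n = n,
         years = data$year, data = data),
    class = "gm11"
  )
}

#' Fitted values and forecasts from a GM(1,1) model
#'
#' Evaluates the exact solution of the fitted grey difference equation
#' \eqn{\hat x^{(1)}(k) = (x^{(0)}(1) - b/a)\beta^{k-1} + b/a} with
#' \eqn{\beta = (1 - a/2)/(1 + a/2)}, and differences it back to the raw
#' scale, \eqn{\hat x^{(0)}(k) = \hat x^{(1)}(k) - \hat x^{(1)}(k-1)},
#' over the observed span plus `horizon` further years. The discrete
#' solution (rather than the continuous-time response \eqn{e^{-ak}}, which
#' agrees with it only to second order in `a`) is used because it
#' reproduces an exactly geometric series without error: the fitted annual
#' ratio is \eqn{\beta} itself.
#'
#' @param object A fitted [fit_gm11()] model.
#' @param horizon Number of years to forecast beyond the observed span
#'   (non-negative integer; 0 returns fitted values only).
#' @param ... Unused.
#' @return A tibble with columns `year`, `value`, and `type`
#'   (`"fitted"` over the observed span, `"forecast"` beyond it).
#' @export
predict.gm11 <- function(object, horizon = 0, ...) {
  stopifnot(length(horizon) == 1, horizon >= 0, horizon == as.integer(horizon))
  n_out <- object$n + horizon
  k <- seq_len(n_out) - 1          # k = 0 .. n_out-1
  ba <- object$b / object$a
  beta <- gm11_ratio(object$a)
  x1_hat <- (object$x0_first - ba) * beta^k + ba
  x0_hat <- c(object$x0_first, diff(x1_hat))
  years <- object$years[1] + k
  tibble(
    year = years,
    value = x0_hat,
    type = rep(c("fitted", "forecast"), c(object$n, horizon))
  )
}

# Annual ratio of the discrete GM(1,1) solution.
gm11_ratio <- function(a) (1 - 0.5 * a) / (1 + 0.5 * a)

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model\n")
  cat(sprintf("  span: %d-%d (n = %d)\n", min(x$years), max(x$years), x$n))
  cat(sprintf("  development coefficient a = %.6g (annual ratio %.4f)\n",
              x$a, gm11_ratio(x$a)))
  cat(sprintf("  grey input b = %.6g\n", x$b))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gm11 <- function(x, ...) {
  fitted <- predict(x, horizon = 0)
  dplyr::left_join(x$data, fitted, by = "year") |>
    dplyr::transmute(
      year = .data$year,
      observed = .data$count,
      fitted = .data$value,
      relative_error = (.data$value - .data$count) / .data$count
    )
}

#' @exportS3Method generics::glance
glance.gm11 <- function(x, ...) {
  td <- tidy(x)
  re <- td$relative_error[-1]   # first point reproduced by construction
  tibble(
    a = x$a, b = x$b, n = x$n,
    annual_factor = gm11_ratio(x$a),
    mean_abs_relative_error = mean(abs(re)),
    max_relative_error = re[which.max(abs(re))]
  )
}
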