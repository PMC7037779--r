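# Shared fixtures, built in code.

# Exact geometric casualty series: x_k = base * ratio^k.
geometric_series <- function(base = 100, ratio = 0.9, n = 4, start_year = 2001) {
  tibble::tibble(year = start_year + seq_len(n) - 1,
                 count = base * ratio^(seq_len(n) - 1))
}

# Observed/fitted pair realising a prescribed relative-residual sequence
# eps_k = (observed - fitted)/fitted on years 2..n, with fitted == 100.
series_with_residuals <- function(eps, start_year = 2001) {
  n <- length(eps) + 1
  list(
    observed = tibble::tibble(year = start_year + 0:(n - 1),
                              count = c(100, 100 * (1 + eps))),
    fitted = tibble::tibble(year = start_year + 1:(n - 1), value = 100)
  )
}

# Minimal condition-distribution table putting chosen mass where needed.
toy_conditions <- function(gear1 = 1, night_unlit = 0, sunny = 1) {
  tibble::tribble(
    ~block, ~category, ~prop_fatalities, ~prop_injuries,
    "gear", "gear1", gear1, gear1,
    "gear", "gear5plus", 1 - gear1, 1 - gear1,
    "light", "day", 1 - night_unlit, 1 - night_unlit,
    "light", "night_unlit", night_unlit, night_unlit,
    "weather", "sunny", sunny, sunny,
    "weather", "rainy", 1 - sunny, 1 - sunny
  ) |> aebimpact::condition_distributions()
}

flat_survival <- function(fraction) {
  tibble::tibble(age = 1:18, fraction = rep(fraction, 18))
}
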