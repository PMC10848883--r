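# Environmental schedules: 12-month periodic cycles of temperature,
# productivity and spawning permission, expanded over the model horizon.

new_environment <- function(tau_C, kappa, spawn, name = "custom") {
  stopifnot(length(tau_C) == 12L, length(kappa) == 12L, length(spawn) == 12L,
            all(kappa > 0), any(spawn))
  out <- tibble::tibble(
    month = 1:12,
    tau_C = as.numeric(tau_C),
    kappa = as.numeric(kappa),
    spawn = as.logical(spawn)
  )
  attr(out, "scenario") <- name
  class(out) <- c("finlife_env", class(out))
  out
}

#' Constant environment
#'
#' All twelve calendar months share the same temperature and productivity;
#' spawning is permitted year-round unless disabled.
#'
#' @param tau_C Temperature in degrees Celsius (constant across months).
#' @param kappa Ecosystem productivity (size-spectrum scale), positive.
#' @param spawn_all_year Permit spawning in every month? Default `TRUE`.
#' @param name Scenario label carried in the result's attributes.
#'
#' @return A 12-row tibble of class `finlife_env` with columns `month`,
#'   `tau_C`, `kappa`, `spawn`. Schedules are 12-month periodic; use
#'   [env_expand()] to unroll one over a model horizon.
#' @export
#' @examples
#' constant_environment(16.85, kappa = 1)
constant_environment <- function(tau_C, kappa, spawn_all_year = TRUE,
                                 name = "constant") {
  stopifnot(tau_C > -50, tau_C < 60, kappa > 0)
  new_environment(rep(tau_C, 12), rep(kappa, 12), rep(spawn_all_year, 12),
                  name = name)
}

#' Seasonal environment
#'
#' A two-season year: `warm_months` consecutive months (placed at the start of
#' the cycle, so a natal cohort appears on the spawning grounds in month 1) at
#' the summer temperature and productivity, the remainder at winter values.
#' Spawning can be restricted to the warm season, representing spawning
#' migrations to warm waters.
#'
#' @param winter_tau_C,summer_tau_C Winter/summer temperature (degrees C).
#' @param winter_kappa,summer_kappa Winter/summer productivity.
#' @param warm_months Number of consecutive warm months (1-12), default 3.
#' @param spawn_in_warm_only Restrict spawning to the warm season? Default
#'   `TRUE`.
#' @param warm_offset Integer rotation of the cycle; 0 (default) places the
#'   warm season in months `1..warm_months`.
#' @param name Scenario label.
#'
#' @return A `finlife_env` tibble; its 12-month mean `kappa` equals
#'   `(warm_months * summer_kappa + (12 - warm_months) * winter_kappa) / 12`.
#' @export
seasonal_environment <- function(winter_tau_C, summer_tau_C,
                                 winter_kappa, summer_kappa,
                                 warm_months = 3, spawn_in_warm_only = TRUE,
                                 warm_offset = 0, name = "seasonal") {
  stopifnot(warm_months >= 1, warm_months <= 12,
            winter_kappa > 0, summer_kappa > 0)
  warm <- seq_len(12) <= warm_months
  warm <- warm[((seq_len(12) - 1 - warm_offset) %% 12) + 1]
  tau <- ifelse(warm, summer_tau_C, winter_tau_C)
  kap <- ifelse(warm, summer_kappa, winter_kappa)
  spw <- if (spawn_in_warm_only) warm else rep(TRUE, 12)
  new_environment(tau, kap, spw, name = name)
}

#' Tuna ecological-lifestyle scenario presets
#'
#' Environmental scenarios matching three ecological lifestyles of tunas:
#' * `tropical_shallow` — constant 26.85 C, kappa 0.1, h 8 (e.g. frigate
#'   tuna remaining above the thermocline);
#' * `tropical_deep` — constant 21.85 C, kappa 1, h 8 (e.g. yellowfin tuna
#'   foraging below the thermocline);
#' * `temperate_deep` — seasonal, winter 11.85 C with a 3-month warm spawning
#'   season 9 C warmer, winter productivity threefold summer with a yearly
#'   mean kappa of 2.5, h 12 (e.g. Atlantic bluefin tuna migrating between
#'   temperate foraging and warm spawning grounds).
#'
#' @param name One of `"tropical_shallow"`, `"tropical_deep"`,
#'   `"temperate_deep"`.
#' @return A list with elements `env` (a `finlife_env`) and `spectrum`
#'   (a [spectrum_params()] holding `h` and the yearly-mean `kappa`).
#' @export
#' @examples
#' lifestyle_preset("tropical_shallow")$env
lifestyle_preset <- function(name = c("tropical_shallow", "tropical_deep",
                                      "temperate_deep")) {
  name <- match.arg(name)
  switch(
    name,
    tropical_shallow = list(
      env = constant_environment(26.85, kappa = 0.1, name = name),
      spectrum = spectrum_params(kappa = 0.1, h = 8)
    ),
    tropical_deep = list(
      env = constant_environment(21.85, kappa = 1, name = name),
      spectrum = spectrum_params(kappa = 1, h = 8)
    ),
    temperate_deep = list(
      # Yearly mean kappa 2.5 with 3 warm months and winter = 3 x summer:
      # (3 * k_s + 9 * 3 * k_s) / 12 = 2.5  =>  k_s = 1, k_w = 3.
      env = seasonal_environment(
        winter_tau_C = 11.85, summer_tau_C = 11.85 + 9,
        winter_kappa = 3, summer_kappa = 1,
        warm_months = 3, spawn_in_warm_only = TRUE, name = name
      ),
      spectrum = spectrum_params(kappa = 2.5, h = 12)
    )
  )
}

#' Expand a 12-month schedule over a model horizon
#'
#' @param env A `finlife_env`.
#' @param n_months Horizon length in months (typically `body_params()$t_max`).
#' @return A tibble with one row per model month `t = 1..n_months`, columns
#'   `t`, `month` (calendar month), `tau_C`, `kappa`, `spawn`; periodic with
#'   period 12.
#' @export
env_expand <- function(env, n_months) {
  stopifnot(inherits(env, "finlife_env"), n_months >= 1)
  idx <- ((seq_len(n_months) - 1L) %% 12L) + 1L
  out <- env[idx, ]
  out$t <- seq_len(n_months)
  out[, c("t", "month", "tau_C", "kappa", "spawn")]
}

#' Yearly mean productivity of a schedule
#'
#' @param env A `finlife_env`.
#' @return The 12-month mean of `kappa`, the value used to compare seasonal
#'   scenarios with constant ones at matched productivity.
#' @export
mean_kappa <- function(env) {
  stopifnot(inherits(env, "finlife_env"))
  mean(env$kappa)
}

#' @export
print.finlife_env <- function(x, ...) {
  cat(sprintf("<environment schedule: %s>\n", attr(x, "scenario")))
  cat(sprintf("  yearly mean kappa = %g; spawning months: %s\n",
              mean_kappa(x), paste(which(x$spawn), collapse = " ")))
  NextMethod()
}
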