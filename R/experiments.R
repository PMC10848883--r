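# Scenario runners: each solves the dynamic program for a family of
# environments and returns a tidy summary table, one row per scenario. The
# whole pipeline is deterministic, so identical inputs give identical tables.

#' Solve one scenario and summarize the emergent life history
#'
#' Convenience wrapper: [solve_policy()] + [simulate_cohort()] + [glance()],
#' returning a one-row tibble that also records the fitness of the birth
#' state from the value function (`V_birth_kg`), which agrees with the
#' forward-pass `lifetime_repro_kg` up to interpolation error.
#'
#' @inheritParams solve_policy
#' @return A one-row tibble.
#' @export
run_scenario <- function(env, sp = spectrum_params(), mp = metabolic_params(),
                         bp = body_params(), grid = state_grid(bp)) {
  pol <- solve_policy(env, sp, mp, bp, grid)
  traj <- simulate_cohort(pol)
  dplyr::bind_cols(
    glance(traj),
    glance(pol)[, c("mean_kappa", "V_birth_kg")]
  )
}

#' Temperature x productivity factorial experiment
#'
#' Solves every combination of constant temperature and productivity and
#' summarizes the emergent life history per cell; the table regenerates the
#' maximum-size and lifetime-reproduction response surfaces.
#'
#' @param tau_values Temperatures in degrees C (default 11.85 to 26.85 in 5
#'   degree steps).
#' @param kappa_values Productivities (default 0.25, 0.5, 1, 2.5, 5).
#' @param sp,mp,bp,grid As in [solve_policy()].
#' @param spawn_all_year Spawning permission for every cell, default `TRUE`.
#' @return A tibble with one row per `(tau_C, kappa)` cell.
#' @export
run_factorial <- function(tau_values = c(11.85, 16.85, 21.85, 26.85),
                          kappa_values = c(0.25, 0.5, 1, 2.5, 5),
                          sp = spectrum_params(), mp = metabolic_params(),
                          bp = body_params(), grid = state_grid(bp),
                          spawn_all_year = TRUE) {
  stopifnot(length(tau_values) >= 1, length(kappa_values) >= 1)
  cells <- tidyr::expand_grid(tau_C = tau_values, kappa = kappa_values)
  purrr::pmap_dfr(cells, function(tau_C, kappa) {
    row <- tryCatch(
      run_scenario(constant_environment(tau_C, kappa, spawn_all_year),
                   sp, mp, bp, grid),
      error = function(e) {
        stop(sprintf("factorial cell tau=%g, kappa=%g failed: %s",
                     tau_C, kappa, conditionMessage(e)), call. = FALSE)
      }
    )
    dplyr::bind_cols(tibble::tibble(tau_C = tau_C, kappa = kappa), row)
  })
}

#' Relative change in a factorial summary under a temperature increase
#'
#' Post-processing of a [run_factorial()] table: for each productivity, the
#' percent change of `metric` between temperature `tau_from` and `tau_to`.
#'
#' @param fact A [run_factorial()] result.
#' @param metric Column to compare, e.g. `"max_length_cm"`.
#' @param tau_from,tau_to The two temperatures (degrees C).
#' @return A tibble with columns `kappa` and `pct_change` (negative =
#'   reduction, in percent).
#' @export
factorial_temperature_effect <- function(fact, metric = "max_length_cm",
                                         tau_from, tau_to) {
  a <- fact[abs(fact$tau_C - tau_from) < 1e-9, c("kappa", metric)]
  b <- fact[abs(fact$tau_C - tau_to) < 1e-9, c("kappa", metric)]
  stopifnot(nrow(a) > 0, nrow(a) == nrow(b))
  m <- dplyr::inner_join(a, b, by = "kappa", suffix = c("_from", "_to"))
  tibble::tibble(
    kappa = m$kappa,
    pct_change = 100 * (m[[paste0(metric, "_to")]] /
                          m[[paste0(metric, "_from")]] - 1)
  )
}

#' Tuna lifestyle scenarios
#'
#' Runs the three [lifestyle_preset()] scenarios and reports the emergent
#' maximum body size, lifespan and reproduction per lifestyle, plus whether
#' more than 10% of the cohort is still alive at the horizon (typical of the
#' temperate deep-diving lifestyle, whose longevity exceeds the modelled 18
#' years).
#'
#' @param mp,bp,grid As in [solve_policy()].
#' @return A three-row tibble.
#' @export
run_lifestyles <- function(mp = metabolic_params(), bp = body_params(),
                           grid = state_grid(bp)) {
  purrr::map_dfr(
    c("tropical_shallow", "tropical_deep", "temperate_deep"),
    function(nm) {
      ps <- lifestyle_preset(nm)
      row <- run_scenario(ps$env, ps$spectrum, mp, bp, grid)
      dplyr::bind_cols(
        tibble::tibble(lifestyle = nm, h = ps$spectrum$h),
        row,
        tibble::tibble(alive_10pct_at_t_max = row$survival_at_t_max > 0.10)
      )
    }
  )
}

#' Seasonality contrast experiment
#'
#' Six scenarios at matched yearly-mean productivity that decompose the
#' effect of seasonality into its parts. Baseline temperature is 16.85 C;
#' seasonal temperature scenarios place a warm season 9 C above winter;
#' seasonal productivity scenarios raise winter productivity threefold over
#' summer (foraging grounds), holding the 12-month mean at the requested
#' value:
#' * `constant` — constant temperature and productivity, year-round spawning;
#' * `seasonal_temp` — 3 warm months (16.85 + 9 C), constant productivity,
#'   spawning only in the warm season;
#' * `seasonal_prod` — constant 16.85 C, threefold winter productivity,
#'   spawning only in the 3 summer months;
#' * `full_seasonal` — winter 11.85 C / summer 20.85 C, threefold winter
#'   productivity, spawning in the 3 warm months;
#' * `full_seasonal_6m` — as `full_seasonal` with a 6-month warm season;
#' * `seasonal_spawn_all_year` — the `full_seasonal` environment but with
#'   spawning permitted in all 12 months.
#'
#' @param kappa_means Yearly-mean productivities, default 0.5 to 2.5.
#' @param sp,mp,bp,grid As in [solve_policy()] (`sp` supplies `h`).
#' @return A tibble with one row per scenario x kappa mean, including a
#'   `spawn_months` column for ordering checks.
#' @export
run_seasonality_contrasts <- function(kappa_means = c(0.5, 1, 1.5, 2, 2.5),
                                      sp = spectrum_params(),
                                      mp = metabolic_params(),
                                      bp = body_params(),
                                      grid = state_grid(bp)) {
  envs_for <- function(k) {
    # threefold winter productivity at matched mean:
    # 3 warm months: (3*ks + 9*3*ks)/12 = k  =>  ks = 2k/5
    # 6 warm months: (6*ks + 6*3*ks)/12 = k  =>  ks = k/2
    ks3 <- 2 * k / 5
    ks6 <- k / 2
    list(
      constant = constant_environment(16.85, k, name = "constant"),
      seasonal_temp = seasonal_environment(
        16.85, 16.85 + 9, winter_kappa = k, summer_kappa = k,
        warm_months = 3, name = "seasonal_temp"),
      seasonal_prod = seasonal_environment(
        16.85, 16.85, winter_kappa = 3 * ks3, summer_kappa = ks3,
        warm_months = 3, name = "seasonal_prod"),
      full_seasonal = seasonal_environment(
        11.85, 20.85, winter_kappa = 3 * ks3, summer_kappa = ks3,
        warm_months = 3, name = "full_seasonal"),
      full_seasonal_6m = seasonal_environment(
        11.85, 20.85, winter_kappa = 3 * ks6, summer_kappa = ks6,
        warm_months = 6, name = "full_seasonal_6m"),
      seasonal_spawn_all_year = seasonal_environment(
        11.85, 20.85, winter_kappa = 3 * ks3, summer_kappa = ks3,
        warm_months = 3, spawn_in_warm_only = FALSE,
        name = "seasonal_spawn_all_year")
    )
  }
  purrr::map_dfr(kappa_means, function(k) {
    envs <- envs_for(k)
    purrr::imap_dfr(envs, function(env, nm) {
      dplyr::bind_cols(
        tibble::tibble(scenario_family = nm, kappa_mean = k,
                       spawn_months = sum(env$spawn)),
        run_scenario(env, sp, mp, bp, grid)
      )
    })
  })
}

#' One-parameter sensitivity sweep
#'
#' Re-runs a baseline scenario varying one of the structurally interesting
#' parameters: predator capture efficiency `h`, reproductive-capacity
#' fraction `phi`, or the metabolic normalization `c` or exponent `theta`.
#'
#' @param axis One of `"h"`, `"phi"`, `"c"`, `"theta"`.
#' @param values Values to sweep.
#' @param env Baseline environment, default constant 16.85 C, kappa 1.
#' @param sp,mp,bp,grid Baseline parameters, modified along `axis`.
#' @return A tibble with one row per value (column `value` holds it).
#' @export
run_sensitivity <- function(axis = c("h", "phi", "c", "theta"), values,
                            env = constant_environment(16.85, 1),
                            sp = spectrum_params(), mp = metabolic_params(),
                            bp = body_params(), grid = state_grid(bp)) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1)
  purrr::map_dfr(values, function(v) {
    sp2 <- sp; mp2 <- mp; bp2 <- bp
    switch(axis,
           h = { sp2$h <- v },
           phi = { bp2$phi <- v },
           c = { mp2$c <- v },
           theta = { mp2$theta <- v })
    dplyr::bind_cols(
      tibble::tibble(axis = axis, value = v),
      run_scenario(env, sp2, mp2, bp2, grid)
    )
  })
}
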