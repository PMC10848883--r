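# ggplot2 methods for the package's result types.

#' Plot a cohort trajectory
#'
#' @param object A [simulate_cohort()] trajectory.
#' @param type `"growth"` (length at age), `"reproduction"`
#'   (survival-discounted monthly output), `"survival"` (survivorship curve,
#'   log y), or `"allocation"` (g and r against age).
#' @param truncate_at_lifespan Drop months past the 3%-survival lifespan, as
#'   is conventional when displaying cohort curves? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.finlife_trajectory <- function(object,
                                        type = c("growth", "reproduction",
                                                 "survival", "allocation"),
                                        truncate_at_lifespan = TRUE, ...) {
  type <- match.arg(type)
  df <- tidy(object)
  df$age_years <- df$age_months / 12
  if (truncate_at_lifespan) {
    df <- df[df$age_months <= lifespan(object), ]
  }
  switch(
    type,
    growth = ggplot2::ggplot(df, ggplot2::aes(.data$age_years,
                                              .data$length_cm)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "age (years)", y = "length (cm)"),
    reproduction = ggplot2::ggplot(
      df[!is.na(df$repro_expected_kg), ],
      ggplot2::aes(.data$age_years, .data$repro_expected_kg)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "age (years)",
                    y = "expected reproductive output (kg/month)"),
    survival = ggplot2::ggplot(df, ggplot2::aes(.data$age_years,
                                                .data$survival_to_age)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "age (years)", y = "survival to age"),
    allocation = {
      dfl <- tidyr::pivot_longer(df[!is.na(df$g), ],
                                 cols = c("g", "r"),
                                 names_to = "allocation",
                                 values_to = "fraction")
      ggplot2::ggplot(dfl, ggplot2::aes(.data$age_years, .data$fraction,
                                        colour = .data$allocation)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "age (years)", y = "fraction of stores allocated")
    }
  )
}

#' Plot a policy slice
#'
#' Heatmap of the optimal growth allocation, reproduction allocation, or
#' value function over the (length, store-fraction) grid at one model month.
#'
#' @param object A [solve_policy()] result.
#' @param month Model month (1-based), default 1.
#' @param what One of `"r"`, `"g"`, `"V"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.finlife_policy <- function(object, month = 1,
                                    what = c("r", "g", "V"), ...) {
  what <- match.arg(what)
  df <- tidy(object, months = month)
  col <- c(r = "r_star", g = "g_star", V = "V")[[what]]
  df$fill <- df[[col]]
  df$fill[!df$feasible] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$length_cm, .data$store_frac,
                                   fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "length (cm)", y = "stores (fraction of body energy)",
                  fill = c(r = "r*", g = "g*", V = "V (J)")[[what]])
}

#' Maximum size against productivity across scenarios
#'
#' Companion plot for [run_factorial()] and [run_seasonality_contrasts()]
#' tables: a chosen response against productivity, coloured by temperature or
#' scenario family.
#'
#' @param results A tibble from a scenario runner.
#' @param metric Response column, default `"max_length_cm"`.
#' @return A ggplot object.
#' @export
plot_size_response <- function(results, metric = "max_length_cm") {
  if ("scenario_family" %in% names(results)) {
    ggplot2::ggplot(results,
                    ggplot2::aes(.data$kappa_mean, .data[[metric]],
                                 colour = .data$scenario_family)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "yearly mean productivity (kappa)")
  } else {
    ggplot2::ggplot(results,
                    ggplot2::aes(.data$kappa, .data[[metric]],
                                 colour = factor(.data$tau_C))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "productivity (kappa)", colour = "temperature (C)")
  }
}
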