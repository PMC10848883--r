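# Forward cohort simulation: deterministic expected-cohort bookkeeping under
# the solved policy (survivorship tracked as probability mass, not Monte
# Carlo individuals).

#' Forward-simulate a cohort under the optimal policy
#'
#' Starting from the birth state, applies the interpolated optimal allocation
#' month by month through [transition()], multiplying survivorship by the
#' monthly predation and starvation survival and accumulating reproductive
#' output both discounted by survival-to-age ("expected" reproduction) and
#' conditional on survival.
#'
#' @param policy A [solve_policy()] result.
#' @param birth_length Length at birth (cm); defaults to
#'   `policy$bp$birth_length`.
#' @param birth_store_frac Initial lipid stores as a fraction of
#'   structural-mass energy; defaults to the starvation threshold fraction
#'   `upsilon`.
#'
#' @return A tibble of class `finlife_trajectory`, one row per month `t =
#'   0..t_max` with columns `age_months`, `length_cm`, `mass_kg`, `stores_J`,
#'   `g`, `r`, `repro_kg` (monthly, conditional on survival),
#'   `repro_expected_kg` (survival-discounted), `monthly_survival`, and
#'   `survival_to_age`. Summarize with [glance()]; plot with
#'   [autoplot()][autoplot.finlife_trajectory].
#' @export
simulate_cohort <- function(policy,
                            birth_length = policy$bp$birth_length,
                            birth_store_frac = policy$bp$upsilon) {
  stopifnot(inherits(policy, "finlife_policy"))
  bp <- policy$bp
  env <- env_expand(policy$env, bp$t_max)
  l <- birth_length
  s <- birth_store_frac * mass_from_length(l, bp) * bp$rho
  n <- bp$t_max

  age <- 0:n
  len <- rep(NA_real_, n + 1); sto <- gg <- rr <- rep(NA_real_, n + 1)
  rep_c <- rep_e <- msurv <- rep(NA_real_, n + 1)
  surv <- rep(NA_real_, n + 1)

  len[1] <- l; sto[1] <- s; surv[1] <- 1
  alive <- 1
  for (t in seq_len(n)) {
    gr <- policy_lookup(policy, l, s, t)
    if (!env$spawn[t]) gr$r <- 0
    tr <- transition(l, s, gr$g, gr$r, env$tau_C[t], env$kappa[t],
                     env$spawn[t], policy$sp, policy$mp, bp)
    gg[t] <- gr$g; rr[t] <- gr$r
    rep_c[t] <- tr$repro / bp$rho
    rep_e[t] <- alive * tr$repro / bp$rho
    msurv[t] <- tr$survival
    alive <- alive * tr$survival
    l <- tr$l_next; s <- tr$s_next
    len[t + 1] <- l; sto[t + 1] <- s; surv[t + 1] <- alive
  }

  out <- tibble::tibble(
    age_months = age, length_cm = len,
    mass_kg = mass_from_length(len, bp), stores_J = sto,
    g = gg, r = rr,
    repro_kg = rep_c, repro_expected_kg = rep_e,
    monthly_survival = msurv, survival_to_age = surv
  )
  attr(out, "scenario") <- attr(policy$env, "scenario")
  attr(out, "bp") <- bp
  class(out) <- c("finlife_trajectory", class(out))
  out
}

#' Cohort lifespan from a survivorship threshold
#'
#' The cohort lifespan is the first age (months) at which expected survival
#' drops below the threshold — by default 3%, i.e. the age past which fewer
#' than 3% of the cohort remain. Returns `t_max` when survival never crosses
#' the threshold.
#'
#' @param traj A [simulate_cohort()] trajectory.
#' @param threshold Survival probability cutoff, default 0.03.
#' @return Age in months.
#' @export
#' @examples
#' # geometric survivorship at 0.97/month crosses 3% at month 116
lifespan <- function(traj, threshold = 0.03) {
  stopifnot(inherits(traj, "finlife_trajectory"),
            threshold >= 0, threshold <= 1)
  below <- which(traj$survival_to_age < threshold)
  if (length(below) == 0L) max(traj$age_months)
  else traj$age_months[below[1]]
}

#' @describeIn simulate_cohort One-row scenario summary: maximum length
#'   attained, lifespan (months and years), survival-discounted lifetime
#'   reproductive output (kg), age at first reproduction (first month with
#'   positive reproductive output), and the fraction of the cohort still alive
#'   at the horizon.
#' @param x,object A `finlife_trajectory`.
#' @param ... Unused.
#' @export
glance.finlife_trajectory <- function(x, ...) {
  ls_m <- lifespan(x)
  first_rep <- which(!is.na(x$repro_kg) & x$repro_kg > 0)
  tibble::tibble(
    scenario = attr(x, "scenario") %||% NA_character_,
    max_length_cm = max(x$length_cm, na.rm = TRUE),
    lifespan_months = ls_m,
    lifespan_years = ls_m / 12,
    lifetime_repro_kg = sum(x$repro_expected_kg, na.rm = TRUE),
    age_first_repro_months =
      if (length(first_rep)) x$age_months[first_rep[1]] else NA_real_,
    survival_at_t_max = x$survival_to_age[nrow(x)]
  )
}

#' @describeIn simulate_cohort Returns the trajectory as a plain tibble.
#' @export
tidy.finlife_trajectory <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "scenario") <- NULL
  attr(x, "bp") <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
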