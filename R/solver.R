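# Backward-induction solver: builds the per-length, per-month allometry
# tables and dispatches to the C++ core.

#' Solve the dynamic programming equation for an environmental scenario
#'
#' Computes the optimal allocation policy by backward induction over the
#' fitness recursion
#' `V(l, s, t) = max over (g, r) of [ r * s + gamma_pred(w) * gamma_s(s', l') * V(l', s', t + 1) ]`
#' with terminal condition `V(., ., t_max) = 0`. Fitness `V` is expected
#' lifetime reproductive energy (J) from month `t` onward. Successor states
#' off the grid are evaluated by bilinear interpolation in (length,
#' store-fraction); allocations that spawn out of season or exceed the
#' reproductive capacity `phi * w * rho` are excluded; states whose stores go
#' negative even at `g = r = 0` are inviable and carry `V = 0`. Ties in the
#' maximization are broken deterministically toward higher `r`, then higher
#' `g`.
#'
#' @param env A [constant_environment()] / [seasonal_environment()] schedule;
#'   its monthly `kappa` is the productivity actually used (the `kappa` field
#'   of `sp` only feeds the standalone allometry helpers).
#' @param sp,mp,bp Parameter sets; see [spectrum_params()],
#'   [metabolic_params()], [body_params()].
#' @param grid A [state_grid()]. Defaults to the documented resolution (200
#'   geometric length nodes x 51 store fractions x 231 allocation pairs).
#'
#' @return An object of class `finlife_policy`: a list with 3-d arrays `V`
#'   (lengths x stores x months+1, J), `g_star`, `r_star` (lengths x stores x
#'   months), `feasible` (lengths x stores x 12), plus the `grid`, `env` and
#'   parameter sets used. Explore it with [tidy()], [glance()],
#'   [autoplot()][autoplot.finlife_policy], or run a cohort through it with
#'   [simulate_cohort()].
#' @export
#' @examples
#' grid <- state_grid(body_params(t_max = 24), n_lengths = 40,
#'                    n_stores = 11, n_alloc = 6)
#' pol <- solve_policy(constant_environment(16.85, 1),
#'                     bp = body_params(t_max = 24), grid = grid)
#' glance(pol)
solve_policy <- function(env, sp = spectrum_params(), mp = metabolic_params(),
                         bp = body_params(), grid = state_grid(bp)) {
  stopifnot(inherits(env, "finlife_env"), inherits(grid, "finlife_grid"))
  if (max(grid$lengths) > bp$max_length + 1e-9) {
    stop("grid lengths exceed bp$max_length; rebuild the grid with these ",
         "body parameters", call. = FALSE)
  }
  fr <- grid$fracs
  if (max(abs(diff(fr) - (fr[2] - fr[1]))) > 1e-9 * fr[length(fr)]) {
    stop("store-fraction grid must be uniform", call. = FALSE)
  }

  w <- mass_from_length(grid$lengths, bp)
  # net energy income (J/month) per length node and calendar month
  net_in <- vapply(1:12, function(m) {
    sp_m <- sp
    sp_m$kappa <- env$kappa[m]
    bp$rho * prey_biomass(w, sp_m) -
      metabolic_cost(w, celsius_to_kelvin(env$tau_C[m]), mp)
  }, numeric(length(w)))

  g_levels <- sort(unique(grid$lattice$g))
  lat_gi <- match(grid$lattice$g, g_levels) - 1L

  sol <- .solve_backward_cpp(
    lengths = grid$lengths, fracs = grid$fracs,
    lat_g = grid$lattice$g, lat_r = grid$lattice$r,
    lat_gi = lat_gi, g_levels = g_levels,
    net_in = net_in, gpred = predation_survival(w, sp),
    spawn = env$spawn, t_max = bp$t_max,
    a = bp$a, rho = bp$rho, upsilon = bp$upsilon,
    store_cap = bp$store_cap_frac, phi = bp$phi,
    q_abs = if (is.na(bp$q)) -1 else bp$q,
    k_rel = starvation_rel_steepness(),
    max_length = bp$max_length
  )
  if (any(!is.finite(sol$V))) {
    stop("non-finite fitness values: parameter pathology", call. = FALSE)
  }

  structure(
    list(V = sol$V, g_star = sol$g_star, r_star = sol$r_star,
         feasible = sol$feasible, grid = grid, env = env,
         sp = sp, mp = mp, bp = bp),
    class = "finlife_policy"
  )
}

#' Interpolate the optimal policy at an off-grid state
#'
#' Bilinear interpolation of `g*` and `r*` (the same scheme the solver uses
#' for the value function), re-projected so that `g + r <= 1` and the
#' reproductive capacity constraint hold.
#'
#' @param policy A `finlife_policy`.
#' @param l Length (cm); `s` stores (J); `t` model month (1-based).
#' @param s,t See `l`.
#' @return A list with elements `g` and `r`.
#' @export
policy_lookup <- function(policy, l, s, t) {
  gr <- policy$grid
  bp <- policy$bp
  f <- s / (mass_from_length(min(l, bp$max_length), bp) * bp$rho)
  g <- interp_bilinear(gr$lengths, gr$fracs, policy$g_star[, , t], l, f)
  r <- interp_bilinear(gr$lengths, gr$fracs, policy$r_star[, , t], l, f)
  g <- max(g, 0); r <- max(r, 0)
  if (g + r > 1) {
    tot <- g + r
    g <- g / tot; r <- r / tot
  }
  r_max <- max_reproduction(mass_from_length(l, bp), bp) / max(s, 1e-300)
  r <- min(r, r_max)
  list(g = g, r = r)
}

#' @describeIn solve_policy One row per (length, store, month) with the value
#'   function and optimal allocations. `months` selects model months (default
#'   month 1) to keep the output a manageable size.
#' @param x,object A `finlife_policy`.
#' @param months Integer vector of model months to extract (1-based).
#' @param ... Unused.
#' @export
tidy.finlife_policy <- function(x, months = 1L, ...) {
  gr <- x$grid
  purrr::map_dfr(months, function(m) {
    tibble::tibble(
      t = m,
      length_cm = rep(gr$lengths, times = length(gr$fracs)),
      store_frac = rep(gr$fracs, each = length(gr$lengths)),
      V = as.vector(x$V[, , m]),
      g_star = as.vector(x$g_star[, , m]),
      r_star = as.vector(x$r_star[, , m]),
      feasible = as.vector(x$feasible[, , ((m - 1) %% 12) + 1])
    )
  })
}

#' @describeIn solve_policy One-row summary: grid dimensions, horizon, and
#'   fitness at the birth state (in J and as lifetime reproductive output in
#'   kg, i.e. divided by `rho`).
#' @export
glance.finlife_policy <- function(x, ...) {
  bp <- x$bp
  s0 <- bp$upsilon * mass_from_length(bp$birth_length, bp) * bp$rho
  f0 <- s0 / (mass_from_length(bp$birth_length, bp) * bp$rho)
  v0 <- interp_bilinear(x$grid$lengths, x$grid$fracs, x$V[, , 1],
                        bp$birth_length, f0)
  tibble::tibble(
    n_lengths = length(x$grid$lengths),
    n_stores = length(x$grid$fracs),
    n_alloc_pairs = nrow(x$grid$lattice),
    t_max = bp$t_max,
    scenario = attr(x$env, "scenario"),
    mean_kappa = mean_kappa(x$env),
    V_birth_J = v0,
    V_birth_kg = v0 / bp$rho
  )
}

#' @export
print.finlife_policy <- function(x, ...) {
  cat("<optimal allocation policy>\n")
  print(glance(x))
  invisible(x)
}
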