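# Shared fixtures: small parameter sets and grids used across test files.
# Everything is built in code; no stored data.

# Nondegenerate toy instance: 4 lengths x 5 stores x 6 months, 3-level
# allocation lattice, seasonal environment with a closed season.
toy_body <- function(...) {
  body_params(birth_length = 20, max_length = 100, t_max = 6, phi = 0.3, ...)
}

toy_instance <- function() {
  bp <- toy_body()
  list(
    bp = bp,
    sp = spectrum_params(kappa = 1, h = 8),
    mp = metabolic_params(),
    env = seasonal_environment(15, 22, winter_kappa = 2, summer_kappa = 1,
                               warm_months = 3, spawn_in_warm_only = TRUE),
    grid = state_grid(bp, n_lengths = 4, n_stores = 5, n_alloc = 3)
  )
}

# Zero-net-income instance: prey intake exactly cancels metabolic costs at
# every mass (matched exponent and coefficient), the starvation term is a
# constant 1/2 (q ~ 0), and phi = 0.5. With the corner allocation lattice
# {(0,0), (0,1), (1,0)}, every transition either stays on a grid node
# (hold, or spawn-everything) or empties the stores, and a stored-out state
# has value exactly 0 at every length under zero income, so interpolating
# the continuation is exact. Backward induction must therefore equal
# exhaustive enumeration of allocation sequences exactly.
zero_income_instance <- function() {
  tau_C <- 16.85
  sp <- spectrum_params(kappa = 1, h = 8, prey_exp = 0.05)
  bp <- body_params(birth_length = 20, max_length = 100, t_max = 6,
                    phi = 0.5, q = 1e-30)
  boltz <- exp(-metabolic_params()$E /
                 (metabolic_params()$kB * celsius_to_kelvin(tau_C)))
  mp <- metabolic_params(c = bp$rho * sp$prey_coef * sp$kappa / boltz,
                         theta = sp$prey_exp)
  env <- seasonal_environment(tau_C, tau_C, winter_kappa = 1,
                              summer_kappa = 1, warm_months = 3,
                              spawn_in_warm_only = FALSE)
  env$spawn <- seq_len(12) >= 4   # closed season in months 1-3
  list(bp = bp, sp = sp, mp = mp, env = env,
       grid = state_grid(bp, n_lengths = 4, n_stores = 5, n_alloc = 2))
}

# Reduced solver grid for experiment-level tests (documented resolutions are
# 200 x 51 x 21; these tests only assert orderings and signs).
small_grid <- function(bp = body_params()) {
  state_grid(bp, n_lengths = 100, n_stores = 26, n_alloc = 11)
}
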