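# Independent reference implementations used to validate the C++ solver.
# These deliberately share no code with the solver: transitions go through
# the R-level transition(), and interpolation is written out here.

bilin_ref <- function(xs, ys, M, x, y) {
  x <- min(max(x, xs[1]), xs[length(xs)])
  y <- min(max(y, ys[1]), ys[length(ys)])
  i <- min(max(findInterval(x, xs, rightmost.closed = TRUE), 1L),
           length(xs) - 1L)
  j <- min(max(findInterval(y, ys, rightmost.closed = TRUE), 1L),
           length(ys) - 1L)
  wx <- (x - xs[i]) / (xs[i + 1] - xs[i])
  wy <- (y - ys[j]) / (ys[j + 1] - ys[j])
  (1 - wx) * ((1 - wy) * M[i, j] + wy * M[i, j + 1]) +
    wx * ((1 - wy) * M[i + 1, j] + wy * M[i + 1, j + 1])
}

# Plain-R backward induction over the same grid semantics: inviable states
# get value 0, infeasible allocations are skipped, successor values are
# bilinearly interpolated in (length, store fraction).
r_solve_backward <- function(env, sp, mp, bp, grid) {
  L <- length(grid$lengths); S <- length(grid$fracs); Tm <- bp$t_max
  V <- array(0, dim = c(L, S, Tm + 1))
  ee <- env_expand(env, Tm)
  lat <- grid$lattice
  for (t in Tm:1) {
    for (i in seq_len(L)) {
      l <- grid$lengths[i]
      wrho <- mass_from_length(l, bp) * bp$rho
      for (j in seq_len(S)) {
        s <- grid$fracs[j] * wrho
        tr0 <- transition(l, s, 0, 0, ee$tau_C[t], ee$kappa[t],
                          ee$spawn[t], sp, mp, bp)
        if (tr0$s_raw < 0) next        # inviable: value stays 0
        best <- 0
        for (k in seq_len(nrow(lat))) {
          tr <- transition(l, s, lat$g[k], lat$r[k], ee$tau_C[t],
                           ee$kappa[t], ee$spawn[t], sp, mp, bp)
          if (!tr$feasible) next
          fn <- tr$s_next / (mass_from_length(tr$l_next, bp) * bp$rho)
          vint <- bilin_ref(grid$lengths, grid$fracs, V[, , t + 1],
                            tr$l_next, fn)
          best <- max(best, tr$repro + tr$survival * vint)
        }
        V[i, j, t] <- best
      }
    }
  }
  V
}

# Exhaustive enumeration of allocation sequences from one start state,
# rolling the continuous state forward through transition(); with
# deterministic transitions this depth-first recursion visits every policy
# sequence once and returns the best total of survival-discounted
# reproduction.
brute_force_value <- function(l, s, t, ee, sp, mp, bp, lattice, t_max) {
  if (t > t_max) return(0)
  best <- 0
  for (k in seq_len(nrow(lattice))) {
    tr <- transition(l, s, lattice$g[k], lattice$r[k], ee$tau_C[t],
                     ee$kappa[t], ee$spawn[t], sp, mp, bp)
    if (!tr$feasible) next
    val <- tr$repro + tr$survival *
      brute_force_value(tr$l_next, tr$s_next, t + 1, ee, sp, mp, bp,
                        lattice, t_max)
    best <- max(best, val)
  }
  best
}
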