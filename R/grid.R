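# State-space discretization for the dynamic programming solver.

#' State grid for the dynamic programming solver
#'
#' Discretizes the two physiological state variables: body length on a
#' geometric grid from `birth_length` to `max_length` (relative growth
#' increments are what matter, so geometric spacing keeps resolution where
#' lengths change fastest), and lipid stores as a fraction of structural-mass
#' energy on a uniform grid from 0 to `store_cap_frac` (a fractional store
#' axis keeps every node meaningful at every length; the joules at node
#' `(l, f)` are `f * w(l) * rho`). The allocation lattice is the simplex
#' lattice of `(g, r)` pairs with `g + r <= 1` at resolution
#' `1 / (n_alloc - 1)`.
#'
#' @param bp [body_params()]; supplies the length range and store cap.
#' @param n_lengths Number of length nodes, default 200.
#' @param n_stores Number of store-fraction nodes, default 51.
#' @param n_alloc Number of allocation levels per axis, default 21 (231
#'   `(g, r)` pairs at 0.05 resolution).
#'
#' @return A list of class `finlife_grid` with elements `lengths`, `fracs`,
#'   and `lattice` (a tibble of `g`, `r`).
#' @export
#' @examples
#' g <- state_grid(body_params(), n_lengths = 50, n_stores = 21, n_alloc = 11)
state_grid <- function(bp = body_params(), n_lengths = 200, n_stores = 51,
                       n_alloc = 21) {
  stopifnot(n_lengths >= 2, n_stores >= 2, n_alloc >= 2)
  lengths <- exp(seq(log(bp$birth_length), log(bp$max_length),
                     length.out = n_lengths))
  lengths[1] <- bp$birth_length
  lengths[n_lengths] <- bp$max_length
  fracs <- seq(0, bp$store_cap_frac, length.out = n_stores)
  structure(
    list(lengths = lengths, fracs = fracs,
         lattice = allocation_lattice(n_alloc)),
    class = "finlife_grid"
  )
}

#' Allocation lattice
#'
#' All pairs `(g, r) = (i, j) / (n_alloc - 1)` with `i + j <= n_alloc - 1`:
#' the candidate allocations of stored energy to growth and reproduction the
#' solver maximizes over. Contains the simplex vertices (0,0), (1,0), (0,1)
#' and has `n_alloc * (n_alloc + 1) / 2` rows.
#'
#' @param n_alloc Number of levels per axis (>= 2).
#' @return A tibble with columns `g` and `r`, each in `[0, 1]`, `g + r <= 1`.
#' @export
#' @examples
#' allocation_lattice(2)   # the three simplex corners
allocation_lattice <- function(n_alloc) {
  stopifnot(n_alloc >= 2)
  step <- n_alloc - 1L
  idx <- expand.grid(i = 0:step, j = 0:step)
  idx <- idx[idx$i + idx$j <= step, ]
  tibble::tibble(g = idx$i / step, r = idx$j / step)
}

#' @export
print.finlife_grid <- function(x, ...) {
  cat(sprintf("<state grid: %d lengths [%g, %g] cm x %d store fractions [0, %g] x %d allocations>\n",
              length(x$lengths), min(x$lengths), max(x$lengths),
              length(x$fracs), max(x$fracs), nrow(x$lattice)))
  invisible(x)
}

# Bilinear interpolation of a matrix M indexed by (lengths, fracs) at a
# single point (l, f), clamping to the grid hull. Exact at grid nodes.
interp_bilinear <- function(lengths, fracs, M, l, f) {
  l <- min(max(l, lengths[1]), lengths[length(lengths)])
  f <- min(max(f, fracs[1]), fracs[length(fracs)])
  il <- findInterval(l, lengths, rightmost.closed = TRUE)
  il <- min(max(il, 1L), length(lengths) - 1L)
  jf <- findInterval(f, fracs, rightmost.closed = TRUE)
  jf <- min(max(jf, 1L), length(fracs) - 1L)
  wl <- (l - lengths[il]) / (lengths[il + 1L] - lengths[il])
  wf <- (f - fracs[jf]) / (fracs[jf + 1L] - fracs[jf])
  (1 - wl) * ((1 - wf) * M[il, jf] + wf * M[il, jf + 1L]) +
    wl * ((1 - wf) * M[il + 1L, jf] + wf * M[il + 1L, jf + 1L])
}
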