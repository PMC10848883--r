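# Monthly state transition: the energy budget that links allocation
# decisions to next-month states and survival. This R implementation is the
# reference semantics; the C++ solver core reproduces the same arithmetic.

#' Monthly state transition
#'
#' Applies one month of the energy budget to an individual of length `l` (cm)
#' with lipid stores `s` (J) allocating fractions `g` of stores to growth and
#' `r` to reproduction:
#' * growth: `l' = (l^3 + g * s / (a * rho))^(1/3)`, capped at `max_length`;
#' * stores: `s' = (1 - g - r) * s + rho * B_prey(w) - C(w, tau)` — the
#'   unallocated stores carry over and the net energy income is added — then
#'   capped at `store_cap_frac * w(l') * rho` and floored at 0;
#' * reproduction: `s * r` joules, feasible only when spawning is permitted
#'   and within the capacity `phi * w * rho`;
#' * survival: `gamma_pred(w) * gamma_s(s'_raw, l')`, with starvation
#'   evaluated on the pre-floor stores so deficits are penalized.
#'
#' Vectorized over `l`, `s`, `g`, `r`.
#'
#' @param l Body length (cm).
#' @param s Lipid stores (J), non-negative.
#' @param g,r Allocation fractions to growth and reproduction; `g + r <= 1`.
#' @param tau_C Temperature this month (degrees C).
#' @param kappa Productivity this month.
#' @param spawn Is spawning permitted this month?
#' @param sp,mp,bp Parameter sets ([spectrum_params()], [metabolic_params()],
#'   [body_params()]).
#'
#' @return A tibble with columns `l_next`, `s_next`, `s_raw` (pre-cap,
#'   pre-floor stores), `repro` (J), `surv_pred`, `surv_starv`, `survival`,
#'   and `feasible`. Infeasible allocations (spawning out of season or
#'   exceeding the reproductive capacity) are flagged and their outcome
#'   should be excluded from any maximization.
#' @export
#' @examples
#' transition(100, 8.4e6, g = 0.5, r = 0, tau_C = 16.85, kappa = 1,
#'            spawn = TRUE)
transition <- function(l, s, g, r, tau_C, kappa, spawn = TRUE,
                       sp = spectrum_params(), mp = metabolic_params(),
                       bp = body_params()) {
  stopifnot(all(s >= 0), all(g >= -1e-12), all(r >= -1e-12),
            all(g + r <= 1 + 1e-12))
  w <- mass_from_length(l, bp)
  income <- bp$rho * sp$prey_coef * kappa * w^sp$prey_exp
  cost <- metabolic_cost(w, celsius_to_kelvin(tau_C), mp)

  feasible <- (r <= 0 | spawn) &
    (r * s <= max_reproduction(w, bp) * (1 + 1e-9))

  s_raw <- (1 - g - r) * s + income - cost
  gain <- g * s / (bp$a * bp$rho)
  # zero allocation leaves length bit-identical (cube/cube-root round trip
  # would otherwise drift by an ulp)
  l_next <- pmin(ifelse(gain == 0, l, (l^3 + gain)^(1 / 3)), bp$max_length)
  surv_starv <- starvation_survival(s_raw, l_next, bp)
  s_cap <- bp$store_cap_frac * mass_from_length(l_next, bp) * bp$rho
  s_next <- pmin(pmax(s_raw, 0), s_cap)
  surv_pred <- predation_survival(w, sp)

  tibble::tibble(
    l_next = l_next, s_next = s_next, s_raw = s_raw,
    repro = r * s,
    surv_pred = surv_pred, surv_starv = surv_starv,
    survival = surv_pred * surv_starv,
    feasible = feasible
  )
}
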