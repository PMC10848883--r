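# Allometric and physiological relationships. All functions are vectorized
# over their first argument(s) and carry no state.

#' Monthly prey biomass available to an individual
#'
#' Integrating the prey field of the size spectrum gives the per-month prey
#' biomass available to an individual of structural mass `w`:
#' `B_prey(w) = prey_coef * kappa * w^prey_exp` (kg/month), increasing and
#' concave in `w` and linear in productivity `kappa`.
#'
#' @param w Structural mass (kg), positive.
#' @param sp [spectrum_params()].
#' @return Prey biomass in kg per month.
#' @export
#' @examples
#' prey_biomass(10, spectrum_params(kappa = 1))
prey_biomass <- function(w, sp = spectrum_params()) {
  check_positive(w, "w")
  sp$prey_coef * sp$kappa * w^sp$prey_exp
}

#' Instantaneous predation mortality rate
#'
#' The predator field of the size spectrum yields a mortality rate
#' `mu_p(w) = mort_coef * h * w^mort_exp` per month, decreasing in mass:
#' larger fish have fewer gape-limited predators.
#'
#' @inheritParams prey_biomass
#' @return Mortality rate per month.
#' @export
predation_rate <- function(w, sp = spectrum_params()) {
  check_positive(w, "w")
  sp$mort_coef * sp$h * w^sp$mort_exp
}

#' Monthly survival from predation
#'
#' Converts the instantaneous predation rate to a monthly survival
#' probability, `gamma_pred(w) = exp(-mu_p(w))`.
#'
#' @inheritParams prey_biomass
#' @return Probability in (0, 1), increasing in `w`.
#' @export
predation_survival <- function(w, sp = spectrum_params()) {
  exp(-predation_rate(w, sp))
}

#' Monthly metabolic cost
#'
#' Metabolic-theory scaling of maintenance costs with mass and temperature:
#' `C(w, tau) = c * w^theta * exp(-E / (kB * tau))` in J per month, with `tau`
#' in Kelvin. Values of `tau_K` below 200 are rejected as almost certainly
#' Celsius supplied by mistake; use [celsius_to_kelvin()].
#'
#' @param w Structural mass (kg), positive.
#' @param tau_K Temperature in Kelvin (> 200).
#' @param mp [metabolic_params()].
#' @return Cost in J per month, increasing in both `w` and `tau_K`.
#' @export
#' @examples
#' metabolic_cost(1, celsius_to_kelvin(26.85))
metabolic_cost <- function(w, tau_K, mp = metabolic_params()) {
  check_positive(w, "w")
  if (any(tau_K < 200)) {
    stop("`tau_K` below 200 K; temperatures must be Kelvin ",
         "(use celsius_to_kelvin())", call. = FALSE)
  }
  mp$c * w^mp$theta * exp(-mp$E / (mp$kB * tau_K))
}

#' Length-mass conversions
#'
#' Structural mass follows the standard cubic relationship `w = a * l^3`;
#' `length_from_mass()` is its inverse `(w / a)^(1/3)`.
#'
#' @param l Body length (cm), positive.
#' @param w Structural mass (kg), positive.
#' @param bp [body_params()].
#' @return Mass in kg / length in cm.
#' @export
#' @examples
#' mass_from_length(100, body_params())   # 10 kg
#' length_from_mass(10, body_params())    # 100 cm
mass_from_length <- function(l, bp = body_params()) {
  check_positive(l, "l")
  bp$a * l^3
}

#' @rdname mass_from_length
#' @export
length_from_mass <- function(w, bp = body_params()) {
  check_positive(w, "w")
  (w / bp$a)^(1 / 3)
}

#' Maximum monthly reproductive expenditure
#'
#' Gonad capacity limits the energy spendable on reproduction in one month to
#' a fraction `phi` of structural mass: the allocation must satisfy
#' `(r * S) / rho <= phi * w`, i.e. at most `phi * w * rho` joules.
#'
#' @inheritParams mass_from_length
#' @param w Structural mass (kg).
#' @return Maximum reproductive energy in J.
#' @export
max_reproduction <- function(w, bp = body_params()) {
  check_positive(w, "w")
  bp$phi * w * bp$rho
}

#' Monthly survival from starvation
#'
#' Survival is a logistic function of lipid stores relative to the critical
#' threshold `upsilon * w(l) * rho`:
#' `gamma_s(s, l) = 1 / (1 + exp(-q * (s - upsilon * w(l) * rho)))`.
#' It equals exactly 1/2 at the threshold and, with the default sharp
#' steepness, is approximately 1 above it and 0 below it.
#'
#' @param s Lipid stores (J), non-negative allowed; the transition evaluates
#'   it on pre-floor stores which may be negative.
#' @param l Body length (cm), positive.
#' @param bp [body_params()]. `bp$q` of `NA` selects the scale-relative
#'   steepness `q = 2 log(99) / (0.01 * upsilon * w(l) * rho)`.
#' @return Probability in (0, 1), increasing in `s`.
#' @export
#' @examples
#' bp <- body_params()
#' thr <- 0.1 * mass_from_length(50, bp) * bp$rho
#' starvation_survival(thr, 50, bp)  # exactly 0.5
starvation_survival <- function(s, l, bp = body_params()) {
  check_positive(l, "l")
  thr <- bp$upsilon * mass_from_length(l, bp) * bp$rho
  z <- if (is.na(bp$q)) {
    starvation_rel_steepness() * (s / thr - 1)
  } else {
    bp$q * (s - thr)
  }
  stats::plogis(z)
}

# Relative steepness: logistic rises 0.01 -> 0.99 over 1% of the threshold,
# i.e. 2*log(99) over a relative width of 0.01.
starvation_rel_steepness <- function(width = 0.01) 2 * log(99) / width

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}
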