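# Parameter constructors. Defaults are the tuna-calibrated values used
# throughout; every field is overridable for sensitivity analysis.

#' Size-spectrum parameters
#'
#' The ecosystem size spectrum `N(w) = kappa * w^lambda` (with `lambda = -1`
#' baked into the derived intake and mortality allometries) determines both the
#' prey field and the predator field of an individual of structural mass `w`.
#' Prey biomass available per month is `prey_coef * kappa * w^prey_exp` (kg)
#' and the instantaneous predation mortality rate is
#' `mort_coef * h * w^mort_exp` (per month).
#'
#' @param kappa Spectrum scale coefficient, interpreted as ecosystem
#'   productivity (kg per month at unit mass). Must be positive. In seasonal
#'   scenarios the monthly `kappa` of the [environment
#'   schedule][constant_environment] takes precedence over this value.
#' @param h Predator capture-efficiency coefficient (dimensionless) scaling
#'   predation mortality. Must be positive.
#' @param prey_coef,prey_exp Coefficient and mass exponent of the prey-biomass
#'   allometry. The literature constants 3.0 and 0.05 are the defaults;
#'   override only for structural sensitivity checks.
#' @param mort_coef,mort_exp Coefficient and mass exponent of the predation
#'   mortality allometry, defaults 0.07 and -0.25.
#'
#' @return A list of class `finlife_spectrum`.
#' @seealso [prey_biomass()], [predation_rate()], [predation_survival()]
#' @export
#' @examples
#' sp <- spectrum_params(kappa = 1, h = 8)
#' prey_biomass(10, sp)
spectrum_params <- function(kappa = 1, h = 8,
                            prey_coef = 3, prey_exp = 0.05,
                            mort_coef = 0.07, mort_exp = -0.25) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(h), length(h) == 1L, h > 0,
            prey_coef > 0, mort_coef > 0)
  structure(
    list(kappa = kappa, h = h, prey_coef = prey_coef, prey_exp = prey_exp,
         mort_coef = mort_coef, mort_exp = mort_exp),
    class = "finlife_spectrum"
  )
}

#' Metabolic-cost parameters
#'
#' Monthly maintenance costs follow the metabolic theory of ecology:
#' `C(w, tau) = c * w^theta * exp(-E / (kB * tau))` with `tau` in Kelvin.
#'
#' @param c Normalization constant (J); default `5e16`, calibrated to tuna
#'   metabolic-rate data.
#' @param theta Mass-scaling exponent, default 0.66 (tuna estimate).
#' @param E Activation energy (J), default `1.04e-19`.
#' @param kB Boltzmann constant (m^2 kg s^-2 K^-1). The default `1.3e-23` is
#'   the (truncated) value used in the original calibration and is kept for
#'   reproducibility; pass `1.380649e-23` for the CODATA value.
#'
#' @return A list of class `finlife_metabolic`.
#' @seealso [metabolic_cost()]
#' @export
metabolic_params <- function(c = 5e16, theta = 0.66, E = 1.04e-19,
                             kB = 1.3e-23) {
  stopifnot(c > 0, theta > 0, E > 0, kB > 0)
  structure(list(c = c, theta = theta, E = E, kB = kB),
            class = "finlife_metabolic")
}

#' Body and allocation parameters
#'
#' Structural constants of the modelled individual: the cubic length-mass
#' relationship `w = a * l^3`, the tissue energy density `rho` used to convert
#' between kg and J, the starvation threshold and reproductive-capacity
#' fractions, the lipid-store ceiling, and the state/horizon bounds.
#'
#' @param a Length-mass coefficient (kg cm^-3), default `1e-5`.
#' @param rho Energy density of body mass (J kg^-1), default `4.2e6`.
#' @param upsilon Fraction of structural-mass energy below which starvation
#'   begins, default 0.1.
#' @param phi Maximum monthly reproductive output as a fraction of structural
#'   mass, default 0.2.
#' @param q Steepness of the starvation sigmoid (J^-1). The default `NA`
#'   selects a scale-relative steepness under which survival rises from 0.01
#'   to 0.99 over 1% of the threshold energy `upsilon * w * rho`, i.e. the
#'   near-step behaviour the model assumes, kept sharp at every body size.
#'   Supply a positive number for an absolute steepness.
#' @param store_cap_frac Maximum lipid stores as a fraction of structural
#'   mass, default 0.6.
#' @param birth_length Length at birth (cm), default 1.
#' @param max_length Maximum attainable length (cm), default 400.
#' @param t_max Maximum lifespan horizon in months, default 216 (18 years).
#'
#' @return A list of class `finlife_body`.
#' @export
body_params <- function(a = 1e-5, rho = 4.2e6, upsilon = 0.1, phi = 0.2,
                        q = NA_real_, store_cap_frac = 0.6,
                        birth_length = 1, max_length = 400, t_max = 216L) {
  stopifnot(a > 0, rho > 0,
            upsilon > 0, upsilon < store_cap_frac, store_cap_frac <= 1,
            phi >= 0, phi <= 1,
            is.na(q) || q > 0,
            birth_length > 0, birth_length < max_length,
            t_max >= 1)
  structure(
    list(a = a, rho = rho, upsilon = upsilon, phi = phi, q = q,
         store_cap_frac = store_cap_frac, birth_length = birth_length,
         max_length = max_length, t_max = as.integer(t_max)),
    class = "finlife_body"
  )
}

#' Temperature unit helpers
#'
#' All public interfaces in this package take temperatures in degrees Celsius
#' and convert internally; the metabolic cost function itself works in Kelvin.
#'
#' @param tau_C,tau_K Temperature in Celsius / Kelvin.
#' @return Converted temperature.
#' @export
celsius_to_kelvin <- function(tau_C) tau_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(tau_K) tau_K - 273.15

#' @export
print.finlife_spectrum <- function(x, ...) {
  cat("<size-spectrum parameters>\n")
  cat(sprintf("  kappa = %g, h = %g\n", x$kappa, x$h))
  cat(sprintf("  prey: %g * kappa * w^%g kg/month; mortality: %g * h * w^%g /month\n",
              x$prey_coef, x$prey_exp, x$mort_coef, x$mort_exp))
  invisible(x)
}

#' @export
print.finlife_metabolic <- function(x, ...) {
  cat("<metabolic parameters>\n")
  cat(sprintf("  C(w, tau) = %g * w^%g * exp(-%g / (%g * tau_K)) J/month\n",
              x$c, x$theta, x$E, x$kB))
  invisible(x)
}

#' @export
print.finlife_body <- function(x, ...) {
  cat("<body parameters>\n")
  cat(sprintf("  w = %g * l^3 kg; rho = %g J/kg\n", x$a, x$rho))
  cat(sprintf("  upsilon = %g, phi = %g, store cap = %g of structural mass\n",
              x$upsilon, x$phi, x$store_cap_frac))
  cat(sprintf("  birth %g cm, max %g cm, horizon %d months\n",
              x$birth_length, x$max_length, x$t_max))
  invisible(x)
}
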