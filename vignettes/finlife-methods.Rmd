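---
title: "Methods: state-dependent allocation in an ecosystem size spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent allocation in an ecosystem size spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finlife)
```

# The model

`finlife` predicts the life history of an individual fish — its growth
curve, reproductive schedule, survivorship and maximum body size — as the
*optimal* solution of a monthly energy-allocation problem, rather than by
fitting a growth function. The individual is embedded in an ecosystem size
spectrum, the empirical power law `N(w) = kappa * w^lambda` (with `lambda`
close to -1) relating abundance to body mass in aquatic ecosystems. An
individual's position in the spectrum fixes both sides of its ecology:

* **Intake.** The prey field (spectrum mass below the individual's own)
  integrates to a monthly prey biomass `B_prey(w) = 3 * kappa * w^0.05` kg —
  nearly flat in mass, linear in the productivity `kappa`.
* **Risk.** The predator field (spectrum mass above) yields an instantaneous
  predation mortality `mu_p(w) = 0.07 * h * w^-0.25` per month, falling with
  mass; `h` scales predator capture efficiency. Monthly survival from
  predation is `exp(-mu_p(w))`.
* **Costs.** Maintenance follows the metabolic theory of ecology,
  `C(w, tau) = c * w^theta * exp(-E / (kB * tau))` joules per month,
  increasing in mass and (Kelvin) temperature.

Two state variables are tracked monthly: body length `l` (cm), which is
irreversible, and lipid stores `s` (J), which are reversible. Structural
mass is `w = a * l^3`; mass and energy interconvert through the tissue
energy density `rho`. Each month the individual allocates fractions `g` and
`r` of its stores to growth and reproduction (`g + r <= 1`); the remainder
carries over, together with the month's net income `rho * B_prey - C`,
subject to a store ceiling of 60% of structural-mass energy:

* growth: `l' = (l^3 + g * s / (a * rho))^(1/3)`;
* stores: `s' = (1 - g - r) * s + rho * B_prey(w) - C(w, tau)`;
* reproduction: `s * r` joules, at most `phi * w * rho` per month (gonad
  capacity);
* survival: `exp(-mu_p(w))` times a starvation term (below).

Fitness is expected lifetime reproductive energy. The optimal policy
solves the dynamic programming equation

```
V(l, s, t) = max over (g, r) of [ s * r +
             gamma_pred(w) * gamma_s(s', l') * V(l', s', t + 1) ]
```

backward from `V(., ., T) = 0` at the maximum lifespan `T` (216 months).
Reproduction in the current month is credited before the survival product,
which discounts only the future value. Forward simulation from the birth
state under the stored policy then produces the emergent trajectory; no
assumption about age or size at maturation is made anywhere — maturation is
wherever the optimal `r` first turns positive.

## Starvation

If allocation and costs drive stores below a critical threshold — a
fraction `upsilon = 0.1` of structural-mass energy — survival drops through
a logistic in the deficit:
`gamma_s = 1 / (1 + exp(-q * (s' - upsilon * w(l') * rho)))`, exactly 1/2 at
the threshold. The steepness `q` is not a measured quantity; the intended
behaviour is a near-step. The default therefore makes `q` *scale-relative*:
the logistic rises from 0.01 to 0.99 over 1% of the threshold energy,
`q = 2 * log(99) / (0.01 * upsilon * w * rho)`, evaluated at the
post-transition length so the step stays equally sharp for a 1 g larva and
a 400 kg adult. An absolute `q` (J^-1) can be supplied through
`body_params(q = )`, and the starvation term is evaluated on *pre-floor*
stores so that deficits are penalized even though physical stores are
floored at zero.

## Units and conventions

All public interfaces take temperatures in degrees Celsius and convert
internally by +273.15; `metabolic_cost()` itself works in Kelvin and
rejects values below 200 K, which are almost certainly Celsius supplied by
mistake. The energy budget runs entirely in joules: prey biomass is
converted through `rho` before it enters the store dynamic, which is the
only reading under which intake, costs and stores are commensurable. The
Boltzmann constant defaults to the truncated value 1.3e-23 used in the
original calibration of the cost function (CODATA 1.380649e-23 can be
passed explicitly); with `c = 5e16` the two differ by a few percent in
`C`, which the sensitivity sweep over `c` dwarfs.

A note on store bookkeeping: a literal one-line reading of the store
dynamic would rebuild stores each month from income alone and discard the
unallocated fraction of the previous month's stores. That reading violates
energy conservation and contradicts the stated role of stores as a carrier
of surplus energy, so the package implements the conserving form above
(unallocated stores carry over, net income is added). With this form the
monthly budget closes exactly: `rho * B_prey` equals costs plus structural
growth plus reproduction plus the change in stores whenever no cap binds,
and the test suite asserts this identity.

# Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `kappa` | spectrum productivity | scenario-specific (0.1–5) | kg/month |
| `h` | predator capture efficiency | 8 (12 temperate preset) | — |
| `c` | metabolic normalization | 5e16 | J |
| `theta` | metabolic mass exponent | 0.66 | — |
| `E` | activation energy | 1.04e-19 | J |
| `kB` | Boltzmann constant | 1.3e-23 | m^2 kg s^-2 K^-1 |
| `a` | length-mass coefficient | 1e-5 | kg/cm^3 |
| `rho` | tissue energy density | 4.2e6 | J/kg |
| `upsilon` | starvation threshold fraction | 0.1 | — |
| `phi` | monthly reproductive capacity fraction | 0.2 | — |
| `store_cap_frac` | store ceiling fraction | 0.6 | — |
| `birth_length` | natal length | 1 | cm |
| `max_length` | length ceiling | 400 | cm |
| `t_max` | horizon | 216 | months |

`kappa` and `h` are the ecological dials: `kappa` scales intake linearly
and is the dominant control on emergent maximum size; `h` scales mortality
and mostly moves survivorship, not growth. `phi` matters structurally: a
smaller gonad-capacity fraction forces surplus energy into growth and
yields larger bodies (the package's sensitivity sweep reproduces this). The
natal state (1 cm, stores at the starvation threshold fraction) is a
convention; early growth is so fast that trajectories from nearby natal
states converge within months.

# Discretization and numerics

The solver discretizes length on a **geometric** grid (200 nodes from
`birth_length` to 400 cm — relative, not absolute, length increments are
what the growth map produces) and stores as a **fraction of
structural-mass energy** (51 uniform nodes on [0, 0.6]). The fractional
store axis keeps every node meaningful at every length: an absolute-joule
axis would waste most nodes at small sizes, where the feasible store range
is tiny. Allocations are searched over the simplex lattice of `(g, r)`
pairs at 0.05 resolution (231 candidates). All three resolutions are
arguments of `state_grid()`; halving or doubling them moves the birth-state
value by a few percent at most (asserted as a convergence smoke test).

Successor states almost never land on grid nodes, so the continuation
value is evaluated by **bilinear interpolation** in (length,
store-fraction); nearest-node snapping produces visible policy artifacts.
Interpolation is exact at the nodes. Ties in the maximization (within a
relative 1e-12) are broken deterministically toward higher `r`, then higher
`g`, so repeated solves are bit-identical. States whose stores would go
negative within one month even with `g = r = 0` are inviable: they carry
`V = 0` and are excluded from the maximization. Allocations that spawn out
of season or exceed gonad capacity are excluded rather than clipped — the
lattice always contains feasible alternatives. The backward sweep is
implemented in C++ (the 200 x 51 x 216 x 231 maximization is far outside
what vectorized R can do in reasonable time); the month-by-month forward
pass and every allometric function live in R, and the C++ core is tested
for exact agreement with an independent plain-R Bellman recursion and with
exhaustive enumeration of allocation sequences on instances built so that
every reachable state stays on the grid.

# Environments

Schedules are 12-month periodic cycles of temperature, productivity and a
spawning-permission mask, expanded over the horizon.
`constant_environment()` and `seasonal_environment()` construct them;
three presets encode tuna ecological lifestyles (tropical shallow-diving,
constant 26.85 C, `kappa` 0.1, `h` 8; tropical deep-diving, constant
21.85 C, `kappa` 1, `h` 8; temperate deep-diving, seasonal, winter 11.85 C
with a 3-month warm spawning season 9 C warmer, winter productivity
threefold summer at a yearly mean of 2.5, `h` 12). For the temperate
preset only the winter temperature and the yearly-mean `kappa` are given
externally; the summer values follow from the +9 C warm season and the
threefold winter productivity, solved so the 12-month mean matches (3 warm
months: summer `kappa` 1, winter 3). The warm season occupies months 1-3
of each cycle so that a natal cohort appears on the spawning grounds at
the start of the spawning season; a `warm_offset` argument rotates the
cycle. Spawning permission is an explicit monthly mask rather than a
runtime temperature rule, because the scenario family deliberately
includes a case where spawning is allowed in cold months. Seasonal
transitions are steps, not ramps — the simplest reading of a two-season
year.

# What the scenarios do and do not emulate

The scenario generator *is* the study system: there are no external data.
Constant scenarios isolate the productivity-temperature interaction;
seasonal scenarios decompose seasonality into spawning-window, thermal and
productivity components at matched yearly-mean `kappa`
(`run_seasonality_contrasts()`). What passing tests demonstrate is
therefore internal: that the solver is exactly optimal for the stated
model, and that the *emergent* patterns — asymptotic growth without any
built-in asymptote, growth-then-reproduction ontogeny, larger bodies under
higher productivity, small temperature effects, and the large effect of a
restricted spawning season — follow from the model's assumptions. They say
nothing about processes the model omits: temperature effects on encounter
and clearance rates, offspring size-number allocation, density dependence,
spatial structure and migration costs (folded into reproductive output),
or stochastic environments (mortality is the only stochastic process, and
it enters fitness as a survival product, so the forward pass is
deterministic expected-cohort bookkeeping, not Monte Carlo).

# Known limitations

The predation allometry at monthly resolution is severe at small sizes:
`mu_p` at 1 cm is about 10 per month at `h = 8`, so expected survivorship
declines extremely steeply through early life and the 3%-of-cohort
lifespan summary is reached within the first months in every default
scenario. Two consequences follow. First, survival-discounted quantities
(lifetime reproductive output, and with them the lifespan column of
scenario tables) are dominated by the first months of life and are best
read comparatively, not absolutely; the undiscounted,
conditional-on-survival reproduction series is reported alongside for this
reason. Second, because the future is so heavily discounted, optimal
growth stops earlier than it would under milder mortality, so emergent
maximum sizes are conservative — most visibly in high-intake constant
scenarios. Classic natural-mortality estimates for fish are close to this
allometry *per year*, and `spectrum_params(mort_coef = )` exposes the
coefficient for users who wish to explore slower mortality timescales; the
package defaults keep the monthly calibration of the rest of the model.

Maximum size in high-productivity scenarios is also shaped by the flatness
of net income in mass: `rho * B_prey - C` varies by only a few percent
across an order of magnitude of adult mass, so the asymptotic size is
sensitive to everything that tilts this balance (`kappa`, `c`, `theta`,
and the mortality discount), which is exactly why the sensitivity runners
exist.

# Problem sizes used by the tests and the acceptance script

Solver-correctness tests run on 4 x 5 x 6 toys where exhaustive
enumeration is possible. Emergence tests (asymptotic growth,
productivity-monotonicity, the lifestyle scenarios) use the default
200 x 51 x 231 grid over 216 months; the factorial and seasonality
orderings, which assert signs and orderings rather than values, use a
100 x 26 x 66 grid, whose orderings agree with the default grid. The
acceptance script runs everything it reports at the default resolution.

# Session

```{r}
sessionInfo()
```
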