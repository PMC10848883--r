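# Allometric and physiological relationships: frozen worked examples and
# structural properties.

test_that("prey biomass matches worked examples and is linear in kappa", {
  expect_equal(prey_biomass(1, spectrum_params(kappa = 1)), 3.0)
  expect_equal(prey_biomass(10, spectrum_params(kappa = 1)), 3.366055363,
               tolerance = 1e-10)
  expect_equal(prey_biomass(10, spectrum_params(kappa = 2)), 6.732110726,
               tolerance = 1e-10)
  set.seed(11)
  w <- 10^runif(20, -5, 3)
  k <- runif(20, 0.1, 5)
  expect_equal(prey_biomass(w, spectrum_params(kappa = 2 * k[1])),
               2 * prey_biomass(w, spectrum_params(kappa = k[1])),
               tolerance = 1e-12)
  # increasing and concave in mass
  b <- prey_biomass(sort(w), spectrum_params())
  expect_true(all(diff(b) > 0))
  expect_true(all(diff(diff(b) / diff(sort(w))) < 0))
})

test_that("predation rate and survival match worked examples", {
  expect_equal(predation_rate(1, spectrum_params(h = 1)), 0.07)
  expect_equal(predation_rate(16, spectrum_params(h = 8)), 0.28,
               tolerance = 1e-12)
  expect_equal(predation_rate(1, spectrum_params(h = 8)), 0.56,
               tolerance = 1e-12)
  expect_equal(predation_survival(16, spectrum_params(h = 8)),
               0.7557837415, tolerance = 1e-10)
  expect_equal(predation_survival(1, spectrum_params(h = 1)),
               0.9323938199, tolerance = 1e-10)
})

test_that("predation rate has the -1/4 scaling and survival is monotone", {
  set.seed(12)
  for (i in 1:10) {
    w <- 10^runif(1, -4, 2)
    h <- runif(1, 1, 16)
    sp <- spectrum_params(h = h)
    expect_equal(predation_rate(w, sp) / predation_rate(256 * w, sp), 4,
                 tolerance = 1e-12)
  }
  w <- sort(10^runif(20, -4, 3))
  g1 <- predation_survival(w, spectrum_params(h = 8))
  expect_true(all(g1 > 0 & g1 < 1))
  expect_true(all(diff(g1) > 0))
  expect_true(all(predation_survival(w, spectrum_params(h = 12)) < g1))
  # survival approaches 1 from below as mass grows
  expect_gt(predation_survival(1e12, spectrum_params(h = 8)), 0.999)
  expect_lt(predation_survival(1e12, spectrum_params(h = 8)), 1)
})

test_that("metabolic cost matches the worked example and scales as w^theta", {
  expect_equal(metabolic_cost(1, 300), 131154.6885, tolerance = 1e-9)
  set.seed(13)
  for (tau in c(285, 290, 300)) {
    w <- 10^runif(5, -3, 3)
    expect_equal(metabolic_cost(w, tau) / metabolic_cost(1, tau), w^0.66,
                 tolerance = 1e-12)
  }
  expect_equal(metabolic_cost(8, 300) / metabolic_cost(1, 300),
               3.944930818, tolerance = 1e-9)
  # increasing in temperature
  expect_true(all(diff(metabolic_cost(2, c(285, 290, 295, 300))) > 0))
})

test_that("temperatures passed in Celsius by mistake are rejected", {
  expect_error(metabolic_cost(1, 26.85), "Kelvin")
  expect_equal(celsius_to_kelvin(26.85), 300)
  expect_equal(kelvin_to_celsius(285), 11.85)
})

test_that("length-mass conversions invert each other", {
  bp <- body_params()
  expect_equal(mass_from_length(100, bp), 10)
  expect_equal(length_from_mass(10, bp), 100)
  expect_equal(mass_from_length(1, bp), 1e-5)
  set.seed(14)
  l <- 10^runif(25, 0, log10(400))
  expect_equal(length_from_mass(mass_from_length(l, bp), bp), l,
               tolerance = 1e-10)
  w <- sort(10^runif(25, -5, 3))
  expect_true(all(diff(length_from_mass(w, bp)) > 0))
})

test_that("reproductive capacity is phi * w * rho", {
  expect_equal(max_reproduction(10, body_params()), 8.4e6)
  expect_equal(max_reproduction(10, body_params(phi = 0)), 0)
})

test_that("starvation survival is a logistic centred on the threshold", {
  bp <- body_params()
  for (l in c(5, 50, 350)) {
    thr <- bp$upsilon * mass_from_length(l, bp) * bp$rho
    expect_equal(starvation_survival(thr, l, bp), 0.5)
    # sharp default: approximately a step around the threshold
    expect_gt(starvation_survival(1.02 * thr, l, bp), 0.999)
    expect_lt(starvation_survival(0.98 * thr, l, bp), 0.001)
    # logistic symmetry about the threshold
    set.seed(15)
    s <- runif(10, 0, 2 * thr)
    expect_equal(starvation_survival(s, l, bp) +
                   starvation_survival(2 * thr - s, l, bp),
                 rep(1, 10), tolerance = 1e-12)
  }
  # absolute steepness: value 10/q above the threshold gives plogis(10)
  bq <- body_params(q = 1e-6)
  thr <- bq$upsilon * mass_from_length(50, bq) * bq$rho
  expect_equal(starvation_survival(thr + 10 / bq$q, 50, bq),
               0.9999546021, tolerance = 1e-10)
})

test_that("domain errors are raised for non-positive inputs", {
  expect_error(prey_biomass(0), "positive")
  expect_error(predation_rate(-1), "positive")
  expect_error(mass_from_length(0), "positive")
  expect_error(length_from_mass(-2), "positive")
})
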