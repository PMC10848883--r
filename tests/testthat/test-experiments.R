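# Scenario runners and configuration plumbing. Solver-heavy assertions use a
# short horizon so these stay fast; orderings at the full horizon are covered
# by the acceptance tests.

fast_bp <- function(...) body_params(t_max = 24, ...)

test_that("a single factorial cell equals a direct scenario run", {
  bp <- fast_bp()
  g <- state_grid(bp, 40, 11, 6)
  fact <- run_factorial(16.85, 1, bp = bp, grid = g)
  expect_equal(nrow(fact), 1)
  direct <- run_scenario(constant_environment(16.85, 1), bp = bp, grid = g)
  expect_equal(fact$max_length_cm, direct$max_length_cm)
  expect_equal(fact$lifetime_repro_kg, direct$lifetime_repro_kg)
})

test_that("factorial tables enumerate all cells and are deterministic", {
  bp <- fast_bp()
  g <- state_grid(bp, 30, 11, 6)
  f1 <- run_factorial(c(16.85, 21.85), c(0.5, 1), bp = bp, grid = g)
  expect_equal(nrow(f1), 4)
  expect_equal(f1, run_factorial(c(16.85, 21.85), c(0.5, 1), bp = bp,
                                 grid = g))
})

test_that("temperature-effect post-processing computes percent changes", {
  fake <- tibble::tibble(
    tau_C = rep(c(10, 20), each = 2), kappa = rep(c(1, 2), 2),
    max_length_cm = c(100, 200, 90, 180)
  )
  eff <- factorial_temperature_effect(fake, "max_length_cm", 10, 20)
  expect_equal(eff$pct_change, c(-10, -10))
})

test_that("sensitivity sweeps modify exactly the requested axis", {
  bp <- fast_bp()
  g <- state_grid(bp, 30, 11, 6)
  sens <- run_sensitivity("h", c(4, 8), bp = bp, grid = g)
  expect_equal(nrow(sens), 2)
  base <- run_sensitivity("h", 8, bp = bp, grid = g)
  expect_equal(sens$max_length_cm[2], base$max_length_cm)
  # h scales mortality, not income: growth trajectories barely move but
  # survival does
  expect_lt(abs(sens$max_length_cm[1] / sens$max_length_cm[2] - 1), 0.2)
  expect_gt(sens$survival_at_t_max[1], sens$survival_at_t_max[2])
})

test_that("a stricter gonad-capacity constraint favours larger body size", {
  bp1 <- body_params(t_max = 48)
  g <- state_grid(bp1, 60, 16, 6)
  sens <- run_sensitivity("phi", c(0.1, 0.2),
                          env = constant_environment(16.85, 1),
                          bp = bp1, grid = g)
  expect_gt(sens$max_length_cm[sens$value == 0.1],
            sens$max_length_cm[sens$value == 0.2])
})

test_that("experiment configs round-trip through YAML and run end to end", {
  cfg <- as_experiment_config(list(
    grid = list(n_lengths = 30, n_stores = 11, n_alloc = 6),
    params = list(body = list(t_max = 24)),
    scenarios = list(
      list(name = "base",
           environment = list(type = "constant", tau_C = 16.85, kappa = 1)),
      list(name = "seasonal",
           environment = list(type = "seasonal", winter_tau_C = 11.85,
                              summer_tau_C = 20.85, winter_kappa = 3,
                              summer_kappa = 1, warm_months = 3),
           overrides = list(spectrum = list(h = 12)))
    ),
    seed = 1
  ))
  path <- file.path(withr::local_tempdir(), "config.yaml")
  write_experiment_config(cfg, path)
  cfg2 <- read_experiment_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))

  out <- withr::local_tempdir()
  res <- run_experiment(cfg2, out_dir = out)
  expect_equal(res$name, c("base", "seasonal"))
  expect_true(file.exists(file.path(out, "results.csv")))
  side <- jsonlite::read_json(file.path(out, "results.json"))
  expect_equal(side$package, "finlife")
  expect_equal(side$grid$n_lengths, 30)
  # byte-identical reruns
  res2 <- run_experiment(cfg2)
  expect_equal(res, res2)

  expect_error(as_experiment_config(list(scenarios = list(list(
    name = "x", environment = list(type = "orbital"))))), "type")
  expect_error(as_experiment_config(list(bogus = 1, scenarios = list(list(
    name = "x", environment = list(type = "constant"))))), "unknown")
})

test_that("plot methods return ggplot objects", {
  toy <- toy_instance()
  pol <- solve_policy(toy$env, toy$sp, toy$mp, toy$bp,
                      state_grid(toy$bp, 30, 11, 6))
  traj <- simulate_cohort(pol)
  expect_s3_class(autoplot(traj, "growth"), "ggplot")
  expect_s3_class(autoplot(traj, "allocation",
                           truncate_at_lifespan = FALSE), "ggplot")
  expect_s3_class(autoplot(pol, month = 1, what = "r"), "ggplot")
  fake <- tibble::tibble(tau_C = c(10, 10), kappa = c(1, 2),
                         max_length_cm = c(100, 150))
  expect_s3_class(plot_size_response(fake), "ggplot")
})
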