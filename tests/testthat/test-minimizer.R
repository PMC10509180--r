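# Unit tests run at reduced n_nodes for speed; the full-resolution study
# conditions are exercised in test-acceptance.R.

test_that("analytic gradient of the shape objective matches finite differences", {
  n <- 60
  f <- phagomorph:::.shape_objective(n, KAPPA, 5e-6, pi * 1e6, 12.5,
                                     lamA = 3, muA = 1e5, lamX = -2, muX = 1e5)
  base <- phagomorph:::.internal_start(rim_cap_profile(pi, 12.5, n), n)
  set.seed(11)
  for (rep in 1:3) {
    p0 <- c(base$theta[-1] + 0.25 * stats::rnorm(1) *
              sin(seq(0, 6, length.out = n - 1)), base$s1 * runif(1, 0.9, 1.1))
    ga <- as.numeric(f(p0))
    idx <- sort(sample(seq_along(p0), 20))
    for (i in idx) {
      e1 <- p0; e1[i] <- e1[i] + 1e-6
      e2 <- p0; e2[i] <- e2[i] - 1e-6
      gn <- (attr(f(e1), "objective") - attr(f(e2), "objective")) / 2e-6
      expect_equal(ga[i], gn, tolerance = 1e-4)
    }
  }
})

test_that("minimizer satisfies constraints and never beats physics", {
  cfg <- minimizer_config(n_nodes = 80, random_seed = 3)
  params <- model_params(n_nodes = 80)
  sol <- minimize_shape(params, cfg)
  expect_true(sol$converged)
  # constraint satisfaction at the reporting quadrature
  expect_equal(membrane_area(sol$profile), pi, tolerance = 1e-6)
  rim <- sol$profile$x[length(sol$profile$x)]
  expect_equal(rim, 12.5, tolerance = 1e-6 * 12.5)
  # spherical-cap candidate dominance at P = 0
  e_cap <- free_energy(rim_cap_profile(pi, 12.5, 80), params)
  expect_lt(free_energy(sol$profile, params)$bending_energy,
            e_cap$bending_energy * (1 + 1e-3))
  # an open shape cannot fall far below the closed-sphere bound
  expect_gt(sol$energy$bending_energy, 0.9 * CLOSED_SPHERE_E)
})

test_that("osmotic suction elongates the equilibrium shape", {
  cfg <- minimizer_config(n_nodes = 100, random_seed = 5)
  ar0 <- describe_shape(minimize_shape(model_params(n_nodes = 100),
                                       cfg)$profile)$aspect_ratio
  ar20 <- describe_shape(minimize_shape(
    model_params(n_nodes = 100, concentration_difference = 20),
    cfg)$profile)$aspect_ratio
  expect_gt(ar20, ar0)
  expect_gt(ar20, 1.5)   # well inside the tubular regime
})

test_that("minimization is deterministic for a fixed seed and config", {
  cfg <- minimizer_config(n_nodes = 60, random_seed = 21)
  params <- model_params(n_nodes = 60, concentration_difference = 3)
  d1 <- describe_shape(minimize_shape(params, cfg)$profile)
  d2 <- describe_shape(minimize_shape(params, cfg)$profile)
  expect_identical(d1, d2)
})

test_that("infeasible constraints are rejected before iteration", {
  expect_error(model_params(total_area = 9e-4, rim_radius = 12.5),
               "flat-double-disc")
})

test_that("non-convergence yields an explicit failure state with a profile", {
  cfg <- minimizer_config(n_nodes = 60, max_iterations = 10,
                          al_max_outer = 1, n_restarts = 1)
  sol <- minimize_shape(model_params(n_nodes = 60), cfg)
  expect_false(sol$converged)
  expect_s3_class(sol$profile, "shape_profile")
  expect_true(is.finite(sol$energy$total_free_energy))
})

test_that("converged solutions are variationally stationary", {
  cfg <- minimizer_config(n_nodes = 80, random_seed = 9)
  params <- model_params(n_nodes = 80, concentration_difference = 5)
  sol <- minimize_shape(params, cfg)
  m <- sol$internal$multipliers
  suction <- phagomorph:::.pressure_to_internal(params$pressure,
                                                params$constants)
  f <- phagomorph:::.shape_objective(80, KAPPA, suction, pi * 1e6, 12.5,
                                     lamA = m$lamA, muA = m$muA,
                                     lamX = m$lamX, muX = m$muX)
  p0 <- c(sol$internal$theta[-1], sol$internal$s1)
  f0 <- attr(f(p0), "objective")
  set.seed(2)
  t <- seq(0, 1, length.out = 79)
  for (rep in 1:8) {
    d <- rnorm(1, 0, 0.01) * sin((sample(1:6, 1) - 0.5) * pi * t)
    dp <- c(d, rnorm(1, 0, 0.5))
    expect_gt(attr(f(p0 + dp), "objective"),
              f0 - cfg$tolerance_energy * max(1, abs(f0)))
  }
})

test_that("minimized energy is stable under grid refinement", {
  for (cc in c(0, 5)) {
    params <- model_params(concentration_difference = cc)
    e1 <- minimize_shape(params,
                         minimizer_config(n_nodes = 100))$energy
    e2 <- minimize_shape(params,
                         minimizer_config(n_nodes = 200))$energy
    expect_lt(abs(e1$total_free_energy / e2$total_free_energy - 1), 5e-3)
  }
})

test_that("sweeps warm-start, classify tubularity and report per-point state", {
  cfg <- minimizer_config(n_nodes = 80, random_seed = 13)
  params <- model_params(n_nodes = 80)
  sw <- sweep_concentration(params, c(0, 2), cfg, bidirectional = FALSE)
  expect_identical(nrow(sw$results), 2L)
  expect_false(any(sw$results$tubular))
  expect_true(all(sw$results$converged))
  expect_true(is.na(tubulation_onset(sw)))
  # zero-pressure single point is spheroidal
  sw0 <- sweep_concentration(params, 0, cfg)
  expect_lt(sw0$results$aspect_ratio, 1.5)
  # descending input rejected
  expect_error(sweep_concentration(params, c(2, 1), cfg), "sorted|unsorted")
})
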