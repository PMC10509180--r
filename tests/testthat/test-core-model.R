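test_that("total curvature matches closed forms for spheres, discs and poles", {
  sph <- sphere_profile(350, n = 401)
  J <- total_curvature(sph)
  expect_equal(J[5], 2 / 350, tolerance = 1e-6)
  expect_lt(max(abs(J[2:400] - 2 / 350)), 1e-6 * (2 / 350) + 1e-9)
  expect_equal(total_curvature(sph, node_index = 5), J[5])

  # flat double disc: theta = 0 everywhere, J = 0
  disc <- shape_profile(theta = rep(0, 101), s1 = 12.5)
  expect_equal(max(abs(total_curvature(disc))), 0)

  # pole of a profile with d(theta)/ds = k: regularised limit 2k
  k <- 1 / 250
  pr <- spherical_cap_profile(1 / k, pi / 2, n = 201)
  expect_equal(total_curvature(pr, node_index = 1), 2 * k, tolerance = 1e-6)

  # x = 0 away from a pole is invalid
  bad <- sphere_profile(350, n = 101)
  bad$x[50] <- 0
  expect_error(total_curvature(bad), "away from a pole")
})

test_that("membrane area and covered volume integrate analytic shapes", {
  sph <- sphere_profile(350, n = 401)
  expect_equal(membrane_area(sph), 8 * pi * 0.35^2, tolerance = 1e-4)
  expect_equal(enclosed_volume(sph), (4 / 3) * pi * 0.35^3, tolerance = 1e-4)

  hemi <- spherical_cap_profile(350, pi / 2, n = 401)
  expect_equal(membrane_area(hemi), 4 * pi * 0.35^2, tolerance = 1e-4)
  expect_equal(enclosed_volume(hemi), (2 / 3) * pi * 0.35^3, tolerance = 1e-4)

  disc <- shape_profile(theta = rep(0, 201), s1 = 12.5)
  expect_equal(membrane_area(disc), 2 * pi * 12.5^2 * 1e-6, tolerance = 1e-6)
  expect_equal(enclosed_volume(disc), 0)
})

test_that("free energy reproduces bending examples and the energy identity", {
  p0 <- model_params()  # c = 0
  e_sph <- free_energy(sphere_profile(350, n = 401), p0)
  expect_equal(e_sph$bending_energy, CLOSED_SPHERE_E, tolerance = 1e-3)
  e_hemi <- free_energy(spherical_cap_profile(350, pi / 2, n = 401), p0)
  expect_equal(e_hemi$bending_energy, CLOSED_SPHERE_E / 2, tolerance = 1e-3)

  # osmotic work on the 350-nm sphere at 1 uM; independent hand arithmetic:
  # P = 2.520529 Pa, V = 0.1795944 um^3 -> PV = 108.15 kB*T
  p1 <- model_params(concentration_difference = 1)
  e1 <- free_energy(sphere_profile(350, n = 401), p1)
  expect_equal(abs(e1$pressure_work), 108.15, tolerance = 1e-3)
  expect_lt(e1$pressure_work, 0)  # interior depleted: work term negative
  # identity holds bit-exactly
  expect_identical(e1$total_free_energy,
                   e1$bending_energy - e1$pressure_work)
})

test_that("bending energy is scale invariant for closed spheres", {
  es <- vapply(c(100, 200, 350, 500, 1000), function(R)
    free_energy(sphere_profile(R, n = 400), model_params())$bending_energy,
    numeric(1))
  expect_lt(diff(range(es)) / mean(es), 1e-3)
})

test_that("quadrature converges and matches spherical-cap closed forms", {
  for (alpha in c(pi / 3, pi / 2, 2.2, pi)) {
    pr <- spherical_cap_profile(350, alpha, n = 400)
    expect_equal(membrane_area(pr), cap_area_um2(350, alpha),
                 tolerance = 1e-3)
    expect_equal(enclosed_volume(pr), cap_volume_um3(350, alpha),
                 tolerance = 1e-3)
    expect_equal(free_energy(pr, model_params())$bending_energy,
                 cap_bending_kBT(alpha), tolerance = 1e-3)
  }
  # doubling the node count moves area/volume/energy by < 0.1%
  for (n in c(200)) {
    a <- spherical_cap_profile(350, 2.2, n = n)
    b <- spherical_cap_profile(350, 2.2, n = 2 * n)
    expect_lt(abs(membrane_area(a) / membrane_area(b) - 1), 1e-3)
    expect_lt(abs(enclosed_volume(a) / enclosed_volume(b) - 1), 1e-3)
    pa <- model_params()
    expect_lt(abs(free_energy(a, pa)$bending_energy /
                  free_energy(b, pa)$bending_energy - 1), 1e-3)
  }
})

test_that("van't Hoff conversion is exact and inverts to machine precision", {
  expect_identical(osmotic_pressure(0), 0)
  # NA*kB = 8.31446 J/(mol K); 1 uM at 303.15 K -> 2.5205 Pa
  expect_equal(osmotic_pressure(1), 2.520529, tolerance = 1e-6)
  for (c0 in c(7.3, 0.01, 150)) {
    expect_equal(concentration_from_pressure(osmotic_pressure(c0)), c0,
                 tolerance = 1e-12)
  }
  expect_error(osmotic_pressure(-1), "non-negative")
  expect_error(concentration_from_pressure(-0.5), "non-negative")
})

test_that("equivalent sphere diameter inverts the double-membrane area", {
  expect_equal(round(equivalent_sphere_diameter(pi), 1), 0.7)
  expect_identical(equivalent_sphere_diameter(2 * pi), 1)
  expect_equal(equivalent_sphere_diameter(8 * pi * 0.35^2), 0.7,
               tolerance = 1e-12)
  expect_error(equivalent_sphere_diameter(0), "positive")
})

test_that("tagged-particle diameters reproduce the worked examples", {
  ribh <- expected_particle_diameter(15, 2)
  expect_identical(ribh$raw, 25)
  expect_identical(ribh$reported, 25)
  dps <- expected_particle_diameter(9, 2)
  expect_identical(dps$raw, 19)
  expect_identical(dps$reported, 20)
  expect_identical(expected_particle_diameter(10, 0)$raw, 10)
  expect_error(expected_particle_diameter(10, 3), "0, 1 or 2")
})

test_that("model parameter invariants are enforced", {
  expect_error(model_params(total_area = 0.99 * 2 * pi * 12.5^2 * 1e-6),
               "flat-double-disc")
  expect_error(model_params(kappa_b = -1), "positive")
  expect_error(model_params(n_nodes = 8), ">= 16")
  expect_error(model_params(concentration_difference = 5, pressure = 99),
               "van't Hoff")
  # consistent pair accepted
  p <- model_params(concentration_difference = 5,
                    pressure = osmotic_pressure(5))
  expect_equal(p$pressure, osmotic_pressure(5))
  # deriving either way round-trips
  expect_equal(model_params(pressure = 10)$concentration_difference,
               concentration_from_pressure(10))
})

test_that("shape profiles enforce pole closure and the geometric constraint", {
  expect_error(shape_profile(theta = c(0.3, 0.5, 0.7), s1 = 100), "pole")
  expect_error(shape_profile(theta = c(0, 0.1, 0.2), s = c(0, 2, 1)),
               "increasing")
  bad_x <- spherical_cap_profile(300, 2, n = 51)
  expect_error(shape_profile(theta = bad_x$theta, s = bad_x$s,
                             x = bad_x$x * seq(1, 2, length.out = 51)),
               "cos\\(theta\\)")
})
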