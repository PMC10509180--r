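test_that("descriptors recover closed-form values for reference shapes", {
  sph <- sphere_profile(350, n = 401)
  d <- describe_shape(sph)
  expect_equal(d$aspect_ratio, 1, tolerance = 1e-4)
  expect_false(d$tubular)
  expect_equal(d$im_size_nm, pi * 350, tolerance = 1e-9)
  expect_equal(d$equivalent_diameter_um, 0.7, tolerance = 1e-4)

  # opening diameter comes from the rim radius
  d2 <- describe_shape(rim_cap_profile(pi, 12.5, 201), model_params())
  expect_identical(d2$opening_diameter_nm, 25)

  # capsule with total length 3x its width
  caps <- capsule_profile(tube_radius = 150, tube_length = 600,
                          rim_radius = 1, n = 801)
  d3 <- describe_shape(caps)
  expect_equal(d3$aspect_ratio, 3, tolerance = 0.02)
  expect_true(d3$tubular)
})

test_that("describe_shape is pure and im_size bounds the axial extent", {
  profiles <- list(sphere_profile(200), spherical_cap_profile(350, 2),
                   capsule_profile(120, 800, 1, 501),
                   rim_cap_profile(pi, 12.5, 301))
  for (pr in profiles) {
    d <- describe_shape(pr)
    expect_identical(d, describe_shape(pr))
    expect_gte(d$im_size_nm, d$axial_length_nm)
  }
})
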