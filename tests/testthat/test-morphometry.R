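make_disc_image <- function(n = 64, r = 10, value = 100) {
  img <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - n / 2 - 0.5)^2 + (j - n / 2 - 0.5)^2 <= r^2) img[i, j] <- value
  img
}

test_that("segmentation counts disjoint structures and tolerates empty images", {
  img <- matrix(0, 64, 64)
  img[10:15, 10:15] <- 50
  img[40:46, 40:46] <- 80
  seg <- segment_projection(img, segmentation_config())
  expect_identical(max(seg$labels), 2L)
  # uniform image: no structures, not an error
  seg0 <- segment_projection(matrix(7, 32, 32), segmentation_config())
  expect_identical(max(seg0$labels), 0L)
  expect_identical(nrow(measure_structures(seg0, matrix(7, 32, 32))), 0L)
})

test_that("a field of seeded rings yields one label per ring", {
  cells <- expand.grid(i = 0:3, j = 0:4)
  structs <- lapply(seq_len(nrow(cells)), function(k)
    structure_ring(center = c(1200 + cells$i[k] * 2210,
                              1200 + cells$j[k] * 2210, 1500),
                   diameter = 350 + 20 * k))
  spec <- stack_spec(shape_xy = 170, n_slices = 15, structures = structs,
                     random_seed = 31)
  proj <- max_intensity_projection(render_stack(spec)$stack)
  seg <- segment_projection(proj, segmentation_config())
  expect_identical(max(seg$labels), 20L)
})

test_that("a filled digital disc is measured to circle geometry within 5%", {
  img <- make_disc_image()
  m <- measure_structures(segment_projection(img, segmentation_config()),
                          img, voxel_xy = 65)
  expect_identical(nrow(m), 1L)
  expect_equal(m$perimeter_nm, 2 * pi * 10 * 65, tolerance = 0.05)
  expect_equal(m$im_size_nm, pi * 650, tolerance = 0.05)
  expect_identical(m$im_size_nm, m$perimeter_nm / 2)
})

test_that("rendered rings and tubules are recovered from projections", {
  ren <- render_ring(600, noisy = TRUE)
  proj <- max_intensity_projection(ren$stack)
  m <- measure_structures(segment_projection(proj, segmentation_config()),
                          proj, voxel_xy = 65)
  expect_identical(m$class, "ring")
  expect_lt(abs(m$major_axis_nm - 600), max(65, 0.05 * 600))

  spec <- stack_spec(shape_xy = 160, n_slices = 17, structures = list(
    structure_tubule(center = c(5200, 5200, 1700), length = 1500,
                     width = 300)), random_seed = 7)
  proj2 <- max_intensity_projection(render_stack(spec)$stack)
  m2 <- measure_structures(segment_projection(proj2, segmentation_config()),
                           proj2, voxel_xy = 65)
  expect_identical(m2$class, "tubule")
  half_outline <- (2 * (1500 - 300) + pi * 300) / 2
  expect_lt(abs(m2$im_size_nm - half_outline), 0.1 * half_outline)
})

test_that("degenerate single-pixel components fall back to pixel metrics", {
  img <- matrix(0, 32, 32)
  img[16, 16] <- 100
  seg <- segment_projection(img, segmentation_config(smoothing_sigma = 0,
                                                     min_area = 1))
  m <- measure_structures(seg, img, voxel_xy = 65)
  expect_identical(nrow(m), 1L)
  expect_identical(m$class, "punctum")
  expect_equal(m$major_axis_nm, 65)
})

test_that("boxplot statistics follow the stated quartile and whisker rules", {
  b1 <- boxplot_stats(42)
  expect_identical(b1$median, 42)
  expect_identical(b1$q1, 42)
  expect_identical(b1$q3, 42)

  b <- boxplot_stats(1:100)
  expect_identical(b$median, 50.5)
  expect_identical(b$q1, 25.75)
  expect_identical(b$q3, 75.25)
  expect_identical(b$whisker_low, 1L)
  expect_identical(b$whisker_high, 100L)

  # outliers fall outside the whiskers
  x <- c(1:20, 100)
  bx <- boxplot_stats(x)
  expect_identical(bx$outliers, 100)
  expect_identical(bx$whisker_high, 20)

  set.seed(99)
  for (rep in 1:200) {
    x <- round(stats::rlnorm(sample(3:60, 1), 5, 0.6), 2)
    got <- boxplot_stats(x)
    want <- oracle_box(x)
    expect_equal(got[c("median", "q1", "q3", "whisker_low", "whisker_high")],
                 want, tolerance = 1e-12)
  }
})

test_that("opening sizes of distinct ring populations stay ordered", {
  meas <- list()
  for (b in 0:1) {
    dd <- if (b == 0) rep(400, 6) else rep(250, 6)
    cells <- expand.grid(i = 0:2, j = 0:1)
    structs <- lapply(1:6, function(k)
      structure_ring(center = c(1200 + cells$i[k] * 2210,
                                1200 + cells$j[k] * 2210, 1500),
                     diameter = dd[k]))
    spec <- stack_spec(shape_xy = 120, n_slices = 15, structures = structs,
                       random_seed = 50 + b)
    proj <- max_intensity_projection(render_stack(spec)$stack)
    meas[[b + 1]] <- measure_structures(
      segment_projection(proj, segmentation_config()), proj, voxel_xy = 65)
  }
  s400 <- opening_size_distribution(meas[[1]])
  s250 <- opening_size_distribution(meas[[2]])
  expect_identical(s400$n, 6L)
  expect_gt(s400$median_nm, s250$median_nm)
  # empty selection gives an explicit empty summary
  expect_identical(nrow(opening_size_distribution(meas[[1]],
                                                  classes = "tubule")), 0L)
})

test_that("the measurement pipeline is deterministic", {
  ren <- render_ring(500, noisy = TRUE, seed = 12)
  proj <- max_intensity_projection(ren$stack)
  m1 <- measure_structures(segment_projection(proj, segmentation_config()),
                           proj, voxel_xy = 65)
  m2 <- measure_structures(segment_projection(proj, segmentation_config()),
                           proj, voxel_xy = 65)
  expect_identical(m1, m2)
})
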