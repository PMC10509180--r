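test_that("maximum intensity projection is the per-pixel max over z", {
  # one bright voxel per column
  a <- array(0, c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) a[i, j, 1 + (i + j) %% 3] <- i * 10 + j
  expect_equal(max_intensity_projection(a),
               outer(1:4, 1:4, function(i, j) i * 10 + j))
  # all-zero stack
  expect_equal(max_intensity_projection(array(0, c(3, 3, 2))),
               matrix(0, 3, 3))
  # two-slice stack is the elementwise max
  b <- array(stats::runif(18), c(3, 3, 2))
  expect_equal(max_intensity_projection(b), pmax(b[, , 1], b[, , 2]))
})

test_that("noise-only stacks have the background as expected value", {
  spec <- stack_spec(shape_xy = 48, n_slices = 6, background_level = 10,
                     read_noise_sd = 0, structures = list(), random_seed = 1)
  vox <- render_stack(spec)$stack$voxels
  se <- sqrt(10 / length(vox))
  expect_lt(abs(mean(vox) - 10), 3 * se)
})

test_that("rendering conserves photons up to blur truncation", {
  spec <- stack_spec(shape_xy = 96, n_slices = 15,
                     structures = list(structure_punctum(
                       center = c(3120, 3120, 1500), diameter = 150)),
                     apply_poisson = FALSE, background_level = 0,
                     read_noise_sd = 0, random_seed = 2)
  vox <- render_stack(spec)$stack$voxels
  expect_equal(sum(vox), spec$photons_per_structure, tolerance = 1e-3)
})

test_that("a rendered ring shows its annular ridge at the true radius", {
  ren <- render_ring(600, noisy = FALSE)
  proj <- max_intensity_projection(ren$stack)
  cx <- 128 / 2
  idx <- which(proj > 0, arr.ind = TRUE)
  r_px <- round(sqrt((idx[, 1] - 0.5 - cx)^2 + (idx[, 2] - 0.5 - cx)^2))
  radial <- tapply(proj[idx], r_px, mean)
  peak_px <- as.numeric(names(radial)[which.max(radial)])
  expect_lt(abs(peak_px - 300 / 65), 1)
})

test_that("rendering is reproducible from its seed", {
  spec <- stack_spec(shape_xy = 48, n_slices = 11,
                     structures = list(structure_punctum(
                       center = c(1560, 1560, 1100), diameter = 150)),
                     random_seed = 3)
  expect_identical(render_stack(spec)$stack$voxels,
                   render_stack(spec)$stack$voxels)
  spec2 <- spec; spec2$random_seed <- 4L
  expect_false(identical(render_stack(spec)$stack$voxels,
                         render_stack(spec2)$stack$voxels))
})

test_that("structures outside the padded bounds are rejected with their index", {
  spec <- stack_spec(shape_xy = 48, n_slices = 11, structures = list(
    structure_punctum(center = c(1560, 1560, 1100), diameter = 150),
    structure_ring(center = c(200, 1560, 1100), diameter = 400)),
    random_seed = 1)
  expect_error(render_stack(spec), "structure 2")
})

test_that("Poisson sampling has variance equal to the mean", {
  base <- stack_spec(shape_xy = 12, n_slices = 4, background_level = 30,
                     read_noise_sd = 0, structures = list(), random_seed = 1)
  reps <- sapply(1:100, function(s) {
    sp <- base; sp$random_seed <- s
    as.vector(render_stack(sp)$stack$voxels)
  })
  ratio <- apply(reps, 1, stats::var) / rowMeans(reps)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("stacks round-trip through 16-bit TIFF with exact metadata", {
  spec <- stack_spec(shape_xy = 48, n_slices = 11,
                     structures = list(structure_punctum(
                       center = c(1560, 1560, 1100), diameter = 150)),
                     random_seed = 8)
  st <- render_stack(spec)$stack
  path <- tempfile(fileext = ".tiff")
  write_stack(st, path)
  rt <- read_stack(path)
  # intensities agree up to 16-bit quantisation
  expect_lt(max(abs(rt$voxels - st$voxels)), max(st$voxels) / 65535)
  expect_equal(rt$voxel_xy, st$voxel_xy)
  expect_equal(rt$voxel_z, st$voxel_z)
  expect_equal(rt$metadata$random_seed, st$metadata$random_seed)
  expect_equal(rt$metadata$spec$psf_sigma_xy, st$metadata$spec$psf_sigma_xy)
})
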