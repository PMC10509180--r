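# Shared fixtures and independent oracles.

KAPPA <- 20
CLOSED_SPHERE_E <- 16 * pi * KAPPA    # doubled Helfrich sphere energy, kB*T

# closed-form spherical-cap geometry (double membrane), radius nm, angle rad
cap_area_um2 <- function(R, alpha) 4 * pi * R^2 * (1 - cos(alpha)) * 1e-6
cap_volume_um3 <- function(R, alpha)
  (pi / 3) * R^3 * (2 - 3 * cos(alpha) + cos(alpha)^3) * 1e-9
cap_bending_kBT <- function(alpha, kappa = KAPPA) 8 * pi * kappa * (1 - cos(alpha))

# brute-force implementation of the boxplot definition: type-7 quartiles
# by the explicit interpolation formula, whiskers by scanning sorted values
oracle_box <- function(x) {
  s <- sort(x); n <- length(s)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
  hi <- NA_real_; lo <- NA_real_
  for (v in s) if (v <= q3 + 1.5 * iqr) hi <- v
  for (v in rev(s)) if (v >= q1 - 1.5 * iqr) lo <- v
  list(median = qt(0.5), q1 = q1, q3 = q3,
       whisker_low = lo, whisker_high = hi)
}

# standard single-ring stack (noiseless unless asked)
render_ring <- function(diameter, seed = 7, noisy = FALSE, shape_xy = 128) {
  ext <- shape_xy * 65
  spec <- stack_spec(
    shape_xy = shape_xy, n_slices = 15,
    structures = list(structure_ring(center = c(ext / 2, ext / 2, 1500),
                                     diameter = diameter)),
    apply_poisson = noisy,
    background_level = if (noisy) 10 else 0,
    read_noise_sd = if (noisy) 2 else 0,
    random_seed = seed)
  render_stack(spec)
}

# grid of seeded rings in batches of 10; returns truth and measurements
measure_ring_field <- function(diameters, seed0 = 100) {
  stopifnot(length(diameters) %% 10 == 0)
  out <- list()
  for (b in seq_len(length(diameters) / 10) - 1L) {
    dd <- diameters[(b * 10 + 1):(b * 10 + 10)]
    cells <- expand.grid(i = 0:3, j = 0:3)[1:10, ]
    structs <- lapply(1:10, function(k)
      structure_ring(center = c(1200 + cells$i[k] * 2210,
                                1200 + cells$j[k] * 2210, 1500),
                     diameter = dd[k]))
    spec <- stack_spec(shape_xy = 140, n_slices = 15, structures = structs,
                       random_seed = seed0 + b)
    ren <- render_stack(spec)
    proj <- max_intensity_projection(ren$stack)
    m <- measure_structures(segment_projection(proj, segmentation_config()),
                            proj, voxel_xy = 65)
    err <- vapply(1:10, function(k) {
      d2 <- (m$centroid_x_px * 65 - ren$truth$x_nm[k])^2 +
            (m$centroid_y_px * 65 - ren$truth$y_nm[k])^2
      m$major_axis_nm[which.min(d2)] - dd[k]
    }, numeric(1))
    out[[b + 1L]] <- data.frame(diameter = dd, error_nm = err)
  }
  do.call(rbind, out)
}
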