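# Synthetic fluorescence z-stacks.
#
# Ground-truth geometries (rings, puncta, cups, tubules, or model output
# profiles) are rendered as fluorophore densities on a voxel grid,
# convolved with an anisotropic Gaussian standing in for the microscope
# point-spread function, scaled to expected photon counts, Poisson-sampled
# and read-noise-corrupted.  The acquisition geometry mirrors the imaging
# protocol the morphometry rules were written for: z-stacks at 0.2-um
# intervals, maximum-intensity projection downstream.

#' Specification of a synthetic fluorescence z-stack
#'
#' @param shape_xy Lateral size of the stack in pixels (square frames).
#' @param n_slices Number of z slices.
#' @param voxel_xy Lateral pixel size, nm.  The default 65 nm is an
#'   assumption recorded with every stack (sampling a ~100x objective on a
#'   sCMOS camera), not a physical constant.
#' @param voxel_z Axial step, nm; default 200 (the acquisition z-interval).
#' @param psf_sigma_xy,psf_sigma_z Gaussian blur sigmas, nm.
#' @param photons_per_structure Expected photon count integrated over one
#'   structure.
#' @param background_level Expected background counts per voxel.
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param apply_poisson Poisson-sample the photon counts (default TRUE);
#'   disable for noiseless ground-truth renders.
#' @param structures List of structure descriptions, see
#'   [structure_ring()].
#' @param random_seed Mandatory integer seed; renders are fully
#'   reproducible from it.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(shape_xy, n_slices, voxel_xy = 65, voxel_z = 200,
                       psf_sigma_xy = 100, psf_sigma_z = 300,
                       photons_per_structure = 40000,
                       background_level = 10, read_noise_sd = 2,
                       apply_poisson = TRUE,
                       structures = list(), random_seed) {
  stopifnot(shape_xy >= 8, n_slices >= 1, voxel_xy > 0, voxel_z > 0,
            psf_sigma_xy > 0, psf_sigma_z > 0, photons_per_structure > 0,
            background_level >= 0, read_noise_sd >= 0, is.list(structures))
  if (missing(random_seed)) stop("`random_seed` is mandatory")
  structure(list(shape_xy = as.integer(shape_xy),
                 n_slices = as.integer(n_slices),
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 photons_per_structure = photons_per_structure,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 apply_poisson = isTRUE(apply_poisson),
                 structures = structures,
                 random_seed = as.integer(random_seed)),
            class = "stack_spec")
}

#' Ground-truth structures for synthetic stacks
#'
#' Constructors for the structure kinds the generator can render:
#' `ring` (a circle of fluorophore, the projected rim of an open
#' isolation membrane), `punctum` (a sub-resolution small ring),
#' `cup` (a spherical-cap shell with a polar opening), `tubule` (a
#' capsule shell) and `profile` (a [shape_profile()] revolved into a
#' shell, e.g. minimiser output).
#'
#' @param center Structure centre, nm, length-3 (x, y, z) in stack
#'   coordinates.
#' @param diameter Ring/punctum/cup diameter, nm.
#' @param length,width Tubule total length and width, nm.
#' @param orientation Euler angles (radians), applied as rotations about
#'   the z, y and x axes in that order.
#' @param opening_half_angle Polar half-angle of the cup opening, radians.
#' @param profile A [shape_profile()] for `structure_profile()`.
#' @param photons Optional per-structure photon count overriding the
#'   spec-level `photons_per_structure`.
#' @return A list describing the structure (class `ground_truth_structure`).
#' @export
structure_ring <- function(center, diameter, orientation = c(0, 0, 0),
                           photons = NULL) {
  .gt_structure("ring", center, orientation, photons, diameter = diameter)
}

#' @rdname structure_ring
#' @export
structure_punctum <- function(center, diameter = 100,
                              orientation = c(0, 0, 0), photons = NULL) {
  .gt_structure("punctum", center, orientation, photons, diameter = diameter)
}

#' @rdname structure_ring
#' @export
structure_cup <- function(center, diameter, opening_half_angle = pi / 3,
                          orientation = c(0, 0, 0), photons = NULL) {
  .gt_structure("cup", center, orientation, photons, diameter = diameter,
                opening_half_angle = opening_half_angle)
}

#' @rdname structure_ring
#' @export
structure_tubule <- function(center, length, width,
                             orientation = c(0, 0, 0), photons = NULL) {
  stopifnot(length >= width)
  .gt_structure("tubule", center, orientation, photons,
                length = length, width = width)
}

#' @rdname structure_ring
#' @export
structure_profile <- function(center, profile, orientation = c(0, 0, 0),
                              photons = NULL) {
  stopifnot(inherits(profile, "shape_profile"))
  .gt_structure("profile", center, orientation, photons, profile = profile)
}

.gt_structure <- function(kind, center, orientation, photons, ...) {
  stopifnot(length(center) == 3L, is.numeric(center),
            length(orientation) == 3L)
  structure(c(list(kind = kind, center = as.numeric(center),
                   orientation = as.numeric(orientation),
                   photons = photons), list(...)),
            class = "ground_truth_structure")
}

# rotation about z, then y, then x
.euler_rotate <- function(pts, ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  pts %*% t(Rx %*% Ry %*% Rz)
}

# deterministic point sampling; returns matrix of xyz (nm, centred) and
# equal/area weights summing to 1
.sample_structure_points <- function(st, step = 12) {
  if (st$kind %in% c("ring", "punctum")) {
    r <- st$diameter / 2
    npt <- max(96L, ceiling(2 * pi * r / (step / 4)))
    phi <- seq(0, 2 * pi, length.out = npt + 1L)[-1L]
    pts <- cbind(r * cos(phi), r * sin(phi), 0)
    wt <- rep(1 / npt, npt)
  } else if (st$kind == "cup") {
    R <- st$diameter / 2
    psi <- seq(st$opening_half_angle, pi, length.out = max(40L, ceiling(R * pi / step)))
    nphi <- max(48L, ceiling(2 * pi * R / step))
    phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-1L]
    g <- expand.grid(psi = psi, phi = phi)
    pts <- cbind(R * sin(g$psi) * cos(g$phi), R * sin(g$psi) * sin(g$phi),
                 R * cos(g$psi))
    wt <- sin(g$psi); wt <- wt / sum(wt)
  } else if (st$kind == "tubule") {
    r <- st$width / 2
    lc <- st$length - st$width           # cylinder part
    nphi <- max(48L, ceiling(2 * pi * r / step))
    phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-1L]
    # capsule axis along x so tubules lie in-plane by default
    zc <- seq(-lc / 2, lc / 2, length.out = max(8L, ceiling(lc / step)))
    gc <- expand.grid(z = zc, phi = phi)
    cyl <- cbind(gc$z, r * cos(gc$phi), r * sin(gc$phi))
    wcyl <- rep(1, nrow(cyl))
    psi <- seq(0, pi / 2, length.out = max(12L, ceiling(r * pi / 2 / step)))
    gcap <- expand.grid(psi = psi, phi = phi)
    cap1 <- cbind(lc / 2 + r * cos(gcap$psi),
                  r * sin(gcap$psi) * cos(gcap$phi),
                  r * sin(gcap$psi) * sin(gcap$phi))
    cap2 <- cap1; cap2[, 1] <- -cap1[, 1]
    wcap <- sin(gcap$psi) * (pi * r / 2 / length(psi)) / (lc / length(zc) + 1e-12)
    if (lc <= 0) { cyl <- cyl[0, , drop = FALSE]; wcyl <- numeric(0); wcap <- sin(gcap$psi) }
    pts <- rbind(cyl, cap1, cap2)
    wt <- c(wcyl, wcap, wcap); wt <- wt / sum(wt)
  } else if (st$kind == "profile") {
    pr <- st$profile
    ns <- length(pr$s)
    ds <- c(diff(pr$s)[1], diff(pr$s))
    nphi <- max(48L, ceiling(2 * pi * max(pr$x) / step))
    phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-1L]
    g <- expand.grid(i = seq_len(ns), phi = phi)
    pts <- cbind(pr$x[g$i] * cos(g$phi), pr$x[g$i] * sin(g$phi),
                 pr$z[g$i] - (max(pr$z) + min(pr$z)) / 2)
    wt <- pr$x[g$i] * ds[g$i]
    keep <- wt > 0
    pts <- pts[keep, , drop = FALSE]; wt <- wt[keep]
    wt <- wt / sum(wt)
  } else stop("unknown structure kind: ", st$kind)
  list(points = .euler_rotate(pts, st$orientation), weights = wt)
}

.gaussian_band <- function(npix, sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  K <- matrix(0, npix, npix)
  for (d in seq(-r, r)) {
    i <- seq_len(npix)
    j <- i + d
    ok <- j >= 1 & j <= npix
    K[cbind(i[ok], j[ok])] <- k[d + r + 1L]
  }
  K
}

# separable anisotropic Gaussian blur of a (nx, ny, nz) array;
# zero boundary, photon mass conserved up to edge truncation
.blur_stack <- function(arr, sigma_xy_px, sigma_z_px) {
  d <- dim(arr)
  Kxy <- .gaussian_band(d[1], sigma_xy_px)
  if (d[2] != d[1]) Ky <- .gaussian_band(d[2], sigma_xy_px) else Ky <- Kxy
  for (k in seq_len(d[3]))
    arr[, , k] <- Kxy %*% arr[, , k] %*% t(Ky)
  if (d[3] > 1L) {
    Kz <- .gaussian_band(d[3], sigma_z_px)
    m <- matrix(arr, d[1] * d[2], d[3]) %*% t(Kz)
    arr <- array(m, d)
  }
  arr
}

#' Render a synthetic fluorescence z-stack
#'
#' Integrates the fluorophore density of every structure into the voxel
#' grid, applies the anisotropic Gaussian blur, scales to photons, adds
#' the background, Poisson-samples (unless disabled) and adds Gaussian
#' read noise.  Structures whose geometry (plus a 3-sigma blur pad) falls
#' outside the stack are rejected with their index.
#'
#' @param spec A [stack_spec()].
#' @return A list with `stack` (class `image_stack`: `voxels` array
#'   indexed x, y, z; voxel sizes; metadata) and `truth` (data frame with
#'   one row of true geometry per structure).
#' @export
render_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  d <- c(spec$shape_xy, spec$shape_xy, spec$n_slices)
  ext <- d * c(spec$voxel_xy, spec$voxel_xy, spec$voxel_z)
  pad <- 3 * c(spec$psf_sigma_xy, spec$psf_sigma_xy, spec$psf_sigma_z)
  signal <- array(0, d)
  truth <- list()
  for (i in seq_along(spec$structures)) {
    st <- spec$structures[[i]]
    sp <- .sample_structure_points(st, step = spec$voxel_xy / 4)
    pts <- sweep(sp$points, 2, st$center, `+`)
    if (any(pts < rep(pad, each = nrow(pts))) ||
        any(pts > rep(ext - pad, each = nrow(pts))))
      stop("structure ", i, " (", st$kind,
           ") out of stack bounds after blur padding")
    ix <- floor(pts[, 1] / spec$voxel_xy) + 1L
    iy <- floor(pts[, 2] / spec$voxel_xy) + 1L
    iz <- floor(pts[, 3] / spec$voxel_z) + 1L
    idx <- (iz - 1L) * d[1] * d[2] + (iy - 1L) * d[1] + ix
    photons <- if (is.null(st$photons)) spec$photons_per_structure else st$photons
    acc <- rowsum(sp$weights * photons, idx)
    signal[as.integer(rownames(acc))] <- signal[as.integer(rownames(acc))] + acc
    truth[[i]] <- data.frame(
      index = i, kind = st$kind,
      x_nm = st$center[1], y_nm = st$center[2], z_nm = st$center[3],
      diameter_nm = if (!is.null(st$diameter)) st$diameter else NA_real_,
      length_nm = if (!is.null(st$length)) st$length else NA_real_,
      width_nm = if (!is.null(st$width)) st$width else NA_real_,
      photons = photons)
  }
  blurred <- .blur_stack(signal, spec$psf_sigma_xy / spec$voxel_xy,
                         spec$psf_sigma_z / spec$voxel_z)
  expected <- blurred + spec$background_level
  vox <- .with_seed(spec$random_seed, {
    v <- if (spec$apply_poisson)
      array(stats::rpois(length(expected), expected), d)
    else expected
    if (spec$read_noise_sd > 0)
      v <- v + array(stats::rnorm(length(v), 0, spec$read_noise_sd), d)
    v
  })
  vox[vox < 0] <- 0
  stack <- structure(
    list(voxels = vox, voxel_xy = spec$voxel_xy, voxel_z = spec$voxel_z,
         metadata = list(spec = spec[setdiff(names(spec), "structures")],
                         n_structures = length(spec$structures),
                         random_seed = spec$random_seed)),
    class = "image_stack")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(index = integer(), kind = character(), x_nm = numeric(),
               y_nm = numeric(), z_nm = numeric(), diameter_nm = numeric(),
               length_nm = numeric(), width_nm = numeric(),
               photons = numeric())
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (%g nm xy, %g nm z)\n",
              d[1], d[2], d[3], x$voxel_xy, x$voxel_z))
  invisible(x)
}

#' Maximum-intensity projection of a stack
#'
#' Per-pixel maximum over the z dimension, the standard reduction applied
#' to the acquired z-stacks before morphometry.
#'
#' @param stack An `image_stack` (or a plain 3D array).
#' @return A matrix (x by y) with attribute `voxel_xy`.
#' @export
max_intensity_projection <- function(stack) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  stopifnot(length(dim(vox)) == 3L)
  proj <- Reduce(pmax, lapply(seq_len(dim(vox)[3]), function(k) vox[, , k]))
  if (inherits(stack, "image_stack"))
    attr(proj, "voxel_xy") <- stack$voxel_xy
  proj
}

#' Write / read a stack as 16-bit multi-page TIFF
#'
#' Intensities are scaled by a recorded gain to the 16-bit range; the gain,
#' voxel sizes and metadata are stored in a JSON sidecar next to the TIFF
#' so that metadata round-trips exactly.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @return `write_stack()` the paths invisibly; `read_stack()` an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$voxels)
  gain <- if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(stack$voxels)[3]), function(k)
    t(round(stack$voxels[, , k] * gain)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(gain = gain, voxel_xy = stack$voxel_xy, voxel_z = stack$voxel_z,
         dim = dim(stack$voxels), metadata = stack$metadata),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(c(path, sidecar))
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  vox <- array(0, d)
  for (k in seq_len(d[3])) vox[, , k] <- t(pages[[k]]) / meta$gain
  structure(list(voxels = vox, voxel_xy = meta$voxel_xy,
                 voxel_z = meta$voxel_z, metadata = meta$metadata),
            class = "image_stack")
}
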