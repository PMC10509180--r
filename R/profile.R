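# Axisymmetric shape profiles and geometric quantities.
#
# A profile is the meridian of a surface of revolution, parametrised by arc
# length s from the closed pole (s = 0, on the symmetry axis) to the open
# rim (s = s1).  theta(s) is the tilt of the meridian tangent against the
# plane normal to the axis, so dx/ds = cos(theta) and dz/ds = sin(theta).

# trapezoid rule on a (possibly non-uniform) grid
.trapz <- function(s, y) sum(diff(s) * (y[-length(y)] + y[-1]) / 2)

#' Construct an axisymmetric shape profile
#'
#' Builds a discretised meridian profile from arc-length positions and tilt
#' angles.  The profile starts at a smoothly closed pole (`x[1] = 0`,
#' `theta[1] = 0`).  If the radial (`x`) and axial (`z`) coordinates are not
#' supplied they are recovered by trapezoidal integration of
#' `dx/ds = cos(theta)`, `dz/ds = sin(theta)`.  If `x` is supplied, the
#' geometric constraint is checked at interior nodes.
#'
#' @param theta Tilt angles (radians), one per node; `theta[1]` must be 0.
#' @param s Arc-length positions (nm), strictly increasing from 0.  May be
#'   omitted if `s1` is given, in which case a uniform grid is used.
#' @param s1 Total meridian arc length (nm); defaults to `max(s)`.
#' @param x,z Optional radial/axial coordinates (nm) at the nodes.
#' @param check Logical; verify profile invariants (default `TRUE`).
#'
#' @return An object of class `shape_profile`: list with fields `s`,
#'   `theta`, `x`, `z`, `s1`.
#' @examples
#' pr <- sphere_profile(350)
#' membrane_area(pr)     # 8*pi*0.35^2 um^2
#' @export
shape_profile <- function(theta, s = NULL, s1 = NULL, x = NULL, z = NULL,
                          check = TRUE) {
  n <- length(theta)
  if (n < 3L) stop("a profile needs at least 3 nodes")
  if (is.null(s)) {
    if (is.null(s1)) stop("give either `s` or `s1`")
    s <- seq(0, s1, length.out = n)
  }
  if (is.null(s1)) s1 <- s[n]
  if (length(s) != n) stop("`s` and `theta` lengths differ")
  if (check) {
    if (s[1] != 0) stop("`s` must start at 0")
    if (any(diff(s) <= 0)) stop("`s` must be strictly increasing")
    if (abs(theta[1]) > 1e-8)
      stop("`theta[1]` must be 0 (smooth closure at the pole)")
  }
  ct <- cos(theta); st <- sin(theta)
  if (is.null(x)) x <- cumsum(c(0, diff(s) * (ct[-n] + ct[-1]) / 2))
  if (is.null(z)) z <- cumsum(c(0, diff(s) * (st[-n] + st[-1]) / 2))
  if (check) {
    if (abs(x[1]) > 1e-8) stop("`x[1]` must be 0 (profile starts on the axis)")
    if (any(x < -1e-6 * s1))
      stop("radial coordinate `x` must be non-negative")
    # geometric constraint dx/ds = cos(theta) at interior nodes
    dxds <- (x[3:n] - x[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
    err <- max(abs(dxds - ct[2:(n - 1)]))
    h <- max(diff(s))
    if (err > 0.05 + 5 * h / s1)
      stop("profile violates dx/ds = cos(theta) (max deviation ",
           format(err, digits = 3), ")")
  }
  structure(list(s = s, theta = theta, x = x, z = z, s1 = s1),
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("shape_profile: %d nodes, s1 = %.1f nm, rim x = %.2f nm\n",
              length(x$s), x$s1, x$x[length(x$x)]))
  cat(sprintf("  area %.4f um^2, volume %.4f um^3\n",
              membrane_area(x), enclosed_volume(x)))
  invisible(x)
}

#' @export
as.data.frame.shape_profile <- function(x, ...) {
  data.frame(s_nm = x$s, theta_rad = x$theta, x_nm = x$x, z_nm = x$z)
}

#' Analytic profiles: spheres, caps and capsules
#'
#' `sphere_profile()` is a fully closed sphere (`theta` runs 0..pi).
#' `spherical_cap_profile()` stops at polar angle `cap_angle`.
#' `rim_cap_profile()` is the near-closed spherical cap whose total
#' (double-membrane) area and rim radius match the given constraints
#' exactly; it is the analytic reference candidate used to initialise the
#' minimiser.  `capsule_profile()` is a cylinder of radius `tube_radius`
#' and length `tube_length` closed by a hemisphere at the pole and by a
#' near-complete spherical cap that comes back to `rim_radius` at the rim.
#'
#' @param radius Sphere radius, nm.
#' @param cap_angle Polar angle at which the cap stops, radians in (0, pi].
#' @param total_area Total membrane area (both membranes), um^2.
#' @param rim_radius Rim radius, nm.
#' @param tube_radius Cylinder radius, nm.
#' @param tube_length Cylinder length, nm.
#' @param n Number of nodes.
#' @return A [shape_profile()].
#' @examples
#' spherical_cap_profile(350, pi / 2)   # hemisphere
#' rim_cap_profile(pi, 12.5)
#' @export
sphere_profile <- function(radius, n = 401) {
  spherical_cap_profile(radius, pi, n)
}

#' @rdname sphere_profile
#' @export
spherical_cap_profile <- function(radius, cap_angle, n = 401) {
  stopifnot(radius > 0, cap_angle > 0, cap_angle <= pi)
  s <- seq(0, radius * cap_angle, length.out = n)
  theta <- s / radius
  shape_profile(theta = theta, s = s,
                x = radius * sin(theta), z = radius * (1 - cos(theta)))
}

#' @rdname sphere_profile
#' @export
rim_cap_profile <- function(total_area = pi, rim_radius = 12.5, n = 401) {
  area_nm2 <- total_area * 1e6
  u <- 2 - 4 * pi * rim_radius^2 / area_nm2
  if (u <= 0) stop("`total_area` below the flat-double-disc bound")
  radius <- sqrt(area_nm2 / (4 * pi * u))
  spherical_cap_profile(radius, acos(1 - u), n)
}

#' @rdname sphere_profile
#' @export
capsule_profile <- function(tube_radius, tube_length, rim_radius = 1,
                            n = 401) {
  stopifnot(tube_radius > 0, tube_length >= 0, rim_radius <= tube_radius)
  psi_top <- pi - asin(min(rim_radius / tube_radius, 1))
  s_b <- tube_radius * pi / 2
  s_t <- tube_radius * (psi_top - pi / 2)
  s1 <- s_b + tube_length + s_t
  s <- seq(0, s1, length.out = n)
  theta <- ifelse(s < s_b, s / tube_radius,
           ifelse(s < s_b + tube_length, pi / 2,
                  pi / 2 + (s - s_b - tube_length) / tube_radius))
  shape_profile(theta = theta, s = s)
}

# capsule matched (approximately) to an area/rim constraint; used as the
# elongated-branch starting candidate for the minimiser
.capsule_for_constraints <- function(total_area, rim_radius, tube_radius, n) {
  area_nm2 <- total_area * 1e6
  psi_top <- pi - asin(min(rim_radius / tube_radius, 1))
  cap_area <- 4 * pi * tube_radius^2 * (1 - cos(psi_top))
  len <- max((area_nm2 - cap_area) / (4 * pi * tube_radius), 25)
  capsule_profile(tube_radius, len, rim_radius, n)
}

#' Total curvature along a profile
#'
#' Returns the total curvature \eqn{J = d\theta/ds + \sin\theta/x} (the sum
#' of the two principal curvatures) at every node, or at one node if
#' `node_index` is given.  At poles (x -> 0 with sin(theta) -> 0) the
#' removable singularity is replaced by its analytic limit
#' \eqn{2\,d\theta/ds}.  A vanishing `x` away from a pole makes the
#' curvature non-finite and signals an invalid profile.
#'
#' @param profile A [shape_profile()].
#' @param node_index Optional single node index.
#' @return Total curvature (1/nm), vector or scalar.
#' @examples
#' total_curvature(sphere_profile(350))[5]   # 2/350
#' @export
total_curvature <- function(profile, node_index = NULL) {
  s <- profile$s; th <- profile$theta; x <- profile$x
  n <- length(s)
  dth <- numeric(n)
  dth[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  dth[1] <- (th[2] - th[1]) / (s[2] - s[1])
  dth[n] <- (th[n] - th[n - 1]) / (s[n] - s[n - 1])
  pole <- x < 1e-6 * profile$s1
  bad <- pole & (abs(sin(th)) > 1e-3)
  if (any(bad))
    stop("x = 0 away from a pole at node(s) ",
         paste(which(bad), collapse = ", "), ": invalid profile")
  J <- ifelse(pole, 2 * dth, dth + sin(th) / ifelse(pole, 1, x))
  if (!is.null(node_index)) {
    stopifnot(node_index >= 1, node_index <= n)
    return(J[node_index])
  }
  J
}

#' Membrane area and covered volume of a profile
#'
#' `membrane_area()` integrates \eqn{A = 4\pi\int_0^{s_1} x\,ds}; the factor
#' 4 (rather than 2) counts both juxtaposed membranes of the cisterna.
#' `enclosed_volume()` integrates \eqn{V = \pi\int_0^{s_1} x^2\sin\theta\,ds},
#' the volume covered by the membrane.  Both use the composite trapezoidal
#' rule on the profile's node grid, so results are deterministic for a
#' given profile.
#'
#' @param profile A [shape_profile()].
#' @return Area in um^2 / volume in um^3.
#' @examples
#' membrane_area(sphere_profile(350))   # 8*pi*0.35^2 = 3.0788
#' enclosed_volume(sphere_profile(350)) # (4/3)*pi*0.35^3 = 0.17959
#' @export
membrane_area <- function(profile) {
  4 * pi * .trapz(profile$s, profile$x) * 1e-6
}

#' @rdname membrane_area
#' @export
enclosed_volume <- function(profile) {
  pi * .trapz(profile$s, profile$x^2 * sin(profile$theta)) * 1e-9
}
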