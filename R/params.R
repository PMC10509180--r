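#' Parameters of the isolation-membrane shape model
#'
#' Collects the physical parameters of the axisymmetric double-membrane
#' model: bending modulus, rim (opening) radius, total membrane area,
#' osmotic pressure difference (or, equivalently, the concentration
#' difference of excluded particles from which it follows by the van't
#' Hoff relation), and the discretisation size.
#'
#' The membrane is a single axisymmetric surface standing for two closely
#' juxtaposed membranes with the same curvature and area, so the bending
#' energy and the area are counted twice: the total area of a closed sphere
#' of radius R is \eqn{8\pi R^2} and its bending energy \eqn{16\pi\kappa_b}.
#' The area must exceed the flat-double-disc lower bound
#' \eqn{2\pi x_r^2} for a rim of radius \eqn{x_r}.
#'
#' `concentration_difference` is the excess concentration of
#' membrane-excluded particles in the cytoplasm relative to the covered
#' interior (non-negative, in uM); `pressure` is the matching osmotic
#' pressure difference (Pa).  Give either one; if both are given they must
#' agree through the van't Hoff relation to within 1e-9 relative.
#'
#' @param kappa_b Bending modulus of one membrane, in units of kB*T.
#'   Default 20.
#' @param rim_radius Radius of the open rim, nm. Default 12.5 (a 25-nm
#'   opening, the particle-exclusion cut-off measured for
#'   sorting-nexin-deficient cells).
#' @param total_area Total membrane area (both membranes), um^2.
#'   Default `pi`, matching a ~0.7-um autophagosome.
#' @param concentration_difference Excluded-particle concentration
#'   difference, uM (non-negative), or `NULL`.
#' @param pressure Osmotic pressure difference, Pa (non-negative), or
#'   `NULL`.  Defaults to 0 when neither is given.
#' @param n_nodes Number of discretisation nodes along the meridian
#'   (>= 16). Default 200.
#' @param constants A [physical_constants()] object.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params()
#' model_params(concentration_difference = 5)
#' @export
model_params <- function(kappa_b = 20,
                         rim_radius = 12.5,
                         total_area = pi,
                         concentration_difference = NULL,
                         pressure = NULL,
                         n_nodes = 200,
                         constants = physical_constants()) {
  stopifnot(is.numeric(kappa_b), length(kappa_b) == 1L, is.finite(kappa_b),
            is.numeric(rim_radius), length(rim_radius) == 1L,
            is.numeric(total_area), length(total_area) == 1L,
            inherits(constants, "physical_constants"))
  if (kappa_b <= 0) stop("`kappa_b` must be positive")
  if (rim_radius <= 0) stop("`rim_radius` must be positive")
  area_nm2 <- total_area * 1e6
  if (area_nm2 <= 2 * pi * rim_radius^2)
    stop("`total_area` must exceed the flat-double-disc bound 2*pi*rim_radius^2")
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 16L) stop("`n_nodes` must be an integer >= 16")

  if (is.null(concentration_difference) && is.null(pressure)) {
    concentration_difference <- 0
    pressure <- 0
  } else if (is.null(pressure)) {
    pressure <- osmotic_pressure(concentration_difference, constants)
  } else if (is.null(concentration_difference)) {
    concentration_difference <- concentration_from_pressure(pressure, constants)
  } else {
    implied <- osmotic_pressure(concentration_difference, constants)
    rel <- abs(pressure - implied) / max(abs(implied), 1e-300)
    if (implied == 0 && pressure == 0) rel <- 0
    if (rel > 1e-9)
      stop("`pressure` and `concentration_difference` disagree under the ",
           "van't Hoff relation (relative difference ", format(rel), ")")
  }

  structure(
    list(kappa_b = kappa_b,
         rim_radius = rim_radius,
         total_area = total_area,
         pressure = pressure,
         concentration_difference = concentration_difference,
         n_nodes = n_nodes,
         constants = constants),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Isolation-membrane model parameters:\n")
  cat(sprintf("  kappa_b    = %g kB*T per membrane\n", x$kappa_b))
  cat(sprintf("  rim radius = %g nm (opening %g nm)\n",
              x$rim_radius, 2 * x$rim_radius))
  cat(sprintf("  total area = %g um^2 (equiv. sphere %.3f um)\n",
              x$total_area, equivalent_sphere_diameter(x$total_area)))
  cat(sprintf("  c = %g uM, Pi = %g Pa (T = %g K)\n",
              x$concentration_difference, x$pressure,
              x$constants$temperature))
  cat(sprintf("  n_nodes = %d\n", x$n_nodes))
  invisible(x)
}
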