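#' Free energy of an axisymmetric membrane shape
#'
#' Evaluates the elastic-bending free energy of the double-membrane
#' cisterna,
#' \deqn{F = 2\pi \int_0^{s_1} \kappa_b\, x \left(\dot\theta +
#'   \frac{\sin\theta}{x}\right)^2 ds \;-\; P V,}
#' where the prefactor (twice the per-membrane Helfrich coefficient
#' \eqn{\kappa_b/2}) counts the two juxtaposed membranes, and
#' \eqn{P} is the trans-membrane pressure difference (inside minus
#' outside).  When large particles are excluded from the covered interior
#' the interior is osmotically depleted, so \eqn{P = -\Pi} with
#' \eqn{\Pi \ge 0} the van't Hoff osmotic pressure stored in
#' `params$pressure`; the pressure work \eqn{P V} is then negative and the
#' total free energy is `bending_energy - pressure_work`
#' \eqn{= E_{bend} + \Pi V}, which penalises covered volume and drives
#' tubulation.
#'
#' Quadrature is the composite trapezoidal rule on the profile grid, with
#' total curvature from [total_curvature()] (pole-regularised).
#'
#' @param profile A [shape_profile()].
#' @param params A [model_params()].
#' @return An object of class `energy_report`: list with
#'   `bending_energy`, `pressure_work`, `total_free_energy` (all kB*T,
#'   `total_free_energy = bending_energy - pressure_work` exactly),
#'   `volume` (um^3), `area` (um^2), `rim_radius` (nm), `temperature` (K).
#' @examples
#' free_energy(sphere_profile(350), model_params(rim_radius = 1e-3))
#' @export
free_energy <- function(profile, params) {
  stopifnot(inherits(profile, "shape_profile"), inherits(params, "model_params"))
  J <- total_curvature(profile)
  bending <- 2 * pi * params$kappa_b * .trapz(profile$s, profile$x * J^2)
  v_nm3 <- pi * .trapz(profile$s, profile$x^2 * sin(profile$theta))
  pi_int <- .pressure_to_internal(params$pressure, params$constants)
  pressure_work <- -pi_int * v_nm3          # P = -Pi (interior depleted)
  structure(
    list(bending_energy = bending,
         pressure_work = pressure_work,
         total_free_energy = bending - pressure_work,
         volume = v_nm3 * 1e-9,
         area = membrane_area(profile),
         rim_radius = profile$x[length(profile$x)],
         temperature = params$constants$temperature),
    class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("Membrane free energy (kB*T):\n")
  cat(sprintf("  bending      %10.3f\n", x$bending_energy))
  cat(sprintf("  pressure P*V %10.3f\n", x$pressure_work))
  cat(sprintf("  total F      %10.3f\n", x$total_free_energy))
  cat(sprintf("  area %.4f um^2, volume %.5f um^3, rim %.2f nm, T %.2f K\n",
              x$area, x$volume, x$rim_radius, x$temperature))
  invisible(x)
}
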