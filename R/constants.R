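# Physical constants and unit conversions.
#
# Internal unit system: lengths nm, areas reported in um^2, volumes in um^3,
# energies in units of kB*T, pressures in Pa.  1 Pa * 1 um^3 = 1e-18 J.

#' Physical constants for the membrane model
#'
#' Bundles the Boltzmann constant, the Avogadro number and the absolute
#' temperature used throughout the package.  Every energy reported by the
#' package is expressed in units of \eqn{k_B T} at this temperature, and the
#' van't Hoff conversion between osmotic pressure and particle concentration
#' uses the same values.  The default temperature is 303.15 K (30 degrees C,
#' a standard budding-yeast culture temperature).
#'
#' @param temperature Absolute temperature in kelvin.
#' @param boltzmann_constant Boltzmann constant in J/K.
#' @param avogadro_number Avogadro number in 1/mol.
#'
#' @return An object of class `physical_constants`: a list with fields
#'   `boltzmann_constant`, `avogadro_number`, `temperature` and the derived
#'   `kBT_joule` (thermal energy in joule).
#' @examples
#' physical_constants()
#' physical_constants(temperature = 298.15)
#' @export
physical_constants <- function(temperature = 303.15,
                               boltzmann_constant = 1.380649e-23,
                               avogadro_number = 6.02214076e23) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            boltzmann_constant > 0, avogadro_number > 0)
  structure(
    list(boltzmann_constant = boltzmann_constant,
         avogadro_number = avogadro_number,
         temperature = temperature,
         kBT_joule = boltzmann_constant * temperature),
    class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  kB = %.6e J/K, NA = %.8e /mol, T = %.2f K\n",
              x$boltzmann_constant, x$avogadro_number, x$temperature))
  cat(sprintf("  kB*T = %.6e J\n", x$kBT_joule))
  invisible(x)
}

#' Osmotic pressure of a dilute particle concentration difference
#'
#' Converts a concentration difference of osmotically active particles into
#' the corresponding osmotic pressure difference through the van't Hoff
#' relation \eqn{\Pi = c\,N_A k_B T}.  In the isolation-membrane model the
#' concentration difference is the excess of membrane-excluded particles
#' (ribosomes and other large complexes) in the cytoplasm relative to the
#' membrane-covered interior; the resulting pressure difference draws water
#' out of the covered volume.
#'
#' @param concentration Concentration difference in micromolar (uM);
#'   must be non-negative.
#' @param constants A [physical_constants()] object.
#' @return Osmotic pressure difference in pascal (Pa).
#' @seealso [concentration_from_pressure()] for the inverse.
#' @examples
#' osmotic_pressure(1)    # ~2.52 Pa at 303.15 K
#' @export
osmotic_pressure <- function(concentration, constants = physical_constants()) {
  stopifnot(is.numeric(concentration), all(is.finite(concentration)))
  if (any(concentration < 0))
    stop("`concentration` must be non-negative (magnitude of the difference)")
  # uM -> mol/m^3 is a factor 1e-3
  concentration * 1e-3 * constants$avogadro_number * constants$kBT_joule
}

#' @rdname osmotic_pressure
#' @param pressure Osmotic pressure difference in pascal; must be
#'   non-negative.
#' @return `concentration_from_pressure()` returns the concentration
#'   difference in uM.
#' @export
concentration_from_pressure <- function(pressure, constants = physical_constants()) {
  stopifnot(is.numeric(pressure), all(is.finite(pressure)))
  if (any(pressure < 0))
    stop("`pressure` must be non-negative (magnitude of the difference)")
  pressure / (1e-3 * constants$avogadro_number * constants$kBT_joule)
}

# Pa -> kB*T per nm^3
.pressure_to_internal <- function(pressure_pa, constants) {
  pressure_pa * 1e-27 / constants$kBT_joule
}

#' Diameter of the sphere matching a given total membrane area
#'
#' The model fixes the total membrane area `A` of the double-membrane
#' cisterna (both juxtaposed membranes counted).  A closed double-membrane
#' sphere of diameter `d` has total area \eqn{A = 2\pi d^2}, so the
#' equivalent sphere diameter is \eqn{\sqrt{A/2\pi}}.  For the default
#' area of pi um^2 this gives 0.71 um, i.e. an autophagosome of about
#' 0.7 um diameter.
#'
#' @param total_area Total membrane area in um^2 (both membranes); positive.
#' @return Equivalent sphere diameter in um.
#' @examples
#' equivalent_sphere_diameter(pi)     # ~0.707
#' equivalent_sphere_diameter(2 * pi) # exactly 1
#' @export
equivalent_sphere_diameter <- function(total_area) {
  stopifnot(is.numeric(total_area), all(is.finite(total_area)))
  if (any(total_area <= 0)) stop("`total_area` must be positive")
  sqrt(total_area / (2 * pi))
}

#' Expected diameter of a tagged model particle
#'
#' Computes the expected end-to-end diameter of a model particle used to
#' probe the size cut-off of the isolation-membrane opening: a multimeric
#' protein core (e.g. a ~9 nm Dps dodecamer or a ~15 nm lumazine-synthase
#' hexacontamer) flanked by fluorescent-protein tags (~5 nm GFP barrels).
#' The raw value `core + n_tags * tag` is also rounded to the nearest 5 nm,
#' the reporting granularity conventional for such estimates.
#'
#' @param core_diameter Core particle diameter in nm; positive.
#' @param n_flanking_tags Number of tags adding to the diameter (0, 1 or 2).
#' @param tag_diameter Diameter of one tag in nm; positive. Default 5 (GFP).
#' @return A list with elements `raw` (nm) and `reported` (nm, rounded to
#'   the nearest 5).
#' @examples
#' expected_particle_diameter(15, 2)  # RibH-GFP: raw 25, reported 25
#' expected_particle_diameter(9, 2)   # Dps-GFP:  raw 19, reported 20
#' @export
expected_particle_diameter <- function(core_diameter, n_flanking_tags,
                                       tag_diameter = 5) {
  stopifnot(is.numeric(core_diameter), core_diameter > 0,
            is.numeric(tag_diameter), tag_diameter > 0)
  if (!n_flanking_tags %in% c(0L, 1L, 2L))
    stop("`n_flanking_tags` must be 0, 1 or 2")
  raw <- core_diameter + n_flanking_tags * tag_diameter
  list(raw = raw, reported = 5 * round(raw / 5))
}
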