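#' Shape descriptors of a membrane profile
#'
#' Aggregates the morphological quantities that connect model shapes to
#' fluorescence morphometry: axial length `L` (extent along the symmetry
#' axis), maximum width `W = 2 max(x)`, aspect ratio `L/W`, opening
#' diameter (twice the rim radius), isolation-membrane size (the meridian
#' arc length `s1`, the model-side analogue of the imaging rule "half of
#' the outline perimeter"), and the equivalent sphere diameter of the
#' total area.  A shape is classified tubular when its aspect ratio
#' reaches `tubular_threshold` (default 1.5); the threshold is a
#' documented package choice, always reported alongside the raw ratio.
#'
#' @param profile A [shape_profile()].
#' @param params Optional [model_params()]; when given, the opening
#'   diameter and equivalent diameter use the parameter values (exact),
#'   otherwise they are measured from the profile.
#' @param tubular_threshold Aspect ratio at and above which a shape is
#'   flagged tubular.
#' @return A one-row `data.frame` (class `shape_descriptors`) with columns
#'   `axial_length_nm`, `max_width_nm`, `aspect_ratio`,
#'   `opening_diameter_nm`, `im_size_nm`, `equivalent_diameter_um`,
#'   `tubular`.
#' @examples
#' describe_shape(sphere_profile(350))
#' @export
describe_shape <- function(profile, params = NULL, tubular_threshold = 1.5) {
  stopifnot(inherits(profile, "shape_profile"))
  L <- max(profile$z) - min(profile$z)
  W <- 2 * max(profile$x)
  ar <- L / W
  opening <- if (is.null(params)) 2 * profile$x[length(profile$x)] else
    2 * params$rim_radius
  area <- if (is.null(params)) membrane_area(profile) else params$total_area
  out <- data.frame(axial_length_nm = L,
                    max_width_nm = W,
                    aspect_ratio = ar,
                    opening_diameter_nm = opening,
                    im_size_nm = profile$s1,
                    equivalent_diameter_um = equivalent_sphere_diameter(area),
                    tubular = ar >= tubular_threshold)
  class(out) <- c("shape_descriptors", class(out))
  out
}
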