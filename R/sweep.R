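#' Equilibrium shapes along a concentration sweep
#'
#' Minimises the free energy at each concentration difference in
#' `c_values` (ascending, uM), warm-starting every point from the previous
#' solution (continuation).  When `bidirectional = TRUE` (the default) a
#' reverse continuation pass (high to low c) is also run and, at every
#' point, the lower-energy branch wins; this guards against hysteresis
#' across the discontinuous spheroid-to-tubule transition.  Energy ties
#' within `config$tolerance_energy` prefer the forward branch, which keeps
#' descriptors smooth where the landscape is flat.
#'
#' @param params A [model_params()]; its pressure/concentration fields are
#'   overridden point by point.
#' @param c_values Ascending non-negative concentration differences, uM.
#' @param config A [minimizer_config()].
#' @param bidirectional Run the reverse continuation pass (default TRUE).
#' @param tubular_threshold Aspect ratio defining the tubular flag.
#' @param verbose Print one line per sweep point.
#' @return An object of class `concentration_sweep`: list with `results`
#'   (one row per c: concentrations, pressures, energy decomposition,
#'   volume, descriptors, `tubular`, `converged`), `profiles` (list of
#'   [shape_profile()]), `params`, `config`.
#' @seealso [tubulation_onset()]
#' @examples
#' \donttest{
#' sw <- sweep_concentration(model_params(n_nodes = 80), c(0, 5),
#'                           minimizer_config(n_nodes = 80))
#' sw$results$aspect_ratio
#' }
#' @export
sweep_concentration <- function(params, c_values, config = minimizer_config(),
                                bidirectional = TRUE, tubular_threshold = 1.5,
                                verbose = FALSE) {
  stopifnot(inherits(params, "model_params"), is.numeric(c_values),
            length(c_values) >= 1, all(c_values >= 0),
            !is.unsorted(c_values, strictly = TRUE))
  m <- length(c_values)
  point_params <- lapply(c_values, function(cc)
    model_params(kappa_b = params$kappa_b, rim_radius = params$rim_radius,
                 total_area = params$total_area,
                 concentration_difference = cc,
                 n_nodes = params$n_nodes, constants = params$constants))
  point_config <- function(i) {
    cf <- config
    cf$random_seed <- config$random_seed + i
    cf
  }

  forward <- vector("list", m)
  warm <- NULL
  for (i in seq_len(m)) {
    sol <- minimize_shape(point_params[[i]], point_config(i), initial = warm)
    forward[[i]] <- sol
    if (sol$converged) warm <- sol$profile
    if (verbose)
      cat(sprintf("c = %5.2f uM  F = %9.3f kB*T  AR = %6.3f\n",
                  c_values[i], sol$internal$physical,
                  describe_shape(sol$profile)$aspect_ratio))
  }

  chosen <- forward
  if (bidirectional && m > 1L) {
    warm <- forward[[m]]$profile
    for (i in rev(seq_len(m))) {
      sol <- minimize_shape(point_params[[i]], point_config(i),
                            initial = warm, starts = "initial-only")
      if (sol$converged) warm <- sol$profile
      fw <- chosen[[i]]
      tie <- config$tolerance_energy * max(1, abs(fw$internal$physical))
      take_reverse <- sol$converged &&
        (!fw$converged || sol$internal$physical < fw$internal$physical - tie)
      if (take_reverse) chosen[[i]] <- sol
    }
  }

  rows <- lapply(seq_len(m), function(i) {
    sol <- chosen[[i]]
    d <- describe_shape(sol$profile, point_params[[i]], tubular_threshold)
    cbind(data.frame(c_uM = c_values[i],
                     pressure_Pa = point_params[[i]]$pressure,
                     bending_kBT = sol$energy$bending_energy,
                     pressure_work_kBT = sol$energy$pressure_work,
                     total_kBT = sol$energy$total_free_energy,
                     volume_um3 = sol$energy$volume,
                     area_um2 = sol$energy$area),
          d,
          data.frame(converged = sol$converged))
  })
  results <- do.call(rbind, rows)
  class(results) <- "data.frame"
  rownames(results) <- NULL
  structure(list(results = results,
                 profiles = lapply(chosen, `[[`, "profile"),
                 params = params, config = config,
                 tubular_threshold = tubular_threshold),
            class = "concentration_sweep")
}

#' Smallest concentration difference with a tubular equilibrium shape
#'
#' @param sweep A [sweep_concentration()] result.
#' @return The smallest `c` (uM) whose converged equilibrium shape is
#'   classified tubular, or `NA` if no swept point is tubular.
#' @export
tubulation_onset <- function(sweep) {
  stopifnot(inherits(sweep, "concentration_sweep"))
  r <- sweep$results
  hit <- r$tubular & r$converged
  if (!any(hit)) return(NA_real_)
  min(r$c_uM[hit])
}

#' @export
print.concentration_sweep <- function(x, ...) {
  r <- x$results
  cat(sprintf("concentration_sweep: %d points, c in [%g, %g] uM\n",
              nrow(r), min(r$c_uM), max(r$c_uM)))
  onset <- tubulation_onset(x)
  cat(sprintf("  aspect ratio %0.3f -> %0.3f; tubulation onset: %s\n",
              r$aspect_ratio[1], r$aspect_ratio[nrow(r)],
              if (is.na(onset)) "none in range" else paste(onset, "uM")))
  invisible(x)
}

#' @export
plot.concentration_sweep <- function(x, ...) {
  r <- x$results
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(r$c_uM, r$aspect_ratio, type = "b", pch = 16,
       xlab = "concentration difference (uM)", ylab = "aspect ratio L/W", ...)
  graphics::abline(h = x$tubular_threshold, lty = 2)
  idx <- unique(round(seq(1, nrow(r), length.out = 5)))
  pal <- grDevices::hcl.colors(length(idx), "viridis")
  xmax <- max(vapply(x$profiles[idx], function(p) max(p$x), numeric(1)))
  zr <- range(unlist(lapply(x$profiles[idx], `[[`, "z")))
  plot(NA, xlim = c(-xmax, xmax) * 1.1, ylim = zr, asp = 1,
       xlab = "x (nm)", ylab = "z (nm)")
  for (k in seq_along(idx)) {
    p <- x$profiles[[idx[k]]]
    graphics::lines(c(rev(-p$x), p$x), c(rev(p$z), p$z), col = pal[k])
  }
  graphics::legend("topright", bty = "n", col = pal, lty = 1, cex = 0.7,
                   legend = sprintf("%g uM", r$c_uM[idx]))
  invisible(x)
}
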