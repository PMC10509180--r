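# Equilibrium-shape minimisation.
#
# The shape is represented by the tilt-angle field theta(s) on a uniform
# arc-length grid plus the total arc length s1; x and z are recovered by
# integrating dx/ds = cos(theta), dz/ds = sin(theta) from the pole.  With
# this parametrisation the geometric-constraint multiplier of the
# constrained functional is identically zero and never needs a value.
#
# Discretisation is staggered: curvature and the bending/pressure
# integrands live on interval midpoints (forward differences of theta), so
# grid-scale oscillations of theta are penalised and the pole singularity
# sin(theta)/x regularises itself; the two remaining constraints (total
# area, rim radius) are measured with the same node-based trapezoidal rule
# as membrane_area(), and are enforced by an augmented-Lagrangian scheme
# with penalty escalation.

#' Minimiser configuration
#'
#' Settings for [minimize_shape()] and [sweep_concentration()].
#'
#' @param n_nodes Number of meridian nodes (>= 16). Default 200.
#' @param tolerance_energy Relative energy tolerance used to declare ties
#'   between candidate solutions. Default 1e-4.
#' @param tolerance_constraint Relative tolerance on the area and rim
#'   constraints. Default 1e-6.
#' @param max_iterations Iteration cap per inner L-BFGS-B solve; an
#'   augmented-Lagrangian outer step re-enters the solver until it reports
#'   convergence, so this bounds one chunk, not the whole minimisation.
#' @param n_restarts Minimum number of optimisation starts (>= 1); starts
#'   beyond the deterministic candidates (warm start, spherical cap,
#'   capsules) are seeded random smooth perturbations. Default 4.
#' @param perturbation_scale Amplitude (radians) of the random restart
#'   perturbations of theta. Default 0.05.
#' @param random_seed Integer seed; recorded in all outputs. Default 1.
#' @param continuation_step Default spacing (uM) of concentration sweeps.
#' @param capsule_radii Tube radii (nm) of the elongated-branch starting
#'   candidates.
#' @param al_max_outer Maximum augmented-Lagrangian outer iterations.
#' @param lbfgs_factr `factr` convergence parameter of L-BFGS-B (small =
#'   tight); the default 1 resolves the nearly flat energy landscape
#'   around the spheroidal branch.
#' @param lbfgs_memory Number of limited-memory correction vectors
#'   (`lmm`); the bending functional is ill-conditioned and benefits from
#'   a large history. Default 25.
#' @return An object of class `minimizer_config`.
#' @export
minimizer_config <- function(n_nodes = 200,
                             tolerance_energy = 1e-4,
                             tolerance_constraint = 1e-6,
                             max_iterations = 2000,
                             n_restarts = 4,
                             perturbation_scale = 0.05,
                             random_seed = 1,
                             continuation_step = 0.5,
                             capsule_radii = c(150, 250),
                             al_max_outer = 18,
                             lbfgs_factr = 1,
                             lbfgs_memory = 25) {
  stopifnot(n_nodes >= 16, tolerance_energy > 0, tolerance_constraint > 0,
            max_iterations >= 10, n_restarts >= 1, perturbation_scale >= 0,
            al_max_outer >= 1, all(capsule_radii > 0))
  structure(list(n_nodes = as.integer(n_nodes),
                 tolerance_energy = tolerance_energy,
                 tolerance_constraint = tolerance_constraint,
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts),
                 perturbation_scale = perturbation_scale,
                 random_seed = as.integer(random_seed),
                 continuation_step = continuation_step,
                 capsule_radii = capsule_radii,
                 al_max_outer = as.integer(al_max_outer),
                 lbfgs_factr = lbfgs_factr,
                 lbfgs_memory = as.integer(lbfgs_memory)),
            class = "minimizer_config")
}

# run expr with a local RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Objective closure.  p = c(theta[2..n], s1); returns gradient, or state
# when grad = FALSE.  suction: osmotic pressure magnitude, kB*T/nm^3;
# the physical objective is  F = E_bend + suction * V.
.shape_objective <- function(n, kappa, suction, area_nm2, rim_radius,
                             lamA = 0, muA = 0, lamX = 0, muX = 0,
                             mu_neg = 1e4, xm_floor = 0.5,
                             mu_res = 1e5, max_step = 0.7) {
  w <- rep(1, n); w[1] <- w[n] <- 0.5
  tk <- 2 * pi * kappa
  function(p, grad = TRUE) {
    th <- c(0, p[1:(n - 1)]); s1 <- p[n]
    h <- s1 / (n - 1)
    thm <- (th[-n] + th[-1]) / 2
    dth <- (th[-1] - th[-n]) / h
    cm <- cos(thm); sm <- sin(thm)
    x <- h * cumsum(c(0, cm))
    xm <- (x[-n] + x[-1]) / 2
    xms <- pmax(xm, xm_floor)
    J <- dth + sm / xms
    Eb <- tk * h * sum(xms * J^2)
    V <- pi * h * sum(xm^2 * sm)
    A <- 4 * pi * h * sum(w * x)
    rA <- (A - area_nm2) / area_nm2
    rX <- (x[n] - rim_radius) / rim_radius
    neg <- pmin(x, 0)
    # resolution guard: a tilt step above the local limit per interval
    # means the feature is unresolved by the grid (midpoint and node-based
    # quadratures then disagree), so it is penalised out of the search
    # space; the limit shrinks with the local radius because bends at
    # radii below the grid spacing cannot be represented
    step <- th[-1] - th[-n]
    lim <- pmin(max_step, 0.25 + xm / (4 * h))
    exc <- pmax(abs(step) - lim, 0)
    O <- Eb + suction * V + lamA * rA + muA * rA^2 + lamX * rX + muX * rX^2 +
      mu_neg * sum(neg^2) + mu_res * sum(exc^2)
    if (!grad)
      return(list(objective = O, bending = Eb, volume_nm3 = V, area_nm2 = A,
                  rA = rA, rX = rX, x = x, theta = th, s1 = s1,
                  physical = Eb + suction * V))
    cA <- (lamA + 2 * muA * rA) / area_nm2
    cX <- (lamX + 2 * muX * rX) / rim_radius
    a <- 2 * tk * h * J * cm + suction * pi * h * xm^2 * cm
    b <- 2 * tk * h * xms * J
    g <- tk * h * (J^2 - 2 * J * sm / xms) * (xm > xm_floor) +
      suction * 2 * pi * h * xm * sm -
      2 * mu_res * exc * (lim < max_step) / (4 * h)
    q <- c(g / 2, 0) + c(0, g / 2) + cA * 4 * pi * h * w + 2 * mu_neg * neg
    q[n] <- q[n] + cX
    Q <- rev(cumsum(rev(q)))
    Ax <- a - h * sm * Q[-1]
    r_res <- 2 * mu_res * exc * sign(step)
    g_th <- c(Ax / 2, 0) + c(0, Ax / 2) + c(-b / h, 0) + c(0, b / h) +
      c(-r_res, 0) + c(0, r_res)
    g_s1 <- suction * 3 * V / s1 + cA * 2 * A / s1 + cX * x[n] / s1 +
      sum(2 * mu_neg * neg * x / s1)
    structure(c(g_th[2:n], g_s1), objective = O)
  }
}

# Augmented-Lagrangian minimisation from one start (internal theta/s1 pair).
.minimize_single <- function(start, n, kappa, suction, area_nm2, rim_radius,
                             config, factr = config$lbfgs_factr) {
  p <- c(start$theta[-1], start$s1)
  lamA <- 0; lamX <- 0
  muA <- 1e5; muX <- 1e5
  tol <- config$tolerance_constraint
  converged <- FALSE
  iterations <- 0L
  lower <- c(rep(-pi / 2, n - 1), 50)
  upper <- c(rep(3 * pi / 2, n - 1), 50000)
  for (k in seq_len(config$al_max_outer)) {
    f <- .shape_objective(n, kappa, suction, area_nm2, rim_radius,
                          lamA, muA, lamX, muX)
    # optim() evaluates fn and gr at the same point back to back; share
    # one evaluation between them
    memo_p <- NULL; memo_g <- NULL
    fn <- function(p) {
      g <- f(p, grad = TRUE)
      memo_p <<- p; memo_g <<- g
      attr(g, "objective")
    }
    gr <- function(p) {
      if (!is.null(memo_p) && identical(p, memo_p)) return(as.numeric(memo_g))
      as.numeric(f(p, grad = TRUE))
    }
    inner_done <- FALSE
    for (chunk in 1:5) {
      res <- stats::optim(p, fn = fn, gr = gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = config$max_iterations,
                                         factr = factr,
                                         pgtol = 0,
                                         lmm = config$lbfgs_memory))
      p <- res$par
      iterations <- iterations + res$counts[[1L]]
      if (res$convergence == 0L) { inner_done <- TRUE; break }
    }
    st <- f(p, grad = FALSE)
    if (abs(st$rA) < tol && abs(st$rX) < tol && inner_done) {
      converged <- TRUE; break
    }
    lamA <- lamA + 2 * muA * st$rA
    lamX <- lamX + 2 * muX * st$rX
    muA <- muA * 4; muX <- muX * 4
  }
  f0 <- .shape_objective(n, kappa, suction, area_nm2, rim_radius)
  st <- f0(p, grad = FALSE)
  list(theta = st$theta, s1 = st$s1, x = st$x,
       physical = st$physical, bending = st$bending,
       volume_nm3 = st$volume_nm3, area_nm2 = st$area_nm2,
       rA = st$rA, rX = st$rX,
       converged = converged, iterations = iterations,
       multipliers = list(lamA = lamA, muA = muA, lamX = lamX, muX = muX))
}

# resample a shape_profile's theta field onto n uniform nodes
.internal_start <- function(profile, n) {
  t_new <- seq(0, profile$s1, length.out = n)
  list(theta = stats::approx(profile$s, profile$theta, xout = t_new,
                             rule = 2)$y,
       s1 = profile$s1)
}

.perturb_start <- function(start, scale) {
  n <- length(start$theta)
  t <- seq(0, 1, length.out = n)
  modes <- sample(1:4, 2)
  pert <- rep(0, n)
  for (m in modes) pert <- pert + stats::rnorm(1, 0, scale) * sin((m - 0.5) * pi * t)
  list(theta = start$theta + pert, s1 = start$s1 * exp(stats::rnorm(1, 0, 0.05)))
}

# internal theta/s1 -> shape_profile (x, z by the same midpoint rule the
# objective uses, so the converged constraints carry over exactly)
.profile_from_internal <- function(theta, s1) {
  n <- length(theta)
  h <- s1 / (n - 1)
  thm <- (theta[-n] + theta[-1]) / 2
  x <- h * cumsum(c(0, cos(thm)))
  z <- h * cumsum(c(0, sin(thm)))
  shape_profile(theta = theta, s = seq(0, s1, length.out = n),
                x = x, z = z, check = FALSE)
}

#' Minimum-free-energy membrane shape
#'
#' Finds the equilibrium (minimum-free-energy) axisymmetric shape for the
#' given parameters, subject to fixed total area, fixed rim radius and
#' smooth pole closure.  Several starting candidates are minimised: the
#' warm start (if `initial` is given), the analytic rim-matched spherical
#' cap, capsules on the elongated branch, and seeded random perturbations;
#' the lowest-energy converged solution wins.  Energy ties within
#' `tolerance_energy` are resolved in favour of the earlier candidate
#' (the warm start first), which keeps continuation sweeps smooth.
#'
#' @param params A [model_params()].
#' @param config A [minimizer_config()]; its `n_nodes` overrides
#'   `params$n_nodes` when they differ.
#' @param initial Optional [shape_profile()] used as the first (warm)
#'   starting candidate.
#' @param starts `"full"` (all candidates) or `"initial-only"` (pure
#'   continuation; requires `initial`).
#' @return An object of class `equilibrium_solution`: list with `profile`
#'   ([shape_profile()]), `energy` ([free_energy()] report), `converged`,
#'   `iterations`, `restart_energies` (physical energy reached from every
#'   start, kB*T) and `internal` (solver state for diagnostics).
#' @examples
#' \donttest{
#' sol <- minimize_shape(model_params(n_nodes = 80),
#'                       minimizer_config(n_nodes = 80))
#' sol$energy
#' }
#' @export
minimize_shape <- function(params, config = minimizer_config(),
                           initial = NULL, starts = c("full", "initial-only")) {
  stopifnot(inherits(params, "model_params"),
            inherits(config, "minimizer_config"))
  starts <- match.arg(starts)
  n <- config$n_nodes
  kappa <- params$kappa_b
  area_nm2 <- params$total_area * 1e6
  rim <- params$rim_radius
  suction <- .pressure_to_internal(params$pressure, params$constants)
  if (area_nm2 <= 2 * pi * rim^2)
    stop("infeasible constraints: total_area below the flat-double-disc bound")

  cands <- list()
  if (!is.null(initial)) {
    stopifnot(inherits(initial, "shape_profile"))
    cands$warm <- .internal_start(initial, n)
  } else if (starts == "initial-only") {
    stop("`starts = \"initial-only\"` requires `initial`")
  }
  if (starts == "full") {
    cands$cap <- .internal_start(rim_cap_profile(params$total_area, rim, n), n)
    for (r in config$capsule_radii) {
      if (r > rim && 4 * pi * r^2 < area_nm2) {
        cands[[paste0("capsule", r)]] <-
          .internal_start(.capsule_for_constraints(params$total_area, rim, r, n), n)
      }
    }
    extra <- config$n_restarts - length(cands)
    if (extra > 0) {
      base <- cands[setdiff(names(cands), "warm")]
      if (length(base) == 0L) base <- cands
      .with_seed(config$random_seed, {
        for (j in seq_len(extra)) {
          src <- base[[1L + (j - 1L) %% length(base)]]
          cands[[paste0("perturbed", j)]] <-
            .perturb_start(src, config$perturbation_scale)
        }
      })
    }
  }

  # scout every candidate at a loose tolerance (branch comparison only
  # needs ~1e-5 kB*T discrimination), then polish the winner tightly
  scout_factr <- max(1e7, config$lbfgs_factr)
  runs <- lapply(cands, .minimize_single, n = n, kappa = kappa,
                 suction = suction, area_nm2 = area_nm2, rim_radius = rim,
                 config = config, factr = scout_factr)
  energies <- vapply(runs, `[[`, numeric(1), "physical")
  conv <- vapply(runs, `[[`, logical(1), "converged")
  pool <- if (any(conv)) which(conv) else seq_along(runs)
  best_e <- min(energies[pool])
  tie <- config$tolerance_energy * max(1, abs(best_e))
  best_i <- pool[which(energies[pool] <= best_e + tie)[1L]]
  best <- runs[[best_i]]
  if (config$lbfgs_factr < scout_factr) {
    polished <- .minimize_single(list(theta = best$theta, s1 = best$s1),
                                 n = n, kappa = kappa, suction = suction,
                                 area_nm2 = area_nm2, rim_radius = rim,
                                 config = config)
    polished$iterations <- polished$iterations + best$iterations
    best <- polished
  }

  profile <- .profile_from_internal(best$theta, best$s1)
  # the energy report is built from the minimiser's own staggered
  # quadrature (the functional that was actually minimised); for shapes
  # resolved by the grid it agrees with free_energy(profile, params) to
  # O(h^2), but at rim radii below the grid spacing only the staggered
  # form is meaningful
  pw <- -.pressure_to_internal(params$pressure, params$constants) *
    best$volume_nm3
  energy <- structure(
    list(bending_energy = best$bending,
         pressure_work = pw,
         total_free_energy = best$bending - pw,
         volume = best$volume_nm3 * 1e-9,
         area = best$area_nm2 * 1e-6,
         rim_radius = best$x[length(best$x)],
         temperature = params$constants$temperature),
    class = "energy_report")
  structure(
    list(profile = profile,
         energy = energy,
         converged = best$converged,
         iterations = sum(vapply(runs, `[[`, integer(1), "iterations")) -
           runs[[best_i]]$iterations + best$iterations,
         restart_energies = energies,
         selected_start = names(cands)[best_i],
         internal = best,
         params = params,
         config = config),
    class = "equilibrium_solution")
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf("equilibrium_solution (%s, start '%s', %d L-BFGS iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$selected_start, x$iterations))
  print(x$energy)
  invisible(x)
}
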