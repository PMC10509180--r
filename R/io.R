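# Profile serialisation, run configuration, manifests.

.fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write / read a shape profile as columnar text
#'
#' Profiles are written as CSV with columns `s_nm`, `theta_rad`, `x_nm`,
#' `z_nm` (9 significant digits) plus a JSON sidecar holding model
#' parameters, physical constants and solver metadata.
#'
#' @param profile A [shape_profile()].
#' @param path CSV path; sidecar at `paste0(path, ".json")`.
#' @param params Optional [model_params()] stored in the sidecar.
#' @param metadata Optional named list of extra sidecar fields.
#' @return `write_profile_csv()` the paths invisibly; `read_profile_csv()`
#'   a list with `profile` and `sidecar`.
#' @export
write_profile_csv <- function(profile, path, params = NULL, metadata = list()) {
  stopifnot(inherits(profile, "shape_profile"))
  df <- as.data.frame(profile)
  df[] <- lapply(df, .fmt9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(s1_nm = profile$s1, n_nodes = length(profile$s),
               metadata = metadata)
  if (!is.null(params)) {
    side$params <- list(
      kappa_b_kBT = params$kappa_b, rim_radius_nm = params$rim_radius,
      total_area_um2 = params$total_area,
      pressure_Pa = params$pressure,
      concentration_uM = params$concentration_difference,
      n_nodes = params$n_nodes)
    side$constants <- unclass(params$constants)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(path, paste0(path, ".json")))
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  list(profile = shape_profile(theta = df$theta_rad, s = df$s_nm,
                               x = df$x_nm, z = df$z_nm, check = FALSE),
       sidecar = side)
}

# ---- run configuration ---------------------------------------------------

#' Read a run configuration (YAML or JSON)
#'
#' Configurations are a single document with sections mirroring the
#' package types: `model` (kappa_b, rim_radius_nm, total_area_um2,
#' concentration_uM, temperature_K), `minimizer`
#' ([minimizer_config()] fields), `sweep` (c_min_uM, c_max_uM, step_uM),
#' `stack` ([stack_spec()] fields plus a `structures` list) and
#' `segmentation` ([segmentation_config()] fields).  All defaults equal
#' the model's stated values; unspecified sections fall back to package
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list
#'   already in memory.
#' @return The configuration as a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (is.character(path) && length(path) == 1L) {
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else stop("configuration must be a mapping (named list) or a file path")
  if (!is.list(cfg)) stop("configuration must be a mapping (named list)")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

.cfg_params <- function(cfg) {
  m <- cfg$model %||% list()
  const <- physical_constants(temperature = m$temperature_K %||% 303.15)
  model_params(
    kappa_b = m$kappa_b %||% 20,
    rim_radius = m$rim_radius_nm %||% 12.5,
    total_area = m$total_area_um2 %||% pi,
    concentration_difference = m$concentration_uM %||% 0,
    n_nodes = m$n_nodes %||% 200,
    constants = const)
}

.cfg_minimizer <- function(cfg, seed = NULL) {
  mc <- cfg$minimizer %||% list()
  args <- mc[intersect(names(mc), names(formals(minimizer_config)))]
  cf <- do.call(minimizer_config, args)
  if (!is.null(seed)) cf$random_seed <- as.integer(seed)
  cf
}

.write_manifest <- function(out_dir, command, cfg, seed, files) {
  files <- files[file.exists(files)]
  man <- list(command = command,
              package_version = as.character(utils::packageVersion("phagomorph")),
              seed = seed,
              config = cfg,
              files = lapply(stats::setNames(nm = basename(files)), function(f)
                unname(tools::md5sum(file.path(out_dir, f)))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  path
}

#' Run the shape-solve, sweep and simulate-measure experiments
#'
#' High-level entry points tying the modules together.  Each writes its
#' outputs plus a `manifest.json` (command, configuration snapshot, seed,
#' package version and MD5 checksums of every written file) to `out_dir`,
#' so a run is reproducible from its manifest.
#'
#' `run_solve()` minimises one equilibrium shape and writes
#' `profile.csv` (+ JSON sidecar) and `energy.json`.
#' `run_sweep()` runs a concentration sweep and writes `sweep.csv` and one
#' profile CSV per concentration.
#' `run_simulate_measure()` renders a synthetic stack, writes it as TIFF
#' with its ground truth, runs the morphometry pipeline and writes the
#' measurement table plus a recovery report comparing measured against
#' true sizes.
#'
#' @param config A configuration list or path, see [read_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding the configured random seed.
#' @return A character vector of written files, invisibly.
#' @export
run_solve <- function(config, out_dir, seed = NULL) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .cfg_params(cfg)
  mcfg <- .cfg_minimizer(cfg, seed)
  sol <- minimize_shape(params, mcfg)
  d <- describe_shape(sol$profile, params)
  write_profile_csv(sol$profile, file.path(out_dir, "profile.csv"),
                    params = params,
                    metadata = list(seed = mcfg$random_seed,
                                    converged = sol$converged))
  jsonlite::write_json(
    c(unclass(sol$energy), as.list(d),
      list(converged = sol$converged, iterations = sol$iterations,
           seed = mcfg$random_seed)),
    file.path(out_dir, "energy.json"), auto_unbox = TRUE, digits = NA)
  files <- c("profile.csv", "profile.csv.json", "energy.json")
  .write_manifest(out_dir, "solve", cfg, mcfg$random_seed,
                  file.path(out_dir, files))
  if (!sol$converged) warning("solver did not converge; outputs carry the best profile found")
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

#' @rdname run_solve
#' @export
run_sweep <- function(config, out_dir, seed = NULL) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .cfg_params(cfg)
  mcfg <- .cfg_minimizer(cfg, seed)
  sw_cfg <- cfg$sweep %||% list()
  cs <- seq(sw_cfg$c_min_uM %||% 0, sw_cfg$c_max_uM %||% 15,
            by = sw_cfg$step_uM %||% mcfg$continuation_step)
  sw <- sweep_concentration(params, cs, mcfg,
                            bidirectional = sw_cfg$bidirectional %||% TRUE)
  res <- sw$results
  out <- data.frame(c_uM = res$c_uM, P_Pa = res$pressure_Pa,
                    bending_kBT = res$bending_kBT,
                    pressure_work_kBT = res$pressure_work_kBT,
                    total_kBT = res$total_kBT,
                    volume_um3 = res$volume_um3,
                    aspect_ratio = res$aspect_ratio,
                    tubular_flag = res$tubular,
                    converged = res$converged)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], .fmt9)
  utils::write.csv(out, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- "sweep.csv"
  for (i in seq_along(cs)) {
    f <- sprintf("profile_c%05.2f.csv", cs[i])
    write_profile_csv(sw$profiles[[i]], file.path(out_dir, f),
                      metadata = list(c_uM = cs[i], seed = mcfg$random_seed))
    files <- c(files, f, paste0(f, ".json"))
  }
  if (isTRUE(sw_cfg$gallery)) {
    grDevices::png(file.path(out_dir, "gallery.png"), 1200, 500, res = 110)
    plot(sw)
    grDevices::dev.off()
    files <- c(files, "gallery.png")
  }
  .write_manifest(out_dir, "sweep", cfg, mcfg$random_seed,
                  file.path(out_dir, files))
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

.cfg_structures <- function(slist) {
  lapply(slist, function(s) {
    kind <- s$kind %||% "ring"
    args <- s[setdiff(names(s), "kind")]
    args$center <- as.numeric(args$center)
    fn <- switch(kind, ring = structure_ring, punctum = structure_punctum,
                 cup = structure_cup, tubule = structure_tubule,
                 stop("unsupported structure kind in config: ", kind))
    do.call(fn, args)
  })
}

#' @rdname run_solve
#' @export
run_simulate_measure <- function(config, out_dir, seed = NULL) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- cfg$stack %||% list()
  spec <- stack_spec(
    shape_xy = st$shape_xy %||% 256, n_slices = st$n_slices %||% 15,
    voxel_xy = st$voxel_xy %||% 65, voxel_z = st$voxel_z %||% 200,
    psf_sigma_xy = st$psf_sigma_xy %||% 100,
    psf_sigma_z = st$psf_sigma_z %||% 300,
    photons_per_structure = st$photons_per_structure %||% 40000,
    background_level = st$background_level %||% 10,
    read_noise_sd = st$read_noise_sd %||% 2,
    structures = .cfg_structures(st$structures %||% list()),
    random_seed = seed %||% st$random_seed %||% 1)
  ren <- render_stack(spec)
  write_stack(ren$stack, file.path(out_dir, "stack.tiff"))
  utils::write.csv(ren$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  seg_cfg <- do.call(segmentation_config,
                     (cfg$segmentation %||% list())[
                       intersect(names(cfg$segmentation %||% list()),
                                 names(formals(segmentation_config)))])
  proj <- max_intensity_projection(ren$stack)
  meas <- measure_structures(segment_projection(proj, seg_cfg), proj,
                             voxel_xy = spec$voxel_xy)
  utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  rec <- .recovery_report(ren$truth, meas, spec)
  jsonlite::write_json(rec, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("stack.tiff", "stack.tiff.json", "ground_truth.csv",
             "measurements.csv", "recovery.json")
  .write_manifest(out_dir, "simulate-measure", cfg, spec$random_seed,
                  file.path(out_dir, files))
  invisible(file.path(out_dir, c(files, "manifest.json")))
}

# match measured structures to ground truth by nearest centroid
.recovery_report <- function(truth, meas, spec) {
  if (!nrow(truth) || !nrow(meas))
    return(list(n_true = nrow(truth), n_measured = nrow(meas),
                matched = 0, median_major_axis_error_px = NA))
  mx <- meas$centroid_x_px * spec$voxel_xy
  my <- meas$centroid_y_px * spec$voxel_xy
  errs <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((mx - truth$x_nm[i])^2 + (my - truth$y_nm[i])^2)
    j <- which.min(dd)
    size_true <- if (!is.na(truth$diameter_nm[i])) truth$diameter_nm[i]
                 else truth$length_nm[i]
    if (dd[j] < max(500, size_true))
      errs[i] <- abs(meas$major_axis_nm[j] - size_true)
  }
  list(n_true = nrow(truth), n_measured = nrow(meas),
       matched = sum(!is.na(errs)),
       median_major_axis_error_px =
         stats::median(errs, na.rm = TRUE) / spec$voxel_xy,
       per_structure_error_nm = errs)
}
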