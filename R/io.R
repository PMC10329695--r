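## Configuration, file formats and pipeline entry points: YAML run configs,
## NIfTI label volumes with JSON sidecars, legacy-ASCII VTK field export,
## CSV traces and JSON scalar results.

#' Read a run configuration from YAML
#'
#' A run config bundles a phantom spec, tissue-model overrides, laser,
#' solver, damage and dose settings. Unknown keys raise an error naming the
#' offending key; all omitted settings fall back to package defaults (2 s
#' time step, 60 degC / 1 s damage model, 55 % ablation threshold, 42 degC
#' organ-at-risk limit, 2-10 W by 50-600 s dose grid).
#'
#' @param path YAML file.
#' @return An object of class `litt_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("phantom", "tissues", "laser", "solver", "damage", "dose",
             "output")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(y$phantom))
    stop("config is missing the 'phantom' block")
  ph <- y$phantom
  required <- if (identical(ph$mode, "axisymmetric")) "domain_size" else
    c("domain_size", "tumor")
  miss <- setdiff(required, names(ph))
  if (length(miss))
    stop("phantom block is missing key(s): ", paste(miss, collapse = ", "))
  spec_args <- list(
    mode = ph$mode %||% "voxel3d",
    domain_size = as.numeric(ph$domain_size),
    voxel_spacing = ph$voxel_spacing %||% 1,
    margin_thickness = ph$margin_thickness %||% 5,
    soft_shell_thickness = ph$soft_shell_thickness %||% 1,
    probe_lateral_mm = ph$probe_lateral_mm %||% 15
  )
  if (!is.null(ph$tumor)) {
    spec_args$tumor_semi_axes <- as.numeric(ph$tumor$semi_axes)
    if (!is.null(ph$tumor$center))
      spec_args$tumor_center <- as.numeric(ph$tumor$center)
  }
  if (!is.null(ph$pancreas_semi_axes))
    spec_args$pancreas_semi_axes <- as.numeric(ph$pancreas_semi_axes)
  if (!is.null(ph$vessels))
    spec_args$vessels <- lapply(ph$vessels, function(v)
      list(name = v$name, p0 = as.numeric(v$p0), p1 = as.numeric(v$p1),
           radius = v$radius, h = v$h))
  if (!is.null(ph$duodenum)) spec_args$duodenum <- ph$duodenum
  if (!is.null(ph$fiber))
    spec_args$fiber <- list(entry = as.numeric(ph$fiber$entry),
                            direction = as.numeric(ph$fiber$direction),
                            tip = if (!is.null(ph$fiber$tip))
                              as.numeric(ph$fiber$tip),
                            radius_um = ph$fiber$radius_um %||% 150)
  if (!is.null(ph$axisym)) spec_args$axisym <- ph$axisym
  spec <- do.call(phantom_spec, spec_args)

  las <- if (!is.null(y$laser))
    laser_config(power = y$laser$power,
                 fiber_radius = y$laser$fiber_radius %||% 150,
                 sigma = y$laser$sigma %||% (y$laser$fiber_radius %||% 150) / 3)
  sol <- do.call(solver_config, y$solver %||% list())
  dmg <- do.call(damage_config, y$damage %||% list())
  dose <- modifyList(list(powers = 2:10, durations = seq(50, 600, 50),
                          ablation_threshold = 55, oar_limit = 42),
                     y$dose %||% list())
  tissues <- y$tissues %||% list()
  structure(list(spec = spec, laser = las, solver = sol, damage = dmg,
                 dose = dose, tissues = tissues,
                 output = y$output %||% "."),
            class = "litt_run_config")
}

#' Write a phantom label volume as NIfTI with a JSON sidecar
#'
#' The integer label grid is written as a NIfTI volume whose pixdim carries
#' the voxel spacing (mm); spacing, label codes, fiber placement, probes and
#' vessel film coefficients go to `<stem>.json`. Voxel-mode phantoms only.
#'
#' @param phantom a voxel `litt_phantom`.
#' @param stem output path stem (writes `<stem>.nii` and `<stem>.json`).
#' @return The NIfTI path, invisibly.
#' @export
write_phantom_nifti <- function(phantom, stem) {
  stopifnot(inherits(phantom, "litt_phantom"))
  if (phantom$mode != "voxel3d")
    stop("NIfTI export is defined for voxel phantoms only")
  nii <- paste0(stem, ".nii")
  img <- RNifti::asNifti(array(as.integer(phantom$label), phantom$dims),
                         pixdim = phantom$spacing)
  RNifti::writeNifti(img, nii)
  sidecar <- list(
    units = "mm; coordinates are voxel centers from the domain corner",
    spacing = phantom$spacing,
    labels = as.list(phantom$label_names),
    tissue_of = as.list(phantom$tissue_of),
    fiber = phantom$fiber,
    probes = if (!is.null(phantom$probes)) unname(phantom$probes),
    vessels = lapply(phantom$vessels, function(v)
      v[c("name", "p0", "p1", "radius", "h", "code")]))
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(nii)
}

#' Read a phantom label volume written by [write_phantom_nifti()]
#'
#' @param stem path stem used at write time.
#' @return A `litt_phantom` with the labels, spacing, fiber, probes and
#'   vessel metadata restored (the generating spec is not recoverable).
#' @export
read_phantom_nifti <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lab <- array(as.integer(img), dim(img))
  spacing <- as.numeric(side$spacing)
  dims <- dim(lab)
  edges <- lapply(seq_along(dims), function(d)
    seq(0, by = spacing[d], length.out = dims[d] + 1L))
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  vessels <- lapply(seq_len(NROW(side$vessels)), function(i) {
    v <- side$vessels[i, ]
    list(name = v$name, p0 = unlist(v$p0), p1 = unlist(v$p1),
         radius = v$radius, h = v$h, code = as.integer(v$code))
  })
  probes <- if (!is.null(side$probes)) as.matrix(side$probes)
  fiber <- side$fiber
  fiber$entry <- as.numeric(fiber$entry)
  fiber$direction <- as.numeric(fiber$direction)
  fiber$tip <- as.numeric(fiber$tip)
  structure(list(mode = "voxel3d", dims = dims, edges = edges,
                 centers = centers, spacing = spacing, label = lab,
                 label_names = stats::setNames(
                   as.integer(unlist(side$labels)), names(side$labels)),
                 tissue_of = stats::setNames(unlist(side$tissue_of),
                                             names(side$tissue_of)),
                 vessels = vessels, fiber = fiber,
                 cell_volume = array(prod(spacing) * 1e-9, dims),
                 probes = probes, spec = NULL),
            class = "litt_phantom")
}

#' Write a scalar field as legacy-ASCII VTK structured points
#'
#' Plain-text VTK for inspection and diffing in standard viewers. Voxel-mode
#' fields only (axisymmetric fields are 2D matrices; export those as CSV).
#'
#' @param field numeric array on the phantom grid.
#' @param phantom the voxel `litt_phantom` the field lives on.
#' @param path output `.vtk` file.
#' @param name data array name.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, phantom, path, name = "field") {
  stopifnot(inherits(phantom, "litt_phantom"))
  if (phantom$mode != "voxel3d")
    stop("VTK export is defined for voxel phantoms only")
  dims <- phantom$dims
  stopifnot(all(dim(field) == dims))
  sp <- phantom$spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("littplan field:", name, "(mm grid, cell centers)"),
               "ASCII", "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", dims[1], dims[2], dims[3]),
               paste("ORIGIN", sp[1] / 2, sp[2] / 2, sp[3] / 2),
               paste("SPACING", sp[1], sp[2], sp[3]),
               paste("POINT_DATA", prod(dims)),
               paste("SCALARS", name, "float 1"),
               "LOOKUP_TABLE default"), con)
  vals <- as.numeric(field)
  vals[is.na(vals)] <- -1
  writeLines(format(vals, trim = TRUE, digits = 7), con)
  invisible(path)
}

#' Write probe traces and the energy ledger of a run as CSV
#'
#' @param sim a `litt_sim`.
#' @param stem path stem; writes `<stem>_probes.csv` and `<stem>_energy.csv`.
#' @return The file paths, invisibly.
#' @export
write_traces_csv <- function(sim, stem) {
  stopifnot(inherits(sim, "litt_sim"))
  f1 <- paste0(stem, "_probes.csv")
  pr <- data.frame(time_s = sim$times, sim$probe_traces)
  names(pr)[-1] <- paste0("probe", seq_len(ncol(sim$probe_traces)), "_degC")
  pr$margin_mean_degC <- sim$margin_trace
  pr$oar_max_degC <- sim$oar_trace
  write.csv(pr, f1, row.names = FALSE)
  f2 <- paste0(stem, "_energy.csv")
  write.csv(sim$energy$ledger, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

provenance <- function(config_path = NULL) {
  list(package = "littplan",
       version = as.character(utils::packageVersion("littplan")),
       config_sha = if (!is.null(config_path) && file.exists(config_path))
         unname(tools::md5sum(config_path)) else NA,
       written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Build and export a phantom from a YAML config (pipeline entry point)
#'
#' @param config_path YAML run config.
#' @param out_dir output directory.
#' @param quiet suppress the summary log.
#' @return The phantom, invisibly.
#' @export
run_phantom <- function(config_path, out_dir = ".", quiet = FALSE) {
  rc <- read_run_config(config_path)
  ph <- build_phantom(rc$spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (rc$spec$mode == "voxel3d")
    write_phantom_nifti(ph, file.path(out_dir, "phantom"))
  vols <- label_volumes(ph)
  jsonlite::write_json(list(label_volumes_mm3 = as.list(vols[vols > 0]),
                            provenance = provenance(config_path)),
                       file.path(out_dir, "phantom_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    message("phantom built: ", paste(ph$dims, collapse = " x "), " cells")
    for (nm in names(vols)[vols > 0])
      message(sprintf("  %-12s %10.1f mm^3", nm, vols[nm]))
  }
  invisible(ph)
}

#' Dispatch on the phantom mode of a spec
#'
#' @param spec a [phantom_spec()].
#' @return A `litt_phantom` built by [build_voxel_phantom()] or
#'   [build_axisymmetric_phantom()].
#' @export
build_phantom <- function(spec) {
  if (spec$mode == "axisymmetric") build_axisymmetric_phantom(spec)
  else build_voxel_phantom(spec)
}

#' Run a full simulation from a YAML config (pipeline entry point)
#'
#' @inheritParams run_phantom
#' @return The `litt_sim`, invisibly.
#' @export
run_simulate <- function(config_path, out_dir = ".", quiet = FALSE) {
  rc <- read_run_config(config_path)
  if (is.null(rc$laser))
    stop("config is missing the 'laser' block")
  ph <- build_phantom(rc$spec)
  models <- config_models(rc)
  sim <- solve_litt(ph, models, rc$laser, config = rc$solver,
                    damage = rc$damage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_traces_csv(sim, file.path(out_dir, "run"))
  if (ph$mode == "voxel3d") {
    write_field_vtk(sim$T_final, ph, file.path(out_dir, "T_final.vtk"),
                    "temperature_degC")
    write_field_vtk(sim$Omega, ph, file.path(out_dir, "Omega.vtk"),
                    "necrotic_fraction")
  }
  met <- tryCatch(ablation_metrics(sim), error = function(e) NULL)
  res <- list(
    peak_temperature_degC = max(sim$T_final, na.rm = TRUE),
    ablated_volume_mm3 = sum(ph$cell_volume[sim$Omega >= 1]) * 1e9,
    energy_closure_rel = sim$energy$closure_rel,
    provenance = provenance(config_path))
  if (!is.null(met))
    res <- c(list(ablated_fraction_pct = met$ablated_fraction,
                  oar_max_degC = met$oar_max), res)
  jsonlite::write_json(res, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    message(sprintf("run finished: peak %.1f degC, ablated %.1f mm^3",
                    res$peak_temperature_degC, res$ablated_volume_mm3))
  }
  invisible(sim)
}

config_models <- function(rc) {
  tis <- lapply(rc$tissues, function(b)
    baseline_props(b$density, b$conductivity, b$specific_heat,
                   b$perfusion %||% 0, b$metabolic_heat %||% 0))
  tissue_model_set(tissues = tis)
}

#' Run the dose-grid optimization from a YAML config (pipeline entry point)
#'
#' @inheritParams run_phantom
#' @return The `litt_dose` selection, invisibly.
#' @export
run_optimize <- function(config_path, out_dir = ".", quiet = FALSE) {
  rc <- read_run_config(config_path)
  ph <- build_phantom(rc$spec)
  models <- config_models(rc)
  grid <- dose_grid_search(ph, models, powers = rc$dose$powers,
                           durations = rc$dose$durations,
                           config = rc$solver, damage = rc$damage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dose_grid_csv(grid, file.path(out_dir, "dose_grid"))
  sel <- select_optimal_dose(grid, rc$dose$ablation_threshold,
                             rc$dose$oar_limit)
  out <- unclass(sel)
  out$provenance <- provenance(config_path)
  jsonlite::write_json(out, file.path(out_dir, "optimal_dose.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet) {
    if (sel$qualified)
      message(sprintf("optimal dose: %g W x %g s (E = %g J)", sel$power,
                      sel$duration, sel$energy))
    else
      message("no combination within the operating range qualifies")
  }
  invisible(sel)
}
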