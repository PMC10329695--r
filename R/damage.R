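## Dwell-time threshold damage model, ablation / organ-at-risk metrics, and
## the laser power-by-time dose-grid optimization.

#' Damage model configuration
#'
#' Threshold dwell-time necrosis model: the injury indicator theta integrates
#' `1/t_n` over the time the local temperature exceeds the damage temperature
#' `T_d`, and the necrotic fraction is `Omega = min(theta, 1)`. The defaults
#' (`T_d = 60` degC, `t_n = 1` s) make ablation effectively instantaneous at
#' 60 degC, so the final necrotic zone closely tracks the 60 degC isotherm.
#'
#' @param T_d damage temperature threshold, degC (> 37).
#' @param t_n dwell time for irreversible necrosis above `T_d`, s (> 0).
#' @return An object of class `litt_damage_config`.
#' @export
damage_config <- function(T_d = 60, t_n = 1) {
  stopifnot(T_d > 37, t_n > 0)
  structure(list(T_d = T_d, t_n = t_n), class = "litt_damage_config")
}

#' Accumulate dwell-time thermal damage from temperature histories
#'
#' `theta = integral of (1/t_n) * (T > T_d) dt` on the uniform time grid of
#' the supplied history, and `Omega = min(theta, 1)`.
#'
#' @param T_history numeric matrix: rows are time points (uniformly spaced),
#'   columns are cells; or a vector for a single cell.
#' @param dt time step of the history, s.
#' @param config a [damage_config()].
#' @return List with vectors `theta` and `Omega` (one entry per cell).
#' @export
accumulate_damage <- function(T_history, dt, config = damage_config()) {
  stopifnot(inherits(config, "litt_damage_config"), dt > 0)
  if (is.vector(T_history)) T_history <- matrix(T_history, ncol = 1)
  theta <- colSums(T_history > config$T_d) * dt / config$t_n
  list(theta = theta, Omega = pmin(theta, 1))
}

#' Ablation and organ-at-risk metrics of a simulation
#'
#' Computes, from a finished [solve_litt()] run: the ablated volume (cells
#' with `Omega = 1`), the ablated percentage of the tumor-plus-safety-margin
#' target, the areas inside the 42 degC and 60 degC isotherms on the plane
#' through the fiber axis, the organ-at-risk maximum temperature, the probe
#' maximum temperatures and the safety-margin surface mean-temperature trace.
#'
#' @param sim a `litt_sim`.
#' @return An object of class `litt_ablation_metrics`.
#' @export
ablation_metrics <- function(sim) {
  stopifnot(inherits(sim, "litt_sim"))
  ph <- sim$phantom
  masks <- phantom_masks(ph)
  target <- masks$tumor | masks$margin
  if (!any(target))
    stop("empty tumor/margin masks: ablation fraction is undefined")
  vol <- ph$cell_volume
  abl <- sim$Omega >= 1
  ablated_volume <- sum(vol[abl]) * 1e9
  frac <- 100 * sum(vol[abl & target]) / sum(vol[target])
  areas <- isotherm_areas(sim, c(42, 60))
  structure(list(
    ablated_volume = ablated_volume,
    ablated_fraction = frac,
    area_42C = areas[["42"]], area_60C = areas[["60"]],
    oar_name = sim$oar_name,
    oar_max = if (all(is.na(sim$oar_trace))) NA_real_ else
      max(sim$oar_trace, na.rm = TRUE),
    probe_max = apply(sim$probe_traces, 2, max),
    margin_trace = data.frame(time = sim$times, mean_T = sim$margin_trace)),
    class = "litt_ablation_metrics")
}

## Areas (mm^2) inside given isotherms on the cross-section through the
## fiber axis at end of exposure.
isotherm_areas <- function(sim, levels) {
  ph <- sim$phantom
  if (ph$mode == "axisymmetric") {
    ## plane through the axis: both half-planes, cell area dr * dz
    dr <- diff(ph$edges[[1]]); dz <- diff(ph$edges[[2]])
    cell_area <- outer(dr, dz)
    Tm <- sim$T_final
    out <- sapply(levels, function(lv)
      2 * sum(cell_area[!is.na(Tm) & Tm >= lv]))
  } else {
    k <- which.min(abs(ph$centers[[2]] - ph$fiber$tip[2]))
    Tm <- sim$T_final[, k, ]
    a <- ph$spacing[1] * ph$spacing[3]
    out <- sapply(levels, function(lv) a * sum(Tm >= lv, na.rm = TRUE))
  }
  stats::setNames(out, as.character(levels))
}

#' @export
print.litt_ablation_metrics <- function(x, ...) {
  cat("Ablation metrics\n")
  cat("  ablated volume:", round(x$ablated_volume, 1), "mm^3\n")
  cat("  ablated fraction of tumor+margin:", round(x$ablated_fraction, 1),
      "%\n")
  cat("  cross-section areas: >=60 degC", round(x$area_60C, 1),
      "mm^2, >=42 degC", round(x$area_42C, 1), "mm^2\n")
  if (!is.na(x$oar_name))
    cat("  organ at risk (", x$oar_name, ") max: ", round(x$oar_max, 2),
        " degC\n", sep = "")
  cat("  probe max temperatures:",
      paste(round(x$probe_max, 2), collapse = ", "), "degC\n")
  invisible(x)
}

#' Laser power-by-time dose-grid search
#'
#' Runs one coupled simulation per laser power (to the longest duration) and
#' reads out, at every duration along the march, the ablated percentage of
#' the tumor-plus-margin target and the running maximum organ-at-risk
#' temperature. Because the necrotic fraction is monotone in time, a single
#' time-marching run per power populates the whole duration axis.
#'
#' @param phantom a `litt_phantom` with tumor and margin masks.
#' @param models a [tissue_model_set()].
#' @param powers laser powers, W (default 2-10 W step 1).
#' @param durations exposure times, s (default 50-600 s step 50).
#' @param config a [solver_config()] (its `t_end`/`readout_times` are
#'   overridden by `durations`).
#' @param boundary a [boundary_spec()].
#' @param damage a [damage_config()].
#' @param fiber_radius,sigma passed to [laser_config()].
#' @return An object of class `litt_dose_grid`: matrices `ablated` (%) and
#'   `oar_max` (degC) with durations in rows and powers in columns, plus the
#'   run metadata. Failed combinations are flagged `NA` and the grid
#'   continues.
#' @export
dose_grid_search <- function(phantom, models, powers = 2:10,
                             durations = seq(50, 600, by = 50),
                             config = solver_config(),
                             boundary = boundary_spec(),
                             damage = damage_config(),
                             fiber_radius = 150, sigma = fiber_radius / 3) {
  stopifnot(length(powers) >= 1, length(durations) >= 1,
            all(powers > 0), all(durations > 0))
  masks <- phantom_masks(phantom)
  if (!any(masks$tumor | masks$margin))
    stop("empty tumor/margin masks: dose metrics are undefined")
  durations <- sort(durations)
  off <- abs(durations / config$dt - round(durations / config$dt))
  if (any(off > 1e-9))
    stop("durations must be multiples of the solver time step (dt = ",
         config$dt, " s)")
  ablated <- oar <- matrix(NA_real_, length(durations), length(powers),
                           dimnames = list(duration = durations,
                                           power = powers))
  oar_name <- NA
  for (pi in seq_along(powers)) {
    cfg <- config
    cfg$t_end <- max(durations)
    cfg$readout_times <- durations
    sim <- tryCatch(
      solve_litt(phantom, models, laser_config(powers[pi], fiber_radius,
                                               sigma),
                 config = cfg, boundary = boundary, damage = damage),
      error = function(e) e)
    if (inherits(sim, "error")) {
      warning("dose combo at P = ", powers[pi],
              " W failed: ", conditionMessage(sim), call. = FALSE)
      next
    }
    ro <- sim$readouts
    m <- match(durations, ro$time)
    ablated[, pi] <- ro$ablated_fraction[m]
    oar[, pi] <- ro$oar_max[m]
    oar_name <- sim$oar_name
  }
  structure(list(powers = powers, durations = durations, ablated = ablated,
                 oar_max = oar, oar_name = oar_name,
                 energy = outer(durations, powers)),
            class = "litt_dose_grid")
}

#' Construct a dose grid from precomputed matrices
#'
#' Useful for assembling synthetic grids when testing selection logic, and
#' for re-reading exported grids.
#'
#' @param powers,durations axes (W, s).
#' @param ablated,oar_max matrices (durations x powers).
#' @param oar_name label of the organ at risk.
#' @return A `litt_dose_grid`.
#' @export
dose_grid <- function(powers, durations, ablated, oar_max,
                      oar_name = NA) {
  ablated <- as.matrix(ablated); oar_max <- as.matrix(oar_max)
  stopifnot(all(dim(ablated) == c(length(durations), length(powers))),
            all(dim(oar_max) == dim(ablated)))
  structure(list(powers = powers, durations = durations, ablated = ablated,
                 oar_max = oar_max, oar_name = oar_name,
                 energy = outer(durations, powers)),
            class = "litt_dose_grid")
}

#' Select the optimal laser dose from a grid
#'
#' Among all (power, duration) combinations whose ablated percentage of the
#' tumor-plus-margin target reaches `ablation_threshold` and whose
#' organ-at-risk maximum temperature stays at or below `oar_limit`, selects
#' the one with the minimum output power; ties at equal power are broken by
#' minimum duration (hence minimum energy). Returns a "none" selection when
#' no combination qualifies within the operating range -- a valid clinical
#' outcome for large tumors.
#'
#' @param grid a `litt_dose_grid`.
#' @param ablation_threshold required ablated percentage (default 55: the
#'   margin-volume ratios make 55 % of tumor-plus-margin cover the tumor).
#' @param oar_limit organ-at-risk temperature limit, degC (default 42).
#' @return An object of class `litt_dose`: either the selected
#'   `power` (W), `duration` (s), `energy` (J, exactly power x duration) and
#'   achieved metrics, or a none-selection with `qualified = FALSE`.
#' @export
select_optimal_dose <- function(grid, ablation_threshold = 55,
                                oar_limit = 42) {
  stopifnot(inherits(grid, "litt_dose_grid"))
  ok <- !is.na(grid$ablated) & grid$ablated >= ablation_threshold &
    (is.na(grid$oar_max) | grid$oar_max <= oar_limit)
  ok[is.na(grid$ablated)] <- FALSE
  if (!any(ok)) {
    return(structure(list(qualified = FALSE, power = NA_real_,
                          duration = NA_real_, energy = NA_real_,
                          ablation_threshold = ablation_threshold,
                          oar_limit = oar_limit),
                     class = "litt_dose"))
  }
  w <- which(ok, arr.ind = TRUE)
  pw <- grid$powers[w[, 2]]
  du <- grid$durations[w[, 1]]
  best <- order(pw, du)[1]
  structure(list(qualified = TRUE,
                 power = pw[best], duration = du[best],
                 energy = pw[best] * du[best],
                 ablated = grid$ablated[w[best, 1], w[best, 2]],
                 oar_max = grid$oar_max[w[best, 1], w[best, 2]],
                 oar_name = grid$oar_name,
                 ablation_threshold = ablation_threshold,
                 oar_limit = oar_limit),
            class = "litt_dose")
}

#' @export
print.litt_dose_grid <- function(x, ...) {
  cat("Dose grid:", length(x$powers), "powers x", length(x$durations),
      "durations\n")
  cat("ablated fraction of tumor+margin (%):\n")
  print(round(x$ablated, 1))
  if (!all(is.na(x$oar_max))) {
    cat("organ-at-risk max temperature (degC):\n")
    print(round(x$oar_max, 1))
  }
  invisible(x)
}

#' Image of the ablated-fraction dose grid
#'
#' @param x a `litt_dose_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.litt_dose_grid <- function(x, ...) {
  image(x$durations, x$powers, x$ablated, xlab = "exposure time (s)",
        ylab = "laser power (W)", main = "ablated fraction (%)",
        col = hcl.colors(32, "viridis"), ...)
  invisible(x)
}

#' @export
print.litt_dose <- function(x, ...) {
  if (!x$qualified) {
    cat("No laser setting within the operating range reaches",
        x$ablation_threshold, "% ablation with the organ at risk kept <=",
        x$oar_limit, "degC\n")
  } else {
    cat("Optimal laser dose: ", x$power, " W for ", x$duration, " s (E = ",
        x$energy, " J)\n", sep = "")
    cat("  ablated fraction:", round(x$ablated, 1), "% (threshold",
        x$ablation_threshold, "%)\n")
    if (!is.null(x$oar_max) && !is.na(x$oar_max))
      cat("  organ-at-risk max: ", round(x$oar_max, 2), " degC (limit ",
          x$oar_limit, " degC)\n", sep = "")
  }
  invisible(x)
}

#' Write a dose grid as CSV tables
#'
#' Writes two CSV files mirroring the clinical dose-table layout (rows:
#' exposure time; columns: output power): `<stem>_ablated.csv` with the
#' ablated percentages and `<stem>_oar.csv` with the organ-at-risk maximum
#' temperatures.
#'
#' @param grid a `litt_dose_grid`.
#' @param stem output path stem.
#' @return The two file paths, invisibly.
#' @export
write_dose_grid_csv <- function(grid, stem) {
  stopifnot(inherits(grid, "litt_dose_grid"))
  f1 <- paste0(stem, "_ablated.csv"); f2 <- paste0(stem, "_oar.csv")
  d1 <- data.frame(duration_s = grid$durations, grid$ablated,
                   check.names = FALSE)
  names(d1)[-1] <- paste0("P", grid$powers, "W")
  write.csv(d1, f1, row.names = FALSE)
  d2 <- data.frame(duration_s = grid$durations, grid$oar_max,
                   check.names = FALSE)
  names(d2)[-1] <- paste0("P", grid$powers, "W")
  write.csv(d2, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
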