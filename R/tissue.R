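## Constitutive models: baseline thermal properties, temperature-dependent
## conductivity and apparent volumetric heat capacity (water evaporation),
## tissue water content W(T), and piecewise-polynomial perfusion multipliers.

#' Baseline thermal properties of a tissue
#'
#' Bundles the properties entering the Pennes bioheat equation at normal body
#' temperature (37 degC): density, thermal conductivity, specific heat,
#' baseline capillary blood perfusion rate and metabolic heat generation.
#'
#' @param density kg/m^3.
#' @param conductivity W/(m*K).
#' @param specific_heat J/(kg*K).
#' @param perfusion baseline blood perfusion rate omega_0, 1/s.
#' @param metabolic_heat volumetric metabolic heat Q_met, W/m^3 (default 0).
#' @return An object of class `litt_baseline` (a named list).
#' @export
baseline_props <- function(density, conductivity, specific_heat,
                           perfusion = 0, metabolic_heat = 0) {
  stopifnot(density > 0, conductivity > 0, specific_heat > 0,
            perfusion >= 0, metabolic_heat >= 0)
  structure(list(density = density, conductivity = conductivity,
                 specific_heat = specific_heat, perfusion = perfusion,
                 metabolic_heat = metabolic_heat),
            class = "litt_baseline")
}

#' Tissue water-content model W(T)
#'
#' Remaining tissue water mass fraction as a function of temperature. Water
#' content holds its native value `W0` up to `onset` (default 80 degC), then
#' declines with a Weibull-type tail `W0 * exp(-((T - onset)/c)^shape)` whose
#' scale `c` is fixed so that exactly half the water is lost at `half_loss_T`
#' (default 103 degC). The high `shape` makes the decline accelerate sharply
#' near 100 degC and drop essentially to zero a few degrees above the
#' half-loss point, reproducing the carbonization-onset behavior of heated
#' soft tissue.
#'
#' @param W0 native water mass fraction (default 0.7, typical soft tissue).
#' @param onset degC at which evaporation begins (default 80).
#' @param half_loss_T degC at which half the water is gone (default 103).
#' @param shape Weibull shape exponent (default 6).
#' @return An object of class `litt_water_model`.
#' @export
water_model <- function(W0 = 0.7, onset = 80, half_loss_T = 103, shape = 6) {
  stopifnot(W0 > 0, W0 <= 1, half_loss_T > onset, shape >= 1)
  scale <- (half_loss_T - onset) / log(2)^(1 / shape)
  structure(list(W0 = W0, onset = onset, half_loss_T = half_loss_T,
                 shape = shape, scale = scale),
            class = "litt_water_model")
}

#' Remaining tissue water fraction at temperature T
#'
#' @param T temperature(s), degC.
#' @param model a [water_model()].
#' @return Remaining water mass fraction(s), monotone non-increasing in `T`,
#'   equal to `W0` at and below the onset temperature.
#' @export
water_fraction <- function(T, model = water_model()) {
  stopifnot(inherits(model, "litt_water_model"), all(T >= 0))
  w <- rep(model$W0, length(T))
  hot <- T > model$onset
  w[hot] <- model$W0 * exp(-((T[hot] - model$onset) / model$scale)^model$shape)
  w
}

#' Piecewise-polynomial blood perfusion multiplier
#'
#' Temperature dependence of the capillary blood perfusion rate relative to
#' its 37 degC baseline, for healthy and tumor tissue. Each model is a set of
#' quadratic branches on stated temperature ranges, derived from heated animal
#' models; healthy tissue peaks near 45 degC and tumor tissue near 42 degC,
#' after which perfusion collapses as the vasculature is destroyed.
#'
#' The multiplier is made total: it is 1 at and below 37 degC, follows the
#' printed branch polynomials on their ranges (the branches are intentionally
#' not continuous across breakpoints and are preserved as printed), holds the
#' last branch-end value above the final breakpoint, and is 0 wherever the
#' necrotic fraction `Omega` has reached 1 (coagulated tissue is not
#' perfused).
#'
#' @param T temperature(s), degC.
#' @param kind `"healthy"` or `"tumor"`.
#' @param Omega necrotic fraction(s) in \[0, 1\] (scalar or same length as
#'   `T`).
#' @return Dimensionless non-negative multiplier(s) of the baseline perfusion.
#' @examples
#' perfusion_multiplier(40, "healthy")
#' perfusion_multiplier(42.5, "tumor")
#' @export
perfusion_multiplier <- function(T, kind = c("healthy", "tumor"), Omega = 0) {
  kind <- match.arg(kind)
  stopifnot(all(T >= 0), all(Omega >= 0), all(Omega <= 1))
  br <- perfusion_branches(kind)
  m <- rep(1, length(T))
  for (i in seq_len(nrow(br))) {
    sel <- T > br$lo[i] & T <= br$hi[i]
    m[sel] <- br$a[i] * T[sel]^2 + br$b[i] * T[sel] + br$c[i]
  }
  last <- nrow(br)
  above <- T > br$hi[last]
  if (any(above)) {
    Tend <- br$hi[last]
    m[above] <- br$a[last] * Tend^2 + br$b[last] * Tend + br$c[last]
  }
  m <- pmax(m, 0)
  m[rep_len(Omega, length(T)) >= 1] <- 0
  m
}

perfusion_branches <- function(kind) {
  if (kind == "healthy") {
    data.frame(lo = c(37, 42, 45), hi = c(42, 45, 48),
               a = c(4.7167e-2, -7.7906e-2, -15.6972e-2),
               b = c(-3.5367, 9.6329, 11.8435),
               c = c(67.2974, -267.0257, -205.5134))
  } else {
    data.frame(lo = c(37, 42), hi = c(42, 44),
               a = c(3.40e-2, -0.6891),
               b = c(-2.5276, 58.5436),
               c = c(47.9933, -1241.5792))
  }
}

#' Temperature-dependent property curves for one tissue
#'
#' Builds the thermal-conductivity and apparent volumetric-heat-capacity
#' curves for a tissue from its baseline properties. Both are piecewise-linear
#' anchor curves in relative (multiplier) units, pinned to 1 at 37 degC so the
#' baseline values are reproduced exactly.
#'
#' The heat-capacity curve carries an apparent-capacity peak spanning the
#' water-evaporation band: a triangular excess rising from `peak_lo` (80 degC)
#' to `peak_T` (100 degC) and returning to baseline at `peak_hi` (104 degC),
#' sized so that its integral equals the latent heat `h_fg` times the tissue
#' water content. Absorbing the evaporation enthalpy in the storage term this
#' way includes the `h_fg * dW/dt` sink of the bioheat equation implicitly.
#'
#' The default conductivity anchors rise modestly towards 100 degC and fall
#' back once evaporation completes, mimicking ex vivo measurements on heated
#' liver; users may substitute digitized curves via `k_anchors`.
#'
#' @param baseline a [baseline_props()] object.
#' @param water a [water_model()]; sets the water content entering the peak.
#' @param h_fg latent heat of water evaporation, kJ/kg (default 2260).
#' @param k_anchors 2-column matrix (degC, multiplier) for conductivity;
#'   `NULL` for the default anchors.
#' @param peak_T,peak_lo,peak_hi degC anchors of the capacity peak.
#' @return An object of class `litt_property_curves`.
#' @export
property_curves <- function(baseline, water = water_model(), h_fg = 2260,
                            k_anchors = NULL,
                            peak_T = 100, peak_lo = 80, peak_hi = 104) {
  stopifnot(inherits(baseline, "litt_baseline"),
            inherits(water, "litt_water_model"),
            h_fg > 0, peak_lo < peak_T, peak_T < peak_hi)
  if (is.null(k_anchors)) {
    k_anchors <- cbind(T = c(0, 37, 80, 100, 110, 200),
                       mult = c(1, 1, 1, 1.3, 0.95, 0.95))
  }
  stopifnot(ncol(k_anchors) == 2, !is.unsorted(k_anchors[, 1]))
  ## Triangle excess area (degC * multiplier) = h_fg * W0 / C_p, so that
  ## integral of (C' - rho*C) dT over the band = h_fg * rho * W0.
  area <- h_fg * 1000 * water$W0 / baseline$specific_heat
  peak_mult <- 1 + 2 * area / (peak_hi - peak_lo)
  c_anchors <- cbind(T = c(0, 37, peak_lo, peak_T, peak_hi, 200),
                     mult = c(1, 1, 1, peak_mult, 1, 1))
  structure(list(baseline = baseline, water = water, h_fg = h_fg,
                 k_anchors = k_anchors, c_anchors = c_anchors,
                 peak = c(lo = peak_lo, T = peak_T, hi = peak_hi)),
            class = "litt_property_curves")
}

#' Volumetric enthalpy relative to 0 degC
#'
#' Integral of the apparent volumetric heat capacity,
#' `H(T) = integral of C'(T') dT'` from 0 to `T`, evaluated exactly on the
#' piecewise-linear capacity anchors (piecewise quadratic in `T`). The
#' secant of `H` between two temperatures is the energy-consistent
#' effective capacity used by the solver when a cell crosses the
#' evaporation band within one time step.
#'
#' @param T temperature(s), degC.
#' @param curves a [property_curves()] object.
#' @return Enthalpy density in J/m^3.
#' @export
volumetric_enthalpy <- function(T, curves) {
  stopifnot(inherits(curves, "litt_property_curves"))
  a <- curves$c_anchors
  scale <- curves$baseline$density * curves$baseline$specific_heat
  Ta <- a[, 1]; Ca <- a[, 2] * scale
  Ha <- c(0, cumsum((Ca[-1] + Ca[-length(Ca)]) / 2 * diff(Ta)))
  Tc <- pmin(pmax(T, Ta[1]), Ta[length(Ta)])
  i <- findInterval(Tc, Ta, rightmost.closed = TRUE)
  slope <- (Ca[pmin(i + 1, length(Ca))] - Ca[i]) /
    pmax(Ta[pmin(i + 1, length(Ta))] - Ta[i], 1e-300)
  dT <- Tc - Ta[i]
  H <- Ha[i] + Ca[i] * dT + 0.5 * slope * dT^2
  ## constant-capacity extension beyond the anchor support
  H + (T - Tc) * Ca[length(Ca)] * (T > Ta[length(Ta)]) +
    (T - Tc) * Ca[1] * (T < Ta[1])
}

curve_mult <- function(T, anchors) {
  stats::approx(anchors[, 1], anchors[, 2], xout = T, rule = 2)$y
}

#' Thermal conductivity at temperature T
#'
#' @param T temperature(s), degC.
#' @param curves a [property_curves()] object.
#' @return k(T) in W/(m*K); boundary values are held outside the anchor
#'   support.
#' @export
thermal_conductivity <- function(T, curves) {
  stopifnot(inherits(curves, "litt_property_curves"))
  curves$baseline$conductivity * curve_mult(T, curves$k_anchors)
}

#' Apparent volumetric heat capacity at temperature T
#'
#' Volumetric heat capacity C' = rho * C augmented by the evaporation peak
#' (see [property_curves()]).
#'
#' @param T temperature(s), degC.
#' @param curves a [property_curves()] object.
#' @return C'(T) in J/(m^3*K).
#' @export
volumetric_heat_capacity <- function(T, curves) {
  stopifnot(inherits(curves, "litt_property_curves"))
  curves$baseline$density * curves$baseline$specific_heat *
    curve_mult(T, curves$c_anchors)
}

#' Default tissue model set
#'
#' Assembles the full constitutive description used by the solver: per-tissue
#' baseline properties at 37 degC, temperature-dependence curves, the
#' perfusion model kind per tissue, shared optical properties, the water
#' model, and blood properties.
#'
#' Defaults are the native-tissue property table of the underlying model:
#' pancreas (rho 1128, k 0.52, C 3164, omega0 0.018), pancreatic tumor (same
#' thermal values, omega0 0.005), duodenum (1126, 0.53, 3690, 0.015) and
#' generic soft tissue (1050, 0.49, 3400, 0.003), with blood at rho_b 1050
#' kg/m^3, C_b 3617 J/(kg*K), T_b 37 degC. The tumor uses the tumor perfusion
#' branches; all other perfused tissues use the healthy branches. Metabolic
#' heat defaults to 0 W/m^3 for every tissue. The embedding background cube is
#' given soft-tissue properties with no perfusion.
#'
#' @param tissues named list of [baseline_props()] overriding or extending the
#'   defaults.
#' @param perfusion_kind named character vector mapping tissue name to
#'   `"healthy"`, `"tumor"` or `"none"`.
#' @param optics an [optical_props()] set shared by all soft tissues.
#' @param water a [water_model()].
#' @param h_fg latent heat of evaporation, kJ/kg.
#' @param blood list with `density` (kg/m^3), `specific_heat` (J/(kg*K)) and
#'   `temperature` (degC).
#' @param temperature_dependent logical; `FALSE` freezes k and C' at their
#'   37 degC values and the perfusion multiplier at 1 (ex vivo style runs
#'   additionally set omega0 = 0 per tissue).
#' @return An object of class `litt_tissue_set`.
#' @export
tissue_model_set <- function(tissues = list(), perfusion_kind = character(),
                             optics = optical_props(), water = water_model(),
                             h_fg = 2260,
                             blood = list(density = 1050, specific_heat = 3617,
                                          temperature = 37),
                             temperature_dependent = TRUE) {
  base <- list(
    pancreas    = baseline_props(1128, 0.52, 3164, 0.018),
    tumor       = baseline_props(1128, 0.52, 3164, 0.005),
    margin      = baseline_props(1128, 0.52, 3164, 0.018),
    duodenum    = baseline_props(1126, 0.53, 3690, 0.015),
    soft_tissue = baseline_props(1050, 0.49, 3400, 0.003),
    background  = baseline_props(1050, 0.49, 3400, 0)
  )
  for (nm in names(tissues)) {
    stopifnot(inherits(tissues[[nm]], "litt_baseline"))
    base[[nm]] <- tissues[[nm]]
  }
  kind <- c(pancreas = "healthy", tumor = "tumor", margin = "healthy",
            duodenum = "healthy", soft_tissue = "healthy",
            background = "none")
  for (nm in names(perfusion_kind)) kind[nm] <- perfusion_kind[nm]
  extra <- setdiff(names(base), names(kind))
  if (length(extra)) kind[extra] <- "healthy"
  stopifnot(all(kind %in% c("healthy", "tumor", "none")))
  curves <- lapply(base, property_curves, water = water, h_fg = h_fg)
  structure(list(baseline = base, curves = curves, perfusion_kind = kind,
                 optics = optics, water = water, h_fg = h_fg, blood = blood,
                 temperature_dependent = temperature_dependent),
            class = "litt_tissue_set")
}

#' @export
print.litt_tissue_set <- function(x, ...) {
  cat("Tissue model set (", length(x$baseline), " tissues)\n", sep = "")
  tab <- do.call(rbind, lapply(names(x$baseline), function(nm) {
    b <- x$baseline[[nm]]
    data.frame(tissue = nm, density = b$density, k = b$conductivity,
               C = b$specific_heat, omega0 = b$perfusion,
               perfusion = unname(x$perfusion_kind[nm]))
  }))
  print(tab, row.names = FALSE)
  cat("blood: rho", x$blood$density, "kg/m3, C", x$blood$specific_heat,
      "J/(kg K), T_b", x$blood$temperature, "degC\n")
  cat("water: W0", x$water$W0, ", 50% loss at", x$water$half_loss_T,
      "degC; h_fg", x$h_fg, "kJ/kg\n")
  cat(if (x$temperature_dependent) "temperature-dependent properties"
      else "constant (37 degC) properties", "\n")
  invisible(x)
}

#' Serialize a tissue model set to YAML
#'
#' @param set a [tissue_model_set()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_tissue_yaml <- function(set, path) {
  stopifnot(inherits(set, "litt_tissue_set"))
  out <- list(
    tissues = lapply(set$baseline, function(b) {
      list(density = b$density, conductivity = b$conductivity,
           specific_heat = b$specific_heat, perfusion = b$perfusion,
           metabolic_heat = b$metabolic_heat)
    }),
    perfusion_kind = as.list(set$perfusion_kind),
    optics = unclass(set$optics),
    water = list(W0 = set$water$W0, onset = set$water$onset,
                 half_loss_T = set$water$half_loss_T, shape = set$water$shape),
    h_fg = set$h_fg,
    blood = set$blood,
    temperature_dependent = set$temperature_dependent
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a tissue model set from YAML
#'
#' @param path YAML file written by [write_tissue_yaml()] (or hand-edited in
#'   the same per-tissue block layout).
#' @return A [tissue_model_set()].
#' @export
read_tissue_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tissues <- lapply(y$tissues, function(b) {
    baseline_props(b$density, b$conductivity, b$specific_heat,
                   b$perfusion %||% 0, b$metabolic_heat %||% 0)
  })
  wm <- if (is.null(y$water)) water_model() else
    water_model(y$water$W0, y$water$onset, y$water$half_loss_T, y$water$shape)
  op <- if (is.null(y$optics)) optical_props() else
    do.call(optical_props, y$optics[c("native", "coagulated")])
  tissue_model_set(tissues = tissues,
                   perfusion_kind = unlist(y$perfusion_kind),
                   optics = op, water = wm,
                   h_fg = y$h_fg %||% 2260,
                   blood = y$blood %||% list(density = 1050,
                                             specific_heat = 3617,
                                             temperature = 37),
                   temperature_dependent = y$temperature_dependent %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
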