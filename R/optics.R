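## Laser-tissue optics: Gaussian-profile irradiance, Beer-Lambert axial decay
## with the effective attenuation coefficient, and coagulation-state blending
## of optical properties.

#' Optical properties of native and coagulated tissue
#'
#' Absorption coefficient `alpha`, scattering coefficient `alpha_s` (both
#' 1/mm) and scattering anisotropy factor `g` for native and coagulated
#' tissue at 1064 nm. Defaults are the soft-tissue values used throughout the
#' model: native (0.018, 4.34, 0.93), coagulated (0.011, 30.46, 0.92).
#' Coagulation strongly increases scattering, so the coagulated effective
#' attenuation exceeds the native one and deposition shifts towards the
#' fiber as tissue coagulates.
#'
#' @param native,coagulated lists with elements `alpha`, `alpha_s` (1/mm) and
#'   `g` (dimensionless, in \[0, 1\]).
#' @return An object of class `litt_optical_props`.
#' @export
optical_props <- function(native = list(alpha = 0.018, alpha_s = 4.34, g = 0.93),
                          coagulated = list(alpha = 0.011, alpha_s = 30.46, g = 0.92)) {
  chk <- function(p) {
    stopifnot(p$alpha >= 0, p$alpha_s >= 0, p$g >= 0, p$g <= 1)
    p[c("alpha", "alpha_s", "g")]
  }
  structure(list(native = chk(native), coagulated = chk(coagulated)),
            class = "litt_optical_props")
}

#' Effective attenuation coefficient
#'
#' `alpha_eff = sqrt(3 * alpha * (alpha + alpha_s * (1 - g)))`, the combined
#' absorption-scattering decay rate of laser fluence along the beam path
#' (diffusion-theory form). Units follow the inputs (1/mm in, 1/mm out).
#'
#' @param alpha linear absorption coefficient (>= 0).
#' @param alpha_s scattering coefficient (>= 0).
#' @param g anisotropy factor in \[0, 1\].
#' @return Effective attenuation coefficient, same units as `alpha`.
#' @examples
#' effective_attenuation(0.018, 4.34, 0.93) # native,    ~0.1318 /mm
#' effective_attenuation(0.011, 30.46, 0.92) # coagulated, ~0.2842 /mm
#' @export
effective_attenuation <- function(alpha, alpha_s, g) {
  if (any(alpha < 0) || any(alpha_s < 0) || any(g < 0) || any(g > 1))
    stop("optical coefficients must be non-negative and g in [0, 1]")
  sqrt(3 * alpha * (alpha + alpha_s * (1 - g)))
}

#' Blend optical properties by coagulated fraction
#'
#' Convex combination of native and coagulated coefficients weighted by the
#' necrotic fraction `Omega`: `alpha = alpha_n (1 - Omega) + alpha_c Omega`,
#' and likewise for `alpha_s` and `g`.
#'
#' @param Omega necrotic fraction(s) in \[0, 1\].
#' @param props an [optical_props()] set.
#' @return List with vectors `alpha`, `alpha_s`, `g` (same length as `Omega`).
#' @export
blend_optics <- function(Omega, props = optical_props()) {
  stopifnot(inherits(props, "litt_optical_props"))
  if (any(Omega < 0) || any(Omega > 1)) stop("Omega must lie in [0, 1]")
  n <- props$native; cg <- props$coagulated
  list(alpha   = n$alpha * (1 - Omega) + cg$alpha * Omega,
       alpha_s = n$alpha_s * (1 - Omega) + cg$alpha_s * Omega,
       g       = n$g * (1 - Omega) + cg$g * Omega)
}

#' Laser configuration
#'
#' Continuous-wave bare-fiber beam: output power `P`, fiber core radius `r_f`
#' (150 um for a 300 um fiber) and transverse Gaussian standard deviation
#' `sigma` (default `r_f / 3` = 50 um, which puts 99% of the output power
#' within the fiber core radius).
#'
#' @param power output laser power P, W (clinical range 2-10 W).
#' @param fiber_radius r_f, um.
#' @param sigma transverse standard deviation, um (default `fiber_radius/3`).
#' @param wavelength nm, informational (default 1064).
#' @return An object of class `litt_laser`.
#' @export
laser_config <- function(power, fiber_radius = 150, sigma = fiber_radius / 3,
                         wavelength = 1064) {
  stopifnot(length(power) == 1)
  if (power <= 0) stop("laser power must be positive")
  stopifnot(sigma > 0, sigma <= fiber_radius)
  structure(list(power = power, fiber_radius = fiber_radius, sigma = sigma,
                 wavelength = wavelength, mode = "cw"),
            class = "litt_laser")
}

#' Transverse Gaussian irradiance
#'
#' `I(x, y) = I_0 exp(-(x^2 + y^2) / (2 sigma^2))` with peak
#' `I_0 = P / (2 pi sigma^2)`; the plane integral equals the output power.
#'
#' @param x,y transverse offsets from the beam axis, um.
#' @param config a [laser_config()].
#' @return Irradiance in W/m^2.
#' @export
irradiance <- function(x, y, config) {
  stopifnot(inherits(config, "litt_laser"))
  s_m <- config$sigma * 1e-6
  I0 <- config$power / (2 * pi * s_m^2)
  I0 * exp(-((x * 1e-6)^2 + (y * 1e-6)^2) / (2 * s_m^2))
}

## Fraction of beam power inside a transverse interval [a, b] (mm) for one
## Cartesian axis; the 2D column mass is the product of the two axis factors.
gaussian_axis_mass <- function(a, b, center_mm, sigma_mm) {
  pnorm(b, mean = center_mm, sd = sigma_mm) -
    pnorm(a, mean = center_mm, sd = sigma_mm)
}

## Fraction of beam power inside the annulus [r1, r2] (mm) around the axis.
gaussian_annulus_mass <- function(r1, r2, sigma_mm) {
  exp(-r1^2 / (2 * sigma_mm^2)) - exp(-r2^2 / (2 * sigma_mm^2))
}

#' Build the volumetric laser heat-source field on a phantom
#'
#' Distributes the beam power over the grid using the Beer-Lambert law with
#' the transverse Gaussian profile: each beam-aligned cell column receives the
#' analytically integrated Gaussian mass of its footprint (power is conserved
#' on coarse grids even though `sigma` is sub-voxel), and along the incidence
#' direction each cell receives the difference of `exp(-tau)` across its
#' faces, where `tau` is the running path integral of the cell-local
#' effective attenuation from the fiber tip. With homogeneous optics this
#' reduces exactly to `Q = alpha_eff * I(x, y) * exp(-alpha_eff * z)` in
#' cell-integrated form. Cells upstream of the tip receive nothing.
#'
#' @param phantom a `litt_phantom` (voxel or axisymmetric).
#' @param config a [laser_config()].
#' @param alpha_eff_cells effective attenuation per cell, 1/mm; either a
#'   scalar (homogeneous optics) or an array matching the grid. Typically
#'   computed from [blend_optics()] + [effective_attenuation()] with the
#'   current necrotic fraction field.
#' @return An object of class `litt_source`: list with `power_cell` (W per
#'   cell, array), `density` (W/m^3, array), and bookkeeping fields.
#' @export
build_source_field <- function(phantom, config, alpha_eff_cells) {
  stopifnot(inherits(phantom, "litt_phantom"), inherits(config, "litt_laser"))
  sig_mm <- config$sigma * 1e-3
  if (phantom$mode == "axisymmetric") {
    src <- source_axisymmetric(phantom, config, alpha_eff_cells, sig_mm)
  } else {
    src <- source_voxel(phantom, config, alpha_eff_cells, sig_mm)
  }
  structure(c(src, list(power = config$power)), class = "litt_source")
}

source_axisymmetric <- function(ph, config, aeff, sig_mm) {
  re <- ph$edges[[1]]; ze <- ph$edges[[2]]
  nr <- length(re) - 1L; nz <- length(ze) - 1L
  if (length(aeff) == 1) aeff <- matrix(aeff, nr, nz)
  stopifnot(all(dim(aeff) == c(nr, nz)))
  ztip <- ph$fiber$tip[2]
  if (ztip < ze[1] || ztip > ze[nz + 1])
    stop("fiber tip lies outside the domain")
  mass_r <- gaussian_annulus_mass(re[-length(re)], re[-1], sig_mm)
  ## beam-path length of each axial cell downstream of the tip, mm
  seg <- pmax(ze[-1] - pmax(ze[-length(ze)], ztip), 0)
  pw <- matrix(0, nr, nz)
  for (i in seq_len(nr)) {
    ## per-column optical depth from the tip, cell-local attenuation (1/mm)
    tau_out <- cumsum(aeff[i, ] * seg)
    tau_in <- c(0, tau_out[-nz])
    pw[i, ] <- config$power * mass_r[i] * (exp(-tau_in) - exp(-tau_out)) *
      (seg > 0)
  }
  list(power_cell = pw, density = pw / ph$cell_volume,
       deposited = sum(pw))
}

source_voxel <- function(ph, config, aeff, sig_mm) {
  dims <- ph$dims
  if (length(aeff) == 1) aeff <- array(aeff, dims)
  stopifnot(all(dim(aeff) == dims))
  dirv <- ph$fiber$direction
  ax <- which(abs(abs(dirv) - 1) < 1e-9)
  if (length(ax) != 1 || sum(abs(dirv)) > 1 + 1e-9)
    stop("beam direction must be aligned with a grid axis (+/- x, y or z)")
  sgn <- sign(dirv[ax])
  tr <- setdiff(1:3, ax)
  tip <- ph$fiber$tip
  ## transverse Gaussian column masses (product of the two axis factors)
  m1 <- gaussian_axis_mass(ph$edges[[tr[1]]][-(dims[tr[1]] + 1L)],
                           ph$edges[[tr[1]]][-1], tip[tr[1]], sig_mm)
  m2 <- gaussian_axis_mass(ph$edges[[tr[2]]][-(dims[tr[2]] + 1L)],
                           ph$edges[[tr[2]]][-1], tip[tr[2]], sig_mm)
  keep1 <- which(m1 > 1e-12); keep2 <- which(m2 > 1e-12)
  e <- ph$edges[[ax]]
  n_ax <- dims[ax]
  pw <- array(0, dims)
  for (i in keep1) for (j in keep2) {
    idx <- vector("list", 3)
    idx[[tr[1]]] <- i; idx[[tr[2]]] <- j; idx[[ax]] <- seq_len(n_ax)
    ## march along the beam direction from the tip
    if (sgn > 0) {
      seg <- pmax(e[-1] - pmax(e[-length(e)], tip[ax]), 0)
      a_line <- do.call(`[`, c(list(aeff), idx))
      tau_out <- cumsum(a_line * seg)
      tau_in <- c(0, tau_out[-n_ax])
      p_line <- config$power * m1[i] * m2[j] *
        (exp(-tau_in) - exp(-tau_out)) * (seg > 0)
    } else {
      seg <- pmax(pmin(e[-1], tip[ax]) - e[-length(e)], 0)
      a_line <- do.call(`[`, c(list(aeff), idx))
      ## march from the tip towards decreasing coordinate
      ord <- rev(seq_len(n_ax))
      tau_out <- cumsum((a_line * seg)[ord])
      tau_in <- c(0, tau_out[-n_ax])
      p_rev <- config$power * m1[i] * m2[j] *
        (exp(-tau_in) - exp(-tau_out)) * (seg[ord] > 0)
      p_line <- p_rev[order(ord)]
    }
    pw <- do.call(`[<-`, c(list(pw), idx, list(p_line)))
  }
  list(power_cell = pw, density = pw / ph$cell_volume, deposited = sum(pw))
}

#' @export
print.litt_source <- function(x, ...) {
  cat("Laser source field: P =", x$power, "W, deposited",
      format(x$deposited, digits = 6), "W (",
      format(100 * x$deposited / x$power, digits = 4), "% of output)\n")
  cat("peak density:", format(max(x$density), digits = 4), "W/m^3\n")
  invisible(x)
}
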