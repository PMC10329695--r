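## Synthetic anatomies: labeled voxel grids (3D) and axisymmetric (r, z)
## grids standing in for segmented patient models. Coordinates are voxel/cell
## centers in mm measured from the domain corner (axisymmetric: from the
## axis/domain base); indices are 1-based in R fashion.

LABELS <- c(background = 1L, pancreas = 2L, tumor = 3L, margin = 4L,
            soft_tissue = 5L, duodenum = 6L)

#' Specification of a synthetic phantom
#'
#' Describes a synthetic stand-in for a segmented patient anatomy: an
#' ellipsoidal tumor embedded in a pancreas ellipsoid, a safety-margin shell
#' dilated around the tumor, optional cylindrical vessels carrying convective
#' cooling, an optional duodenum slab, and the laser fiber placement. The
#' anatomy is embedded in a background cube whose outer surface carries the
#' fixed-temperature boundary.
#'
#' @param mode `"voxel3d"` or `"axisymmetric"`.
#' @param domain_size domain extent per axis, mm (3 values; axisymmetric: 2
#'   values, radial then axial extent).
#' @param voxel_spacing isotropic voxel edge, mm (voxel mode).
#' @param tumor_semi_axes ellipsoid semi-axes (a, b, c), mm.
#' @param tumor_center mm; default domain center.
#' @param margin_thickness safety-margin shell thickness, mm (default 5; the
#'   clinical margin is "up to 5 mm").
#' @param pancreas_semi_axes mm; default `tumor_semi_axes + margin_thickness
#'   + 8` so the margin always lies in parenchyma.
#' @param vessels list of vessels, each
#'   `list(name, p0, p1, radius, h)` with segment endpoints `p0`, `p1` (mm),
#'   radius (mm) and convective film coefficient `h` (W/(m^2 K)).
#' @param soft_shell_thickness soft-tissue sheath around each vessel, mm
#'   (default 1).
#' @param duodenum optional `list(axis, offset, thickness)`: a slab normal to
#'   the given axis (1, 2 or 3) spanning `[offset, offset + thickness]` mm.
#' @param fiber `list(entry, direction, tip, radius_um)`; `direction` must be
#'   a unit vector (voxel mode: grid-axis aligned for the beam builder);
#'   `tip` defaults to the tumor center (end-firing bare fiber).
#' @param probe_lateral_mm perpendicular probe distance from the fiber axis,
#'   mm (default 15).
#' @param axisym list of axisymmetric grid controls: `fine_spacing` (mm,
#'   spacing in the refined region near the axis and fiber tip),
#'   `fine_span` (mm extent of the refined region), `growth` (geometric
#'   coarsening ratio) and `max_spacing` (mm cap).
#' @return An object of class `litt_phantom_spec`.
#' @export
phantom_spec <- function(mode = c("voxel3d", "axisymmetric"),
                         domain_size,
                         voxel_spacing = 1,
                         tumor_semi_axes = c(9.2, 9.2, 9.2),
                         tumor_center = NULL,
                         margin_thickness = 5,
                         pancreas_semi_axes = NULL,
                         vessels = list(),
                         soft_shell_thickness = 1,
                         duodenum = NULL,
                         fiber = NULL,
                         probe_lateral_mm = 15,
                         axisym = list()) {
  mode <- match.arg(mode)
  stopifnot(voxel_spacing > 0, margin_thickness >= 0)
  if (mode == "voxel3d") {
    stopifnot(length(domain_size) == 3, all(domain_size > 0))
    if (is.null(tumor_center)) tumor_center <- domain_size / 2
    stopifnot(length(tumor_semi_axes) == 3, all(tumor_semi_axes > 0))
    if (is.null(pancreas_semi_axes))
      pancreas_semi_axes <- tumor_semi_axes + margin_thickness + 8
    clearance <- pmin(tumor_center - tumor_semi_axes,
                      domain_size - tumor_center - tumor_semi_axes)
    if (any(clearance < margin_thickness))
      stop("geometry error: tumor (plus margin clearance) exceeds the domain")
    if (is.null(fiber))
      fiber <- list(entry = c(tumor_center[1], tumor_center[2], 0),
                    direction = c(0, 0, 1))
    fiber$tip <- fiber$tip %||% tumor_center
    fiber$radius_um <- fiber$radius_um %||% 150
    if (abs(sqrt(sum(fiber$direction^2)) - 1) > 1e-6)
      stop("fiber direction must have unit norm")
  } else {
    stopifnot(length(domain_size) == 2, all(domain_size > 0))
    if (length(vessels))
      stop("unsupported in axisymmetric mode: vessels (homogeneous tissue only)")
    if (is.null(fiber)) fiber <- list(entry = c(0, 0), direction = c(0, 1))
    fiber$tip <- fiber$tip %||% c(0, domain_size[2] / 3)
    fiber$radius_um <- fiber$radius_um %||% 150
    if (abs(sqrt(sum(fiber$direction^2)) - 1) > 1e-6)
      stop("fiber direction must have unit norm")
  }
  for (v in vessels) {
    stopifnot(!is.null(v$radius), !is.null(v$h))
    if (v$radius <= 0) stop("vessel radii must be positive")
    if (v$h < 0) stop("vessel h must be non-negative")
  }
  ax <- modifyList(list(fine_spacing = 0.2, fine_span = 4, growth = 1.3,
                        max_spacing = 2), axisym)
  structure(list(mode = mode, domain_size = domain_size,
                 voxel_spacing = voxel_spacing,
                 tumor_semi_axes = tumor_semi_axes,
                 tumor_center = tumor_center,
                 margin_thickness = margin_thickness,
                 pancreas_semi_axes = pancreas_semi_axes,
                 vessels = vessels,
                 soft_shell_thickness = soft_shell_thickness,
                 duodenum = duodenum, fiber = fiber,
                 probe_lateral_mm = probe_lateral_mm, axisym = ax),
            class = "litt_phantom_spec")
}

#' Build a labeled 3D voxel phantom
#'
#' Rasterizes a [phantom_spec()] onto a uniform voxel grid: each voxel gets
#' exactly one tissue label (background cube, pancreas, tumor, safety margin,
#' soft tissue, duodenum, or a vessel). The safety margin is the morphological
#' dilation of the voxelized tumor by `margin_thickness` (Euclidean distance
#' to the tumor surface) minus the tumor, clipped to the pancreas. Vessel
#' voxels are excluded from the conduction domain downstream; their surface
#' faces carry the convective boundary.
#'
#' @param spec a [phantom_spec()] with `mode = "voxel3d"`.
#' @return An object of class `litt_phantom`.
#' @export
build_voxel_phantom <- function(spec) {
  stopifnot(inherits(spec, "litt_phantom_spec"), spec$mode == "voxel3d")
  h <- spec$voxel_spacing
  if (spec$margin_thickness > 0 && h > spec$margin_thickness)
    stop("resolution error: voxel spacing is coarser than the margin thickness")
  dims <- as.integer(round(spec$domain_size / h))
  stopifnot(all(dims >= 3))
  edges <- lapply(dims, function(n) seq(0, by = h, length.out = n + 1L))
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  X <- array(centers[[1]], dims)
  Y <- array(rep(centers[[2]], each = nx), dims)
  Z <- array(rep(centers[[3]], each = nx * ny), dims)

  lab <- array(LABELS[["background"]], dims)
  ell <- function(cen, ax) ((X - cen[1]) / ax[1])^2 +
    ((Y - cen[2]) / ax[2])^2 + ((Z - cen[3]) / ax[3])^2
  lab[ell(spec$tumor_center, spec$pancreas_semi_axes) <= 1] <-
    LABELS[["pancreas"]]

  ## duodenum slab (only over non-pancreas or pancreas? it is its own organ:
  ## carve from whatever is there except tumor/margin, applied before tumor)
  if (!is.null(spec$duodenum)) {
    d <- spec$duodenum
    crd <- list(X, Y, Z)[[d$axis]]
    lab[crd >= d$offset & crd <= d$offset + d$thickness] <-
      LABELS[["duodenum"]]
  }

  ## soft-tissue sheath then vessels (vessels overwrite their sheath core)
  vessel_labels <- integer(0)
  next_code <- max(LABELS) + 1L
  for (v in spec$vessels) {
    dseg <- point_segment_distance(X, Y, Z, v$p0, v$p1)
    if (spec$soft_shell_thickness > 0)
      lab[dseg <= v$radius + spec$soft_shell_thickness & dseg > v$radius &
            lab != LABELS[["tumor"]]] <- LABELS[["soft_tissue"]]
    lab[dseg <= v$radius] <- next_code
    vessel_labels[v$name] <- next_code
    next_code <- next_code + 1L
  }

  tum <- ell(spec$tumor_center, spec$tumor_semi_axes) <= 1
  ## safety margin: dilation of the voxelized tumor by the margin thickness
  if (spec$margin_thickness > 0) {
    marg <- dilate_mask(tum, dims, centers, spec$margin_thickness)
    lab[marg & !tum & lab == LABELS[["pancreas"]]] <- LABELS[["margin"]]
  }
  lab[tum] <- LABELS[["tumor"]]

  label_names <- c(LABELS, vessel_labels)
  tissue_of <- c(names(LABELS), rep("vessel", length(vessel_labels)))
  names(tissue_of) <- names(label_names)

  vol <- array(prod(rep(h, 3)) * 1e-9, dims)  # m^3
  ph <- structure(list(mode = "voxel3d", dims = dims, edges = edges,
                       centers = centers, spacing = rep(h, 3), label = lab,
                       label_names = label_names, tissue_of = tissue_of,
                       vessels = lapply(spec$vessels, function(v) {
                         v$code <- vessel_labels[[v$name]]; v
                       }),
                       fiber = spec$fiber, cell_volume = vol, spec = spec),
                  class = "litt_phantom")
  place_probes(ph, spec$probe_lateral_mm)
}

point_segment_distance <- function(X, Y, Z, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - p0[1] - t * v[1])^2 + (Y - p0[2] - t * v[2])^2 +
         (Z - p0[3] - t * v[3])^2)
}

## Euclidean dilation of a voxel mask by `dist` mm: voxels whose distance to
## the nearest tumor-surface voxel center is <= dist. Brute force against the
## surface voxel set, chunked to bound memory.
dilate_mask <- function(mask, dims, centers, dist) {
  if (!any(mask)) return(mask)
  surf <- mask_surface_nd(mask, dims)
  sidx <- which(surf)
  scoord <- cbind(centers[[1]][(sidx - 1L) %% dims[1] + 1L],
                  centers[[2]][((sidx - 1L) %/% dims[1]) %% dims[2] + 1L],
                  centers[[3]][(sidx - 1L) %/% (dims[1] * dims[2]) + 1L])
  ## candidates: non-tumor voxels within the expanded tumor bounding box
  h <- centers[[1]][2] - centers[[1]][1]
  pad <- dist + 2 * h
  bb <- apply(scoord, 2, range)
  cand <- which(!mask)
  cc <- cbind(centers[[1]][(cand - 1L) %% dims[1] + 1L],
              centers[[2]][((cand - 1L) %/% dims[1]) %% dims[2] + 1L],
              centers[[3]][(cand - 1L) %/% (dims[1] * dims[2]) + 1L])
  inbb <- cc[, 1] >= bb[1, 1] - pad & cc[, 1] <= bb[2, 1] + pad &
    cc[, 2] >= bb[1, 2] - pad & cc[, 2] <= bb[2, 2] + pad &
    cc[, 3] >= bb[1, 3] - pad & cc[, 3] <= bb[2, 3] + pad
  cand <- cand[inbb]; cc <- cc[inbb, , drop = FALSE]
  out <- mask
  if (length(cand)) {
    block <- max(1L, as.integer(2e7 / max(1L, nrow(scoord))))
    starts <- seq(1L, length(cand), by = block)
    hit <- logical(length(cand))
    for (s in starts) {
      e <- min(s + block - 1L, length(cand))
      d2 <- outer(cc[s:e, 1], scoord[, 1], `-`)^2 +
        outer(cc[s:e, 2], scoord[, 2], `-`)^2 +
        outer(cc[s:e, 3], scoord[, 3], `-`)^2
      hit[s:e] <- apply(d2, 1, min) <= dist^2
    }
    out[cand[hit]] <- TRUE
  }
  out
}

#' Build a homogeneous axisymmetric phantom
#'
#' Constructs a 2D (r, z) cell-centered grid with the laser fiber on the
#' symmetry axis and every cell labeled pancreas: the fast configuration for
#' homogeneous-tissue benchmarks (ex vivo style runs, analytic oracles, mesh
#' studies). The grid is graded: `fine_spacing` in a refined block around the
#' axis and the fiber tip, coarsening geometrically outward up to
#' `max_spacing`.
#'
#' @param spec a [phantom_spec()] with `mode = "axisymmetric"`. Vessels are
#'   not supported in this mode.
#' @return An object of class `litt_phantom` with `dims = c(nr, nz)`.
#' @export
build_axisymmetric_phantom <- function(spec) {
  stopifnot(inherits(spec, "litt_phantom_spec"))
  if (spec$mode != "axisymmetric")
    stop("spec mode must be axisymmetric")
  R <- spec$domain_size[1]; L <- spec$domain_size[2]
  a <- spec$axisym
  r_edges <- c(graded_out(0, min(a$fine_span, R), a$fine_spacing, 1, Inf),
               graded_out(min(a$fine_span, R), R, a$fine_spacing, a$growth,
                          a$max_spacing)[-1])
  ztip <- spec$fiber$tip[2]
  z_lo <- rev(ztip - (graded_out(0, ztip, a$fine_spacing, a$growth,
                                 a$max_spacing)))
  z_fine_end <- min(ztip + a$fine_span, L)
  z_mid <- graded_out(ztip, z_fine_end, a$fine_spacing, 1, Inf)[-1]
  z_hi <- graded_out(z_fine_end, L, a$fine_spacing, a$growth,
                     a$max_spacing)[-1]
  z_edges <- c(z_lo, z_mid, z_hi)
  edges <- list(r = r_edges, z = z_edges)
  dims <- c(length(r_edges) - 1L, length(z_edges) - 1L)
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  lab <- matrix(LABELS[["pancreas"]], dims[1], dims[2])
  ## cell volumes pi (r2^2 - r1^2) dz, in m^3
  r1 <- r_edges[-length(r_edges)]; r2 <- r_edges[-1]
  dz <- diff(z_edges)
  vol <- outer(pi * (r2^2 - r1^2), dz) * 1e-9
  ph <- structure(list(mode = "axisymmetric", dims = dims, edges = edges,
                       centers = centers, spacing = NA, label = lab,
                       label_names = LABELS,
                       tissue_of = stats::setNames(names(LABELS),
                                                   names(LABELS)),
                       vessels = list(), fiber = spec$fiber,
                       cell_volume = vol, spec = spec),
                  class = "litt_phantom")
  place_probes(ph, spec$probe_lateral_mm)
}

## Edge sequence from `from` towards `to` with spacing h0 * growth^k capped
## at hmax; the last edge is clamped onto `to`.
graded_out <- function(from, to, h0, growth, hmax) {
  if (abs(to - from) < 1e-12) return(from)
  e <- from; h <- h0
  while (e[length(e)] < to - 1e-9) {
    e <- c(e, min(e[length(e)] + h, to))
    h <- min(h * growth, hmax)
  }
  ## merge a trailing sliver into the previous cell
  n <- length(e)
  if (n > 2 && (e[n] - e[n - 1]) < 0.4 * (e[n - 1] - e[n - 2])) e <- e[-(n - 1)]
  e
}

#' Place lateral temperature probes
#'
#' Sets probe points at the stated perpendicular distance from the fiber
#' axis, at the axial height of the fiber tip (two mirrored points in voxel
#' mode; one radial point in axisymmetric mode, where the azimuth is
#' degenerate).
#'
#' @param phantom a `litt_phantom`.
#' @param lateral_distance perpendicular distance from the fiber axis, mm.
#' @return The phantom with `probes` (matrix of mm coordinates) replaced.
#' @export
place_probes <- function(phantom, lateral_distance = 15) {
  stopifnot(inherits(phantom, "litt_phantom"), lateral_distance >= 0)
  if (phantom$mode == "axisymmetric") {
    p <- matrix(c(lateral_distance, phantom$fiber$tip[2]), 1, 2,
                dimnames = list(NULL, c("r", "z")))
    if (lateral_distance > phantom$edges[[1]][length(phantom$edges[[1]])])
      stop("probe-placement error: probe outside the domain")
  } else {
    dirv <- phantom$fiber$direction
    ax <- which.max(abs(dirv))
    lat <- setdiff(1:3, ax)[1]
    tip <- phantom$fiber$tip
    p1 <- p2 <- tip
    p1[lat] <- tip[lat] + lateral_distance
    p2[lat] <- tip[lat] - lateral_distance
    p <- rbind(p1, p2)
    colnames(p) <- c("x", "y", "z")
    lims <- sapply(phantom$edges, range)
    if (any(t(p) < lims[1, ]) || any(t(p) > lims[2, ]))
      stop("probe-placement error: probe outside the domain")
  }
  phantom$probes <- p
  phantom
}

#' Named logical masks of a phantom
#'
#' @param phantom a `litt_phantom`.
#' @return Named list of logical arrays, one per label present plus `vessel`
#'   (union of all vessels).
#' @export
phantom_masks <- function(phantom) {
  stopifnot(inherits(phantom, "litt_phantom"))
  m <- lapply(phantom$label_names, function(code) phantom$label == code)
  m$vessel <- phantom$tissue_of[match(phantom$label,
                                      phantom$label_names)] == "vessel"
  dim(m$vessel) <- dim(phantom$label)
  m
}

#' Tumor, margin and label volumes of a phantom
#'
#' @param phantom a `litt_phantom`.
#' @return Named numeric vector of volumes in mm^3 per label.
#' @export
label_volumes <- function(phantom) {
  stopifnot(inherits(phantom, "litt_phantom"))
  sapply(phantom$label_names, function(code)
    sum(phantom$cell_volume[phantom$label == code]) * 1e9)
}

#' @export
print.litt_phantom <- function(x, ...) {
  cat("LITT phantom (", x$mode, "), grid ",
      paste(x$dims, collapse = " x "), " cells\n", sep = "")
  v <- label_volumes(x)
  v <- v[v > 0]
  cat("label volumes (mm^3):\n")
  print(round(v, 1))
  cat("fiber tip at (", paste(signif(x$fiber$tip, 4), collapse = ", "),
      ") mm, direction (", paste(x$fiber$direction, collapse = ", "), ")\n")
  if (!is.null(x$probes)) {
    cat("probes (mm):\n")
    print(round(x$probes, 2))
  }
  invisible(x)
}

#' @export
summary.litt_phantom <- function(object, ...) {
  print(object)
  if (object$mode == "voxel3d") {
    a <- object$spec$tumor_semi_axes
    cat("analytic tumor ellipsoid volume:",
        round(4 / 3 * pi * prod(a), 1), "mm^3\n")
  }
  invisible(object)
}

#' Mid-plane label image of a phantom
#'
#' @param x a `litt_phantom`.
#' @param ... passed to [graphics::image()].
#' @export
plot.litt_phantom <- function(x, ...) {
  if (x$mode == "axisymmetric") {
    image(x$centers[[1]], x$centers[[2]], x$label, xlab = "r (mm)",
          ylab = "z (mm)", main = "phantom labels", ...)
  } else {
    k <- which.min(abs(x$centers[[2]] - x$fiber$tip[2]))
    image(x$centers[[1]], x$centers[[3]], x$label[, k, ],
          xlab = "x (mm)", ylab = "z (mm)",
          main = sprintf("phantom labels, y = %.1f mm", x$centers[[2]][k]),
          ...)
  }
  invisible(x)
}
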