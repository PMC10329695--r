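# Shared fixtures: small phantoms and model sets built in code.

# Homogeneous axisymmetric phantom for solver benchmarks.
ax_phantom <- function(R = 25, L = 60, fine = 0.25, span = 4,
                       growth = 1.25, hmax = 2, tip_z = L / 3,
                       probe = 15) {
  build_axisymmetric_phantom(phantom_spec(
    mode = "axisymmetric", domain_size = c(R, L),
    fiber = list(entry = c(0, 0), direction = c(0, 1), tip = c(0, tip_z)),
    probe_lateral_mm = probe,
    axisym = list(fine_spacing = fine, fine_span = span, growth = growth,
                  max_spacing = hmax)))
}

# Small 3D phantom: 5 mm spherical tumor, 4 mm margin, one lateral vessel.
tumor_phantom <- function(spacing = 1.25, vessel = TRUE) {
  vs <- if (vessel)
    list(list(name = "splenic_vein", p0 = c(25.5, 0, 15),
              p1 = c(25.5, 30, 15), radius = 2, h = 750)) else list()
  build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(30, 30, 30), voxel_spacing = spacing,
    tumor_semi_axes = c(5, 5, 5), margin_thickness = 4, vessels = vs,
    probe_lateral_mm = 12))
}

# Constant-property model set for linear benchmarks (no perfusion unless
# omega0 is given; all tissues share pancreas thermal values).
const_models <- function(omega0 = 0) {
  tissue_model_set(
    temperature_dependent = FALSE,
    tissues = list(pancreas = baseline_props(1128, 0.52, 3164, omega0),
                   tumor = baseline_props(1128, 0.52, 3164, omega0),
                   margin = baseline_props(1128, 0.52, 3164, omega0)))
}

# Configuration that keeps the problem linear: no extrapolation warning,
# damage threshold far above any temperature reached.
linear_damage <- function() damage_config(T_d = 1e6, t_n = 1)

linear_config <- function(dt, t_end) {
  solver_config(dt = dt, t_end = t_end, warn_temperature = Inf)
}
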