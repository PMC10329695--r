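test_that("a source-free uniform field stays at body temperature", {
  ph <- ax_phantom(R = 20, L = 50, fine = 0.5)
  sim <- solve_litt(ph, tissue_model_set(), laser = NULL,
                    config = solver_config(dt = 2, t_end = 10))
  expect_lt(max(abs(sim$T_final - 37), na.rm = TRUE), 1e-9)
  # and a single step with zero source leaves the state untouched
  st <- solver_init(ph, tissue_model_set(), boundary_spec(),
                    solver_config(dt = 2))
  st2 <- bioheat_step(st, 2)
  expect_lt(max(abs(st2$T - 37)), 1e-9)
})

test_that("steady 1D slab with a convective face matches the textbook closed form", {
  m <- const_models()
  sp <- phantom_spec(mode = "voxel3d", domain_size = c(20, 4, 4),
                     voxel_spacing = 1, tumor_semi_axes = c(1, 1, 1),
                     tumor_center = c(10, 2, 2), margin_thickness = 0,
                     pancreas_semi_axes = c(1000, 1000, 1000),
                     probe_lateral_mm = 0)
  ph <- build_voxel_phantom(sp)
  h <- 250; k <- 0.52; L <- 0.020; T0 <- 50
  bc <- boundary_spec(outer = "neumann", T_dirichlet = T0,
                      faces = list(xlo = "dirichlet",
                                   xhi = list(type = "robin", h = h)))
  sim <- solve_litt(ph, m, laser = NULL, boundary = bc,
                    config = linear_config(dt = 200, t_end = 60000),
                    damage = linear_damage())
  # steady linear profile with flux q = (T0 - Tb) / (L/k + 1/h)
  q <- (T0 - 37) / (L / k + 1 / h)
  Tan <- T0 - q * (ph$centers[[1]] * 1e-3) / k
  expect_equal(sim$T_final[, 2, 2], Tan, tolerance = 5e-3)
})

test_that("steady perfused point source matches the closed-form Green's function", {
  wb <- 0.52 / (1050 * 3617 * 25e-6)  # penetration depth delta = 5 mm
  m <- const_models(omega0 = wb)
  sp <- phantom_spec(mode = "axisymmetric", domain_size = c(30, 60),
                     fiber = list(entry = c(0, 0), direction = c(0, 1),
                                  tip = c(0, 30)),
                     axisym = list(fine_spacing = 0.15, fine_span = 2,
                                   growth = 1.15, max_spacing = 1.5))
  ph <- build_axisymmetric_phantom(sp)
  topo <- littplan:::solver_topology(ph, boundary_spec())
  jc <- which.min(abs(ph$centers[[2]] - 30))
  src <- numeric(topo$n)
  src[topo$amap[(jc - 1) * ph$dims[1] + 1]] <- 0.5
  sim <- solve_litt(ph, m, laser = NULL, source_power = src,
                    config = linear_config(dt = 60, t_end = 4800),
                    damage = linear_damage())
  d_nom <- seq(2, 10, by = 2)
  js <- sapply(d_nom, function(d) which.min(abs(ph$centers[[2]] - (30 + d))))
  d_act <- ph$centers[[2]][js] - ph$centers[[2]][jc]
  Tnum <- sim$T_final[1, js]
  Tan <- analytic_perfused_point_source(0.5, 0.52, 1050, 3617, wb, d_act)
  expect_lt(max(abs(Tnum - Tan) / (Tan - 37)), 0.02)
})

test_that("the analytic point-source oracle is self-consistent", {
  # pure-conduction limit
  expect_equal(analytic_perfused_point_source(1, 0.5, omega_b = 0,
                                              r_mm = 5),
               1 / (4 * pi * 0.5 * 5e-3) + 37)
  # linear in source power
  t1 <- analytic_perfused_point_source(1, 0.52, 1050, 3617, 0.005, 5) - 37
  t2 <- analytic_perfused_point_source(2, 0.52, 1050, 3617, 0.005, 5) - 37
  expect_equal(t2, 2 * t1)
  expect_error(analytic_perfused_point_source(1, 0.5, r_mm = 0), "singular")
  # against high-resolution quadrature of the transient Green's function
  k <- 0.52; rho_c <- 1128 * 3164; wb <- 0.005
  b <- 1050 * 3617 * wb
  r <- 5e-3; q <- 1
  alpha <- k / rho_c
  g <- integrate(function(t)
    q / (rho_c * (4 * pi * alpha * t)^1.5) *
      exp(-r^2 / (4 * alpha * t) - b * t / rho_c),
    0, Inf, rel.tol = 1e-10)$value
  expect_equal(analytic_perfused_point_source(q, k, 1050, 3617, wb, 5),
               g + 37, tolerance = 1e-7)
})

test_that("the transient obeys the maximum principle away from the source", {
  # hot Dirichlet face, no source: interior never leaves [37, 50]
  m <- const_models()
  ph <- build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(20, 4, 4), voxel_spacing = 1,
    tumor_semi_axes = c(1, 1, 1), tumor_center = c(10, 2, 2),
    margin_thickness = 0, pancreas_semi_axes = c(1000, 1000, 1000),
    probe_lateral_mm = 0))
  bc <- boundary_spec(outer = "neumann", T_dirichlet = 50,
                      faces = list(xlo = "dirichlet"))
  st <- solver_init(ph, m, bc, linear_config(dt = 5, t_end = 100))
  for (s in 1:20) {
    st <- bioheat_step(st, 5)
    expect_true(all(st$T >= 37 - 1e-9))
    expect_true(all(st$T <= 50 + 1e-9))
    # monotone decay away from the hot face
    profile <- st$T[littplan:::solver_topology(ph, bc)$amap[
      (1:20) + ((2 - 1) + (2 - 1) * 4) * 20]]
    expect_true(all(diff(profile) <= 1e-9))
  }
})

test_that("halving the time step leaves the ablated volume nearly unchanged", {
  models <- tissue_model_set()
  run <- function(dt) {
    ph <- ax_phantom(R = 20, L = 50, fine = 0.25, span = 4, tip_z = 15,
                     probe = 10)
    suppressWarnings(solve_litt(ph, models, laser_config(3),
                                config = solver_config(dt = dt,
                                                       t_end = 200)))
  }
  a <- sapply(c(2, 1), function(dt) {
    s <- run(dt); sum(s$phantom$cell_volume[s$Omega >= 1]) * 1e9
  })
  expect_lt(abs(a[1] - a[2]) / a[2], 0.02)
})

test_that("grid refinement converges the ablation zone", {
  models <- tissue_model_set()
  a <- sapply(c(0.5, 0.25, 0.125), function(f) {
    ph <- ax_phantom(R = 20, L = 50, fine = f, span = 4, tip_z = 15,
                     probe = 10)
    s <- suppressWarnings(solve_litt(ph, models, laser_config(3),
                                     config = solver_config(dt = 2,
                                                            t_end = 120)))
    sum(s$phantom$cell_volume[s$Omega >= 1]) * 1e9
  })
  ch <- abs(diff(a)) / a[-1]
  expect_lt(ch[2], ch[1])       # successive changes shrink
  expect_lt(ch[2], 0.05)
})

test_that("probe traces heat monotonically during exposure", {
  models <- tissue_model_set()
  ph <- ax_phantom(R = 20, L = 50, fine = 0.25, span = 4, tip_z = 15,
                   probe = 10)
  sim <- suppressWarnings(solve_litt(ph, models, laser_config(3),
                                     config = solver_config(dt = 2,
                                                            t_end = 200)))
  expect_true(all(diff(sim$probe_traces[, 1]) > -1e-9))
  expect_gt(max(sim$probe_traces[, 1]), 37)
})

test_that("BDF2 and backward Euler agree on a smooth linear problem", {
  m <- const_models()
  ph <- build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(20, 4, 4), voxel_spacing = 1,
    tumor_semi_axes = c(1, 1, 1), tumor_center = c(10, 2, 2),
    margin_thickness = 0, pancreas_semi_axes = c(1000, 1000, 1000),
    probe_lateral_mm = 0))
  bc <- boundary_spec(outer = "neumann", T_dirichlet = 45,
                      faces = list(xlo = "dirichlet"))
  run <- function(order) {
    cfg <- solver_config(dt = 20, t_end = 2000, order = order,
                         warn_temperature = Inf)
    solve_litt(ph, m, laser = NULL, boundary = bc, config = cfg,
               damage = linear_damage())$T_final[, 2, 2]
  }
  expect_equal(run(2), run(1), tolerance = 1e-3)
})

test_that("mesh convergence check validates its inputs and trivial cases", {
  expect_error(mesh_convergence_check(0.04), "two spacings")
  rep0 <- mesh_convergence_check(c(0.04, 0.04))
  expect_equal(rep0$table$rel_change, 0)
  expect_equal(rep0$converged_at, 0.04)
})

test_that("the energy ledger closes for a coupled run", {
  models <- tissue_model_set()
  ph <- ax_phantom(R = 20, L = 50, fine = 0.3, span = 4, tip_z = 15,
                   probe = 10)
  sim <- suppressWarnings(solve_litt(ph, models, laser_config(2),
                                     config = solver_config(dt = 2,
                                                            t_end = 100)))
  expect_lt(sim$energy$closure_rel, 1e-8)
  expect_gt(sim$energy$totals[["deposited"]], 0)
  expect_gt(sim$energy$totals[["stored"]], 0)
})
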