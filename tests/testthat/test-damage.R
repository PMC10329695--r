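test_that("dwell-time damage accumulates linearly with closed-form anchors", {
  cfg <- damage_config(T_d = 60, t_n = 2)
  dt <- 0.5
  # exactly t_n above threshold -> full necrosis
  hist <- c(rep(65, 4), rep(50, 4))
  d <- accumulate_damage(hist, dt, cfg)
  expect_equal(d$theta, 1)
  expect_equal(d$Omega, 1)
  # never above threshold -> no damage
  expect_equal(accumulate_damage(rep(59.9, 10), dt, cfg)$Omega, 0)
  # half the dwell time -> Omega = 0.5, and theta is linear in dwell time
  expect_equal(accumulate_damage(rep(65, 2), dt, cfg)$Omega, 0.5)
  th <- sapply(1:8, function(k)
    accumulate_damage(rep(61, k), dt, cfg)$theta)
  expect_equal(th, (1:8) * dt / 2)
  # theta keeps growing past 1 but Omega saturates
  d2 <- accumulate_damage(rep(70, 12), dt, cfg)
  expect_gt(d2$theta, 1)
  expect_equal(d2$Omega, 1)
})

test_that("damage config validates its parameters", {
  expect_error(damage_config(T_d = 30))
  expect_error(damage_config(t_n = 0))
})

test_that("ablation metrics count voxels against the tumor+margin target", {
  ph <- tumor_phantom(spacing = 1.25)
  masks <- phantom_masks(ph)
  # synthetic finished run: everything inside the tumor ablated, nothing else
  sim <- structure(list(
    phantom = ph,
    Omega = ifelse(masks$tumor, 1, 0),
    T_final = array(37, ph$dims),
    oar_trace = c(37, 37.5), oar_name = "splenic_vein",
    probe_traces = matrix(37, 2, 2), margin_trace = c(37, 37),
    times = c(1, 2)), class = "litt_sim")
  met <- ablation_metrics(sim)
  v <- label_volumes(ph)
  expect_equal(met$ablated_volume, v[["tumor"]], tolerance = 1e-9)
  expect_equal(met$ablated_fraction,
               100 * v[["tumor"]] / (v[["tumor"]] + v[["margin"]]))
  # nothing ablated
  sim$Omega[] <- 0
  met0 <- ablation_metrics(sim)
  expect_equal(met0$ablated_volume, 0)
  expect_equal(met0$ablated_fraction, 0)
  # no target masks -> error
  ph2 <- ax_phantom(R = 20, L = 50, fine = 0.5)
  sim2 <- structure(list(phantom = ph2,
                         Omega = array(0, ph2$dims),
                         T_final = array(37, ph2$dims),
                         oar_trace = NA, oar_name = NA,
                         probe_traces = matrix(37, 1, 1),
                         margin_trace = 37, times = 1), class = "litt_sim")
  expect_error(ablation_metrics(sim2), "empty")
})

test_that("the necrotic zone tracks the 60 degC isotherm when t_n is short", {
  models <- tissue_model_set()
  ph <- ax_phantom(R = 20, L = 50, fine = 0.25, span = 4, tip_z = 15,
                   probe = 10)
  sim <- suppressWarnings(solve_litt(ph, models, laser_config(3),
                                     config = solver_config(dt = 2,
                                                            t_end = 200)))
  ar <- littplan:::isotherm_areas(sim, c(42, 60))
  dr <- diff(ph$edges[[1]]); dz <- diff(ph$edges[[2]])
  cell_area <- outer(dr, dz)
  ablated_area <- 2 * sum(cell_area[sim$Omega >= 1])
  expect_equal(ablated_area, ar[["60"]], tolerance = 0.1)
  # the mild-hyperthermia contour encloses the ablative one
  expect_gt(ar[["42"]], ar[["60"]])
})

test_that("dose selection picks the minimum power, then the minimum duration", {
  g <- dose_grid(powers = c(7, 8), durations = c(450, 550),
                 ablated = rbind(c(40, 60), c(58, 70)),
                 oar_max = rbind(c(40, 41), c(41, 41.5)))
  sel <- select_optimal_dose(g, 55, 42)
  expect_true(sel$qualified)
  expect_equal(sel$power, 7)
  expect_equal(sel$duration, 550)
  expect_identical(sel$energy, 7 * 550)
  # organ-at-risk limit disqualifies otherwise-ablative combos
  g2 <- dose_grid(powers = c(7, 8), durations = c(450, 550),
                  ablated = rbind(c(40, 60), c(58, 70)),
                  oar_max = rbind(c(40, 43), c(44, 43)))
  expect_false(select_optimal_dose(g2, 55, 42)$qualified)
  # single qualifying combo
  g3 <- dose_grid(powers = 5, durations = 550, ablated = matrix(60),
                  oar_max = matrix(39))
  sel3 <- select_optimal_dose(g3)
  expect_equal(sel3$power, 5)
  expect_equal(sel3$energy, 2750)
  # equal power ties break by minimum duration
  g4 <- dose_grid(powers = 6, durations = c(300, 400),
                  ablated = matrix(c(56, 58), 2, 1),
                  oar_max = matrix(c(40, 40), 2, 1))
  expect_equal(select_optimal_dose(g4)$duration, 300)
})

test_that("selection is never dominated and thresholds act monotonically", {
  set.seed(42)
  for (i in 1:25) {
    np <- sample(2:5, 1); nd <- sample(2:5, 1)
    pw <- sort(sample(2:10, np)); du <- sort(sample(seq(50, 600, 50), nd))
    abl <- matrix(runif(nd * np, 0, 100), nd, np)
    # make metrics physically monotone in power and time
    abl <- t(apply(apply(abl, 2, cummax), 1, cummax))
    oar <- 37 + abl / 20
    g <- dose_grid(pw, du, abl, oar)
    s55 <- select_optimal_dose(g, 55, 42)
    if (s55$qualified) {
      # no qualifying combo strictly dominates the selection
      ok <- !is.na(g$ablated) & g$ablated >= 55 & g$oar_max <= 42
      w <- which(ok, arr.ind = TRUE)
      dominated <- any(g$powers[w[, 2]] < s55$power &
                         g$durations[w[, 1]] < s55$duration)
      expect_false(dominated)
      # raising the ablation requirement never lowers the selected power
      s70 <- select_optimal_dose(g, 70, 42)
      if (s70$qualified) expect_gte(s70$power, s55$power)
    }
  }
})

test_that("the dose-grid search populates metrics that are monotone in power and time", {
  models <- tissue_model_set()
  ph <- tumor_phantom(spacing = 1.5)
  grid <- suppressWarnings(dose_grid_search(
    ph, models, powers = c(2, 5), durations = c(60, 120),
    config = solver_config(dt = 4)))
  expect_false(any(is.na(grid$ablated)))
  expect_false(any(is.na(grid$oar_max)))
  expect_identical(grid$oar_name, "splenic_vein")
  # non-decreasing down the duration axis and across the power axis
  expect_true(all(apply(grid$ablated, 2, diff) >= 0))
  expect_true(all(apply(grid$ablated, 1, diff) >= 0))
  expect_true(all(apply(grid$oar_max, 2, diff) >= -1e-9))
  expect_identical(grid$energy, outer(c(60, 120), c(2, 5)))
  # durations must sit on the time-step lattice
  expect_error(dose_grid_search(ph, models, powers = 2, durations = 50,
                                config = solver_config(dt = 4)),
               "multiples")
})

test_that("dose grids round-trip through the CSV export layout", {
  g <- dose_grid(powers = c(2, 3), durations = c(100, 200),
                 ablated = rbind(c(10, 20), c(15, 30)),
                 oar_max = rbind(c(38, 39), c(38.5, 40)))
  stem <- file.path(tempdir(), "grid")
  write_dose_grid_csv(g, stem)
  a <- read.csv(paste0(stem, "_ablated.csv"), check.names = FALSE)
  expect_identical(names(a), c("duration_s", "P2W", "P3W"))
  expect_equal(as.matrix(a[, -1]), g$ablated, ignore_attr = TRUE)
  o <- read.csv(paste0(stem, "_oar.csv"), check.names = FALSE)
  expect_equal(as.matrix(o[, -1]), g$oar_max, ignore_attr = TRUE)
})
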