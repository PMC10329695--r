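test_that("voxelized tumor volume matches the analytic ellipsoid volume", {
  sp <- phantom_spec(mode = "voxel3d", domain_size = c(30, 30, 30),
                     voxel_spacing = 0.5, tumor_semi_axes = c(5, 5, 5),
                     margin_thickness = 3)
  ph <- build_voxel_phantom(sp)
  v <- label_volumes(ph)
  expect_equal(v[["tumor"]], 4 / 3 * pi * 125, tolerance = 0.02)
  # voxelization error shrinks with spacing
  err <- sapply(c(2, 0.5), function(h) {
    p <- build_voxel_phantom(phantom_spec(
      mode = "voxel3d", domain_size = c(30, 30, 30), voxel_spacing = h,
      tumor_semi_axes = c(5, 5, 5), margin_thickness = 0))
    abs(label_volumes(p)[["tumor"]] - 4 / 3 * pi * 125) / (4 / 3 * pi * 125)
  })
  expect_lt(err[2], err[1])
})

test_that("labels partition the grid and the margin is a proper dilation shell", {
  ph <- tumor_phantom(spacing = 1.25)
  counts <- sapply(ph$label_names, function(code) sum(ph$label == code))
  expect_identical(sum(counts), length(ph$label))
  m <- phantom_masks(ph)
  expect_false(any(m$tumor & m$margin))
  expect_true(any(m$margin))
  # margin voxels lie within margin_thickness + voxel diagonal of the tumor
  # (independent brute-force distance to tumor voxel centers)
  tc <- which(m$tumor); mc <- which(m$margin)
  co <- function(idx) {
    d <- ph$dims
    cbind(ph$centers[[1]][(idx - 1) %% d[1] + 1],
          ph$centers[[2]][((idx - 1) %/% d[1]) %% d[2] + 1],
          ph$centers[[3]][(idx - 1) %/% (d[1] * d[2]) + 1])
  }
  ct <- co(tc); cm <- co(mc)
  dmin <- apply(cm, 1, function(p)
    sqrt(min(colSums((t(ct) - p)^2))))
  diag_v <- sqrt(3) * ph$spacing[1]
  expect_lte(max(dmin), ph$spec$margin_thickness + diag_v)
  # every margin voxel is outside the tumor but near it
  expect_true(all(dmin > 0))
})

test_that("zero margin thickness yields an empty margin mask", {
  ph <- build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(24, 24, 24), voxel_spacing = 1.5,
    tumor_semi_axes = c(4, 4, 4), margin_thickness = 0,
    probe_lateral_mm = 10))
  expect_identical(sum(ph$label == ph$label_names[["margin"]]), 0L)
})

test_that("geometry and resolution violations are rejected", {
  expect_error(build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(20, 20, 20), voxel_spacing = 1,
    tumor_semi_axes = c(9, 9, 9), margin_thickness = 5)), "geometry")
  expect_error(build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(40, 40, 40), voxel_spacing = 6,
    tumor_semi_axes = c(6, 6, 6), margin_thickness = 5)), "resolution")
  expect_error(phantom_spec(
    mode = "voxel3d", domain_size = c(30, 30, 30),
    tumor_semi_axes = c(5, 5, 5),
    fiber = list(entry = c(15, 15, 0), direction = c(0, 0, 2))), "unit")
})

test_that("axisymmetric phantoms are homogeneous with the requested near-axis resolution", {
  sp <- phantom_spec(mode = "axisymmetric", domain_size = c(40, 60),
                     axisym = list(fine_spacing = 0.04, fine_span = 1.5,
                                   growth = 1.4, max_spacing = 3))
  ph <- build_axisymmetric_phantom(sp)
  expect_true(all(ph$label == ph$label_names[["pancreas"]]))
  # spacing in the refined source region is at most 0.04 mm
  dr <- diff(ph$edges[[1]])
  expect_lte(max(dr[ph$centers[[1]] < 1.5]), 0.04 + 1e-12)
  tipz <- ph$fiber$tip[2]
  dz <- diff(ph$edges[[2]])
  near_tip <- ph$centers[[2]] > tipz & ph$centers[[2]] < tipz + 1.5
  expect_lte(max(dz[near_tip]), 0.04 + 1e-12)
  # vessels are unsupported in this mode
  expect_error(phantom_spec(
    mode = "axisymmetric", domain_size = c(40, 60),
    vessels = list(list(name = "v", p0 = c(0, 0), p1 = c(0, 1),
                        radius = 1, h = 750))), "unsupported")
})

test_that("probes are placed at the requested perpendicular distance", {
  ph <- tumor_phantom()
  ph15 <- place_probes(ph, 15)
  tip <- ph$fiber$tip
  d <- apply(ph15$probes, 1, function(p) sqrt(sum((p[1:2] - tip[1:2])^2)))
  expect_equal(unname(d), c(15, 15), tolerance = 1e-9)
  expect_true(all(ph15$probes[, 3] == tip[3]))
  ph0 <- place_probes(ph, 0)
  expect_true(all(apply(ph0$probes, 1, function(p)
    sqrt(sum((p[1:2] - tip[1:2])^2))) == 0))
  ph10 <- place_probes(ph, 10)
  expect_equal(unname(apply(ph10$probes, 1, function(p)
    sqrt(sum((p[1:2] - tip[1:2])^2)))), c(10, 10), tolerance = 1e-9)
  expect_error(place_probes(ph, 200), "probe")
  # axisymmetric: default 15 mm probes need a domain radius of 15 mm
  expect_error(build_axisymmetric_phantom(phantom_spec(
    mode = "axisymmetric", domain_size = c(12, 40))), "probe")
})

test_that("build_phantom dispatches on the spec mode", {
  pa <- build_phantom(phantom_spec(mode = "axisymmetric",
                                   domain_size = c(20, 40)))
  expect_identical(pa$mode, "axisymmetric")
  pv <- build_phantom(phantom_spec(mode = "voxel3d",
                                   domain_size = c(24, 24, 24),
                                   voxel_spacing = 1.5,
                                   tumor_semi_axes = c(4, 4, 4),
                                   margin_thickness = 3,
                                   probe_lateral_mm = 10))
  expect_identical(pv$mode, "voxel3d")
})

test_that("duodenum slabs and vessel sheaths are labeled", {
  ph <- build_voxel_phantom(phantom_spec(
    mode = "voxel3d", domain_size = c(30, 30, 30), voxel_spacing = 1.5,
    tumor_semi_axes = c(4, 4, 4), margin_thickness = 3,
    vessels = list(list(name = "pv", p0 = c(25, 0, 15), p1 = c(25, 30, 15),
                        radius = 2, h = 750)),
    duodenum = list(axis = 1, offset = 1, thickness = 3)))
  v <- label_volumes(ph)
  expect_gt(v[["duodenum"]], 0)
  expect_gt(v[["soft_tissue"]], 0)
  expect_gt(v[["pv"]], 0)
  # the vessel mask approximates the analytic cylinder volume
  expect_equal(v[["pv"]], pi * 4 * 30, tolerance = 0.15)
})
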