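test_that("cord curve construction validates its inputs", {
  good <- cbind(0, 0, seq(0, 300, 100))
  expect_error(make_cord_curve(good[1:3, ]), "4 control points")
  bad <- good; bad[2, ] <- bad[1, ]
  expect_error(make_cord_curve(bad), "coincident")
  expect_error(make_cord_curve(good, 8), "16")
})

test_that("cord curve arc length matches analytic geometry", {
  straight <- make_cord_curve(cbind(0, 0, seq(0, 300, 100)), 50)
  expect_equal(total_length(straight), 300, tolerance = 1e-9)
  # quarter circle of radius 2000: arc length vs dense quadrature of the
  # analytic arc (pi * R / 2)
  th <- seq(0, pi / 2, length.out = 10)
  arc <- make_cord_curve(cbind(2000 * cos(th), 2000 * sin(th), 0), 400)
  expect_lt(abs(total_length(arc) - pi * 1000) / (pi * 1000), 0.01)
  # refinement consistency
  arc2 <- make_cord_curve(cbind(2000 * cos(th), 2000 * sin(th), 0), 800)
  expect_lt(abs(total_length(arc2) - total_length(arc)) / total_length(arc),
            0.001)
})

test_that("phantom specs enforce their invariants", {
  expect_error(phantom_spec("cord", tube_radius_um = -1), "> 0")
  expect_error(phantom_spec("brain", hires_shape = c(300, 64, 64)), "256")
  # radius above the curve's minimal radius of curvature is rejected
  th <- seq(0, pi / 2, length.out = 6)
  tight <- cbind(500 * cos(th), 500 * sin(th), seq(0, 500, 100))
  expect_error(phantom_spec("cord", control_points = tight,
                            tube_radius_um = 800), "curvature")
})

test_that("noiseless artifact-free cord rasterization uses exact levels", {
  sp <- small_cord_spec(seed = 5, ring_amplitude = 0, noise_sigma = c(0, 0))
  ph <- render_cord_phantom(sp)
  expect_setequal(unique(as.vector(ph$hires$data)),
                  unname(sp$levels[c("background", "medium", "tissue",
                                     "butterfly")]))
})

test_that("straight tube voxel count matches the analytic cylinder volume", {
  sp <- small_cord_spec(seed = 1, ring_amplitude = 0, noise_sigma = c(0, 0),
                        control_points = cbind(480, 480,
                                               seq(-150, 2050, length.out = 5)),
                        warp_amplitude_um = 0)
  ph <- render_cord_phantom(sp)
  L <- diff(range(ph$truth$centerline_hires$points[, 3]))
  L <- min(L, (sp$hires_shape[3] - 1) * sp$hires_spacing[3])
  expected <- pi * sp$tube_radius_um^2 * L / prod(sp$hires_spacing)
  expect_lt(abs(sum(ph$truth$mask_hires$data) / expected - 1), 0.03)
})

test_that("phantom rendering is bit-identical under a fixed seed", {
  sp <- small_cord_spec(seed = 11)
  a <- render_cord_phantom(sp)
  b <- render_cord_phantom(sp)
  expect_identical(a$hires$data, b$hires$data)
  expect_identical(a$lores$data, b$lores$data)
  sp2 <- small_cord_spec(seed = 12)
  expect_false(identical(render_cord_phantom(sp2)$hires$data, a$hires$data))
})

test_that("exported truth maps landmarks across modalities exactly", {
  ph <- render_cord_phantom(small_cord_spec(seed = 2))
  mapped <- apply_true_transform(ph$truth, ph$truth$landmarks_hires)
  expect_lt(max(abs(mapped - ph$truth$landmarks_lores)), 1e-6)
  phb <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  mb <- apply_true_transform(phb$truth, phb$truth$landmarks_hires)
  expect_lt(max(abs(mb - phb$truth$landmarks_lores)), 1e-6)
})

test_that("centerline lies well inside the exported cord mask", {
  ph <- render_cord_phantom(small_cord_spec(seed = 2))
  er <- erode_ball(ph$truth$mask_hires,
                   floor(ph$spec$tube_radius_um / 2 /
                           mean(ph$spec$hires_spacing)))
  pts <- ph$truth$centerline_hires$points
  zmax <- (ph$spec$hires_shape[3] - 1) * ph$spec$hires_spacing[3]
  # stay clear of the axial grid faces, where erosion also bites axially
  inside <- pts[, 3] > 6 * ph$spec$hires_spacing[3] &
    pts[, 3] < zmax - 6 * ph$spec$hires_spacing[3]
  vox <- round(world_to_voxel(ph$truth$mask_hires, pts[inside, ]))
  ok <- vapply(seq_len(nrow(vox)), function(i)
    er$data[vox[i, 1], vox[i, 2], vox[i, 3]], logical(1))
  expect_true(all(ok))
})

test_that("brain modalities agree voxelwise at identity and matched spacing", {
  # no boundary artifact here: the check is about the shared scene, and the
  # ring corrupts only the high-res modality by construction
  sp <- small_brain_spec(seed = 6, rotation_deg = 0,
                         translation_um = c(0, 0, 0), scale = 1,
                         lores_shape = c(72L, 72L, 72L),
                         lores_spacing = c(25, 25, 25),
                         noise_sigma = c(0, 0), ring_amplitude = 0)
  ph <- render_brain_phantom(sp)
  fg <- ph$truth$mask_hires$data
  rc <- cor(ph$hires$data[fg], ph$lores$data[fg], method = "spearman")
  expect_gt(rc, 0.8)
})

test_that("ring artifact perturbs exactly the boundary band", {
  d <- c(20, 20, 20)
  co <- lapply(1:3, function(ax) slice.index(array(0, d), ax))
  ball <- (co[[1]] - 10)^2 + (co[[2]] - 10)^2 + (co[[3]] - 10)^2 <= 36
  v <- vol3d(array(100, d) + 50 * ball, 1)
  m <- bin_mask(ball, 1)
  expect_identical(add_ring_artifact(v, m, 0, 2)$data, v$data)
  r <- add_ring_artifact(v, m, 0.5, 2)
  changed <- r$data != v$data
  band <- dilate_ball(m, 2)$data & !erode_ball(m, 2)$data
  expect_identical(changed, band)
  # not idempotent
  r2 <- add_ring_artifact(r, m, 0.5, 2)
  expect_false(identical(r2$data, r$data))
  expect_error(add_ring_artifact(v, m, -1, 2), ">= 0")
})

test_that("true affine carries the low-res mask onto the high-res mask", {
  ph <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  moved <- apply_transform(ph$truth$mask_lores, ph$truth$transform,
                           grid_of(ph$truth$mask_hires),
                           interpolation = "nearest")
  expect_gte(dice(moved$data > 0.5, ph$truth$mask_hires$data), 0.95)
})
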