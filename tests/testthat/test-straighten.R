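test_that("frames on a straight line are constant and axis-aligned", {
  cl <- centerline(cbind(0, 0, seq(0, 100, 5)))
  fr <- build_frames(cl)
  expect_lt(max(abs(sweep(fr$tangent, 2, c(0, 0, 1)))), 1e-9)
  expect_lt(max(abs(sweep(fr$normal, 2, fr$normal[1, ]))), 1e-9)
  expect_lt(max(abs(sweep(fr$binormal, 2, fr$binormal[1, ]))), 1e-9)
})

test_that("frames are orthonormal right-handed triads everywhere", {
  th <- seq(0, 4 * pi, length.out = 200)
  helix <- resample_centerline(centerline(cbind(300 * cos(th), 300 * sin(th),
                                                40 * th)), 30)
  fr <- build_frames(helix)
  for (i in seq_len(nrow(helix$points))) {
    M <- rbind(fr$tangent[i, ], fr$normal[i, ], fr$binormal[i, ])
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
    expect_gt(det(M), 0.999999999)
  }
})

test_that("rotation-minimizing frames keep a constant binormal on planar arcs", {
  th <- seq(0, pi / 2, length.out = 400)
  arc <- centerline(cbind(2000 * cos(th), 2000 * sin(th), 0))
  fr <- build_frames(arc)
  spread <- max(abs(sweep(fr$binormal, 2, fr$binormal[1, ])))
  expect_lt(spread, 1e-6)
})

test_that("frame field converges under sampling refinement on a helix", {
  th1 <- seq(0, 2 * pi, length.out = 200)
  th2 <- seq(0, 2 * pi, length.out = 399)
  h1 <- centerline(cbind(500 * cos(th1), 500 * sin(th1), 150 * th1))
  h2 <- centerline(cbind(500 * cos(th2), 500 * sin(th2), 150 * th2))
  f1 <- build_frames(h1)
  f2 <- build_frames(h2)
  # compare at shared samples (every second sample of the fine curve)
  ang <- acos(pmin(1, rowSums(f1$normal * f2$normal[seq(1, 399, 2), ])))
  expect_lt(max(ang) * 180 / pi, 0.5)
})

test_that("the injectivity guard rejects over-wide tubes", {
  th <- seq(0, pi / 2, length.out = 100)
  arc <- resample_centerline(centerline(cbind(500 * cos(th), 500 * sin(th),
                                              0)), 10)
  expect_error(straightening_transform(arc, 600, 5), "injectivity")
  tr <- straightening_transform(arc, 300, 5)
  expect_lt(tr$radius * tr$max_curvature, 1)
})

test_that("straightened axial extent equals the centerline arc length", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  st <- straighten_volume(ph$hires, tr, fill = 10)
  axial <- (dim(st$data)[3] - 1) * st$spacing[3]
  expect_lt(abs(axial - total_length(cl)), tr$axial_step + 1e-9)
})

test_that("a straight axis-aligned tube round-trips as a near-identity", {
  sp <- small_cord_spec(seed = 1, ring_amplitude = 0, noise_sigma = c(0, 0),
                        control_points = cbind(480, 480,
                                               seq(-150, 2050, length.out = 5)),
                        warp_amplitude_um = 0)
  ph <- render_cord_phantom(sp)
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  st <- straighten_volume(ph$hires, tr, fill = 10)
  back <- unstraighten_volume(st, tr, grid_of(ph$hires), fill = 10)
  tube <- erode_ball(ph$truth$mask_hires, 2L)$data
  expect_gte(cor(ph$hires$data[tube], back$data[tube]), 0.999)
})

test_that("curved cord round-trip stays interpolation-limited", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2,
                                                   noise_sigma = c(0, 0))))
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  st <- straighten_volume(ph$hires, tr, fill = 10)
  back <- unstraighten_volume(st, tr, grid_of(ph$hires), fill = 10)
  tube <- erode_ball(ph$truth$mask_hires, 2L)$data
  # the reduced 20 um fixture has proportionally sharper interior edges
  # than the study phantom, so the interpolation floor sits slightly lower
  expect_gte(cor(ph$hires$data[tube], back$data[tube]), 0.97)
})

test_that("centerline points map to the straight axis and back", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  s_probe <- c(200, 800, 1500)
  straight_pts <- cbind(0, 0, s_probe)
  curved <- transform_points(cnscoreg:::invert_tr(tr), straight_pts)
  expected <- vapply(1:3, function(c_)
    stats::approx(cl$arclen, cl$points[, c_], xout = s_probe)$y,
    numeric(3))
  expect_lt(max(abs(curved - expected)), 1e-6)
})

test_that("map transport preserves label sets and matches straightening", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  # binary mask with nearest stays strictly binary
  sm <- apply_transform_to_map(ph$truth$mask_hires, tr,
                               interpolation = "nearest")
  expect_true(all(sm$data %in% c(0, 1)))
  # scalar map equals straighten_volume on the same data
  fa <- vol3d(ph$hires$data / max(ph$hires$data), ph$hires$spacing,
              ph$hires$origin)
  a <- apply_transform_to_map(fa, tr)
  b <- straighten_volume(fa, tr)
  expect_identical(a$data, b$data)
  # label map keeps its label set under nearest interpolation
  labels <- vol3d(array(ifelse(ph$truth$mask_hires$data, 7, 2),
                        dim(ph$hires$data)), ph$hires$spacing)
  lt <- apply_transform_to_map(labels, tr, interpolation = "nearest", fill = 2)
  expect_true(all(lt$data %in% c(2, 7)))
})

test_that("straightening transforms survive a serialization round trip", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  cl <- resample_centerline(ph$truth$centerline_hires, 20)
  tr <- straightening_transform(cl, 220, 20)
  f <- tempfile(fileext = ".json")
  save_straightening_transform(tr, f)
  tr2 <- load_straightening_transform(f)
  expect_equal(tr2$radius, tr$radius)
  expect_lt(max(abs(tr2$centerline$points - tr$centerline$points)), 1e-8)
  expect_lt(max(abs(tr2$frames$normal - tr$frames$normal)), 1e-8)
})
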