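test_that("edge detection: empty on constant, slab on a step plane", {
  cst <- vol3d(array(4, c(12, 12, 12)) * 2, 1)
  expect_false(any(detect_edges_3d(cst, 1, 0.1, 0.5)$data))
  d <- c(24, 24, 24)
  step <- array(0, d); step[, , 13:24] <- 100
  e <- detect_edges_3d(vol3d(step, 1), 1, 0.5, 0.8)
  zs <- apply(e$data, 3, sum)
  on <- which(zs > 0)
  expect_lte(length(on), 3)                    # slab at most 3 voxels thick
  expect_true(any(on %in% 12:14))              # containing the step plane
  expect_gte(max(zs), 0.99 * 24 * 24)          # covering the plane area
  expect_error(detect_edges_3d(vol3d(step, 1), 1, 0.7, 0.4), "below")
})

test_that("hysteresis keeps weak edges only when linked to strong ones", {
  d <- c(40, 16, 16)
  base <- array(0, d)
  base[20:40, , ] <- 100                        # strong step at x~20
  weak_far <- base; weak_far[1:4, , ] <- 12     # weak blob far from it
  e1 <- detect_edges_3d(vol3d(weak_far, 1), 0.8, 0.05, 0.5)
  expect_false(any(e1$data[1:8, , ]))           # excluded by hysteresis
  weak_touch <- base; weak_touch[14:17, , ] <- 12  # weak ramp touching it
  e2 <- detect_edges_3d(vol3d(weak_touch, 1), 0.8, 0.05, 0.5)
  expect_true(any(e2$data[13:17, , ]))          # linked, so included
})

test_that("slice centroids of symmetric contours recover the axis exactly", {
  d <- c(21, 21, 8)
  m <- array(FALSE, d)
  for (z in 1:8) {
    ring <- as.matrix(expand.grid(1:21, 1:21))
    r2 <- (ring[, 1] - 11)^2 + (ring[, 2] - 11)^2
    sel <- ring[r2 >= 16 & r2 <= 36, ]
    m[cbind(sel, z)] <- TRUE
  }
  cl <- centerline_from_slices(bin_mask(m, c(2, 2, 5)), smooth_window = 1)
  expect_equal(unname(cl$points[, 1]), rep(20, 8))   # (11-1)*2
  expect_equal(unname(cl$points[, 2]), rep(20, 8))
  one <- array(FALSE, d); one[5, 5, 3] <- TRUE
  expect_error(centerline_from_slices(bin_mask(one, 1)), "2")
})

test_that("region growing equals an independent flood-fill oracle", {
  for (s in 1:6) {
    set.seed(300 + s)
    dims <- c(14, 14, 14)
    edges <- array(runif(prod(dims)) > 0.75, dims)
    open <- !edges
    seed_vox <- c(7, 7, 7)
    if (!open[7, 7, 7]) { edges[7, 7, 7] <- FALSE; open[7, 7, 7] <- TRUE }
    grown <- region_grow_mask(bin_mask(edges, 1), seed_vox)
    oracle <- flood_oracle(open, seed_vox)
    # the op closes with ball 1 after growing; apply the same closing to
    # the oracle region
    oracle_closed <- erode_ball(dilate_ball(bin_mask(oracle, 1), 1), 1,
                                border = "foreground")$data
    expect_identical(grown$data, oracle_closed)
  }
})

test_that("region growing separates interior and exterior of a shell", {
  d <- c(20, 20, 20)
  co <- lapply(1:3, function(ax) slice.index(array(0, d), ax))
  r2 <- (co[[1]] - 10)^2 + (co[[2]] - 10)^2 + (co[[3]] - 10)^2
  shell <- r2 >= 36 & r2 <= 56
  inside <- region_grow_mask(bin_mask(shell, 1), c(10, 10, 10))
  expect_true(inside$data[10, 10, 10])
  expect_false(inside$data[1, 1, 1])
  outside <- region_grow_mask(bin_mask(shell, 1), c(1, 1, 1))
  expect_true(outside$data[1, 1, 1])
  expect_false(outside$data[10, 10, 10])
  # no edges at all: the whole grid
  none <- region_grow_mask(bin_mask(array(FALSE, d), 1), c(3, 3, 3))
  expect_true(all(none$data))
  expect_error(region_grow_mask(bin_mask(shell, 1), c(10, 10, 16)), "edge")
  expect_error(region_grow_mask(bin_mask(shell, 1), c(50, 1, 1)), "outside")
})

test_that("centerline resampling is uniform and length-preserving", {
  seg <- centerline(cbind(0, 0, c(0, 30, 100)))
  r <- resample_centerline(seg, 10)
  expect_equal(nrow(r$points), 11)
  expect_equal(unname(r$points[, 3]), seq(0, 100, 10))
  expect_error(resample_centerline(seg, 200), "exceeds")
  th <- seq(0, pi / 2, length.out = 200)
  arc <- centerline(cbind(1000 * cos(th), 1000 * sin(th), 0))
  ra <- resample_centerline(arc, 50)
  chords <- sqrt(rowSums(diff(ra$points)^2))
  expect_lt(diff(range(chords)) / mean(chords), 0.01)
  expect_lt(abs(total_length(ra) - total_length(arc)), 50)
})

test_that("centerline invariants are enforced", {
  expect_error(centerline(matrix(c(0, 0, 0), 1)), "at least 2")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1))),
               "coincident")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                                c(0, 0, 300))), "gap")
})

test_that("phantom centerline extraction is accurate and noise-robust", {
  ph <- cached("cord_default", render_cord_phantom(phantom_spec("cord",
                                                                seed = 3)))
  truth <- ph$truth$centerline_hires
  ds <- nn_downsample(saturate_intensity(ph$hires), 2L)
  edges <- cord_contours(ds, detect_edges_3d(ds, 1.5 * mean(ds$spacing)))
  cl <- centerline_from_slices(edges)
  expect_lt(rms_to_curve(cl$points, truth), mean(ph$spec$hires_spacing))
  # invariance under SNR-10 noise: extracted line shifts < 0.5 voxel RMS
  phn <- render_cord_phantom(phantom_spec("cord", seed = 3,
                                          noise_sigma = c(18, 5)))
  dsn <- nn_downsample(saturate_intensity(phn$hires), 2L)
  en <- cord_contours(dsn, detect_edges_3d(dsn, 1.5 * mean(dsn$spacing)))
  cln <- centerline_from_slices(en)
  common <- min(nrow(cl$points), nrow(cln$points))
  shift <- sqrt(mean(rowSums((cl$points[1:common, 1:2] -
                                cln$points[1:common, 1:2])^2)))
  expect_lt(shift, 0.5 * mean(ds$spacing))
})
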