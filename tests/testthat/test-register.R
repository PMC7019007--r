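test_that("affine composition and inversion behave algebraically", {
  a <- affine_from_params(c(0.1, -0.05, 0.2, 30, -10, 5, 0.02, 0, -0.01,
                            0.01, 0, 0), center = c(50, 50, 50))
  b <- affine_from_params(c(0, 0.3, 0, -5, 8, 2, 0, 0, 0, 0, 0.02, 0))
  p <- matrix(rnorm(30, 50, 20), 10)
  expect_lt(max(abs(transform_points(compose_affine(a, b), p) -
                      transform_points(b, transform_points(a, p)))), 1e-9)
  rt <- compose_affine(a, invert_affine(a))
  expect_lt(max(abs(rt$matrix - diag(4))), 1e-9)
  expect_lt(max(abs(affine_from_params(rep(0, 12))$matrix - diag(4))), 1e-12)
  expect_error(affine3d(matrix(0, 4, 4)), "row")
})

test_that("two-point landmark initialization maps segments exactly", {
  id <- landmark_init(rbind(c(0, 0, 0), c(0, 0, 10)),
                      rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_lt(max(abs(id$matrix - diag(4))), 1e-9)
  tr <- landmark_init(rbind(c(1, 2, 3), c(4, 5, 6)),
                      rbind(c(11, 2, 3), c(14, 5, 6)))
  expect_lt(max(abs(tr$matrix[1:3, 1:3] - diag(3))), 1e-9)
  expect_equal(unname(tr$matrix[1:3, 4]), c(10, 0, 0))
  # z-segment of length 100 onto y-segment of length 200, with scale
  fx <- rbind(c(0, 0, -50), c(0, 0, 50))
  mv <- rbind(c(5, -100, 2), c(5, 100, 2))
  lm <- landmark_init(fx, mv, allow_scale = TRUE)
  expect_lt(max(abs(transform_points(lm, fx) - mv)), 1e-9)
  expect_error(landmark_init(rbind(c(0, 0, 0), c(0, 0, 0)), fx), "zero-length")
})

test_that("Mattes MI is optimal at self-registration over a probe set", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  v <- nn_downsample(ph$hires, 2L)
  set.seed(41)
  base <- mattes_mi(v, v)
  worse <- 0L
  for (i in 1:20) {
    p <- affine_from_params(c(rnorm(3, 0, 0.02), rnorm(3, 0, 25),
                              rnorm(3, 0, 0.01), rep(0, 3)),
                            center = (dim(v$data) - 1) / 2 * v$spacing)
    if (mattes_mi(v, v, p) < base) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("Mattes MI is invariant to affine intensity maps and near zero for
           independent volumes", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  v <- nn_downsample(ph$hires, 2L)
  resc <- vol3d(3.7 * v$data + 11, v$spacing, v$origin)
  expect_lt(abs(mattes_mi(v, resc) - mattes_mi(v, v)), 1e-3)
  set.seed(17)
  a <- vol3d(array(rnorm(32^3), c(32, 32, 32)), 1)
  b <- vol3d(array(rnorm(32^3), c(32, 32, 32)), 1)
  expect_lt(-mattes_mi(a, b), 0.05)
})

test_that("MI raises a distinguishable error on insufficient overlap", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  v <- nn_downsample(ph$hires, 2L)
  far <- affine_from_params(c(0, 0, 0, 1e5, 1e5, 1e5, rep(0, 6)))
  expect_error(mattes_mi(v, v, far), "overlap")
})

test_that("apply_transform: identity lossless, voxel shift, composition", {
  v <- rand_vol(c(10, 12, 14), seed = 5)
  same <- apply_transform(v, affine3d(), grid_of(v))
  expect_equal(same$data, v$data, tolerance = 1e-12)
  # translation by exactly one voxel: interior equals an index shift
  shift <- affine_from_params(c(0, 0, 0, v$spacing[1], 0, 0, rep(0, 6)))
  sh <- apply_transform(v, shift, grid_of(v))
  expect_equal(sh$data[1:9, , ], v$data[2:10, , ], tolerance = 1e-12)
  a <- affine_from_params(c(0.05, 0, 0, 2, 1, 0, rep(0, 6)), center = c(5, 6, 7))
  b <- affine_from_params(c(0, 0, 0.08, -1, 0, 2, rep(0, 6)), center = c(5, 6, 7))
  two_step <- apply_transform(v, list(a, b), grid_of(v))
  composed <- apply_transform(v, compose_affine(a, b), grid_of(v))
  expect_lt(max(abs(two_step$data[3:8, 3:10, 3:12] -
                      composed$data[3:8, 3:10, 3:12])), 1e-6)
})

test_that("Jacobian determinant matches analytic fields", {
  d <- c(12, 12, 12)
  zero <- disp_field(array(0, c(d, 3)), 1)
  expect_lt(max(abs(jacobian_determinant(zero)$data - 1)), 1e-12)
  co <- lapply(1:3, function(ax) (slice.index(array(0, d), ax) - 1))
  u <- array(0, c(d, 3)); u[, , , 1] <- 0.1 * co[[1]]
  lin <- disp_field(u, 1)
  jd <- jacobian_determinant(lin)$data
  expect_lt(max(abs(jd[2:11, 2:11, 2:11] - 1.1)), 1e-9)
  # small linearized rotation: det = 1 + O(theta^2)
  theta <- 0.01
  ur <- array(0, c(d, 3))
  ur[, , , 1] <- -theta * (co[[2]] - 5.5)
  ur[, , , 2] <- theta * (co[[1]] - 5.5)
  jr <- jacobian_determinant(disp_field(ur, 1))$data
  expect_lt(max(abs(jr[2:11, 2:11, 2:11] - 1)), 2 * theta^2)
})

test_that("self-registration recovers the identity", {
  ph <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  v <- antialias_downsample(ph$hires, ph$lores$spacing)
  set.seed(8)
  reg <- register_affine(v, v, levels = 2, iters_per_level = 40)
  expect_true(reg$converged)
  ctr <- v$origin + (dim(v$data) - 1) / 2 * v$spacing
  moved <- transform_points(reg$transform, matrix(ctr, 1))
  expect_lt(sqrt(sum((moved - ctr)^2)), 0.2 * min(v$spacing))
})

test_that("registration recovers the small phantom's true affine", {
  ph <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  ds <- antialias_downsample(ph$hires, ph$lores$spacing)
  set.seed(9)
  mask <- brain_mask_pipeline(ds, "auto")
  reg <- register_affine(ds, ph$lores, fixed_mask = mask)
  ctr <- (ph$spec$hires_shape - 1) / 2 * ph$spec$hires_spacing
  corners <- sweep(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) %*%
                     diag(ph$spec$brain_semiaxes_um * 0.7), 2, ctr, "+")
  tre <- sqrt(rowSums((transform_points(reg$transform, corners) -
                         apply_true_transform(ph$truth, corners))^2))
  expect_lt(max(tre), min(ph$lores$spacing))
})

test_that("registration errors cleanly when the init destroys overlap", {
  ph <- cached("cord_small",
               render_cord_phantom(small_cord_spec(seed = 2)))
  v <- nn_downsample(ph$hires, 2L)
  far <- affine_from_params(c(0, 0, 0, 1e5, 0, 0, rep(0, 6)))
  expect_error(register_affine(v, v, far), "overlap")
})

test_that("diffeomorphic refinement: null case and Jacobian positivity", {
  ph <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  v <- antialias_downsample(ph$hires, ph$lores$spacing)
  dr <- register_diffeomorphic(v, v, iters = 10)
  expect_true(dr$accepted)
  expect_lt(max(abs(dr$field$u)), 0.1 * min(v$spacing))
  expect_gt(dr$min_jacobian, 0)
  expect_error(register_diffeomorphic(v, v, integration_steps = 3), "6")
})

test_that("diffeomorphic refinement recovers a known smooth warp", {
  ph <- cached("brain_small", render_brain_phantom(small_brain_spec(
    seed = 4, noise_sigma = c(0, 0))))
  f <- antialias_downsample(ph$hires, ph$lores$spacing)
  set.seed(10)
  mask <- brain_mask_pipeline(f, "auto")
  d <- dim(f$data)
  co <- lapply(1:3, function(ax) (slice.index(array(0, d), ax) - 1) *
                 f$spacing[ax])
  amp <- 2 * min(f$spacing)   # two low-res voxels
  s_field <- amp * sin(pi * co[[3]] / max(co[[3]])) *
    sin(pi * co[[2]] / max(co[[2]]))
  pts <- cbind(as.vector(co[[1]] + s_field) / f$spacing[1],
               as.vector(co[[2]]) / f$spacing[2],
               as.vector(co[[3]]) / f$spacing[3])
  mv <- vol3d(array(cnscoreg:::cpp_trilinear_sample(as.vector(f$data), d,
                                                    pts, 100), d),
              f$spacing, f$origin)
  dr <- register_diffeomorphic(f, mv, iters = 60, fixed_mask = mask)
  expect_true(dr$accepted)
  expect_gt(dr$min_jacobian, 0)
  err <- sqrt((dr$field$u[, , , 1] + s_field)^2 + dr$field$u[, , , 2]^2 +
                dr$field$u[, , , 3]^2)
  expect_lt(mean(err[mask$data]), 0.75 * min(f$spacing))
})

test_that("affine transforms survive the text round trip", {
  a <- affine_from_params(c(0.12, -0.03, 0.3, 12.5, -7, 3,
                            0.05, 0, 0, 0.01, 0, 0.02), center = c(9, 8, 7))
  f <- tempfile(fileext = ".txt")
  save_affine(a, f)
  expect_lt(max(abs(load_affine(f)$matrix - a$matrix)), 1e-12)
})
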