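#' Affine transform between world frames
#'
#' A 4 x 4 homogeneous matrix mapping fixed-image world coordinates (um)
#' to moving-image world coordinates. Internally parameterized as three
#' Euler angles, three translations, three log-scales and three shears
#' applied about a centre point: \code{T(p) = R Sh S (p - c) + c + t}.
#'
#' @param matrix 4 x 4 homogeneous matrix (last row 0 0 0 1).
#' @return An object of class \code{affine3d}.
#' @export
affine3d <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L))) stop("need a 4x4 matrix")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0, 0, 0, 1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("linear part is singular")
  structure(list(matrix = matrix), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> fixed world -> moving world (um)\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Build an affine from pose parameters
#'
#' @param params Numeric length 12: Euler angles (rad, applied z-y-x),
#'   translations (um), log-scales, shears (xy, xz, yz).
#' @param center Centre of rotation/scaling (world um).
#' @return An [affine3d()].
#' @export
affine_from_params <- function(params = rep(0, 12), center = c(0, 0, 0)) {
  stopifnot(length(params) == 12L)
  a <- params[1:3]; t <- params[4:6]; ls <- params[7:9]; sh <- params[10:12]
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  L <- Rz %*% Ry %*% Rx %*% Sh %*% diag(exp(ls))
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- center - L %*% center + t
  affine3d(M)
}

#' Compose and invert affine transforms
#'
#' \code{compose_affine(a, b)} is "a then b": the returned transform maps
#' \code{p} to \code{b(a(p))} (matrix \code{B \%*\% A}).
#'
#' @param a,b,x [affine3d()] objects.
#' @return An [affine3d()].
#' @export
compose_affine <- function(a, b) affine3d(b$matrix %*% a$matrix)

#' @rdname compose_affine
#' @export
invert_affine <- function(x) affine3d(solve(x$matrix))

#' Dense displacement field on a fixed grid
#'
#' Vectors in micrometres; the mapped point of world coordinate \code{p}
#' is \code{p + u(p)} with \code{u} sampled trilinearly. Fields produced by
#' [register_diffeomorphic()] come from a stationary velocity field
#' integrated by scaling-and-squaring and are checked for positive
#' Jacobian determinant (diffeomorphism).
#'
#' @param u 4D array \code{nx x ny x nz x 3} of displacements (um).
#' @param spacing,origin Grid geometry (um).
#' @param n_integration_steps Scaling-and-squaring steps used (recorded).
#' @return An object of class \code{disp_field}.
#' @export
disp_field <- function(u, spacing, origin = c(0, 0, 0),
                       n_integration_steps = NA_integer_) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be nx x ny x nz x 3")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(u = u, spacing = spacing, origin = as.numeric(origin),
                 n_integration_steps = n_integration_steps),
            class = "disp_field")
}

#' Map world points through a transform
#'
#' @param transform An [affine3d()], [disp_field()], or a plain list of
#'   transforms (applied in order: first element first).
#' @param pts N x 3 matrix of world coordinates (um).
#' @return N x 3 matrix of mapped world coordinates.
#' @export
transform_points <- function(transform, pts) UseMethod("transform_points")

#' @export
transform_points.affine3d <- function(transform, pts) {
  pts <- as_pts_matrix(pts)
  h <- cbind(pts, 1) %*% t(transform$matrix)
  h[, 1:3, drop = FALSE]
}

#' @export
transform_points.disp_field <- function(transform, pts) {
  pts <- as_pts_matrix(pts)
  d <- dim(transform$u)[1:3]
  vox <- sweep(sweep(pts, 2, transform$origin, "-"), 2,
               transform$spacing, "/")
  u <- vapply(1:3, function(c_)
    cpp_trilinear_sample(as.vector(transform$u[, , , c_]), d, vox, 0),
    numeric(nrow(pts)))
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  pts + u
}

#' @export
transform_points.list <- function(transform, pts) {
  pts <- as_pts_matrix(pts)
  for (tr in transform) pts <- transform_points(tr, pts)
  pts
}

#' @export
transform_points.default <- function(transform, pts) {
  stop("unsupported transform type: ", paste(class(transform), collapse = "/"))
}

#' Two-point landmark initialization
#'
#' Builds the similarity transform carrying the fixed landmark segment onto
#' the moving one: midpoints are matched by translation, the segment
#' directions aligned by the minimal rotation (roll about the segment axis
#' is unconstrained by two points and fixed to zero -- the intensity-based
#' registration absorbs residual roll), and an optional uniform scale set
#' to the length ratio. This mirrors the practice of marking two consensus
#' reference coordinates near the sample extremities in each modality to
#' place both acquisitions in a common space.
#'
#' @param fixed_points,moving_points 2 x 3 matrices of world landmarks
#'   (um), distinct within each pair.
#' @param allow_scale If \code{TRUE}, include the uniform length-ratio
#'   scale.
#' @return An [affine3d()] mapping fixed world to moving world.
#' @export
landmark_init <- function(fixed_points, moving_points, allow_scale = TRUE) {
  fp <- as_pts_matrix(fixed_points); mp <- as_pts_matrix(moving_points)
  if (nrow(fp) != 2L || nrow(mp) != 2L) stop("need exactly 2 points per image")
  df <- fp[2, ] - fp[1, ]; dm <- mp[2, ] - mp[1, ]
  lf <- sqrt(sum(df^2)); lm <- sqrt(sum(dm^2))
  if (lf < 1e-9 || lm < 1e-9) stop("zero-length landmark segment")
  uf <- df / lf; um <- dm / lm
  ax <- c(uf[2] * um[3] - uf[3] * um[2],
          uf[3] * um[1] - uf[1] * um[3],
          uf[1] * um[2] - uf[2] * um[1])
  s_ <- sqrt(sum(ax^2)); c_ <- sum(uf * um)
  if (s_ < 1e-12) {
    R <- if (c_ > 0) diag(3) else {
      # opposite directions: rotate pi about any axis orthogonal to uf
      perp <- if (abs(uf[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * uf) * uf
      perp <- perp / sqrt(sum(perp^2))
      2 * outer(perp, perp) - diag(3)
    }
  } else {
    k <- ax / s_
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  }
  sc <- if (allow_scale) lm / lf else 1
  midf <- (fp[1, ] + fp[2, ]) / 2; midm <- (mp[1, ] + mp[2, ]) / 2
  M <- diag(4)
  M[1:3, 1:3] <- sc * R
  M[1:3, 4] <- midm - sc * R %*% midf
  affine3d(M)
}

#' Mattes mutual information between two volumes under a transform
#'
#' Fixed voxel centres (optionally a seeded random subset) are mapped
#' through the transform and the moving image sampled trilinearly. The
#' joint histogram uses the Mattes formulation: zero-order binning of the
#' fixed intensities and a cubic B-spline Parzen window on the moving
#' intensities, both min-max normalized to the bin range. Returns
#' \emph{negative} MI in bits (lower is better).
#'
#' @param fixed,moving [vol3d()] volumes.
#' @param transform Transform mapping fixed world to moving world.
#' @param bins Histogram bins per axis (default 32).
#' @param n_samples \code{"all"} or a sample count (uses the current RNG
#'   state; seed externally for determinism).
#' @param fixed_mask Optional [bin_mask()] restricting the fixed samples.
#' @param min_overlap Minimum fraction of samples that must land inside
#'   the moving grid (default 0.1); below it an error is raised so a
#'   failed overlap is distinguishable from a genuinely bad metric value.
#' @return Negative MI (scalar) with attribute \code{n_used}.
#' @export
mattes_mi <- function(fixed, moving, transform = affine3d(), bins = 32L,
                      n_samples = "all", fixed_mask = NULL,
                      min_overlap = 0.1) {
  sp <- mi_sample_points(fixed, n_samples, fixed_mask)
  res <- mi_eval(sp$pts, sp$fvals, range(fixed$data), moving, transform, bins)
  if (res$n_used < min_overlap * nrow(sp$pts))
    stop(sprintf(paste0("insufficient overlap: only %d of %d fixed samples ",
                        "map inside the moving volume"),
                 res$n_used, nrow(sp$pts)))
  structure(res$neg_mi, n_used = res$n_used)
}

# Fixed-image sample set: voxel-centre world coords + intensities.
mi_sample_points <- function(fixed, n_samples, fixed_mask = NULL) {
  d <- dim(fixed$data)
  if (!is.null(fixed_mask)) {
    idx <- which(fixed_mask$data)
  } else {
    idx <- seq_len(prod(d))
  }
  if (!identical(n_samples, "all")) {
    n_samples <- min(as.integer(n_samples), length(idx))
    idx <- sort(sample(idx, n_samples))
  }
  k <- (idx - 1L) %/% (d[1] * d[2])
  r <- (idx - 1L) %% (d[1] * d[2])
  j <- r %/% d[1]
  i <- r %% d[1]
  pts <- cbind(fixed$origin[1] + i * fixed$spacing[1],
               fixed$origin[2] + j * fixed$spacing[2],
               fixed$origin[3] + k * fixed$spacing[3])
  list(pts = pts, fvals = fixed$data[idx])
}

mi_eval <- function(pts, fvals, frange, moving, transform, bins) {
  mapped <- transform_points(transform, pts)
  vox <- sweep(sweep(mapped, 2, moving$origin, "-"), 2, moving$spacing, "/")
  mvals <- cpp_trilinear_sample(as.vector(moving$data), dim(moving$data),
                                vox, NA_real_)
  mr <- range(moving$data)
  cpp_mattes_mi(fvals, mvals, frange[1], frange[2], mr[1], mr[2],
                as.integer(bins))
}

#' Multi-resolution Mattes-MI affine registration
#'
#' Gradient descent on the 12 affine pose parameters (finite-difference
#' gradients, parameters scaled so a unit step means ~0.01 rad, one fixed
#' voxel, or 0.01 in log-scale/shear) with an adaptive step and an
#' anti-aliased image pyramid (default level factors 4, 2, 1). Metric
#' samples use every in-mask voxel at the coarse levels and a seeded 20%
#' random subset at the finest level. Deterministic for a fixed RNG state.
#'
#' @param fixed,moving [vol3d()] volumes (fixed defines the reference
#'   frame).
#' @param init Initial [affine3d()] (e.g. from [landmark_init()]).
#' @param levels Pyramid levels (default 3: factors 4, 2, 1).
#' @param iters_per_level Maximum gradient-descent iterations per level.
#' @param bins,fixed_mask Passed to the metric.
#' @param sample_fraction Sampling fraction at the finest level.
#' @return A \code{registration_result}: list with \code{transform}
#'   ([affine3d()]), \code{metric} (final negative MI), \code{trace}
#'   (per-level iteration metric values), \code{converged}.
#' @export
register_affine <- function(fixed, moving, init = affine3d(), levels = 3L,
                            iters_per_level = 60L, bins = 32L,
                            fixed_mask = NULL, sample_fraction = 0.2) {
  factors <- 2^((levels:1) - 1)
  # a pyramid level with too few voxels makes the joint histogram spurious;
  # keep at least ~24 voxels per axis at the coarsest level
  max_f <- 2^max(0, floor(log2(min(dim(fixed$data)) / 24)))
  factors <- unique(pmin(factors, max_f))
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  delta <- rep(0, 12)
  trace <- list()
  worse_levels <- 0L
  for (li in seq_along(factors)) {
    f <- factors[li]
    if (f > 1) {
      fx <- antialias_downsample(fixed, fixed$spacing * f)
      mv <- antialias_downsample(moving, moving$spacing * f)
      msk <- if (!is.null(fixed_mask))
        downsample_mask(fixed_mask, fx) else NULL
      ns <- "all"
    } else {
      fx <- fixed; mv <- moving
      msk <- fixed_mask
      ns <- max(1000L, as.integer(sample_fraction *
        (if (is.null(fixed_mask)) prod(dim(fx$data)) else sum(fixed_mask$data))))
    }
    sp <- mi_sample_points(fx, ns, msk)
    frange <- range(fx$data)
    # parameter scaling: unit internal step = 0.01 rad / 1 voxel / 0.01
    w <- c(rep(100, 3), 1 / fx$spacing, rep(100, 6))
    objective <- function(d_) {
      # a line-search excursion can request a degenerate pose (e.g. a
      # log-scale that underflows); repel it rather than abort
      tr <- tryCatch(compose_affine(affine_from_params(d_, center), init),
                     error = function(e) NULL)
      if (is.null(tr)) return(Inf)
      r <- mi_eval(sp$pts, sp$fvals, frange, mv, tr, bins)
      if (r$n_used < 0.1 * nrow(sp$pts)) return(Inf)
      r$neg_mi
    }
    m_cur <- objective(delta)
    if (!is.finite(m_cur))
      stop("insufficient overlap at initialization: check the initial ",
           "transform (e.g. landmark correspondence)")
    m_level_start <- m_cur
    # optimize in scaled units (1 unit ~ 0.01 rad / 1 voxel / 0.01 log-scale)
    eval_log <- new.env(); eval_log$m <- m_cur
    obj_scaled <- function(u) {
      m <- objective(u / w)
      if (!is.finite(m)) m <- 1  # out-of-overlap excursions are repelled
      eval_log$m <- c(eval_log$m, m)
      m
    }
    fit <- stats::optim(delta * w, obj_scaled, method = "BFGS",
                        control = list(maxit = iters_per_level,
                                       reltol = 1e-7))
    if (is.finite(fit$value) && fit$value < m_cur) {
      delta <- fit$par / w
      m_cur <- fit$value
    }
    trace[[li]] <- eval_log$m
    worse_levels <- if (m_cur > m_level_start + 1e-12) worse_levels + 1L else 0L
    if (worse_levels >= 3L) break
  }
  structure(list(transform = compose_affine(affine_from_params(delta, center),
                                            init),
                 metric = m_cur, trace = trace,
                 converged = worse_levels < 3L),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> metric %.5f, converged: %s\n",
              x$metric, x$converged))
  invisible(x)
}

# Nearest-neighbour restriction of a fixed-grid mask onto a coarser grid.
downsample_mask <- function(mask, target_vol) {
  d <- dim(target_vol$data)
  g <- lapply(1:3, function(ax)
    (seq_len(d[ax]) - 1) * target_vol$spacing[ax] / mask$spacing[ax])
  pts <- cbind(rep(g[[1]], times = d[2] * d[3]),
               rep(rep(g[[2]], each = d[1]), times = d[3]),
               rep(g[[3]], each = d[1] * d[2]))
  vals <- cpp_nearest_sample(as.vector(as.numeric(mask$data)),
                             dim(mask$data), pts, 0)
  bin_mask(array(vals > 0.5, d), target_vol$spacing, target_vol$origin,
           "downsample_mask")
}

#' Diffeomorphic demons-style refinement
#'
#' Optimizes a stationary velocity field with demons forces computed on
#' intensity-normalized images (a local-correlation proxy for the MI
#' gradient, valid once both images are z-scored), Gaussian-smoothing both
#' the update and the accumulated field. The displacement is obtained from
#' the velocity by scaling-and-squaring (>= 6 steps), and the Jacobian
#' determinant of the accepted field is checked to be strictly positive
#' everywhere; a failing field triggers one doubling of the field
#' smoothing, then rejection.
#'
#' @param fixed,moving [vol3d()] volumes.
#' @param init Affine pre-alignment ([affine3d()]).
#' @param smooth_update_sigma,smooth_field_sigma Gaussian sigmas (um).
#' @param iters Demons iterations.
#' @param step Force step length multiplier.
#' @param integration_steps Scaling-and-squaring steps (>= 6).
#' @param fixed_mask Optional [bin_mask()]; forces outside it are zeroed.
#' @return A \code{registration_result} with \code{transform = list(field,
#'   init)} (displacement first, then the affine), \code{field} (a
#'   [disp_field()] or \code{NULL} if rejected), \code{min_jacobian},
#'   \code{accepted}, \code{trace}.
#' @export
register_diffeomorphic <- function(fixed, moving, init = affine3d(),
                                   smooth_update_sigma = NULL,
                                   smooth_field_sigma = NULL,
                                   iters = 30L, step = 1,
                                   integration_steps = 6L,
                                   fixed_mask = NULL) {
  if (integration_steps < 6L) stop("use at least 6 integration steps")
  if (is.null(smooth_update_sigma)) smooth_update_sigma <- mean(fixed$spacing)
  if (is.null(smooth_field_sigma)) smooth_field_sigma <- mean(fixed$spacing)
  d <- dim(fixed$data)
  mov_a <- apply_transform(moving, init, grid_of(fixed))
  f <- zscore(fixed$data)
  mov_a$data <- zscore(mov_a$data)
  gf <- lapply(1:3, function(ax) central_diff(f, ax) / fixed$spacing[ax])
  gf2 <- gf[[1]]^2 + gf[[2]]^2 + gf[[3]]^2
  s2 <- mean(fixed$spacing)^2
  v <- array(0, c(d, 3))
  trace <- numeric(0)
  sig_u <- smooth_update_sigma / fixed$spacing
  sig_f <- smooth_field_sigma / fixed$spacing
  for (it in seq_len(iters)) {
    u <- exp_velocity(v, fixed, integration_steps)
    mw <- warp_on_grid(mov_a, u, fixed)
    diffi <- mw - f
    denom <- gf2 + diffi^2 / s2
    denom[denom < 1e-12] <- 1e-12
    for (c_ in 1:3) {
      upd <- -step * diffi * gf[[c_]] / denom
      if (!is.null(fixed_mask)) upd[!fixed_mask$data] <- 0
      v[, , , c_] <- gauss_smooth3(v[, , , c_] + gauss_smooth3(upd, sig_u),
                                   sig_f)
    }
    trace <- c(trace, mean(diffi^2))
  }
  u <- exp_velocity(v, fixed, integration_steps)
  field <- disp_field(u, fixed$spacing, fixed$origin, integration_steps)
  jd <- jacobian_determinant(field)
  minj <- min(jd$data)
  if (minj <= 0) {
    for (c_ in 1:3)
      v[, , , c_] <- gauss_smooth3(v[, , , c_], 2 * sig_f)
    u <- exp_velocity(v, fixed, integration_steps)
    field <- disp_field(u, fixed$spacing, fixed$origin, integration_steps)
    jd <- jacobian_determinant(field)
    minj <- min(jd$data)
  }
  accepted <- minj > 0
  if (!accepted) {
    warning("diffeomorphic field rejected: non-positive Jacobian ",
            "determinant even after increased smoothing")
    field <- NULL
  }
  structure(list(transform = if (accepted) list(field, init) else init,
                 field = field, min_jacobian = minj, accepted = accepted,
                 metric = trace[length(trace)], trace = trace,
                 converged = accepted),
            class = "registration_result")
}

zscore <- function(a) {
  s <- sd(as.vector(a))
  if (s == 0) return(a * 0)
  (a - mean(a)) / s
}

# exp(v) by scaling and squaring: u <- v / 2^K, then K self-compositions
# u(x) <- u(x) + u(x + u(x)).
exp_velocity <- function(v, ref, K) {
  d <- dim(v)[1:3]
  u <- v / 2^K
  g <- lapply(1:3, function(ax)
    (slice.index(array(0, d), ax) - 1) * ref$spacing[ax])
  for (s_ in seq_len(K)) {
    pts <- cbind(as.vector(g[[1]] + u[, , , 1]) / ref$spacing[1],
                 as.vector(g[[2]] + u[, , , 2]) / ref$spacing[2],
                 as.vector(g[[3]] + u[, , , 3]) / ref$spacing[3])
    nu <- u
    for (c_ in 1:3) {
      samp <- cpp_trilinear_sample(as.vector(u[, , , c_]), d, pts, 0)
      nu[, , , c_] <- u[, , , c_] + array(samp, d)
    }
    u <- nu
  }
  u
}

# Warp a grid-aligned volume by a displacement field on the same grid.
warp_on_grid <- function(vol, u, ref) {
  d <- dim(vol$data)
  g <- lapply(1:3, function(ax) (slice.index(array(0, d), ax) - 1))
  pts <- cbind(as.vector(g[[1]] + u[, , , 1] / ref$spacing[1]),
               as.vector(g[[2]] + u[, , , 2] / ref$spacing[2]),
               as.vector(g[[3]] + u[, , , 3] / ref$spacing[3]))
  array(cpp_trilinear_sample(as.vector(vol$data), d, pts, 0), d)
}

#' Resample a volume through a transform (pull-back)
#'
#' For each target-grid voxel, the transform maps its world coordinate
#' into the moving volume's world frame and the moving volume is sampled
#' there. Use nearest-neighbour interpolation for label maps.
#'
#' @param volume The moving [vol3d()] (or [bin_mask()], resampled as 0/1).
#' @param transform [affine3d()], [disp_field()], or list (applied in
#'   order).
#' @param target_grid Output grid (see [grid_of()]); defaults to the
#'   volume's own grid.
#' @param interpolation \code{"trilinear"} or \code{"nearest"}.
#' @param fill Value outside the moving grid.
#' @return A [vol3d()] on the target grid.
#' @export
apply_transform <- function(volume, transform, target_grid = NULL,
                            interpolation = c("trilinear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  if (is_bin_mask(volume))
    volume <- vol3d(array(as.numeric(volume$data), dim(volume$data)),
                    volume$spacing, volume$origin)
  if (is.null(target_grid)) target_grid <- grid_of(volume)
  d <- as.integer(target_grid$dims)
  g <- lapply(1:3, function(ax)
    target_grid$origin[ax] + (seq_len(d[ax]) - 1) * target_grid$spacing[ax])
  pts <- cbind(rep(g[[1]], times = d[2] * d[3]),
               rep(rep(g[[2]], each = d[1]), times = d[3]),
               rep(g[[3]], each = d[1] * d[2]))
  mapped <- transform_points(transform, pts)
  vox <- sweep(sweep(mapped, 2, volume$origin, "-"), 2, volume$spacing, "/")
  sampler <- if (interpolation == "trilinear") cpp_trilinear_sample
             else cpp_nearest_sample
  vals <- sampler(as.vector(volume$data), dim(volume$data), vox, fill)
  vol3d(array(vals, d), target_grid$spacing, target_grid$origin)
}

#' Jacobian determinant of a displacement field
#'
#' Central-difference Jacobian of the mapping \code{x + u(x)}; the
#' determinant is 1 for the zero field and must stay strictly positive for
#' a diffeomorphism. Edge voxels use replicated-edge differences; interior
#' voxels are exact central differences.
#'
#' @param field A [disp_field()].
#' @return A [vol3d()] of determinant values on the field's grid.
#' @export
jacobian_determinant <- function(field) {
  d <- dim(field$u)[1:3]
  J <- array(0, c(d, 3, 3))
  for (c_ in 1:3)
    for (ax in 1:3) {
      J[, , , c_, ax] <- central_diff(field$u[, , , c_], ax) /
        field$spacing[ax]
      if (c_ == ax) J[, , , c_, ax] <- J[, , , c_, ax] + 1
    }
  det_ <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] -
                           J[, , , 2, 3] * J[, , , 3, 2]) -
          J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] -
                           J[, , , 2, 3] * J[, , , 3, 1]) +
          J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                           J[, , , 2, 2] * J[, , , 3, 1])
  vol3d(det_, field$spacing, field$origin)
}

#' Save / load an affine as a 4 x 4 row-major text matrix
#' @param x An [affine3d()].
#' @param path File path.
#' @export
save_affine <- function(x, path) {
  writeLines(apply(format(x$matrix, digits = 17), 1, paste, collapse = " "),
             path)
  invisible(path)
}

#' @rdname save_affine
#' @export
load_affine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  affine3d(m)
}
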