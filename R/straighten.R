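#' Rotation-minimizing frames along a centerline
#'
#' Builds per-sample orthonormal right-handed triads (tangent, normal,
#' binormal) by the double-reflection method, which propagates the initial
#' normal with minimal twist. Unlike the Frenet frame it is defined at
#' inflection points and stays stable on near-straight curves. The initial
#' normal is the world x-axis projected orthogonal to the first tangent
#' (falling back to the y-axis when the tangent is near-parallel to x),
#' making the construction deterministic.
#'
#' @param cl A [centerline()] with >= 3 samples at uniform arc-length steps.
#' @return An object of class \code{frame_field}: list of N x 3 matrices
#'   \code{tangent}, \code{normal}, \code{binormal}.
#' @export
build_frames <- function(cl) {
  p <- cl$points
  n <- nrow(p)
  if (n < 3L) stop("need at least 3 centerline samples")
  steps <- diff(cl$arclen)
  if (max(steps) / min(steps) > 1.5)
    stop("centerline must be uniformly resampled (use resample_centerline)")
  # tangents by central differences (one-sided at the ends), normalized
  tg <- matrix(0, n, 3)
  tg[1, ] <- p[2, ] - p[1, ]
  tg[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2L) tg[2:(n - 1), ] <- p[3:n, ] - p[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  # deterministic initial normal
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(0, 1, 0)
  n0 <- ref - sum(ref * tg[1, ]) * tg[1, ]
  n0 <- n0 / sqrt(sum(n0^2))
  nor <- matrix(0, n, 3)
  nor[1, ] <- n0
  for (i in seq_len(n - 1L)) {
    v1 <- p[i + 1L, ] - p[i, ]
    c1 <- sum(v1^2)
    rL <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2^2)
    nor[i + 1L, ] <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # guard against drift: re-orthogonalize and normalize
    nn <- nor[i + 1L, ] - sum(nor[i + 1L, ] * tg[i + 1L, ]) * tg[i + 1L, ]
    nor[i + 1L, ] <- nn / sqrt(sum(nn^2))
  }
  bi <- cbind(tg[, 2] * nor[, 3] - tg[, 3] * nor[, 2],
              tg[, 3] * nor[, 1] - tg[, 1] * nor[, 3],
              tg[, 1] * nor[, 2] - tg[, 2] * nor[, 1])
  structure(list(tangent = tg, normal = nor, binormal = bi),
            class = "frame_field")
}

# Maximum discrete curvature (1/um) of a uniformly sampled centerline.
max_discrete_curvature <- function(cl) {
  tg <- build_frames(cl)$tangent
  ds <- diff(cl$arclen)
  max(sqrt(rowSums(diff(tg)^2)) / ds)
}

#' Straightening transform: centerline + frames + straight-grid geometry
#'
#' Defines the invertible mapping between the curved volume and a straight
#' frame in which the centerline becomes the axis u = v = 0. A point at
#' arc length s with in-plane offsets (u, v) corresponds to the world point
#' \code{c(s) + u * normal(s) + v * binormal(s)}. Injectivity inside the
#' tube requires \code{radius * max_curvature < 1}; violating
#' configurations are rejected, never silently folded.
#'
#' @param cl A uniformly resampled [centerline()].
#' @param radius In-plane radius of the straightened tube (um).
#' @param in_plane_spacing Spacing of the straight (u, v) grid (um).
#' @param axial_step Arc-length step of the straight grid (um); defaults to
#'   the centerline step.
#' @return An object of class \code{straightening_transform}.
#' @export
straightening_transform <- function(cl, radius, in_plane_spacing,
                                    axial_step = NULL) {
  if (radius <= 0) stop("`radius` must be > 0")
  fr <- build_frames(cl)
  kmax <- max_discrete_curvature(cl)
  if (radius * kmax >= 1)
    stop(sprintf(paste0("straightening radius %.1f um violates injectivity: ",
                        "max curvature %.3g/um gives radius*kappa = %.3f >= 1"),
                 radius, kmax, radius * kmax))
  step <- mean(diff(cl$arclen))
  if (is.null(axial_step)) axial_step <- step
  structure(list(centerline = cl, frames = fr, radius = radius,
                 in_plane_spacing = in_plane_spacing,
                 axial_step = axial_step, max_curvature = kmax),
            class = "straightening_transform")
}

#' @export
print.straightening_transform <- function(x, ...) {
  cat(sprintf(paste0("<straightening_transform> %d samples, length %.1f um, ",
                     "radius %.1f um, in-plane %.2f um, axial %.2f um\n"),
              nrow(x$centerline$points), total_length(x$centerline),
              x$radius, x$in_plane_spacing, x$axial_step))
  invisible(x)
}

# Straight-grid geometry: (u, v, s) with u, v in [-R, R] and s in [0, L].
straight_grid <- function(tr) {
  nuv <- 2L * as.integer(ceiling(tr$radius / tr$in_plane_spacing)) + 1L
  L <- total_length(tr$centerline)
  ns <- as.integer(floor(L / tr$axial_step + 1e-9)) + 1L
  list(nuv = nuv, ns = ns,
       u0 = -(nuv - 1L) / 2 * tr$in_plane_spacing,
       spacing = c(tr$in_plane_spacing, tr$in_plane_spacing, tr$axial_step))
}

#' Resample a curved volume into the straightened frame
#'
#' Builds the straight grid (u, v, s) -- s the arc length along the
#' centerline, (u, v) in-plane offsets along the rotation-minimizing
#' normal/binormal -- and fills each straight voxel by trilinear
#' interpolation of the curved volume at \code{c(s) + u*n(s) + v*b(s)}.
#' The straightened axial extent equals the centerline arc length by
#' construction.
#'
#' @param volume A [vol3d()] in the curved (native) frame.
#' @param transform A [straightening_transform()].
#' @param fill Value for points outside the source grid.
#' @param interpolation \code{"trilinear"} (default) or \code{"nearest"}
#'   (for label maps).
#' @return A [vol3d()] on the straight grid; origin \code{(-R', -R', 0)} so
#'   the centerline maps to u = v = 0.
#' @export
straighten_volume <- function(volume, transform, fill = 0,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  g <- straight_grid(transform)
  cl <- transform$centerline
  fr <- transform$frames
  us <- g$u0 + (seq_len(g$nuv) - 1L) * transform$in_plane_spacing
  ss <- (seq_len(g$ns) - 1L) * transform$axial_step
  # interpolate centerline and frames at the axial stations
  ci <- vapply(1:3, function(c_)
    stats::approx(cl$arclen, cl$points[, c_], xout = ss)$y, numeric(g$ns))
  ni <- interp_unit(cl$arclen, fr$normal, ss)
  bi <- interp_unit(cl$arclen, fr$binormal, ss)
  nu <- g$nuv
  U <- rep(us, times = nu * g$ns)
  V <- rep(rep(us, each = nu), times = g$ns)
  idxs <- rep(seq_len(g$ns), each = nu * nu)
  world <- ci[idxs, , drop = FALSE] + U * ni[idxs, , drop = FALSE] +
    V * bi[idxs, , drop = FALSE]
  vox0 <- sweep(sweep(world, 2, volume$origin, "-"), 2, volume$spacing, "/")
  sampler <- if (interpolation == "trilinear") cpp_trilinear_sample
             else cpp_nearest_sample
  vals <- sampler(as.vector(volume$data), dim(volume$data), vox0, fill)
  vol3d(array(vals, c(nu, nu, g$ns)), g$spacing, c(g$u0, g$u0, 0))
}

# Linear interpolation of unit-vector rows followed by renormalization.
interp_unit <- function(s, mat, s_new) {
  out <- vapply(1:3, function(c_)
    stats::approx(s, mat[, c_], xout = s_new)$y, numeric(length(s_new)))
  if (is.null(dim(out))) out <- matrix(out, ncol = 3)
  out / sqrt(rowSums(out^2))
}

#' Map a straightened volume back to a curved target grid
#'
#' The inverse of [straighten_volume()]: each target voxel is projected
#' onto the centerline (exact closed-form projection onto the polyline
#' segments adjacent to the discrete nearest sample), giving (s, u, v)
#' coordinates at which the straight volume is sampled. Voxels farther than
#' the transform radius from the centerline receive \code{fill}.
#'
#' @param straight A [vol3d()] produced by [straighten_volume()].
#' @param transform The same [straightening_transform()].
#' @param target_grid List with \code{dims}, \code{spacing}, \code{origin}
#'   describing the curved output grid (e.g. from [grid_of()]).
#' @param fill Fill value outside the tube or straight grid.
#' @param interpolation \code{"trilinear"} or \code{"nearest"}.
#' @return A [vol3d()] on the target grid.
#' @export
unstraighten_volume <- function(straight, transform, target_grid, fill = 0,
                                interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  cl <- transform$centerline
  fr <- transform$frames
  pr <- cpp_project_to_curve(as.integer(target_grid$dims),
                             as.numeric(target_grid$spacing),
                             as.numeric(target_grid$origin),
                             cl$points, fr$normal, fr$binormal, cl$arclen,
                             transform$radius)
  g <- straight_grid(transform)
  inside <- is.finite(pr$dist)
  vals <- rep(fill, length(pr$dist))
  if (any(inside)) {
    # straight-volume 0-based voxel coordinates of the (u, v, s) points
    pu <- (pr$u[inside] - g$u0) / transform$in_plane_spacing
    pv <- (pr$v[inside] - g$u0) / transform$in_plane_spacing
    ps <- pr$s[inside] / transform$axial_step
    sampler <- if (interpolation == "trilinear") cpp_trilinear_sample
               else cpp_nearest_sample
    vals[inside] <- sampler(as.vector(straight$data), dim(straight$data),
                            cbind(pu, pv, ps), fill)
  }
  vol3d(array(vals, target_grid$dims), target_grid$spacing,
        target_grid$origin)
}

#' Grid specification of a volume
#' @param vol A [vol3d()] or [bin_mask()].
#' @return List with \code{dims}, \code{spacing}, \code{origin}.
#' @export
grid_of <- function(vol) {
  list(dims = dim(vol$data), spacing = vol$spacing, origin = vol$origin)
}

#' Carry a parametric map through the straightening transform
#'
#' Applies the curved-to-straight or straight-to-curved mapping to a scalar
#' map (e.g. an FA map resampled into the cord's native frame), with
#' nearest-neighbour interpolation available for label maps so no new label
#' values are created.
#'
#' @param map A [vol3d()] (or [bin_mask()], straightened as 0/1).
#' @param transform A [straightening_transform()].
#' @param direction \code{"curved_to_straight"} or
#'   \code{"straight_to_curved"}.
#' @param interpolation \code{"trilinear"} or \code{"nearest"}.
#' @param target_grid Required for \code{"straight_to_curved"}: the curved
#'   output grid.
#' @param fill Fill value.
#' @return A [vol3d()].
#' @export
apply_transform_to_map <- function(map, transform,
                                   direction = c("curved_to_straight",
                                                 "straight_to_curved"),
                                   interpolation = c("trilinear", "nearest"),
                                   target_grid = NULL, fill = 0) {
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  if (is_bin_mask(map))
    map <- vol3d(array(as.numeric(map$data), dim(map$data)), map$spacing,
                 map$origin)
  if (direction == "curved_to_straight") {
    straighten_volume(map, transform, fill = fill,
                      interpolation = interpolation)
  } else {
    if (is.null(target_grid))
      stop("straight_to_curved needs a `target_grid`")
    unstraighten_volume(map, transform, target_grid, fill = fill,
                        interpolation = interpolation)
  }
}

#' Serialize / load a straightening transform
#'
#' Sidecar text format: a JSON header (radius, spacings) plus the
#' centerline CSV columns and per-sample 3 x 3 frame matrices (row-major:
#' tangent, normal, binormal rows).
#'
#' @param transform A [straightening_transform()].
#' @param path Output / input file path (JSON).
#' @return \code{save_straightening_transform}: the path, invisibly;
#'   \code{load_straightening_transform}: the transform.
#' @export
save_straightening_transform <- function(transform, path) {
  cl <- transform$centerline
  fr <- transform$frames
  obj <- list(
    radius_um = transform$radius,
    in_plane_spacing_um = transform$in_plane_spacing,
    axial_step_um = transform$axial_step,
    centerline = cbind(x_um = cl$points[, 1], y_um = cl$points[, 2],
                       z_um = cl$points[, 3], arclen_um = cl$arclen),
    frames = t(vapply(seq_len(nrow(cl$points)), function(i)
      c(fr$tangent[i, ], fr$normal[i, ], fr$binormal[i, ]), numeric(9))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_straightening_transform
#' @export
load_straightening_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- centerline(obj$centerline[, 1:3, drop = FALSE])
  straightening_transform(cl, obj$radius_um, obj$in_plane_spacing_um,
                          obj$axial_step_um)
}
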