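#' 3D scalar volume with world geometry
#'
#' The universal image carrier: a 3D numeric array plus per-axis voxel
#' spacing and a world origin, both in micrometres. Axis order is (x, y, z)
#' with z the long/axial axis for spinal cord data. The world coordinate of
#' voxel \code{(i, j, k)} (1-based) is \code{origin + (i-1, j-1, k-1) *
#' spacing}; all resampling operations in the package preserve the world
#' position of voxel centres under this convention.
#'
#' @param data 3D numeric array of finite values, at least 2 voxels per axis.
#' @param spacing Numeric length-3, voxel spacing in micrometres (> 0).
#' @param origin Numeric length-3, world coordinate of the first voxel
#'   centre in micrometres.
#' @return An object of class \code{vol3d}.
#' @export
vol3d <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (um)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (um)")
  if (!all(is.finite(data)))
    stop("volume values must all be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing (%s) um, origin (%s) um\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

is_vol3d <- function(x) inherits(x, "vol3d")

#' Binary mask sharing a volume's grid
#'
#' A strictly binary (\code{TRUE}/\code{FALSE}) 3D grid with the spacing and
#' origin of its source volume, plus a provenance note recording which
#' operation produced it.
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing,origin Grid geometry in micrometres, as in [vol3d()].
#' @param provenance Character note on the producing operation.
#' @return An object of class \code{bin_mask}.
#' @export
bin_mask <- function(data, spacing, origin = c(0, 0, 0),
                     provenance = "unspecified") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be strictly binary")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("`data` must be logical or 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 provenance = as.character(provenance)[1]),
            class = "bin_mask")
}

#' @export
print.bin_mask <- function(x, ...) {
  cat(sprintf("<bin_mask> %s voxels, %d foreground (%.1f%%), from: %s\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data), x$provenance))
  invisible(x)
}

#' @export
dim.bin_mask <- function(x) dim(x$data)

is_bin_mask <- function(x) inherits(x, "bin_mask")

mask_like <- function(vol, data, provenance) {
  bin_mask(data, vol$spacing, vol$origin, provenance)
}

vol_like <- function(vol, data) vol3d(data, vol$spacing, vol$origin)

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop("grid mismatch: shapes, spacings and origins must agree")
  invisible(TRUE)
}

#' Convert between world and voxel coordinates
#'
#' @param vol A [vol3d()] or [bin_mask()].
#' @param pts N x 3 matrix of points. For \code{world_to_voxel}, world
#'   micrometres; for \code{voxel_to_world}, 1-based voxel indices
#'   (possibly fractional).
#' @return N x 3 matrix in the other coordinate system.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- as_pts_matrix(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- as_pts_matrix(pts)
  sweep(sweep(pts - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

as_pts_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (ncol(pts) != 3L) stop("points must be N x 3")
  storage.mode(pts) <- "double"
  pts
}

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks.
#'
#' @param a,b Masks ([bin_mask()]) or logical arrays on the same grid.
#' @return Dice coefficient in [0, 1]; \code{NaN} if both masks are empty.
#' @export
dice <- function(a, b) {
  av <- if (is_bin_mask(a)) a$data else a
  bv <- if (is_bin_mask(b)) b$data else b
  if (!identical(dim(av), dim(bv))) stop("masks must share a grid")
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

## ---- shared numeric helpers ----

# Shift a 3D array by `by` voxels along `axis`, replicating edge values.
shift_replicate <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with per-axis sigma in voxels.
# Edge handling: kernel renormalized over in-grid support via replication.
gauss_smooth3 <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  out <- a
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(out))
    for (t in seq_along(w))
      acc <- acc + w[t] * shift_replicate(out, ax, t - r - 1L)
    out <- acc
  }
  out
}

# Central-difference gradient along one axis, per voxel step (edges one-sided
# via replication, which halves the edge estimate -- consistent everywhere).
central_diff <- function(a, axis) {
  (shift_replicate(a, axis, 1L) - shift_replicate(a, axis, -1L)) / 2
}

# Gradient magnitude; spacing = NULL gives voxel units, otherwise per um.
gradient_magnitude <- function(a, spacing = NULL) {
  gx <- central_diff(a, 1L)
  gy <- central_diff(a, 2L)
  gz <- central_diff(a, 3L)
  if (!is.null(spacing)) {
    gx <- gx / spacing[1]; gy <- gy / spacing[2]; gz <- gz / spacing[3]
  }
  sqrt(gx^2 + gy^2 + gz^2)
}

# Largest 26-connected component of a logical array.
largest_component <- function(m) {
  lab <- array(cpp_label_components(as.logical(m), dim(m), 26L), dim(m))
  if (max(lab) <= 1L) return(m)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
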