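#' Centerline: an ordered 3D polyline with arc length
#'
#' Ordered samples in world micrometres with cumulative arc length; the
#' 1D skeleton of an elongated structure such as the spinal cord.
#'
#' @param points N x 3 matrix of world coordinates (um), N >= 2.
#' @return An object of class \code{centerline} with \code{points} and
#'   \code{arclen} (cumulative, \code{arclen[1] = 0}, strictly increasing).
#' @export
centerline <- function(points) {
  points <- as_pts_matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 samples")
  steps <- sqrt(rowSums(diff(points)^2))
  if (any(steps <= 1e-12))
    stop("coincident consecutive centerline samples")
  if (any(steps > 10 * median(steps)))
    stop("centerline has a gap wider than 10x the median step")
  structure(list(points = points, arclen = c(0, cumsum(steps))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, arc length %.1f um\n",
              nrow(x$points), total_length(x)))
  invisible(x)
}

#' Total arc length of a centerline (um)
#' @param cl A [centerline()].
#' @export
total_length <- function(cl) cl$arclen[length(cl$arclen)]

#' 3D edge detection with hysteresis (approximate Canny)
#'
#' Gaussian-smooths the volume, computes the gradient magnitude, and keeps
#' strong edges (above \code{high_thr} x max gradient) plus weak edges
#' (between the two thresholds) that are 26-connected to a strong voxel.
#' With \code{"auto"} thresholds, \code{high} is the Otsu threshold of the
#' gradient-magnitude volume (as a fraction of its maximum) and
#' \code{low = 0.4 * high}.
#'
#' @param volume A [vol3d()].
#' @param sigma Gaussian smoothing sigma in micrometres.
#' @param low_thr,high_thr Fractions of the maximum gradient magnitude, or
#'   \code{"auto"}.
#' @return A [bin_mask()] of edge voxels.
#' @export
detect_edges_3d <- function(volume, sigma, low_thr = "auto",
                            high_thr = "auto") {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0 um")
  sm <- gauss_smooth3(volume$data, sigma / volume$spacing)
  g <- gradient_magnitude(sm, volume$spacing)
  gmax <- max(g)
  if (gmax <= 0)
    return(mask_like(volume, array(FALSE, dim(g)), "detect_edges_3d(empty)"))
  if (identical(high_thr, "auto")) high_thr <- threshold_otsu(g) / gmax
  if (identical(low_thr, "auto")) low_thr <- 0.4 * high_thr
  if (low_thr >= high_thr) stop("`low_thr` must be below `high_thr`")
  strong <- g >= high_thr * gmax
  weak <- g >= low_thr * gmax
  if (!any(strong))
    return(mask_like(volume, array(FALSE, dim(g)), "detect_edges_3d(none)"))
  # hysteresis: weak components (26-connected) containing a strong voxel
  lab <- array(cpp_label_components(as.logical(weak), dim(weak), 26L),
               dim(weak))
  keep <- unique(lab[strong])
  keep <- keep[keep > 0L]
  edges <- array(lab %in% keep, dim(weak))
  mask_like(volume, edges,
            sprintf("detect_edges_3d(sigma=%.3g, low=%.3g, high=%.3g)",
                    sigma, low_thr, high_thr))
}

#' Restrict an edge image to the cord contours
#'
#' An edge image of a cord-in-medium tomogram also contains the container
#' and cell-interface edges. This keeps only edge voxels adjacent (within
#' \code{dilate} voxels) to tissue-intensity voxels, where the tissue
#' threshold is the upper value of the two-stage Otsu band -- separating
#' the cord from the embedding medium -- so slice centroids and region
#' growing see the cord boundary only.
#'
#' @param volume The intensity [vol3d()] the edges were computed from.
#' @param edges A [bin_mask()] from [detect_edges_3d()].
#' @param dilate Adjacency radius in voxels (default 1).
#' @return A [bin_mask()] of cord-contour voxels.
#' @export
cord_contours <- function(volume, edges, dilate = 1L) {
  stopifnot_same_grid(volume, edges)
  high <- auto_band(volume)[2]
  tissue <- mask_like(volume, volume$data > high, "tissue")
  near <- dilate_ball(tissue, check_radius(dilate))
  mask_like(volume, edges$data & near$data, "cord_contours")
}

#' Centerline from slice-wise centres of mass of a contour image
#'
#' For each z with a non-empty contour, the centerline sample is the
#' unweighted centroid of the contour voxels in world coordinates; empty
#' slices are skipped and the samples are ordered by z. The raw centroid
#' polyline is then smoothed with a moving average (in-plane coordinates
#' only; shrinking window at the ends, so a constant-centre cord is left
#' exact).
#'
#' @param contours A [bin_mask()] of edge/contour voxels.
#' @param smooth_window Moving-average window in samples (odd; default 5;
#'   1 disables smoothing).
#' @return A [centerline()].
#' @export
centerline_from_slices <- function(contours, smooth_window = 5L) {
  d <- dim(contours$data)
  counts <- apply(contours$data, 3, sum)
  zs <- which(counts > 0L)
  if (length(zs) < 2L) stop("need contour voxels in at least 2 xy slices")
  pts <- t(vapply(zs, function(z) {
    w <- which(contours$data[, , z], arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]), z)
  }, numeric(3)))
  world <- voxel_to_world(contours, pts)
  if (smooth_window > 1L) {
    half <- floor(smooth_window / 2)
    n <- nrow(world)
    for (col in 1:2) {
      sm <- vapply(seq_len(n), function(i) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        mean(world[lo:hi, col])
      }, numeric(1))
      world[, col] <- sm
    }
  }
  centerline(world)
}

#' Cord mask by 3D seeded region growing of an edge image
#'
#' Grows the 6-connected component of non-edge voxels containing the seed
#' (the edge shell itself is excluded from growth, and 6-connectivity
#' prevents diagonal leakage through one-voxel shells), then closes the
#' result with a ball of radius 1 to absorb the shell.
#'
#' @param edges A [bin_mask()] of edge voxels.
#' @param seed 1-based voxel index \code{c(i, j, k)}; must not lie on an
#'   edge voxel.
#' @return A [bin_mask()].
#' @export
region_grow_mask <- function(edges, seed) {
  seed <- as.integer(seed)
  d <- dim(edges$data)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel lies outside the grid")
  if (edges$data[seed[1], seed[2], seed[3]])
    stop("seed voxel lies on an edge; choose a seed inside the structure")
  open <- !edges$data
  grown <- array(cpp_flood_region(as.logical(open), d, seed - 1L, 6L), d)
  m <- mask_like(edges, grown, "region_grow_mask")
  erode_ball(dilate_ball(m, 1L), 1L, border = "foreground")
}

#' Moving-average smoothing of a centerline polyline
#'
#' Centroid-based centerlines carry voxel-scale jitter that dominates
#' discrete curvature estimates at fine arc-length steps; a moving average
#' over \code{window} samples (shrinking symmetrically at the ends)
#' suppresses it while leaving smooth bends intact.
#'
#' @param cl A [centerline()].
#' @param window Odd window length in samples (1 = no-op).
#' @param trim_ends Drop the half-window samples at each end, where the
#'   average is one-sided and residual jitter would leave curvature kinks
#'   (default \code{TRUE}).
#' @return A [centerline()].
#' @export
smooth_centerline <- function(cl, window = 9L, trim_ends = TRUE) {
  if (window <= 1L) return(cl)
  half <- floor(window / 2)
  n <- nrow(cl$points)
  pts <- cl$points
  for (col in 1:3)
    pts[, col] <- vapply(seq_len(n), function(i) {
      h <- min(half, i - 1L, n - i)
      mean(cl$points[(i - h):(i + h), col])
    }, numeric(1))
  if (trim_ends && n > 2L * half + 3L)
    pts <- pts[(half + 1L):(n - half), , drop = FALSE]
  centerline(pts)
}

#' Resample a centerline at (approximately) equal arc-length steps
#'
#' Linear interpolation along the polyline at uniform arc-length spacing as
#' close as possible to \code{step} while keeping both endpoints exact.
#'
#' @param cl A [centerline()].
#' @param step Target arc-length step (um); must not exceed the total
#'   length.
#' @return A [centerline()] with uniform steps.
#' @export
resample_centerline <- function(cl, step) {
  L <- total_length(cl)
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0")
  if (step > L) stop("`step` exceeds the total arc length")
  n_out <- max(2L, as.integer(floor(L / step + 0.5)) + 1L)
  s_new <- seq(0, L, length.out = n_out)
  pts <- vapply(1:3, function(col)
    stats::approx(cl$arclen, cl$points[, col], xout = s_new)$y,
    numeric(n_out))
  centerline(pts)
}
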