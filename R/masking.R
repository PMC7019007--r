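#' Otsu threshold of a volume
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' finite voxel values; the threshold is reported on the original intensity
#' scale as the centre of the optimal bin boundary.
#'
#' @param volume A [vol3d()] (or numeric array/vector of intensities).
#' @param nbins Number of histogram bins (default 256).
#' @return The threshold intensity (scalar).
#' @export
threshold_otsu <- function(volume, nbins = 256L) {
  v <- if (is_vol3d(volume)) as.vector(volume$data) else as.vector(volume)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(unique(v)) < 2L || diff(rng) == 0)
    stop("degenerate input: volume is constant, no threshold exists")
  width <- diff(rng) / nbins
  b <- pmin(floor((v - rng[1]) / width), nbins - 1)
  h <- tabulate(b + 1L, nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * width
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for a cut after bin t
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t_best <- which.max(bcv)
  # threshold at the upper edge of bin t_best, reported as a bin-boundary
  # centre between the two adjacent bin centres
  rng[1] + t_best * width
}

#' Foreground mask from a bimodal intensity band
#'
#' Marks every voxel whose intensity falls outside the band
#' \code{(low, high)} -- i.e. darker than \code{low} or brighter than
#' \code{high}. Designed for phase-contrast tomograms where the embedding
#' medium occupies a middle intensity band and ring artifacts at the tissue
#' boundary swing both bright and dark: tissue and both artifact polarities
#' land in the mask while the medium does not.
#'
#' @param volume A [vol3d()].
#' @param band Numeric length-2 \code{c(low, high)}, with \code{low < high}.
#' @return A [bin_mask()]; if empty, it carries
#'   \code{attr(, "empty_warning") = TRUE} and a warning is emitted.
#' @export
bimodal_foreground <- function(volume, band) {
  if (length(band) != 2L || !(band[1] < band[2]))
    stop("`band` must be c(low, high) with low < high")
  m <- volume$data < band[1] | volume$data > band[2]
  out <- mask_like(volume, m, "bimodal_foreground")
  if (!any(m)) {
    warning("bimodal_foreground produced an empty mask")
    attr(out, "empty_warning") <- TRUE
  }
  out
}

#' Morphological dilation and erosion with a discrete ball
#'
#' Structuring element: all integer offsets with Euclidean norm at most
#' \code{radius}. Voxels beyond the grid count as background for both
#' operations, so erosion shrinks the mask at the grid border; the duality
#' \code{erode(M) = !dilate(!M)} holds exactly on padded grids.
#'
#' @param mask A [bin_mask()].
#' @param radius Non-negative integer radius in voxels; 0 is the identity.
#' @return A [bin_mask()].
#' @export
dilate_ball <- function(mask, radius) {
  radius <- check_radius(radius)
  d <- array(cpp_ball_morph(as.logical(mask$data), dim(mask$data), radius, TRUE),
             dim(mask$data))
  mask_like(mask, d, sprintf("dilate_ball(r=%d)", radius))
}

#' @rdname dilate_ball
#' @param border How erosion treats out-of-grid voxels:
#'   \code{"background"} (default; the mask erodes at the grid border) or
#'   \code{"foreground"} (the border acts as padding, e.g. for closing a
#'   region that touches the grid edge).
#' @export
erode_ball <- function(mask, radius, border = c("background", "foreground")) {
  radius <- check_radius(radius)
  border <- match.arg(border)
  d <- array(cpp_ball_morph(as.logical(mask$data), dim(mask$data), radius,
                            FALSE, as.integer(border == "foreground")),
             dim(mask$data))
  mask_like(mask, d, sprintf("erode_ball(r=%d)", radius))
}

check_radius <- function(radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0 ||
      radius != round(radius))
    stop("`radius` must be a single non-negative integer")
  as.integer(radius)
}

#' Slice-wise 2D hole filling
#'
#' For every slice perpendicular to \code{slice_axis}, background regions
#' (4-connected within the slice) not reachable from the slice border become
#' foreground. Because it operates per slice, a tunnel running through the
#' whole stack along the slice axis -- open in 3D but closed in every slice
#' -- is filled, unlike 3D hole filling.
#'
#' @param mask A [bin_mask()].
#' @param slice_axis Axis perpendicular to the slices: 1, 2 or 3 (default 3,
#'   i.e. xy slices).
#' @return A [bin_mask()]. Idempotent.
#' @export
fill_holes_2d <- function(mask, slice_axis = 3L) {
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  d <- array(cpp_fill_holes_slices(as.logical(mask$data), dim(mask$data),
                                   as.integer(slice_axis)),
             dim(mask$data))
  mask_like(mask, d, sprintf("fill_holes_2d(axis=%d)", slice_axis))
}

#' Erode until a single connected component remains
#'
#' Repeatedly erodes with a ball of the given radius until the mask has
#' exactly one 26-connected component. Intended to detach and dissolve
#' debris outside the main object; the iteration count is returned so the
#' matching re-dilation can restore the eroded margin.
#'
#' @param mask A non-empty [bin_mask()].
#' @param radius Ball radius per erosion step (voxels).
#' @return List with \code{mask} (a [bin_mask()]) and \code{n_iterations}.
#' @export
erode_until_single_component <- function(mask, radius) {
  radius <- check_radius(radius)
  if (radius < 1L) stop("`radius` must be >= 1 for iterated erosion")
  if (!any(mask$data)) stop("mask is empty")
  cur <- mask$data
  n <- 0L
  repeat {
    ncomp <- max(cpp_label_components(as.logical(cur), dim(cur), 26L))
    if (ncomp == 1L) break
    nxt <- array(cpp_ball_morph(as.logical(cur), dim(cur), radius, FALSE),
                 dim(cur))
    if (!any(nxt))
      stop(sprintf(paste0("erosion collapse: mask vanished before reaching ",
                          "a single component (last non-empty iteration %d)"), n))
    cur <- nxt
    n <- n + 1L
  }
  list(mask = mask_like(mask, cur,
                        sprintf("erode_until_single_component(r=%d, n=%d)",
                                radius, n)),
       n_iterations = n)
}

#' Threshold-and-morphology foreground masking for tomographic volumes
#'
#' The full masking recipe for a high-resolution volume whose tissue
#' boundary carries ring artifacts: (1) a bimodal intensity mask admitting
#' both dark and bright voxels outside the medium band; (2) dilation with a
#' ball (default radius 2 voxels) to close the borders; (3) slice-wise 2D
#' hole filling; (4) iterated erosion until a single 26-connected component
#' survives; (5) re-dilation by \code{radius * (1 + n_iterations)},
#' intersected with the hole-filled pre-erosion mask so the restored margin
#' cannot overshoot or re-admit exterior debris.
#'
#' With \code{band = "auto"} the band is derived by two-stage Otsu
#' thresholding: a global Otsu split at t, then \code{low} = Otsu of the
#' values below t and \code{high} = Otsu of the values above t.
#'
#' @param volume A non-constant [vol3d()].
#' @param band \code{c(low, high)} or \code{"auto"}.
#' @param dilate_radius Ball radius in voxels (default 2).
#' @param slice_axis Axis for 2D hole filling (default 3).
#' @return A [bin_mask()]: one 26-connected component, no in-slice holes.
#' @export
brain_mask_pipeline <- function(volume, band = "auto", dilate_radius = 2L,
                                slice_axis = 3L) {
  dilate_radius <- check_radius(dilate_radius)
  if (identical(band, "auto")) band <- auto_band(volume)
  m0 <- bimodal_foreground(volume, band)
  if (!any(m0$data)) stop("auto/explicit band produced an empty initial mask")
  m1 <- dilate_ball(m0, dilate_radius)
  m2 <- fill_holes_2d(m1, slice_axis)
  er <- erode_until_single_component(m2, dilate_radius)
  core <- er$mask$data
  core <- largest_component(core)  # guaranteed single; kept for safety
  grown <- cpp_ball_morph(as.logical(core), dim(core),
                          dilate_radius * (1L + er$n_iterations), TRUE)
  final <- array(grown, dim(core)) & m2$data
  final <- array(cpp_fill_holes_slices(as.logical(final), dim(final),
                                       as.integer(slice_axis)), dim(final))
  final <- largest_component(final)
  mask_like(volume, final,
            sprintf("brain_mask_pipeline(band=[%.3g,%.3g], r=%d, n_erode=%d)",
                    band[1], band[2], dilate_radius, er$n_iterations))
}

# Two-stage Otsu band: global split, then one Otsu per side. The side
# splits are meant to separate a minority class (dark artifacts/structures
# below; bright tissue above) from the dominant medium; if a side split
# instead lands inside the medium mass -- detectable because most of the
# volume ends up outside the band on that side -- that side has no
# minority class and the band edge is pushed past the data range.
auto_band <- function(volume) {
  t0 <- threshold_otsu(volume)
  v <- as.vector(volume$data)
  rng <- range(v)
  lo_side <- v[v <= t0]
  hi_side <- v[v > t0]
  low <- if (length(unique(lo_side)) >= 2L) threshold_otsu(lo_side) else t0
  high <- if (length(unique(hi_side)) >= 2L) threshold_otsu(hi_side) else t0
  if (mean(v < low) > 0.25) low <- rng[1] - 1
  if (mean(v > high) > 0.5) high <- rng[2] + 1
  c(low, high)
}
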