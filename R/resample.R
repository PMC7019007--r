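#' Percentile intensity saturation
#'
#' Clips the darkest \code{lower_frac} and brightest \code{upper_frac}
#' fraction of voxels to the corresponding nearest-rank quantile (default
#' 0.3% each side, the usual display-normalization for phase-contrast
#' tomograms). With n finite voxels and k = floor(frac * n), exactly the k
#' most extreme values on each side are replaced by the (k+1)-th order
#' statistic. Idempotent at fixed fractions.
#'
#' @param volume A [vol3d()].
#' @param lower_frac,upper_frac Fractions in [0, 0.5).
#' @return A [vol3d()] with clipped intensities.
#' @export
saturate_intensity <- function(volume, lower_frac = 0.003,
                               upper_frac = 0.003) {
  if (lower_frac < 0 || upper_frac < 0 || lower_frac >= 0.5 ||
      upper_frac >= 0.5)
    stop("saturation fractions must lie in [0, 0.5)")
  v <- volume$data
  s <- sort(as.vector(v))
  n <- length(s)
  k_lo <- floor(lower_frac * n)
  k_hi <- floor(upper_frac * n)
  lo <- s[k_lo + 1L]
  hi <- s[n - k_hi]
  vol_like(volume, array(pmin(pmax(v, lo), hi), dim(v)))
}

#' Anti-aliased down-sampling to a target spacing
#'
#' Gaussian low-pass filtering followed by trilinear resampling onto the
#' coarser grid. The per-axis Gaussian sigma is \code{factor / 2} voxels
#' where \code{factor = target / source} spacing, placing the filter cutoff
#' near the new Nyquist limit. The world position of the first voxel centre
#' is preserved, so transforms estimated on the down-sampled grid compose
#' with the original geometry.
#'
#' @param volume A [vol3d()].
#' @param target_spacing Numeric (scalar or length 3), micrometres; must be
#'   >= the source spacing on every axis (use a dedicated up-sampler to go
#'   finer).
#' @return A [vol3d()] on the target grid.
#' @export
antialias_downsample <- function(volume, target_spacing) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(target_spacing < volume$spacing - 1e-9))
    stop("target spacing finer than source: this is an up-sampling request, ",
         "use a dedicated up-sampling operation")
  factor <- target_spacing / volume$spacing
  sm <- gauss_smooth3(volume$data, factor / 2)
  d <- dim(volume$data)
  n_out <- pmax(2L, floor((d - 1) * volume$spacing / target_spacing) + 1L)
  # 0-based source voxel coordinates of output voxel centres
  g <- lapply(1:3, function(ax) (seq_len(n_out[ax]) - 1) * factor[ax])
  pts <- cbind(rep(g[[1]], times = n_out[2] * n_out[3]),
               rep(rep(g[[2]], each = n_out[1]), times = n_out[3]),
               rep(g[[3]], each = n_out[1] * n_out[2]))
  vals <- cpp_trilinear_sample(as.vector(sm), d, pts, NA_real_)
  vol3d(array(vals, n_out), target_spacing, volume$origin)
}

#' Nearest-neighbour down-sampling by integer factors
#'
#' Output voxel \code{(i, j, k)} takes the input value at the source voxel
#' nearest to the output voxel centre; with the shared voxel-centre
#' convention this is exactly \code{input[f*(i-1)+1, ...]}, so no new
#' intensity values are created. Spacing is multiplied by the factor.
#'
#' @param volume A [vol3d()] or [bin_mask()].
#' @param factor Integer >= 1, scalar or per-axis length 3.
#' @return Same class as the input, on the coarser grid.
#' @export
nn_downsample <- function(volume, factor) {
  factor <- as.numeric(factor)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (any(!is.finite(factor)) || any(factor < 1) ||
      any(abs(factor - round(factor)) > 1e-9))
    stop("`factor` must be integer >= 1 per axis; ",
         "use antialias_downsample for fractional factors")
  factor <- as.integer(round(factor))
  d <- dim(volume$data)
  idx <- lapply(1:3, function(ax) seq(1L, d[ax], by = factor[ax]))
  sub <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (is_bin_mask(volume))
    bin_mask(sub, volume$spacing * factor, volume$origin,
             paste0(volume$provenance, " | nn_downsample"))
  else
    vol3d(sub, volume$spacing * factor, volume$origin)
}

#' Mean gradient magnitude over an interface band
#'
#' Scores how sharp the sample--medium interface is: the mean
#' central-difference gradient magnitude (voxel units) over the band voxels
#' restricted to the listed xy slices. Invariant to adding a constant to
#' the volume; a step edge of height h scores h/2.
#'
#' @param volume A [vol3d()].
#' @param interface_band A [bin_mask()] marking the interface neighbourhood.
#' @param slices Integer z-indices (1-based) of the slices to evaluate.
#' @return Scalar score (mean gradient magnitude).
#' @export
interface_gradient_score <- function(volume, interface_band, slices) {
  stopifnot_same_grid(volume, interface_band)
  slices <- as.integer(slices)
  nz <- dim(volume$data)[3]
  slices <- slices[slices >= 1L & slices <= nz]
  if (length(slices) == 0L) stop("no valid slices selected")
  sel <- array(FALSE, dim(volume$data))
  sel[, , slices] <- interface_band$data[, , slices]
  if (!any(sel)) stop("interface band is empty on every selected slice")
  g <- gradient_magnitude(volume$data)
  mean(g[sel])
}

#' Choose a down-sampling factor by interface sharpness
#'
#' Evaluates [interface_gradient_score()] on the nearest-neighbour
#' down-sampled volume for each candidate factor (the band and slice
#' indices are down-sampled consistently) and returns the factor with the
#' highest score; ties break toward the smaller factor.
#'
#' @param volume A [vol3d()].
#' @param candidate_factors Integer vector of >= 2 candidate factors.
#' @param interface_band A [bin_mask()] on the source grid.
#' @param slices z-indices (1-based) on the source grid.
#' @return The selected factor, with the per-candidate scores attached as
#'   \code{attr(, "scores")}.
#' @export
select_downsample_scale <- function(volume, candidate_factors,
                                    interface_band, slices) {
  if (length(candidate_factors) < 2L)
    stop("need at least 2 candidate factors")
  stopifnot_same_grid(volume, interface_band)
  cf <- sort(unique(as.integer(candidate_factors)))
  scores <- vapply(cf, function(f) {
    ds <- nn_downsample(volume, f)
    db <- nn_downsample(interface_band, f)
    sl <- unique(pmax(1L, as.integer(floor((as.integer(slices) - 1L) / f)) + 1L))
    sl <- sl[sl <= dim(ds$data)[3]]
    interface_gradient_score(ds, db, sl)
  }, numeric(1))
  if (max(scores) <= 0)
    stop("no gradient signal in the interface band at any candidate factor")
  best <- cf[which.max(scores)]  # which.max takes the first (smallest) on ties
  structure(best, scores = stats::setNames(scores, cf))
}
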