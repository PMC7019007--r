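#' Phantom specification
#'
#' Describes a paired multimodal synthetic acquisition: a high-resolution
#' modality (sharp, ring-artifacted at the sample boundary, embedded in a
#' medium -- emulating phase-contrast tomography of a sample in agar) and a
#' low-resolution modality (smooth, noisy, related to the first by a known
#' affine plus, for the cord, a smooth bend -- emulating a diffusion-MRI
#' derived map acquired in a different holder). The two grids keep the
#' high/low resolution asymmetry of the emulated acquisitions at a reduced
#' desk scale (high-res grid <= 256^3).
#'
#' @param kind \code{"brain"} or \code{"cord"}.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @param hires_shape,hires_spacing,lores_shape,lores_spacing Grid shapes
#'   (voxels) and spacings (um/axis) per modality.
#' @param levels Named intensities (arbitrary units): \code{background},
#'   \code{medium}, \code{tissue}, \code{butterfly} (cord gray matter).
#' @param ring_amplitude,ring_width Boundary ring artifact: amplitude as a
#'   fraction of the mean tissue intensity, band half-width in voxels.
#' @param noise_sigma Additive Gaussian noise (intensity units), length 2
#'   \code{c(hires, lores)}.
#' @param rotation_deg,translation_um,scale True inter-modality affine
#'   (rotation about z through the volume centre, translation, uniform
#'   scale), mapping high-res world coordinates to low-res world
#'   coordinates.
#' @param warp_amplitude_um Cord only: amplitude of a smooth sinusoidal
#'   bend added to the affine, so the two modalities carry different
#'   curvatures.
#' @param control_points Cord only: N x 3 matrix of curve control points in
#'   high-res world um (default: a gentle planar C-bend along z).
#' @param tube_radius_um Cord tube radius (um); must stay below the
#'   minimal radius of curvature of the control curve so straightening is
#'   invertible.
#' @param brain_semiaxes_um Brain only: ellipsoid semi-axes (um).
#' @param texture_period_um,texture_amplitude Tissue texture (shared
#'   between modalities so mutual information has signal).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(kind = c("brain", "cord"), seed = 1L,
                         hires_shape = NULL, hires_spacing = NULL,
                         lores_shape = NULL, lores_spacing = NULL,
                         levels = c(background = 10, medium = 100,
                                    tissue = 180, butterfly = 140),
                         ring_amplitude = 0.5, ring_width = 1L,
                         noise_sigma = c(4, 4),
                         rotation_deg = 8, translation_um = NULL,
                         scale = NULL, warp_amplitude_um = NULL,
                         control_points = NULL, tube_radius_um = 280,
                         brain_semiaxes_um = c(2750, 2550, 2350),
                         texture_period_um = 250, texture_amplitude = 25) {
  kind <- match.arg(kind)
  if (kind == "brain") {
    if (is.null(hires_shape)) hires_shape <- c(240L, 240L, 240L)
    if (is.null(hires_spacing)) hires_spacing <- c(25, 25, 25)
    if (is.null(lores_shape)) lores_shape <- c(48L, 48L, 48L)
    if (is.null(lores_spacing)) lores_spacing <- c(125, 125, 125)
    if (is.null(translation_um)) translation_um <- c(500, 250, 125)
    if (is.null(scale)) scale <- 1.05
    if (is.null(warp_amplitude_um)) warp_amplitude_um <- 0
  } else {
    if (is.null(hires_shape)) hires_shape <- c(96L, 96L, 224L)
    if (is.null(hires_spacing)) hires_spacing <- c(10, 10, 10)
    if (is.null(lores_shape)) lores_shape <- c(30L, 30L, 58L)
    if (is.null(lores_spacing)) lores_spacing <- c(40, 40, 40)
    if (is.null(translation_um)) translation_um <- c(60, 40, 100)
    if (is.null(scale)) scale <- 1.0      # same physical cord, rigid holders
    if (is.null(warp_amplitude_um)) warp_amplitude_um <- 80
    if (is.null(control_points)) {
      # the cord runs axially through (and slightly beyond) the whole stack
      zz <- seq(-220, 2340, length.out = 6)
      L <- max(zz) - min(zz)
      control_points <- cbind(480 + 140 * sin(pi * (zz - min(zz)) / L),
                              480 + 60 * sin(pi * (zz - min(zz)) / L),
                              zz)
    }
  }
  hires_shape <- as.integer(hires_shape); lores_shape <- as.integer(lores_shape)
  if (any(hires_shape > 256L) || any(lores_shape > 256L))
    stop("grid shapes must fit in <= 256^3")
  if (any(hires_spacing <= 0) || any(lores_spacing <= 0))
    stop("spacings must be > 0")
  if (tube_radius_um <= 0) stop("tube radius must be > 0")
  if (ring_amplitude < 0 || ring_width < 1) stop("invalid ring parameters")
  if (length(noise_sigma) == 1L) noise_sigma <- rep(noise_sigma, 2L)
  spec <- structure(list(
    kind = kind, seed = as.integer(seed),
    hires_shape = hires_shape, hires_spacing = as.numeric(hires_spacing),
    lores_shape = lores_shape, lores_spacing = as.numeric(lores_spacing),
    levels = levels, ring_amplitude = ring_amplitude,
    ring_width = as.integer(ring_width), noise_sigma = noise_sigma,
    rotation_deg = rotation_deg, translation_um = translation_um,
    scale = scale, warp_amplitude_um = warp_amplitude_um,
    control_points = control_points, tube_radius_um = tube_radius_um,
    brain_semiaxes_um = brain_semiaxes_um,
    texture_period_um = texture_period_um,
    texture_amplitude = texture_amplitude), class = "phantom_spec")
  if (kind == "cord") {
    curve <- make_cord_curve(spec$control_points, 64L)
    rcmin <- 1 / max_discrete_curvature(curve)
    if (tube_radius_um >= rcmin)
      stop(sprintf(paste0("tube radius %.0f um must stay below the minimal ",
                          "radius of curvature of the control curve ",
                          "(%.0f um)"), tube_radius_um, rcmin))
  }
  spec
}

# Run code with a deterministic RNG without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Smooth interpolating curve through cord control points
#'
#' Cubic spline through the control points (per coordinate, against the
#' cumulative chordal parameter), sampled at \code{n_samples} points. The
#' chordal parameterization keeps the sample spacing near-uniform; use
#' [resample_centerline()] for exactly uniform arc-length steps.
#'
#' @param control_points >= 4 control points (N x 3, world um), no two
#'   consecutive ones coincident.
#' @param n_samples Number of output samples (>= 16).
#' @return A [centerline()].
#' @export
make_cord_curve <- function(control_points, n_samples = 200L) {
  cp <- as_pts_matrix(control_points)
  if (nrow(cp) < 4L)
    stop("invalid spec: need at least 4 control points")
  seg <- sqrt(rowSums(diff(cp)^2))
  if (any(seg <= 1e-9))
    stop("invalid spec: coincident consecutive control points")
  if (n_samples < 16L) stop("invalid spec: n_samples must be >= 16")
  tpar <- c(0, cumsum(seg))
  tt <- seq(0, tpar[length(tpar)], length.out = n_samples)
  pts <- vapply(1:3, function(c_)
    stats::spline(tpar, cp[, c_], xout = tt, method = "natural")$y,
    numeric(n_samples))
  centerline(pts)
}

# True inter-modality mapping (high-res world -> low-res world):
# affine about the high-res FOV centre, plus an optional sinusoidal bend
# along x for cord phantoms.
true_transform_affine <- function(spec) {
  center <- (spec$hires_shape - 1) / 2 * spec$hires_spacing
  affine_from_params(c(0, 0, spec$rotation_deg * pi / 180,
                       spec$translation_um, rep(log(spec$scale), 3),
                       rep(0, 3)), center)
}

#' Apply a phantom's exported true transform to points
#'
#' Maps high-res world points into the low-res world frame using the
#' ground-truth affine plus, when present, the smooth bend. This is the
#' mapping the registration stage is asked to recover.
#'
#' @param truth The \code{truth} element of a rendered phantom.
#' @param pts N x 3 high-res world points (um).
#' @return N x 3 low-res world points.
#' @export
apply_true_transform <- function(truth, pts) {
  pts <- transform_points(truth$transform, as_pts_matrix(pts))
  if (!is.null(truth$warp) && truth$warp$amplitude != 0) {
    w <- truth$warp
    pts[, 1] <- pts[, 1] +
      w$amplitude * sin(pi * (pts[, 3] - w$z0) / w$length)
  }
  pts
}

# World coordinate arrays for a grid spec (origin 0).
coord_arrays <- function(shape, spacing) {
  lapply(1:3, function(ax)
    (slice.index(array(0L, shape), ax) - 1) * spacing[ax])
}

ellipsoid_q <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2
}

# Smooth random texture field on the high-res grid: white noise smoothed
# to a correlation length of `texture_period_um` / 2.35 (FWHM) and scaled
# to sd = texture_amplitude. The field lives in the high-res world frame;
# the low-res modality samples the SAME field at its (affinely mapped)
# coordinates, so the two modalities share their fine structure -- which is
# what gives the mutual-information metric its signal.
brain_texture_field <- function(spec) {
  sigma_vox <- spec$texture_period_um / 2.35 / spec$hires_spacing
  tex <- array(rnorm(prod(spec$hires_shape)), spec$hires_shape)
  tex <- gauss_smooth3(tex, sigma_vox)
  tex / sd(tex) * spec$texture_amplitude
}

# Brain scene evaluated at world coordinates (high-res frame).
# Ellipsoidal tissue with a textured body, a bright curved "callosum" band,
# two "hippocampus" blobs and two dark "ventricles", embedded in a uniform
# medium filling the field of view. `tex` holds the texture values at the
# same points as X/Y/Z.
brain_scene <- function(spec, X, Y, Z, tex) {
  ctr <- (spec$hires_shape - 1) / 2 * spec$hires_spacing
  semi <- spec$brain_semiaxes_um
  lv <- spec$levels
  e <- ellipsoid_q(X, Y, Z, ctr, semi)
  fg <- e <= 1
  # internal structures scale with the brain so small custom specs keep
  # proportional anatomy
  sc <- semi / c(2750, 2550, 2350)
  img <- array(lv[["medium"]], dim(X))
  # two-phase parenchyma: a bright patch phase (65% of the body) over a
  # darker base, plus mild continuous variation -- patchy tissue contrast
  # whose bright phase forms a connected net in every cross-section
  amp <- spec$texture_amplitude
  phase <- tex > stats::qnorm(0.35, 0, amp)
  body <- (lv[["tissue"]] - 10) + 1.4 * amp * phase + 0.3 * tex
  img[fg] <- body[fg]
  # thin cortical rim at the surface, uniformly in the bright phase, so the
  # tissue boundary presents one intensity class to thresholding
  rim <- fg & e > 0.90
  img[rim] <- ((lv[["tissue"]] - 10) + 1.4 * amp + 0.3 * tex)[rim]
  hip1 <- ellipsoid_q(X, Y, Z, ctr + c(900, -600, 0) * sc,
                      c(550, 380, 380) * sc) <= 1
  hip2 <- ellipsoid_q(X, Y, Z, ctr + c(-900, -600, 0) * sc,
                      c(550, 380, 380) * sc) <= 1
  hip <- (hip1 | hip2) & fg
  img[hip] <- (lv[["tissue"]] - 40 + 0.6 * tex)[hip]
  cal <- e >= 0.28 & e <= 0.42 & (Y - ctr[2]) > 0
  img[cal] <- lv[["tissue"]] + 45
  ven <- (ellipsoid_q(X, Y, Z, ctr + c(350, 500, 300) * sc,
                      c(420, 260, 260) * sc) <= 1) |
         (ellipsoid_q(X, Y, Z, ctr + c(-350, 500, 300) * sc,
                      c(420, 260, 260) * sc) <= 1)
  ven <- ven & fg
  img[ven] <- lv[["medium"]] - 45
  list(img = img, fg = fg)
}

#' Render the paired brain phantom
#'
#' High-res modality: the brain scene on the fine grid, with a ring
#' artifact added at the tissue/medium interface and additive noise.
#' Low-res modality: the same scene pulled through the inverse of the true
#' inter-modality transform onto the coarse grid, lightly smoothed and
#' noised -- so the low-res volume relates to the high-res one exactly by
#' the exported ground-truth affine. Landmarks are the two lateral poles
#' of the brain ellipsoid, exported in both frames.
#'
#' @param spec A brain [phantom_spec()].
#' @return List of class \code{phantom}: \code{hires}, \code{lores}
#'   ([vol3d()]), and \code{truth} (foreground masks per modality, the
#'   4 x 4 true affine as [affine3d()], landmark pairs).
#' @export
render_brain_phantom <- function(spec) {
  if (spec$kind != "brain") stop("spec is not a brain phantom spec")
  ctr <- (spec$hires_shape - 1) / 2 * spec$hires_spacing
  margin <- (spec$ring_width + 3) * spec$hires_spacing
  if (any(spec$brain_semiaxes_um + margin >
          (spec$hires_shape - 1) / 2 * spec$hires_spacing))
    stop("invalid spec: brain structures overlap the grid boundary")
  with_seed(spec$seed, {
    tex_field <- brain_texture_field(spec)
    co <- coord_arrays(spec$hires_shape, spec$hires_spacing)
    sc <- brain_scene(spec, co[[1]], co[[2]], co[[3]], tex_field)
    hires <- vol3d(sc$img, spec$hires_spacing)
    mask_hi <- bin_mask(sc$fg, spec$hires_spacing,
                        provenance = "phantom truth foreground")
    if (spec$ring_amplitude > 0)
      hires <- add_ring_artifact(hires, mask_hi, spec$ring_amplitude,
                                 spec$ring_width)
    if (spec$noise_sigma[1] > 0)
      hires$data <- hires$data +
        array(rnorm(length(hires$data), 0, spec$noise_sigma[1]),
              dim(hires$data))
    # low-res frame: centred on the high-res FOV
    tr <- true_transform_affine(spec)
    lo_extent <- (spec$lores_shape - 1) * spec$lores_spacing
    lo_origin <- ctr - lo_extent / 2
    lo_co <- coord_arrays(spec$lores_shape, spec$lores_spacing)
    lo_pts <- cbind(as.vector(lo_co[[1]]) + lo_origin[1],
                    as.vector(lo_co[[2]]) + lo_origin[2],
                    as.vector(lo_co[[3]]) + lo_origin[3])
    hi_pts <- transform_points(invert_affine(tr), lo_pts)
    tex_lo <- cpp_trilinear_sample(as.vector(tex_field), spec$hires_shape,
                                   sweep(hi_pts, 2, spec$hires_spacing, "/"),
                                   0)
    sc_lo <- brain_scene(spec,
                         array(hi_pts[, 1], spec$lores_shape),
                         array(hi_pts[, 2], spec$lores_shape),
                         array(hi_pts[, 3], spec$lores_shape),
                         array(tex_lo, spec$lores_shape))
    lo_img <- gauss_smooth3(sc_lo$img, 0.5)
    if (spec$noise_sigma[2] > 0)
      lo_img <- lo_img + array(rnorm(length(lo_img), 0, spec$noise_sigma[2]),
                               dim(lo_img))
    lores <- vol3d(lo_img, spec$lores_spacing, lo_origin)
    mask_lo <- bin_mask(sc_lo$fg, spec$lores_spacing, lo_origin,
                        "phantom truth foreground (low-res)")
    lm_hi <- rbind(ctr + c(-0.85 * spec$brain_semiaxes_um[1], 0, 0),
                   ctr + c(0.85 * spec$brain_semiaxes_um[1], 0, 0))
    truth <- list(mask_hires = mask_hi, mask_lores = mask_lo,
                  transform = tr, warp = NULL,
                  landmarks_hires = lm_hi,
                  landmarks_lores = transform_points(tr, lm_hi))
    structure(list(spec = spec, hires = hires, lores = lores, truth = truth),
              class = "phantom")
  })
}

# Rasterize a tube (plus interior butterfly) around a curve onto a grid.
rasterize_tube <- function(curve, shape, spacing, origin, radius, lv,
                           medium_radius_um) {
  cl <- resample_centerline(curve, mean(spacing))
  fr <- build_frames(cl)
  # tube must stay inside the grid laterally; axially (z) the cord may run
  # out of the stack, as in a real acquisition
  hi_edge <- origin + (shape - 1) * spacing
  marg <- pmin(t(cl$points) - origin, hi_edge - t(cl$points))
  bad <- which(pmin(marg[1, ], marg[2, ]) < radius)
  if (length(bad) > 0)
    stop(sprintf(paste0("invalid spec: tube exits the grid at arc length ",
                        "%.1f um"), cl$arclen[bad[1]]))
  pr <- cpp_project_to_curve(as.integer(shape), as.numeric(spacing),
                             as.numeric(origin), cl$points, fr$normal,
                             fr$binormal, cl$arclen, radius * 1.05)
  d3 <- as.integer(shape)
  inside <- array(is.finite(pr$dist) & pr$dist <= radius, d3)
  # cut the spherical caps beyond the end planes so the tube is finite
  co <- coord_arrays(d3, spacing)
  n <- nrow(cl$points)
  t0 <- cl$points[2, ] - cl$points[1, ]; t0 <- t0 / sqrt(sum(t0^2))
  tL <- cl$points[n, ] - cl$points[n - 1, ]; tL <- tL / sqrt(sum(tL^2))
  ax0 <- (co[[1]] + origin[1] - cl$points[1, 1]) * t0[1] +
         (co[[2]] + origin[2] - cl$points[1, 2]) * t0[2] +
         (co[[3]] + origin[3] - cl$points[1, 3]) * t0[3]
  axL <- (co[[1]] + origin[1] - cl$points[n, 1]) * tL[1] +
         (co[[2]] + origin[2] - cl$points[n, 2]) * tL[2] +
         (co[[3]] + origin[3] - cl$points[n, 3]) * tL[3]
  inside <- inside & ax0 >= 0 & axL <= 0
  # butterfly: two ellipses in the (u, v) plane mirrored about u = 0
  au <- 0.32 * radius; av <- 0.22 * radius; off <- 0.30 * radius
  bf <- array(FALSE, d3)
  ok <- is.finite(pr$u)
  q1 <- ((pr$u[ok] - off) / au)^2 + (pr$v[ok] / av)^2
  q2 <- ((pr$u[ok] + off) / au)^2 + (pr$v[ok] / av)^2
  bf[ok] <- q1 <= 1 | q2 <= 1
  bf <- bf & inside
  ctr_xy <- (d3[1:2] - 1) / 2 * spacing[1:2]
  incyl <- (co[[1]] - ctr_xy[1])^2 + (co[[2]] - ctr_xy[2])^2 <=
    medium_radius_um^2
  img <- array(lv[["background"]], d3)
  img[incyl] <- lv[["medium"]]
  img[inside] <- lv[["tissue"]]
  img[bf] <- lv[["butterfly"]]
  list(img = img, mask = inside, centerline = cl)
}

#' Render the paired spinal-cord phantom
#'
#' High-res modality: a tissue tube with an interior butterfly-shaped
#' sub-region (two mirrored ellipses in the rotation-minimizing frame
#' cross-section) around the given curve, inside a medium-filled
#' cylindrical cell, with a boundary ring artifact and noise. Low-res
#' modality: the same cord rendered around the curve mapped through the
#' true inter-modality transform (affine + optional smooth bend), so the
#' two acquisitions carry different curvatures, then smoothed and noised.
#' Landmarks sit on the centerline near the two cord extremities.
#'
#' @param spec A cord [phantom_spec()].
#' @param curve Optional [centerline()]; default built from the spec's
#'   control points via [make_cord_curve()].
#' @return List of class \code{phantom}: \code{hires}, \code{lores},
#'   \code{truth} (masks, centerlines in both frames, true affine, warp
#'   parameters, landmark pairs).
#' @export
render_cord_phantom <- function(spec, curve = NULL) {
  if (spec$kind != "cord") stop("spec is not a cord phantom spec")
  if (is.null(curve)) curve <- make_cord_curve(spec$control_points)
  r <- spec$tube_radius_um
  kmax <- max_discrete_curvature(resample_centerline(curve,
                                   total_length(curve) / 127))
  if (r >= 1 / kmax)
    stop("invalid spec: tube radius exceeds the minimal radius of curvature")
  with_seed(spec$seed, {
    lv <- spec$levels
    med_r <- 0.45 * min((spec$hires_shape[1:2] - 1) * spec$hires_spacing[1:2])
    hi <- rasterize_tube(curve, spec$hires_shape, spec$hires_spacing,
                         c(0, 0, 0), r, lv, med_r)
    hires <- vol3d(hi$img, spec$hires_spacing)
    mask_hi <- bin_mask(hi$mask, spec$hires_spacing,
                        provenance = "phantom truth cord mask")
    if (spec$ring_amplitude > 0)
      hires <- add_ring_artifact(hires, mask_hi, spec$ring_amplitude,
                                 spec$ring_width)
    if (spec$noise_sigma[1] > 0)
      hires$data <- hires$data +
        array(rnorm(length(hires$data), 0, spec$noise_sigma[1]),
              dim(hires$data))
    # low-res frame: cord curve mapped by the true transform
    tr <- true_transform_affine(spec)
    warp <- list(amplitude = spec$warp_amplitude_um,
                 z0 = min(curve$points[, 3]),
                 length = diff(range(curve$points[, 3])) + 1e-9)
    truth_fun <- function(p) {
      p <- transform_points(tr, p)
      p[, 1] <- p[, 1] + warp$amplitude * sin(pi * (p[, 3] - warp$z0) /
                                                warp$length)
      p
    }
    curve_lo <- centerline(truth_fun(curve$points))
    ctr_hi <- (spec$hires_shape - 1) / 2 * spec$hires_spacing
    lo_extent <- (spec$lores_shape - 1) * spec$lores_spacing
    lo_origin <- ctr_hi - lo_extent / 2
    med_r_lo <- 0.48 * min((spec$lores_shape[1:2] - 1) *
                             spec$lores_spacing[1:2])
    lo <- rasterize_tube(curve_lo, spec$lores_shape, spec$lores_spacing,
                         lo_origin, r * spec$scale, lv, med_r_lo)
    lo_img <- gauss_smooth3(lo$img, 0.6)
    if (spec$noise_sigma[2] > 0)
      lo_img <- lo_img + array(rnorm(length(lo_img), 0, spec$noise_sigma[2]),
                               dim(lo_img))
    lores <- vol3d(lo_img, spec$lores_spacing, lo_origin)
    mask_lo <- bin_mask(lo$mask, spec$lores_spacing, lo_origin,
                        "phantom truth cord mask (low-res)")
    L <- total_length(hi$centerline)
    s_lm <- c(r, L - r)
    lm_hi <- t(vapply(s_lm, function(s_)
      vapply(1:3, function(c_)
        stats::approx(hi$centerline$arclen, hi$centerline$points[, c_],
                      xout = s_)$y, numeric(1)), numeric(3)))
    truth <- list(mask_hires = mask_hi, mask_lores = mask_lo,
                  centerline_hires = hi$centerline,
                  centerline_lores = lo$centerline,
                  transform = tr, warp = warp,
                  landmarks_hires = lm_hi,
                  landmarks_lores = truth_fun(lm_hi))
    structure(list(spec = spec, hires = hires, lores = lores, truth = truth),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind=%s seed=%d\n", x$spec$kind, x$spec$seed))
  cat("  hires: "); print(x$hires)
  cat("  lores: "); print(x$lores)
  invisible(x)
}

#' Add a boundary ring artifact
#'
#' Perturbs the voxels within \code{width} of the mask boundary (the
#' morphological band between the mask dilated and eroded by \code{width})
#' with alternating bright/dark rings, as phase-contrast reconstructions
#' show at interfaces between materials of different density: the layer
#' adjacent to the boundary is brightened on the tissue side and darkened
#' on the medium side, with signs alternating in deeper layers. The
#' magnitude is \code{amplitude} times the mean in-mask intensity.
#' Interior voxels are untouched; amplitude 0 is the identity.
#'
#' @param volume A [vol3d()].
#' @param mask A [bin_mask()] on the same grid (the sample support).
#' @param amplitude Fraction of the mean in-mask intensity (>= 0).
#' @param width Band half-width in voxels (>= 1).
#' @return A [vol3d()].
#' @export
add_ring_artifact <- function(volume, mask, amplitude, width) {
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  width <- check_radius(width)
  if (width < 1L) stop("`width` must be >= 1")
  if (amplitude == 0) return(volume)
  stopifnot_same_grid(volume, mask)
  ref <- mean(volume$data[mask$data])
  d <- dim(volume$data)
  out <- volume$data
  dil <- lapply(0:width, function(r)
    array(cpp_ball_morph(as.logical(mask$data), d, r, TRUE), d))
  ero <- lapply(0:width, function(r)
    array(cpp_ball_morph(as.logical(mask$data), d, r, FALSE), d))
  for (layer in seq_len(width)) {
    ring_in <- ero[[layer]] & !ero[[layer + 1]]        # depth `layer` inside
    ring_out <- dil[[layer + 1]] & !dil[[layer]]       # distance `layer` out
    out[ring_in] <- out[ring_in] + (-1)^(layer + 1) * amplitude * ref
    out[ring_out] <- out[ring_out] + (-1)^layer * amplitude * ref
  }
  vol_like(volume, out)
}
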