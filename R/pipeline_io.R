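#' Read a 3D volume from NIfTI-1 or multi-page TIFF
#'
#' NIfTI: voxel spacing comes from the header pixdim (stored in mm,
#' reported here in micrometres) and the world origin from the sform
#' offset; both can be overridden. TIFF stacks carry no spacing, so
#' \code{spacing_override} is required.
#'
#' @param path File path (\code{.nii}, \code{.nii.gz}, \code{.tif},
#'   \code{.tiff}).
#' @param spacing_override Optional spacing in micrometres (scalar or
#'   length 3).
#' @param origin_override Optional world origin (um).
#' @return A [vol3d()].
#' @export
read_volume <- function(path, spacing_override = NULL,
                        origin_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop("TIFF stack must contain >= 2 pages (3D)")
    if (is.null(spacing_override))
      stop("TIFF input requires a spacing override (no spacing in header)")
    first <- pages[[1]]
    if (length(dim(first)) > 2L) first <- first[, , 1]  # drop channels
    arr <- array(0, c(ncol(first), nrow(first), length(pages)))
    for (k in seq_along(pages)) {
      pg <- pages[[k]]
      if (length(dim(pg)) > 2L) pg <- pg[, , 1]
      arr[, , k] <- t(pg)  # row-major page -> (x, y)
    }
    sp <- spacing_override
    if (length(sp) == 1L) sp <- rep(sp, 3L)
    return(vol3d(arr, sp,
                 if (is.null(origin_override)) c(0, 0, 0) else origin_override))
  }
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop("expected a 3D volume, got ", length(dim(im)), "D")
  sp_mm <- RNifti::pixdim(im)
  sp <- if (is.null(spacing_override)) sp_mm * 1000 else spacing_override
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  orig <- if (is.null(origin_override)) {
    x <- try(RNifti::xform(im), silent = TRUE)
    if (inherits(x, "try-error")) c(0, 0, 0) else as.numeric(x[1:3, 4]) * 1000
  } else origin_override
  vol3d(array(as.numeric(im), dim(im)), sp, orig)
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing is written to pixdim and the origin to the sform, both
#' converted to millimetres per NIfTI convention.
#'
#' @param vol A [vol3d()] or [bin_mask()].
#' @param path Output path (\code{.nii} / \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  data <- if (is_bin_mask(vol)) array(as.numeric(vol$data), dim(vol$data))
          else vol$data
  im <- RNifti::asNifti(data)
  RNifti::pixdim(im) <- vol$spacing / 1000
  m <- diag(c(vol$spacing / 1000, 1))
  m[1:3, 4] <- vol$origin / 1000
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  writeNifti_safe(im, path)
  invisible(path)
}

writeNifti_safe <- function(im, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(im, path)
}

#' Centerline CSV I/O
#'
#' Columns \code{x_um, y_um, z_um, arclen_um}.
#'
#' @param cl A [centerline()].
#' @param path CSV path.
#' @export
write_centerline_csv <- function(cl, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(x_um = cl$points[, 1], y_um = cl$points[, 2],
                       z_um = cl$points[, 3], arclen_um = cl$arclen),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path)
  centerline(as.matrix(df[, c("x_um", "y_um", "z_um")]))
}

#' Landmark CSV I/O (columns x_um, y_um, z_um; one row per landmark)
#' @param pts N x 3 matrix (um).
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(pts, path) {
  pts <- as_pts_matrix(pts)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path)
  as.matrix(df[, c("x_um", "y_um", "z_um")])
}

#' Export a rendered phantom with its ground truth
#'
#' Writes both modality volumes and truth masks as NIfTI, the true affine
#' as a 4 x 4 row-major text matrix, landmarks and (for cords) centerlines
#' as CSV.
#'
#' @param phantom A rendered phantom (from [render_brain_phantom()] or
#'   [render_cord_phantom()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$hires, file.path(dir, "hires.nii.gz"))
  write_volume(phantom$lores, file.path(dir, "lores.nii.gz"))
  write_volume(phantom$truth$mask_hires, file.path(dir, "mask_hires.nii.gz"))
  write_volume(phantom$truth$mask_lores, file.path(dir, "mask_lores.nii.gz"))
  save_affine(phantom$truth$transform, file.path(dir, "true_affine.txt"))
  write_landmarks_csv(phantom$truth$landmarks_hires,
                      file.path(dir, "landmarks_hires.csv"))
  write_landmarks_csv(phantom$truth$landmarks_lores,
                      file.path(dir, "landmarks_lores.csv"))
  if (!is.null(phantom$truth$centerline_hires)) {
    write_centerline_csv(phantom$truth$centerline_hires,
                         file.path(dir, "centerline_hires.csv"))
    write_centerline_csv(phantom$truth$centerline_lores,
                         file.path(dir, "centerline_lores.csv"))
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by
#' [run_brain_pipeline()] / [run_cord_pipeline()]. Volumes may be given as
#' file paths or as in-memory [vol3d()] objects; referenced paths must
#' exist at construction time.
#'
#' @param branch \code{"brain"} or \code{"cord"}.
#' @param hires,lores Paths or [vol3d()] objects (high-res fixed modality,
#'   low-res moving modality).
#' @param hires_spacing,lores_spacing Optional spacing overrides (um).
#' @param band Masking band for the high-res volume: \code{"auto"} or
#'   \code{c(low, high)} (brain branch).
#' @param mask_radius Morphology ball radius (voxels).
#' @param landmarks_hires,landmarks_lores Cord branch: 2 x 3 matrices or
#'   CSV paths with the two consensus reference coordinates per modality.
#' @param centerline_method \code{"com"} (slice centres of mass) or
#'   \code{"grow"} (seeded region growing).
#' @param region_grow_seed Optional voxel index for the grow route;
#'   derived from the centre-of-mass centerline when omitted.
#' @param downsample_factor Cord branch: integer factor or \code{"auto"}
#'   (gradient-maximizing selection).
#' @param candidate_factors Candidates for the auto selection.
#' @param straighten_radius Straightened tube radius (um) or \code{"auto"}
#'   (1.3 x the cord's estimated mean radius).
#' @param levels,iters_per_level Registration pyramid settings.
#' @param diffeo Run the diffeomorphic refinement after the affine stage.
#' @param seed Integer seed controlling all stochastic steps.
#' @param out_dir Optional output directory; when given, volumes,
#'   transforms and the JSON report are written there.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(branch = c("brain", "cord"), hires, lores,
                            hires_spacing = NULL, lores_spacing = NULL,
                            band = "auto", mask_radius = 2L,
                            landmarks_hires = NULL, landmarks_lores = NULL,
                            centerline_method = c("com", "grow"),
                            region_grow_seed = NULL,
                            downsample_factor = "auto",
                            candidate_factors = c(2L, 4L, 8L),
                            straighten_radius = "auto",
                            levels = 3L, iters_per_level = 60L,
                            diffeo = FALSE, seed = 1L, out_dir = NULL) {
  branch <- match.arg(branch)
  centerline_method <- match.arg(centerline_method)
  for (p in list(hires, lores, landmarks_hires, landmarks_lores))
    if (is.character(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  if (branch == "cord" &&
      (is.null(landmarks_hires) || is.null(landmarks_lores)))
    stop("cord branch requires landmark coordinates for both modalities")
  structure(list(branch = branch, hires = hires, lores = lores,
                 hires_spacing = hires_spacing,
                 lores_spacing = lores_spacing, band = band,
                 mask_radius = as.integer(mask_radius),
                 landmarks_hires = landmarks_hires,
                 landmarks_lores = landmarks_lores,
                 centerline_method = centerline_method,
                 region_grow_seed = region_grow_seed,
                 downsample_factor = downsample_factor,
                 candidate_factors = as.integer(candidate_factors),
                 straighten_radius = straighten_radius,
                 levels = as.integer(levels),
                 iters_per_level = as.integer(iters_per_level),
                 diffeo = isTRUE(diffeo), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

config_volume <- function(x, spacing_override) {
  if (is_vol3d(x)) return(x)
  read_volume(x, spacing_override)
}

config_landmarks <- function(x) {
  if (is.character(x)) read_landmarks_csv(x) else as_pts_matrix(x)
}

# Run a pipeline stage, rethrowing errors tagged with the stage name.
run_stage <- function(log, name, expr) {
  log$stages <- c(log$stages, name)
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Brain co-registration pipeline
#'
#' Anti-alias down-samples the high-res volume to the low-res spacing,
#' builds foreground masks for both modalities with the
#' threshold-and-morphology recipe, runs masked Mattes-MI affine
#' registration (high-res down-sampled volume fixed, low-res moving), and
#' optionally the diffeomorphic refinement. Outputs resampled overlays,
#' transforms and a JSON report with pre/post mask Dice and the metric
#' trace.
#'
#' @param config A [pipeline_config()] (or YAML path) with
#'   \code{branch = "brain"}.
#' @return The run report (list), invisibly containing the result objects
#'   in \code{$objects}.
#' @export
run_brain_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (config$branch != "brain") stop("config is not a brain-branch config")
  set.seed(config$seed)
  log <- new.env(); log$stages <- character(0)
  hires <- run_stage(log, "read_hires",
                     config_volume(config$hires, config$hires_spacing))
  lores <- run_stage(log, "read_lores",
                     config_volume(config$lores, config$lores_spacing))
  hires_ds <- run_stage(log, "antialias_downsample",
                        antialias_downsample(hires, lores$spacing))
  mask_hi <- run_stage(log, "mask_hires",
                       brain_mask_pipeline(hires_ds, config$band,
                                           config$mask_radius))
  mask_lo <- run_stage(log, "mask_lores",
                       brain_mask_pipeline(lores, "auto",
                                           config$mask_radius))
  dice_pre <- dice(mask_hi,
                   resample_mask_binary(mask_lo, affine3d(),
                                        grid_of(hires_ds)))
  reg <- run_stage(log, "register_affine",
                   register_affine(hires_ds, lores, affine3d(),
                                   levels = config$levels,
                                   iters_per_level = config$iters_per_level,
                                   fixed_mask = mask_hi))
  final_tr <- reg$transform
  diffeo_res <- NULL
  if (config$diffeo) {
    diffeo_res <- run_stage(log, "register_diffeomorphic",
                            register_diffeomorphic(hires_ds, lores,
                                                   reg$transform,
                                                   fixed_mask = mask_hi))
    if (diffeo_res$accepted) final_tr <- diffeo_res$transform
  }
  mask_lo_on_hi <- resample_mask_binary(mask_lo, final_tr, grid_of(hires_ds))
  overlay <- apply_transform(lores, final_tr, grid_of(hires_ds))
  report <- list(
    branch = "brain", seed = config$seed,
    stages = log$stages,
    downsampled_spacing_um = hires_ds$spacing,
    dice_masks_pre = dice_pre,
    dice_masks_post = dice(mask_hi, mask_lo_on_hi),
    affine_metric = reg$metric,
    affine_converged = reg$converged,
    metric_trace = reg$trace,
    diffeo_min_jacobian = if (!is.null(diffeo_res)) diffeo_res$min_jacobian
                          else NULL,
    software_version = as.character(packageVersion("cnscoreg")))
  objects <- list(hires_ds = hires_ds, mask_hires = mask_hi,
                  mask_lores = mask_lo, affine = reg,
                  diffeo = diffeo_res, transform = final_tr,
                  overlay = overlay)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(hires_ds, file.path(config$out_dir, "hires_downsampled.nii.gz"))
    write_volume(mask_hi, file.path(config$out_dir, "mask_hires.nii.gz"))
    write_volume(mask_lo, file.path(config$out_dir, "mask_lores.nii.gz"))
    write_volume(overlay, file.path(config$out_dir, "lores_registered.nii.gz"))
    save_affine(reg$transform, file.path(config$out_dir, "affine.txt"))
    write_report(report, config$out_dir, config)
  }
  report$objects <- objects
  invisible(report)
}

resample_mask_binary <- function(mask, transform, target_grid) {
  v <- apply_transform(mask, transform, target_grid,
                       interpolation = "nearest")
  bin_mask(array(v$data > 0.5, target_grid$dims), target_grid$spacing,
           target_grid$origin, "resampled mask")
}

#' Spinal-cord co-registration pipeline
#'
#' Saturates the high-res intensities (0.3% both tails), nearest-neighbour
#' down-samples it (factor fixed or chosen to maximize the interface
#' gradient), detects cord contours by 3D hysteresis edge detection,
#' extracts the centerline (slice centres of mass, or a region-grown mask
#' whose slice centroids give the centerline), straightens both modality
#' volumes along their own centerlines, initializes from the straightened
#' landmark pair, registers in the straightened frame, and carries the
#' low-res parametric map into the straightened reference frame.
#'
#' @param config A [pipeline_config()] (or YAML path) with
#'   \code{branch = "cord"}; landmarks are required.
#' @return The run report, invisibly carrying \code{$objects}.
#' @export
run_cord_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (config$branch != "cord") stop("config is not a cord-branch config")
  set.seed(config$seed)
  log <- new.env(); log$stages <- character(0)
  hires <- run_stage(log, "read_hires",
                     config_volume(config$hires, config$hires_spacing))
  lores <- run_stage(log, "read_lores",
                     config_volume(config$lores, config$lores_spacing))
  lm_hi <- config_landmarks(config$landmarks_hires)
  lm_lo <- config_landmarks(config$landmarks_lores)
  sat <- run_stage(log, "saturate_intensity", saturate_intensity(hires))
  factor <- config$downsample_factor
  if (identical(factor, "auto"))
    factor <- run_stage(log, "select_downsample_scale", {
      th <- threshold_otsu(sat)
      rough <- mask_like(sat, sat$data > th, "rough cord")
      band <- bin_mask(dilate_ball(rough, 2L)$data & !erode_ball(rough, 2L)$data,
                       sat$spacing, sat$origin, "interface band")
      nz <- dim(sat$data)[3]
      # the point of this step is to roughly match the low-res modality:
      # never down-sample beyond the inter-modality spacing ratio
      ratio <- max(1, floor(min(lores$spacing / sat$spacing)))
      cand <- config$candidate_factors[config$candidate_factors <= ratio]
      if (length(cand) < 2L) cand <- unique(c(1L, cand, ratio))
      as.integer(select_downsample_scale(sat, cand, band,
                                         round(nz * c(0.25, 0.5, 0.75))))
    })
  hires_ds <- run_stage(log, "nn_downsample",
                        nn_downsample(sat, as.integer(factor)))
  edge_sigma <- 1.5 * mean(hires_ds$spacing)
  edges <- run_stage(log, "detect_edges_3d",
                     cord_contours(hires_ds,
                                   detect_edges_3d(hires_ds, edge_sigma)))
  cl_com <- run_stage(log, "centerline_com", centerline_from_slices(edges))
  seed_vox <- config$region_grow_seed
  if (is.null(seed_vox))
    seed_vox <- run_stage(log, "derive_grow_seed",
                          derive_grow_seed(hires_ds, edges, cl_com))
  # fill enclosed sub-structures slice-wise, then grow the mask back to the
  # tissue interface: region growing stops at the inner side of the
  # hysteresis band, so dilate until half of the outer edge band is
  # covered -- at that point the boundary sits at the band centre, which
  # is the interface
  cord_mask <- run_stage(log, "region_grow_mask", {
    grown <- fill_holes_2d(region_grow_mask(edges, seed_vox))
    outer_band <- edges$data & !grown$data
    out <- grown
    for (d in 1:4) {
      cand <- dilate_ball(grown, d)
      out <- cand
      if (!any(outer_band) || mean(cand$data[outer_band]) >= 0.5) break
    }
    out
  })
  cord_mask <- mask_like(hires_ds, largest_component(cord_mask$data),
                         "cord mask (region grow)")
  cl <- if (config$centerline_method == "com") cl_com
        else run_stage(log, "centerline_grow",
                       centerline_from_slices(cord_mask))
  step <- hires_ds$spacing[3]
  cl_u <- run_stage(log, "resample_centerline",
                    smooth_centerline(resample_centerline(cl, step), 9L))
  radius <- config$straighten_radius
  if (identical(radius, "auto")) {
    area <- sum(cord_mask$data) * prod(hires_ds$spacing[1:2]) /
      max(1L, length(unique(which(cord_mask$data, arr.ind = TRUE)[, 3])))
    radius <- 1.3 * sqrt(area / pi)
  }
  tr_hi <- run_stage(log, "straightening_transform",
                     straightening_transform(cl_u, radius,
                                             mean(hires_ds$spacing[1:2])))
  straight_hi <- run_stage(log, "straighten_hires",
                           straighten_volume(hires_ds, tr_hi,
                                             fill = min(hires_ds$data)))
  mask_straight_hi <- run_stage(log, "straighten_mask",
    binarize(apply_transform_to_map(cord_mask, tr_hi,
                                    interpolation = "nearest")))
  # low-res branch: its own (smoother) cord segmentation and straightening
  lo_mask <- run_stage(log, "mask_lores", {
    th <- auto_band(lores)[2]  # tissue/medium split of the two-stage band
    mask_like(lores, largest_component(lores$data > th), "cord mask (otsu)")
  })
  cl_lo <- run_stage(log, "centerline_lores", centerline_from_slices(lo_mask))
  cl_lo_u <- smooth_centerline(resample_centerline(cl_lo, lores$spacing[3]), 7L)
  tr_lo <- run_stage(log, "straightening_transform_lores",
                     straightening_transform(cl_lo_u, radius * 1.1,
                                             mean(hires_ds$spacing[1:2])))
  straight_lo <- run_stage(log, "straighten_lores",
                           straighten_volume(lores, tr_lo,
                                             fill = min(lores$data)))
  mask_straight_lo <- binarize(apply_transform_to_map(lo_mask, tr_lo,
                                                      interpolation = "nearest"))
  # landmark initialization in the straightened frames
  init <- run_stage(log, "landmark_init",
                    landmark_init(straighten_points(tr_hi, lm_hi),
                                  straighten_points(tr_lo, lm_lo)))
  reg <- run_stage(log, "register_affine",
                   register_affine(straight_hi, straight_lo, init,
                                   levels = config$levels,
                                   iters_per_level = config$iters_per_level,
                                   fixed_mask = mask_straight_hi))
  final_tr <- reg$transform
  diffeo_res <- NULL
  if (config$diffeo) {
    diffeo_res <- run_stage(log, "register_diffeomorphic",
                            register_diffeomorphic(straight_hi, straight_lo,
                                                   reg$transform,
                                                   fixed_mask = mask_straight_hi))
    if (diffeo_res$accepted) final_tr <- diffeo_res$transform
  }
  fa_straight <- run_stage(log, "apply_transform_to_map",
                           apply_transform(lores, list(final_tr, invert_tr(tr_lo)),
                                           grid_of(straight_hi)))
  mask_lo_on_hi <- resample_mask_binary(mask_straight_lo, final_tr,
                                        grid_of(straight_hi))
  # straightness check: recompute the centerline on the straightened output
  straightness <- run_stage(log, "straightness_check", {
    e2 <- cord_contours(straight_hi,
                        detect_edges_3d(straight_hi,
                                        1.5 * mean(straight_hi$spacing)))
    c2 <- centerline_from_slices(e2, smooth_window = 1L)
    max(sqrt(rowSums(c2$points[, 1:2]^2)))  # deviation from u = v = 0 (um)
  })
  report <- list(
    branch = "cord", seed = config$seed, stages = log$stages,
    downsample_factor = as.integer(factor),
    straighten_radius_um = radius,
    centerline_method = config$centerline_method,
    n_centerline_samples = nrow(cl_u$points),
    cord_length_um = total_length(cl_u),
    dice_cord_masks_post = dice(mask_straight_hi, mask_lo_on_hi),
    straightness_max_lateral_um = straightness,
    affine_metric = reg$metric, affine_converged = reg$converged,
    metric_trace = reg$trace,
    diffeo_min_jacobian = if (!is.null(diffeo_res)) diffeo_res$min_jacobian
                          else NULL,
    software_version = as.character(packageVersion("cnscoreg")))
  objects <- list(hires_ds = hires_ds, edges = edges, cord_mask = cord_mask,
                  centerline = cl_u, transform_hi = tr_hi,
                  transform_lo = tr_lo, straight_hires = straight_hi,
                  straight_lores = straight_lo,
                  mask_straight_hi = mask_straight_hi,
                  affine = reg, diffeo = diffeo_res, transform = final_tr,
                  fa_straight = fa_straight)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(straight_hi, file.path(config$out_dir, "straight_hires.nii.gz"))
    write_volume(fa_straight, file.path(config$out_dir, "fa_straightened.nii.gz"))
    write_volume(cord_mask, file.path(config$out_dir, "cord_mask.nii.gz"))
    write_centerline_csv(cl_u, file.path(config$out_dir, "centerline.csv"))
    save_affine(reg$transform, file.path(config$out_dir, "affine.txt"))
    write_report(report, config$out_dir, config)
  }
  report$objects <- objects
  invisible(report)
}

# Seed for region growing: mid-centerline sample, offset laterally so the
# seed falls in the homogeneous outer tissue compartment rather than in an
# interior sub-structure (e.g. the gray-matter butterfly, whose own edge
# shell would confine the growth). Among in-plane candidate offsets the
# brightest non-edge voxel wins (white matter is the bright compartment).
derive_grow_seed <- function(volume, edges, cl) {
  mid <- cl$points[round(nrow(cl$points) / 2), ]
  midvox <- round(world_to_voxel(volume, mid)[1, ])
  z <- min(max(midvox[3], 1L), dim(volume$data)[3])
  sl <- which(edges$data[, , z], arr.ind = TRUE)
  r_out <- if (nrow(sl) > 0)
    max(sqrt((sl[, 1] - midvox[1])^2 + (sl[, 2] - midvox[2])^2)) else 5
  cand <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(-1, -1), c(1, -1), c(-1, 1), c(0, 0))
  best <- NULL; best_val <- -Inf
  for (q in seq_len(nrow(cand))) {
    for (fr in c(0.55, 0.4, 0.7)) {
      v <- midvox + c(round(fr * r_out * cand[q, ]), 0)
      if (any(v < 1L) || any(v > dim(volume$data))) next
      if (edges$data[v[1], v[2], v[3]]) next
      val <- volume$data[v[1], v[2], v[3]]
      if (val > best_val) { best_val <- val; best <- v }
    }
  }
  if (is.null(best))
    best <- nearest_open_voxel(edges, midvox)
  as.integer(best)
}

# Nearest non-edge voxel to a target index (deterministic outward scan).
nearest_open_voxel <- function(edges, vox) {
  d <- dim(edges$data)
  vox <- pmin(pmax(as.integer(vox), 1L), d)
  if (!edges$data[vox[1], vox[2], vox[3]]) return(vox)
  for (r in 1:10) {
    off <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
    off <- off[order(rowSums(off^2)), , drop = FALSE]
    for (q in seq_len(nrow(off))) {
      cand <- vox + as.integer(off[q, ])
      if (any(cand < 1L) || any(cand > d)) next
      if (!edges$data[cand[1], cand[2], cand[3]]) return(cand)
    }
  }
  stop("no non-edge voxel found near the requested seed")
}

binarize <- function(vol) {
  bin_mask(array(vol$data > 0.5, dim(vol$data)), vol$spacing, vol$origin,
           "binarized map")
}

# world coordinates in the straightened frame of curved-frame points
straighten_points <- function(tr, pts) {
  pts <- as_pts_matrix(pts)
  cl <- tr$centerline
  fr <- tr$frames
  out <- matrix(0, nrow(pts), 3)
  for (q in seq_len(nrow(pts))) {
    d2 <- colSums((t(cl$points) - pts[q, ])^2)
    i <- which.min(d2)
    best <- list(d2 = d2[i], s = cl$arclen[i], a = i, b = i, t = 0)
    for (seg in c(-1, 0)) {
      a <- i + seg; b <- a + 1L
      if (a < 1L || b > nrow(cl$points)) next
      e <- cl$points[b, ] - cl$points[a, ]
      tt <- sum((pts[q, ] - cl$points[a, ]) * e) / sum(e^2)
      tt <- min(max(tt, 0), 1)
      proj <- cl$points[a, ] + tt * e
      dd <- sum((pts[q, ] - proj)^2)
      if (dd < best$d2) best <- list(d2 = dd,
                                     s = cl$arclen[a] +
                                       tt * (cl$arclen[b] - cl$arclen[a]),
                                     a = a, b = b, t = tt)
    }
    nrm <- (1 - best$t) * fr$normal[best$a, ] + best$t * fr$normal[best$b, ]
    bin <- (1 - best$t) * fr$binormal[best$a, ] + best$t * fr$binormal[best$b, ]
    nrm <- nrm / sqrt(sum(nrm^2)); bin <- bin / sqrt(sum(bin^2))
    cpt <- stats::approx(cl$arclen, cl$points[, 1], xout = best$s)$y
    cpt <- c(cpt, stats::approx(cl$arclen, cl$points[, 2], xout = best$s)$y,
             stats::approx(cl$arclen, cl$points[, 3], xout = best$s)$y)
    rel <- pts[q, ] - cpt
    out[q, ] <- c(sum(rel * nrm), sum(rel * bin), best$s)
  }
  out
}

# A straightening transform wrapped as a point-mapping for apply_transform:
# maps straightened-frame world points back into the curved frame.
invert_tr <- function(tr) {
  structure(list(tr = tr), class = "straight_to_curved")
}

#' @export
transform_points.straight_to_curved <- function(transform, pts) {
  tr <- transform$tr
  pts <- as_pts_matrix(pts)
  cl <- tr$centerline; fr <- tr$frames
  ci <- vapply(1:3, function(c_)
    stats::approx(cl$arclen, cl$points[, c_], xout = pmin(pmax(pts[, 3], 0),
                                                          total_length(cl)))$y,
    numeric(nrow(pts)))
  if (is.null(dim(ci))) ci <- matrix(ci, ncol = 3)
  ni <- interp_unit(cl$arclen, fr$normal,
                    pmin(pmax(pts[, 3], 0), total_length(cl)))
  bi <- interp_unit(cl$arclen, fr$binormal,
                    pmin(pmax(pts[, 3], 0), total_length(cl)))
  ci + pts[, 1] * ni + pts[, 2] * bi
}

#' Write a pipeline run report
#'
#' JSON report plus a plain-text log and provenance (configuration echo,
#' seed, package version). Field order is deterministic; the timestamp is
#' the only field that differs between identical runs.
#'
#' @param report Report list from a pipeline run.
#' @param dir Output directory.
#' @param config Optional configuration to echo.
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(report, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create report directory: ", dir)
  report$objects <- NULL
  out <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              report = report[order(names(report))])
  if (!is.null(config)) {
    cfg <- config
    cfg$hires <- if (is.character(cfg$hires)) cfg$hires else "<in-memory>"
    cfg$lores <- if (is.character(cfg$lores)) cfg$lores else "<in-memory>"
    cfg$landmarks_hires <- NULL; cfg$landmarks_lores <- NULL
    out$config <- cfg[order(names(cfg))]
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(c(sprintf("stages: %s", paste(report$stages, collapse = " -> ")),
               sprintf("seed: %d", report$seed)),
             file.path(dir, "run.log"))
  invisible(path)
}
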