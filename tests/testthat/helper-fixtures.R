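# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight phantoms are cached per test run.

# Small cord phantom for unit-level geometry tests (coarser and shorter
# than the default study phantom, same structure).
small_cord_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    kind = "cord", seed = seed,
    hires_shape = c(48L, 48L, 96L), hires_spacing = c(20, 20, 20),
    lores_shape = c(24L, 24L, 46L), lores_spacing = c(40, 40, 40),
    control_points = cbind(480 + 90 * sin(pi * seq(0, 1, length.out = 5)),
                           480, seq(-200, 2100, length.out = 5)),
    tube_radius_um = 180), list(...))
  do.call(phantom_spec, args)
}

small_brain_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    kind = "brain", seed = seed,
    hires_shape = c(72L, 72L, 72L), hires_spacing = c(25, 25, 25),
    lores_shape = c(18L, 18L, 18L), lores_spacing = c(100, 100, 100),
    brain_semiaxes_um = c(780, 720, 660),
    translation_um = c(150, 80, 40)), list(...))
  do.call(phantom_spec, args)
}

.fixture_env <- new.env()
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

rand_vol <- function(dims, seed, levels = NULL) {
  set.seed(seed)
  v <- if (is.null(levels)) array(rnorm(prod(dims)), dims)
       else array(sample(levels, prod(dims), replace = TRUE), dims)
  vol3d(v, 1)
}

# ---- independent oracles ----

# Otsu oracle: exhaustive search over all integer cut points, between-class
# variance computed directly from the data (no histogram).
otsu_oracle_best <- function(v) {
  v <- as.vector(v)
  cuts <- sort(unique(v))
  cuts <- cuts[-length(cuts)]
  obj <- vapply(cuts, function(t) between_class_variance(v, t), numeric(1))
  list(cut = cuts[which.max(obj)], objective = max(obj))
}

between_class_variance <- function(v, thr) {
  a <- v[v <= thr]; b <- v[v > thr]
  if (length(a) == 0L || length(b) == 0L) return(-Inf)
  w0 <- length(a) / length(v)
  w0 * (1 - w0) * (mean(a) - mean(b))^2
}

# Brute-force 6-connected flood fill by iterated frontier dilation with
# axis shifts (no shared code with the C++ BFS).
flood_oracle <- function(open, seed_vox) {
  d <- dim(open)
  cur <- array(FALSE, d)
  cur[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
  repeat {
    nxt <- cur
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      idx <- pmin(pmax(seq_len(d[ax]) + s, 1L), d[ax])
      shifted <- switch(ax, cur[idx, , , drop = FALSE],
                        cur[, idx, , drop = FALSE],
                        cur[, , idx, drop = FALSE])
      nxt <- nxt | shifted
    }
    nxt <- nxt & open
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# RMS of distances from each point to its nearest sample of a reference
# polyline.
rms_to_curve <- function(pts, ref) {
  d <- vapply(seq_len(nrow(pts)), function(i)
    sqrt(min(colSums((t(ref$points) - pts[i, ])^2))), numeric(1))
  sqrt(mean(d^2))
}

expect_binary_equal <- function(a, b) {
  expect_identical(as.vector(a), as.vector(b))
}
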