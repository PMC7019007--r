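---
title: "Methods: multimodal co-registration of CNS volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal co-registration of CNS volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diffusion-MRI derived maps (for example fractional anisotropy, FA) of an
ex vivo mouse brain or spinal cord come at ~125 um isotropic resolution;
synchrotron X-ray phase-contrast tomograms (SXRPCT) of the same sample
resolve a few micrometres. Validating the MRI contrast against the
microstructural reference requires placing both acquisitions in one
reference frame. Two obstacles dominate:

* the sample is imaged in different holders, so the global pose — and for
  the floppy spinal cord, the *curvature* — differs between acquisitions;
* the tomogram carries ring artifacts at interfaces between materials of
  different density, and the two modalities have unrelated intensity
  scales, so similarity must be measured with mutual information rather
  than intensity difference.

`cnscoreg` implements two branches. The **brain branch** assumes the
curvature difference is negligible: resolution matching, foreground
masking by thresholding and mathematical morphology, then Mattes mutual
information (MI) affine registration with an optional diffeomorphic
refinement. The **cord branch** additionally extracts each acquisition's
cord centerline, straightens both volumes along their own centerlines
with rotation-minimizing frames, and registers in the straightened frame
— which removes the curvature difference entirely and puts any cord into
a canonical straight frame.

# Pipeline components and their parameters

## Foreground masking (`brain_mask_pipeline`)

The high-res tomogram has no off-the-shelf masking tool, so the mask is
built from first principles:

1. `bimodal_foreground(volume, band)` marks voxels *outside* a medium
   intensity band. The embedding agar occupies the middle of the
   histogram; tissue is brighter and ring artifacts swing both bright and
   dark, so both polarities land in the initial mask — using the artifact
   rather than fighting it.
2. `dilate_ball(radius = 2)` closes small gaps in the boundary shell.
3. `fill_holes_2d` fills per-slice: a background pocket not reachable
   from the slice border becomes foreground. Per-slice (rather than 3D)
   filling also closes tunnels that run axially through the stack.
4. `erode_until_single_component(radius = 2)` dissolves debris outside
   the object; the iteration count `n` is recorded.
5. Re-dilation by `radius * (1 + n)`, intersected with the hole-filled
   pre-erosion mask so the restored margin cannot overshoot or re-admit
   debris, followed by a final per-slice fill.

With `band = "auto"` the band comes from two-stage Otsu thresholding:
a global Otsu split, then one Otsu per side. Each side split is meant to
separate a *minority* class (dark artifacts below; bright tissue above)
from the dominant medium. When a side has no minority class the side
split lands inside the medium mass; this is detected (most of the volume
would fall outside the band on that side) and the band edge is pushed
past the data range instead. The 25% (low side) and 50% (high side)
detection fractions are far from both legitimate regimes observed on the
phantoms (<2% vs >55%), so their exact values are uncritical.

Structuring elements are discrete Euclidean balls; connectivity is 26
for components and 4-in-slice for hole filling. Erosion treats
out-of-grid voxels as background (so masks erode at the stack faces);
an explicit `border = "foreground"` option supports closing regions that
legitimately touch the grid boundary (used after region growing).

## Resolution matching

`antialias_downsample` low-pass filters with a Gaussian of sigma =
`factor / 2` voxels per axis — placing the cutoff near the new Nyquist
limit — then resamples trilinearly. `nn_downsample` takes every
`factor`-th voxel, exactly matching the voxel-centre convention: the
world coordinate of voxel `(i, j, k)` is `origin + (i-1, j-1, k-1) *
spacing`, and every resampling operation preserves the world position of
the first voxel centre so transforms compose across grids.
`saturate_intensity` clips the extreme 0.3% tails (nearest-rank
quantiles) before processing the tomogram.

`select_downsample_scale` scores candidate factors by the mean
central-difference gradient magnitude (voxel units) over an interface
band on selected xy slices. On a noise-free sharp interface this score
grows monotonically with the factor — the step height is fixed while the
denominator shrinks — so the coarsest candidate always wins; this
behaviour is frozen in a characterization test. The pipeline therefore
caps the candidates at the inter-modality spacing ratio: the purpose of
the step is to roughly match the low-res modality, not to minimize
voxel count.

## Cord centerline extraction

`detect_edges_3d` is a 3D approximate-Canny detector: Gaussian
smoothing (default sigma 1.5 voxels), gradient magnitude, two thresholds
expressed as fractions of the maximum gradient, and hysteresis linking —
weak edges survive only when 26-connected to a strong edge. `"auto"`
thresholds take the Otsu threshold of the gradient magnitude as the high
threshold and 0.4 x that as the low one.

The edge image of a cord-in-agar tomogram also contains the container
walls, so `cord_contours` keeps only edge voxels adjacent to
tissue-intensity voxels (upper value of the two-stage band) before
either route:

* **Centre-of-mass route**: per-slice unweighted centroids of the
  contour voxels, ordered by z. Raw centroids carry voxel-scale jitter
  that would dominate curvature estimates, so the polyline is smoothed
  with a moving average (window 5 samples in-slice; a wider window of 9
  after arc-length resampling) and the half-window at each end — where
  the average is one-sided — is trimmed.
* **Region-growing route**: 6-connected growth of the non-edge region
  from a seed, closed with a ball of radius 1. 6-connectivity prevents
  diagonal leakage through one-voxel edge shells. The seed is taken at
  the mid-centerline sample, displaced laterally to land in the
  homogeneous white-matter compartment (the brightest non-edge
  candidate): a seed on the axis would fall inside the gray-matter
  butterfly, whose own edge shell would confine the growth. The grown
  region stops at the *inner* side of the hysteresis band, so the mask
  is dilated until half of the outer edge band is covered — at that
  point its boundary sits at the band centre, i.e. the physical
  interface. Interior structures enclosed by the mask are filled
  slice-wise.

Both routes end in per-slice centroids; the route is a pipeline
configuration choice and the two agree to ~1 voxel RMS on phantoms.

## Straightening

`build_frames` constructs rotation-minimizing frames by the
double-reflection method. The Frenet frame is undefined at inflection
points and twists violently on near-straight cords, which makes it
unusable here; rotation-minimizing frames propagate the initial normal
(the world x-axis projected orthogonal to the first tangent, falling
back to y) with minimal twist and are deterministic.

`straightening_transform` fixes the straight grid: in-plane offsets
(u, v) along the normal/binormal up to a radius R, arc length s along
the centerline. The mapping is injective inside the tube iff
`R * max_curvature < 1`; violating configurations are rejected up front,
never silently folded. `straighten_volume` pulls the curved volume back
through `c(s) + u n(s) + v b(s)` with trilinear (or nearest, for labels)
interpolation; `unstraighten_volume` inverts it by projecting each
curved-frame voxel onto the centerline polyline. The projection is the
closed-form orthogonal projection onto the two segments adjacent to the
discrete nearest sample — on a polyline this is the exact minimizer, so
no iterative 1D search is needed — with frames linearly interpolated and
renormalized at the projection parameter.

Default straight-grid spacings: in-plane = the processing in-plane
spacing, axial = the centerline resampling step. The straightened axial
extent equals the centerline arc length by construction.

## Registration

`landmark_init` builds the similarity transform from the two consensus
reference coordinates marked near the sample extremities in each
modality: midpoints matched by translation, directions aligned by the
minimal rotation, optional uniform scale from the length ratio. Two
points cannot determine roll about the segment axis; roll is fixed to
zero and left to the intensity metric.

`mattes_mi` computes mutual information from a joint histogram with
zero-order binning of the fixed intensities and a cubic B-spline Parzen
window on the moving intensities (32 bins, min-max normalized; the
moving axis is mapped to [1.5, bins-2.5] so the spline support stays in
range). It reports *negative* MI in bits and raises a distinguishable
error when fewer than 10% of the fixed samples land inside the moving
volume, so a lost overlap is never mistaken for a bad similarity value.

`register_affine` optimizes the 12 pose parameters (Euler angles,
translations, log-scales, shears, about the fixed-volume centre) with
BFGS in a scaled parameter space (one internal unit ~ 0.01 rad, one
fixed voxel, or 0.01 log-scale/shear) over an anti-aliased image pyramid
(factors 4, 2, 1). Levels whose coarsest grid would drop below ~24
voxels per axis are skipped — a 32^2-bin joint histogram over a few
thousand voxels produces spurious optima. Coarse levels use every
in-mask voxel; the finest level uses a seeded 20% random sample.

`register_diffeomorphic` refines with a demons-style scheme on a
stationary velocity field: forces from intensity-normalized (z-scored)
images, Gaussian smoothing of both the update and the field (default
sigmas: one voxel), displacement by scaling-and-squaring with >= 6
integration steps. The Jacobian determinant of `id + u` is checked to be
strictly positive everywhere; a failing field triggers one doubling of
the field smoothing and is otherwise rejected rather than returned.
This is a deliberate simplification relative to full symmetric
normalization: it keeps the same contract (smooth, diffeomorphic,
MI-compatible via normalization) at a fraction of the complexity, and
recovers the phantom's 2-voxel sinusoidal bends to well under a voxel.

## Pipelines

The brain branch registers the low-res map (moving) to the anti-aliased,
down-sampled tomogram (fixed) in the native frame. The cord branch
processes the saturated tomogram at a nearest-neighbour factor (by
default capped at the modality ratio; the end-to-end validation uses
factor 2, i.e. half the low-res spacing, which keeps enough boundary
detail for mask-overlap scoring at an 8-fold volume reduction),
extracts centerline and cord mask, straightens *both* modalities along
their own centerlines — the low-res map is segmented by the two-stage
band threshold, its smoother boundary needing no edge detection — and
registers in the straightened frame, where initialization reduces to
matching the landmark arc-length positions. Parametric maps are carried
into the straightened reference frame by composing the affine with the
inverse straightening of the low-res side. Reports are JSON with a
deterministic field order; identical configuration and seed give
byte-identical reports except for the timestamp.

# The synthetic phantoms

The generator is first-class, tested code: every validation quantity is
computed against its exported ground truth.

**Geometry.** Grids are desk-scale (high-res <= 256^3). The emulated
acquisitions differ in spacing by ~20:1 (6 vs 125 um); keeping that
ratio inside a 256^3 grid would leave the low-res modality fewer than 13
voxels per axis — too few to carry any structure — so the default
phantoms keep the qualitative asymmetry (sharp, ring-artifacted
high-res; smooth, noisy low-res) at ratios of 4–5:1 with ~30–50 low-res
voxels per axis: brain 240^3 at 25 um vs 48^3 at 125 um, cord
96 x 96 x 224 at 10 um vs 30 x 30 x 58 at 40 um.

**Brain.** An ellipsoidal brain (semi-axes 2.75 x 2.55 x 2.35 mm) in a
uniform medium, with a two-phase parenchyma texture — a smooth Gaussian
random field (correlation length 250 um FWHM) split into a bright patch
phase covering 65% of the body over a darker base, plus mild continuous
variation — a thin uniformly-bright cortical rim, a bright curved
callosum band, two hippocampal blobs and two dark ventricles. The patch
phase serves two purposes: a threshold anywhere between the phases
leaves a connected per-slice net (so morphological filling can solidify
the mask even without the boundary artifact), and both modalities sample
the *same* world-frame field, which is what gives mutual information its
signal. The low-res volume is the same scene pulled through the inverse
of the true inter-modality affine (default: 8 deg rotation, (500, 250,
125) um translation, uniform scale 1.05 about the volume centre),
lightly smoothed and noised, so the exported affine is exact ground
truth. Landmarks are the two lateral poles.

**Cord.** A tissue tube (radius 280 um) around a gentle spline curve
that runs axially through and slightly beyond the whole stack — as a
real cord does; a tube ending inside the grid would leave open tube
ends through which region growing escapes. The interior carries a
butterfly-shaped gray-matter region (two mirrored ellipses in the
rotation-minimizing cross-section). The tube sits in an agar cylinder
inside a dark reconstruction field of view. The low-res cord is rendered
around the curve mapped through the true transform: a rigid pose change
plus a smooth sinusoidal bend (default amplitude 80 um) standing in for
the unknown holder-induced curvature difference — the quantity the
straightening approach exists to remove. Landmarks sit on the centerline
one tube radius from each extremity.

**Artifacts and noise.** `add_ring_artifact` perturbs the morphological
boundary band: bright on the tissue side, dark on the medium side
(alternating in deeper layers), with amplitude 0.5 x the mean in-mask
intensity and width 1 voxel by default — the bright inner ring closes
the boundary shell for masking, and the dark outer ring gives the
bimodal band its dark class, both as in phase-contrast reconstructions.
Additive Gaussian noise defaults to ~2% of the tissue level; rendering
is bit-deterministic given the spec and seed, and the generator restores
the caller's RNG state.

**What the phantoms do not emulate** — and hence what passing tests do
not show about real data: anatomical realism; imaging physics (no
k-space, no Fresnel propagation, no phase retrieval); spatially varying
or structured noise; susceptibility distortions beyond a smooth global
bend; partial-volume anisotropy of the diffusion model. A method that
passes here has been shown correct in geometry, calibration and
bookkeeping, not clinically validated.

# Numerical choices and degenerate inputs

* Otsu threshold: 256-bin histogram, threshold reported on the original
  intensity scale at the optimal bin boundary; constant volumes raise a
  degenerate-input error rather than returning an arbitrary cut.
* Quantiles: nearest-rank on sorted values — deterministic and
  oracle-checkable by sorting.
* Gradients: central differences with replicated edges (edge estimates
  are halved, consistently everywhere).
* Tie-breaks: scale selection breaks ties toward the smaller factor;
  component selection takes the first-largest label.
* Injectivity, overlap, erosion collapse, seed-on-edge and empty-band
  conditions are errors with named causes, not warnings.
* All world coordinates are micrometres internally; NIfTI headers are
  converted (mm) only at the I/O boundary.

# Validation scale and what is measured

The test-suite and `scripts/acceptance.R` regenerate all inputs and
recompute, at the default study conditions above: the Otsu / region-grow
/ saturation oracle agreements (20 random cases each); brain-mask Dice
against truth with and without the ring artifact (target >= 0.95; the
geometric ceiling set by the ~2–3 voxel boundary band on the 100-voxel
brain is ~0.96); centerline RMS against the generating curve for both
routes, noiseless and at SNR 10 (target <= 1 high-res voxel);
straightening round-trip correlations (>= 0.98 curved, >= 0.999
straight) and the straightness of the re-extracted centerline (<= 1
processing voxel); recovery of the known affine over five seeds (target
landmark TRE <= 1 low-res voxel at 8 corner points), MI self-registration
optimality over 20 probe perturbations, and Jacobian positivity of every
accepted diffeomorphic field; and the end-to-end cord run (mask Dice
>= 0.90, bit-deterministic under a fixed seed). Registration of one
brain pair takes ~10 s and a full cord run ~5 s on one CPU at these
sizes.

# Known limitations

* The cord branch assumes the long axis is z (a configuration flag can
  permute axes) and one non-branching cord per volume.
* Straightening is only defined inside the injectivity tube; structures
  farther than R from the centerline are not transported.
* The demons-style refinement is not inverse-consistent; only the
  forward field is produced and checked.
* Manual mask fine-tuning as practised interactively is out of scope; a
  voxel add/remove edit list can be applied externally to the NIfTI
  masks instead.
* The two-point initialization cannot observe roll; with an extreme roll
  difference (> ~60 deg) the MI basin may be missed.
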