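---
title: "Models and methods: simulated projector-based AR navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated projector-based AR navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`arnav` models a surgical-navigation platform in which a tracked laser
pico-projector paints pre-operative image content directly onto the surgical
field. This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulation does and does not capture.

## Coordinate frames and transforms

All geometry is expressed in named right-handed frames with lengths in mm.
The optical tracker defines the world frame. Transforms are stored
child-to-parent (tool to tracker, image to tracker), matching the way optical
trackers report tool poses; composing a chain therefore reads right to left.
Rotations are stored as matrices and validated to be orthonormal with
determinant +1 at construction (tolerance 1e-6 on entry; test assertions use
1e-9). Quaternions appear only in the pose-stream CSV (scalar-first) and are
renormalized on input; a deviation from unit length beyond about 1e-3 is
treated as a corrupt record rather than silently repaired.

## Fiducial registration and FRE

Image space is registered to tracker space from paired landmarks by the
closed-form least-squares rigid fit: centroid subtraction, SVD of the
cross-covariance, and a determinant sign correction that forbids reflections.
Correspondence is by label order; there is no automatic matching, mirroring
the manual pairing of landmarks in practice. The fiducial registration error
is reported as the root-mean-square residual (not the mean), consistent with
RMS reporting throughout the accuracy study. A brute-force search over the six
transform parameters serves as an independent optimality oracle in the tests.

Pivot calibration solves the stacked linear system
`[R_k | -I] (p_tip; p_pivot) = -t_k` by SVD. Identical orientations make tip
and pivot inseparable (the system loses rank); a condition-number guard at
1e6 rejects pose sets with insufficient orientation span instead of returning
an arbitrary solution from the null space.

## The projector model

The projector is a zero-skew pinhole with no lens distortion. Laser
pico-projectors are focus-free and nearly distortion-free, and at the
sub-millimeter error scale of the accuracy protocol a distortion term would
be unidentifiable; the calibration residual absorbs what remains. Pixels are
0-based with the origin at the top-left pixel center, +u right, +v down, and
the device looks along +z of its own frame.

Calibration uses the normalized direct linear transform: pixels and world
points are isotropically normalized (mean distance sqrt(2) and sqrt(3) from
their centroids) before the 2n x 12 homogeneous system is solved by SVD —
without this the system's conditioning is dominated by the raw coordinate
scale. The 3 x 4 projection matrix is decomposed by RQ into intrinsics and
pose, the sign fixed so calibration points have positive depth, and the skew
entry dropped. The extrinsics are folded with the simultaneously tracked
sensor pose into the fixed sensor-to-projector mounting transform — the
quantity that makes the calibration valid at any later device position. This
independence from repositioning is asserted to 1e-6 mm in the tests
(continuous pixel coordinates; see below).

With at least 6 non-coplanar correspondences the noiseless recovery is exact
to numerical precision; coplanarity is detected on the smallest singular
value of the centered point cloud and refused.

## Volumes

Volumes are axis-aligned grids: `world = origin + spacing * index`, 0-based,
origin at the center of voxel (0,0,0). NIfTI-1 I/O goes through RNifti with
the geometry written into the sform; oblique direction matrices are rejected
with a clear error since the rigid, scanner-aligned setting never produces
them. NIfTI-1 stores geometry as float32, so spacings like 0.154 mm survive a
round trip to about 1e-9 relative accuracy while float64 voxel data is
bit-exact.

Resampling interpolates trilinearly on the world grid with edge clamping;
the output covers the input extent with `ceil(dim * old / new)` voxels.
Threshold segmentation is a closed intensity window, the standard
Hounsfield-unit bone/soft-tissue rule.

### Iso-surfaces

Meshes are extracted by marching tetrahedra on the Kuhn (Freudenthal)
6-tetrahedron cube decomposition, which is conforming across the lattice and
therefore yields watertight surfaces (the sphere test asserts Euler
characteristic 2). Binary masks are first smoothed with a separable 3-voxel
box filter: the 0.5-level set of the smoothed field interpolates the true
boundary instead of the voxel staircase, bringing the surface area of a
voxelized sphere from roughly +28% (raw mid-edge surface) to within a
fraction of a percent of the analytic value. Interpolated vertices are merged
by their grid-edge key, and zero-area triangles are dropped at construction.

### Slice fusion

Fused displays blend a grayscale anatomical slice with a colormapped
functional slice: `(1 - alpha) * gray(anat) + alpha * lut(func)`. The four
256-entry lookup tables are fixed in code: `hot` (black-red-yellow-white,
piecewise linear in thirds), `rainbow` (HSV sweep blue to red), `gray`, and
`purple` (black-purple-white, used for bone renderings). Intensities window
to each volume's full range unless an explicit window is given. Misaligned
grids are refused with an instruction to resample first, rather than silently
resampling.

### NMI registration

Multimodality volumes are aligned by maximizing normalized mutual
information, `NMI = (H(A) + H(B)) / H(A,B)`, from a 64 x 64 joint histogram,
over three translations (mm) and three rotations (degrees, applied about the
fixed-volume center — parameterizing rotation about a far-away origin couples
the parameters needlessly). Identical images give exactly 2; independent
images approach 1.

Optimization is the part that deserves care. A hard-binned histogram makes
the score piecewise constant in the parameters, so derivative-free searches
stall on the plateaus; the optimizer therefore maximizes a partial-volume
(bilinearly soft-binned) surrogate, which is continuous in the parameters,
while the reported NMI at the optimum is the plain hard-binned score. The
search runs as a pyramid: a smoothed, 2x-downsampled level is registered
first (3-level translation grid, 3-level rotation grid, cyclic coordinate
descent with steps shrinking from 2 to 0.1, Nelder-Mead polish) and its
result initializes the same refinement at full resolution. The coarse level
exists because translation error and rotation error trade against each other
on the fine-scale NMI surface; optimizing them jointly from scratch at full
resolution can be captured in an off-axis local optimum. Fixed grids are
subsampled to at most 40,000 voxels per evaluation.

Two caveats are documented rather than hidden. First, at coarse voxel sizes
(around 1 mm for the synthetic subject) the NMI optimum itself is displaced
from the ground-truth pose by up to a degree or two — an estimator bias from
interpolation smoothing, not an optimization failure; parameter-recovery
guarantees are therefore stated at the generator's native 0.3 mm resolution.
Second, registering a volume to itself returns a pose within a tenth of a
voxel of the identity, but the hard-binned NMI at that slightly offset pose
is below the theoretical ceiling of 2, which is attained exactly at zero
offset only.

## The simulated tracker

Tools are rigid marker bodies (at least 3 non-collinear markers). A
measurement maps the template through the true pose, perturbs every marker
coordinate with iid Gaussian noise, and re-fits the pose by rigid
registration. Applying noise at the marker level rather than to the pose
directly is deliberate: it reproduces the lever-arm coupling in which
orientation noise grows tip error linearly with offset length and projection
error linearly with standoff distance — the mechanism behind the
distance-dependent degradation the accuracy study measures. The default
marker sigma of 0.10 mm per axis is a free parameter of Polaris-class
magnitude, not a measured device figure; pointer samples add a further
0.05 mm of tip noise for hand tremor and divot seating. Fewer than three
visible markers invalidates the pose.

## Rendering

The virtual camera shares the projector's intrinsics and pose, so rendered
content lands where the physical device projects it. Rasterization is
software, at projector resolution (800 x 600 default), flat-colored with a
z-buffer and perspective-correct interpolation; there is no shading because
the overlays are flat contours and slices. The fused slice quad is drawn
first at its true world position (scrolling chooses which plane, not how it
drapes); mesh structures follow back-to-front by centroid depth with alpha
compositing. How overlapping translucent structures combine is a choice, not
a physical fact; back-to-front by centroid is predictable and cheap.
Structures whose mesh has vertices but no triangles render as single-pixel
point markers, and their continuous (sub-pixel) image coordinates are kept in
the framebuffer object: rasterized pixels quantize to about 0.4 mm on the
phantom, so quantitative invariance checks (repositioning the projector must
leave the illuminated world point unchanged to 1e-6 mm) are made on the
continuous coordinates.

Pointer-driven slice scrolling maps the tip into image space and rounds to
the nearest voxel plane (0-based, matching the pixel convention); out-of-range
tips error unless clamping is requested. The safety-margin alert reports
whether the tip's voxel is inside the margin mask and the Euclidean distance
to the nearest margin voxel center otherwise — exact for the query point, so
no distance-transform grid resolution enters.

## The accuracy phantom and protocol

The phantom is a plane bearing a rows x cols grid of conical divots (default
5 x 5 at 20 mm pitch over a 10 mm checker pattern; pitch and checker size are
independent parameters because divots occupy alternating squares). The four
outer corner divots serve as registration fiducials by default,
configurable.

One protocol run simulates a session:

1. Registration: one noisy pointer pick per registration divot (repeated
   localization in the protocol applies to the accuracy divots; fiducial
   registration in practice takes a single pick per landmark), then the rigid
   fit; its FRE is the run's registration quality.
2. For each standoff distance the projector faces the phantom center at that
   distance. Its pose is measured through the simulated tracker (optionally
   with additional pure orientation jitter for controlled studies).
3. Each divot is localized `reps` times with the tracked pointer at randomized
   approach angles within a 20-degree cone; the "real" position is the mean.
4. The "virtual" position follows the physical mechanism: the navigation
   software computes the divot's pixel from the *measured* (noisy) pose and
   the *estimated* registration, but the light leaves the projector at its
   *true* pose — so the virtual point is that pixel's ray cast from the true
   pose, intersected with the true phantom plane. Casting from the measured
   pose instead would cancel the pose noise identically and no distance
   dependence could arise.

`Err = ||real - virtual||` per divot; per distance the report gives the RMS
and SD over divots. The overall figure is the unweighted arithmetic mean of
the per-distance RMS values — each distance condition weighs equally — with
the pooled RMS (root mean square over all divots and distances) and pooled SD
reported alongside for transparency. With everything noiseless the whole
chain (registration, calibration, pose, ray, plane) closes exactly: FRE and
every Err are zero to machine precision, which the tests assert at 1e-9 mm.

## The synthetic subject

The generator emulates a small-animal multimodality session: an ellipsoidal
soft-tissue body (semi-axes 9 x 7 x 25 mm), a spine rod and two lateral bone
rods (700 HU), an off-axis liver-like organ (90 HU, elevated functional
uptake), and a spherical tumour (default radius 4 mm, 60 HU) whose mask is
exactly the voxelized sphere; the functional volume adds a Gaussian hotspot
co-located with the tumour over a faint body background. Default spacing is
0.3 mm isotropic, the working resolution of a down-sampled micro-CT.
Gaussian noise (15 HU CT, 0.1 functional) is seeded and reproducible. The
asymmetric organ layout is intentional: a featureless ellipsoid leaves
azimuthal rotation nearly unidentifiable for intensity-based registration,
which would say nothing about real anatomy.

What the generator does not emulate: scanner physics (beam hardening,
partial-volume blur, reconstruction artifacts), non-rigid tissue deformation,
and anatomical texture. Tests passing on this subject demonstrate the
geometry and the estimation chain, not robustness to clinical image quality.

## Problem sizes and tolerances in the test suite

Property tests use 100-200 random transforms (1e-9 tolerances), a 0.6 mm
sphere grid for surface checks (5% area, exact Euler number), 20
NMI-perturbation trials at 0.3 mm (0.5 voxel / 0.5 degree, at least 90%
success), 200 seeded protocol runs for the distance-monotonicity and
RMS(400)/RMS(200) ratio checks (+-25% around the small-angle prediction of
2), and 1000-frame noise calibrations (20% bands around closed-form values).
These sizes keep the full suite in the tens of minutes on one CPU while
leaving the Monte-Carlo bands comfortably away from their thresholds.

## Known limitations

- Rigid geometry only; no deformation, no affine scaling.
- Axis-aligned volumes only; oblique NIfTI orientations are rejected.
- The renderer has no near-plane clipping (triangles partially behind the
  projector are skipped whole) and drapes nothing onto curved surfaces —
  projection onto non-planar anatomy distorts, and quantifying that is out
  of scope here as it is for the physical device.
- Tracker noise is isotropic and iid per marker; real optical trackers have
  camera-geometry-dependent anisotropy and marker-occlusion effects.
- The manual element of divot localization is modelled as Gaussian tip noise
  plus approach-angle variation, not as a human-factors model.
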