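# arnav: projector-based augmented-reality surgical navigation, in silico

`arnav` implements the computational core of a tracked-projector
augmented-reality surgical-navigation (AR-SN) platform, with every piece of
hardware — the infrared optical tracker, the tracked pointer, and the
pico-projector — replaced by seeded simulation. It is aimed at
image-guided-intervention researchers who want to study how tracking noise,
registration error, and projector standoff distance propagate into the
accuracy of images projected onto the surgical field, without a physical rig.

## What it computes

**Frames and registration.** All geometry lives in named right-handed frames
(lengths in mm) connected by rigid transforms `p' = R p + t`, with the
optical tracker as the world frame. Image space is registered to tracker
space by paired-point rigid registration: given matched fiducials
{m_i} (image) and {f_i} (tracker), the closed-form SVD solution of

    argmin_{R,t} sum_i || R m_i + t - f_i ||^2      (det R = +1)

with the fiducial registration error reported as the RMS residual

    FRE = sqrt( mean_i || R m_i + t - f_i ||^2 ).

**The tracked projector.** The pico-projector is a pinhole device
(`u = f_u x/z + c_u`, `v = f_v y/z + c_v`) calibrated by a normalized direct
linear transform from pixel/3-D correspondences; the estimated pose is folded
with the simultaneously tracked sensor pose into the fixed sensor-to-projector
mounting transform, so the device can be repositioned freely without
re-registration. A virtual camera with the same intrinsics renders surgical
plans (tumour/margin/critical/bone meshes, fused multimodality slices) into
the projector framebuffer; each rendered pixel is physically emitted along
the matching ray.

**Volumes.** NIfTI I/O, trilinear resampling, Hounsfield-window threshold
segmentation, marching-tetrahedra iso-surfaces, alpha-blended fused slices
(CT gray under PET/SPECT colormaps), and rigid multimodality registration by
normalized mutual information, NMI = (H(A)+H(B))/H(A,B), maximized over the
six rigid parameters with a multi-resolution pyramid. A seeded generator
builds mouse-like CT + PET/SPECT volumes with exact tumour and bone masks.

**Accuracy phantom.** The checkerboard accuracy protocol places a 5 x 5 divot
grid (20 mm pitch) in the scene, registers it from noisy pointer picks of the
4 corner divots, and at each projector standoff (200/300/400 mm) localizes
every divot three times with the simulated tracked pointer ("real") while
the renderer projects the divot marker whose ray-plane intersection is the
"virtual" location. Per divot, `Err = || real - virtual ||`; per distance the
RMS +/- SD over divots is reported, and the overall figure is the unweighted
mean of the per-distance RMS values.

## Worked example

```r
library(arnav)

run <- run_protocol(seed = 42)      # default: 5x5 divots, 3 reps, 200/300/400 mm
summarize_accuracy(run)
```

```
<accuracy_report FRE = 0.311 mm, 225 localizations>
   200 mm: RMS 0.540 +/- 0.156 mm (n = 25 divots)
   300 mm: RMS 0.808 +/- 0.160 mm (n = 25 divots)
   400 mm: RMS 0.228 +/- 0.088 mm (n = 25 divots)
  overall: 0.525 +/- 0.276 mm (pooled RMS 0.576 mm)
```

One run is a single simulated session: the FRE is the residual of the 4-divot
registration, each distance row is the RMS spread of the 25 projected divots
around their pointer-localized positions, and the overall line averages the
three distance conditions. Any single session is dominated by the particular
projector-pose draws (here the 400 mm condition happened to catch a quiet
one); averaged over many seeded sessions — which is what
`scripts/acceptance.R` reports — the per-distance RMS stabilizes near
0.43/0.55/0.68 mm, growing with standoff because tracked-pose orientation
noise displaces the projected image in proportion to distance.

A multimodality overlay in a few lines:

```r
sub  <- make_synthetic_subject(seed = 7)
bone <- threshold_segment(sub$ct, low = 300, structure = "bone")
mesh <- extract_isosurface(bone)
img  <- fuse_slice(sub$ct, sub$func, axis = "coronal",
                   index = 30, alpha = 0.5, colormap = "hot")
write_rgb_png(aperm(img, c(2, 1, 3)), "fused.png")
```

A command-line front end wrapping the same functions is installed at
`inst/scripts/arnav.R` (subcommands `register`, `pivot`,
`calibrate-projector`, `segment`, `fuse`, `simulate`, `phantom-study`).

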