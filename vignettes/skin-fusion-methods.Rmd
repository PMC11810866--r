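---
title: "Skin-surface segmentation and rigid co-registration: models and methods"
author: "SkinFusion package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin-surface segmentation and rigid co-registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SkinFusion implements the geometric core of a markerless ultrasound-CT/MR
fusion system: the patient's skin is segmented from the volumetric image,
and that surface is rigidly registered to a depth-camera acquisition of
the same skin, which lives in the tracking frame of the ultrasound probe.
This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and — because the
validation is entirely synthetic — what the passing tests do and do not
demonstrate about real data.

## Coordinate conventions

A `VolumetricImage` places 0-based voxel index $(i,j,k)$ at world
position $o + A\,(s \circ (i,j,k))$, with origin $o$ (mm), orthonormal
right-handed direction matrix $A$, and per-axis spacing $s$ (mm). This
matches the common NIfTI/MetaImage reading and makes surfaces extracted
at different resolutions directly comparable. Slices are stacked along
the third array axis by default (configurable), and all slice-wise
operations act in the plane orthogonal to that axis. A `RigidTransform`
is $x \mapsto Rx + t$ with $\det R = +1$; applying it to a volume
changes only the header ($o \to Ro + t$, $A \to RA$), never the voxel
data — fusion must not resample or deform the image.

## Skin segmentation by background region growing

The segmentation exploits the large intensity gap between air and
tissue. For each slice, a mock-up label grid is initialised to 2
("untouched"). Growth starts from the slice corners that lie below the
skin iso-value; a visited pixel below the iso-value is background
(label 0) and enqueues its 4-neighbours, a pixel **at or above** the
iso-value is the body edge (label 1) and enqueues nothing. Every pixel
is evaluated at most once. The body — everything the background flood
never reaches — keeps label 2, so internal air pockets (bowel gas, a
hollow phantom) are part of the body *by exclusion*, which is exactly
what a skin surface should enclose.

Choices worth making explicit:

* **4-connectivity.** Diagonal (8-) connectivity would let background
  leak through a one-pixel skin boundary at corner contacts;
  4-connectivity cannot cross a closed 8-connected edge ring.
* **Equality goes to the body.** A pixel exactly at the iso-value is
  edge, not background.
* **Seeds and padding.** All four corners below the iso-value seed the
  growth; if none qualifies the slice is rejected with an error rather
  than silently searching elsewhere. `padVolume()` adds a border filled
  with the global minimum intensity around every slice, which guarantees
  corner seeds even when the scanner bed or the body touches the slice
  border, and lets the background flow around a bed that is darker than
  the iso-value. Padding only adds background, so it is kept for surface
  extraction; the origin shift preserves every original voxel's world
  position.
* **Queue discipline is irrelevant.** The label of a pixel depends only
  on reachability, not visiting order; the implementation processes the
  whole frontier in vectorised sweeps, which is equivalent to FIFO
  breadth-first search. The unit and acceptance tests verify exact
  agreement with an independently written stack-based flood fill on
  hundreds of random slices.
* **Subsampling** is pure decimation (every `factor`-th voxel, spacing
  multiplied, no smoothing): the point of the robustness study is the
  raw lower-resolution image, and anti-alias filtering would blur the
  air/tissue edge the method depends on.

## Surface extraction

The binarised mask (labels 1 and 2 = body) — not the raw intensities —
is isosurfaced at level 0.5. Using the mask removes internal anatomy
that intensity isosurfacing would also pick up. The marching step
decomposes every grid cell into the six Kuhn tetrahedra sharing the main
diagonal; because every cell uses the same decomposition, adjacent cells
agree on the shared face diagonals and the extracted mesh is watertight
by construction, which the classic 256-case cell table does not
guarantee on binary data (its ambiguous faces can produce holes). On a
binary field the level-0.5 crossing lies at the midpoint of every
inside/outside cell edge. The mask is first enclosed in a one-voxel
background shell so bodies truncated by the field of view still yield
closed surfaces. Triangle winding is oriented outward using the
inside-to-outside direction of each tetrahedron, and vertex normals are
the normalised area-weighted average of incident face normals.

Accuracy: every vertex sits on a cell edge between an inside and an
outside sample, so its distance to the true surface is bounded by half
the voxel diagonal; on the analytic sphere phantom (radius 20 mm, 1 mm
voxels) the measured maximum radial error is 0.83 mm against the bound
of 0.866 mm, and the error scales with the voxel diagonal at coarser
spacing. The same bound explains the subsampling study: surfaces from a
volume and its factor-2 decimation differ by at most about one coarse
voxel diagonal (measured: ~0.4 of it).

## Co-registration pipeline

Inputs: the segmented skin `X1`, the camera surface `X2` (frontal
acquisition, same patient orientation), and one operator-picked landmark
per surface (snapped to the nearest vertex; more than 5 mm off-surface
is rejected).

1. **Front cut.** Only the front of `X1` can be seen by the camera:
   vertices whose unit normal has a strictly positive dot product with
   the anterior direction are kept (angle < 90°; boundary vertices at
   exactly 90° are dropped). The anterior direction is a configuration
   parameter (default $+y$, an LPS-style convention) because anatomical
   axis detection from headers is unreliable.
2. **Principal-component alignment.** The rotation maps the eigenvectors
   of the vertex covariance of the front surface onto those of `X2`
   (descending eigenvalues). Eigenvector signs are fixed by requiring a
   positive dot product with the destination axis — valid because both
   surfaces are consistently oriented (head-feet, right-left) — and a
   residual improper combination is repaired by flipping the axis with
   the weakest agreement. Covariance eigenvalues closer than a 1%
   relative gap (spheres, circular cylinders) make the axes meaningless
   and raise an error.
3. **Landmark translation.** The translation is replaced by
   $t = y_{lm} - R\,x_{lm}$ so the rotated skin landmark lands exactly
   on the camera landmark.
4. **Region of interest.** Both surfaces are cropped to a sphere
   (default radius 100 mm) around the camera landmark — the landmark is
   the only shared reference the operator has provided.
5. **ICP stage 1** (all pairs) and **stage 2** (trimmed refinement,
   default 80% closest pairs) refine the pose; the composed transform is
   returned together with per-stage RMS, Hausdorff distance and
   per-vertex error maps.

### ICP details

Each iteration matches points, keeps the `trimFraction` of pairs with
the smallest distances, and solves the rigid least-squares update in
closed form (SVD/Kabsch). The trimmed RMS is recorded every iteration
and is provably non-increasing (matching can only shrink per-point
distances, trimming keeps the smallest, and the closed-form update
minimises the trimmed sum of squares); the tests assert this on every
iteration of every seeded trial. Iterations stop when the RMS change
falls below `convergenceTol` (default 1e-4 mm) or at `maxIterations`
(default 100 — point-to-point ICP converges by slow tangential sliding
on smooth skin, and measurements showed stage 1 needing ~90 iterations
on partial-coverage registrations; a cap of 50 left ~2° of residual
rotation).

Two choices depart from the most literal reading of the design and were
forced by measurement:

* **Correspondence direction.** Pairs are formed from the sparse,
  partial camera cloud *into* the dense segmented surface. Every camera
  point genuinely lies on the skin, whereas matching skin vertices to
  the camera cloud pairs everything outside the camera's field of view
  with arbitrary points; the measured pose-recovery error grows by an
  order of magnitude in the reverse direction. The returned transform
  still moves the segmented surface (and the volume) into the camera
  frame — the fitted transform is inverted.
* **Point-to-triangle matching.** Camera points are matched to their
  closest point *on* the triangulated skin surface (k-d tree proposes
  nearest vertices, the incident triangles are searched exactly), not to
  the nearest vertex. At clinical voxel sizes the vertex lattice (~3 mm)
  quantises the objective and left 1.5–2 mm spurious translation minima
  in about a fifth of the seeded trials; the continuous surface removes
  the lattice while keeping the point-to-point least-squares update (and
  with it the monotonicity proof). Point-to-plane minimisation was not
  adopted: it abandons that proof for little additional gain here.

### Operator independence: the landmark-correction search

The virtual landmark only initialises the translation, yet a ~15 mm
picking error can strand greedy ICP in a tilted local minimum whose
trimmed RMS is clearly worse than the global fit (measured 1.2 mm vs
0.7 mm, with 3–5° of rotation error). Restarting ICP from shifted
initial transforms cannot help: with absolute closed-form updates, the
initialisation only influences the first correspondence set. The
pipeline therefore treats the landmark itself as the uncertain quantity:
it evaluates a 3×3 tangential grid of corrected camera-side landmarks
(step `startOffset`, default 15 mm — the plausible picking error; 0
disables the search), scores each candidate with a short full-trim ICP
run, and keeps the correction with the lowest trimmed RMS before running
the two full stages. The search is deterministic, objective-driven, and
in the misplacement study it re-finds the identical optimum for every
displacement direction, making the recovered rotation independent of
where the operator clicked.

## Error metrics

Hausdorff distances are vertex-to-vertex with exact k-d-tree nearest
neighbours (verified against an $O(n^2)$ brute force to machine
precision, together with the metric axioms). Per-vertex distances are
mapped to colours linearly: 0 mm is pure blue $(0,0,255)$, distances at
or above the 5 mm cap are pure red $(255,0,0)$, in between
$d \mapsto (255d/5,\ 0,\ 255(1-d/5))$ rounded to integers — so the red
channel is monotone in the error. TRE is the mean Euclidean distance
between corresponding landmark lists; the clinical protocol uses a
single internal anatomical target ($N=1$). Note that the symmetric
Hausdorff distance between a dense mesh and a sparse camera cloud is
dominated by the sampling density of the cloud; the camera-to-skin
direction is the one that reflects registration quality, and the
pipeline's residual warning uses it.

## The synthetic phantom generator

The generator defines the study conditions for everything that cannot be
tested without hardware:

* **Volumes.** 96×96×48 voxels at 4×4×5 mm (a 384×384×240 mm abdominal
  field of view), air at −1000, soft tissue at +40, skin iso-value −400,
  intensity noise σ = 30 — CT-like numbers. Shapes: ellipsoid, circular
  cylinder (deliberately symmetric, in the spirit of cylindrical
  calibration phantoms), and an "abdomen" (in-plane superellipsoid,
  exponent 2.5, with a Gaussian anterior belly bulge). The body centroid
  sits at the world origin (scanner isocentre), keeping registration
  lever arms realistic. Noise is clipped so no voxel can cross the
  iso-value (a σ above a quarter of the air/body margin is rejected):
  real CT noise does not flip air into tissue either, and this keeps the
  analytic body the exact ground truth for the segmentation tests.
  Optional extras: a bed slab under the body touching the posterior
  slice border (bright like a real couch, or dark to exercise the
  padding logic) and an internal air cavity (which must end up inside
  the segmented body).
* **Camera surfaces.** Front cut of the skin mesh, a contiguous window
  holding a coverage fraction around the front centroid (tilt moves the
  window off-axis about the cranio-caudal axis rather than simulating a
  projective depth sensor), resampling to `sampleCount` points (1500 by
  default — a decimated consumer depth-camera cloud), isotropic Gaussian
  positional noise, then the ground-truth pose. Everything is driven by
  one seed; equal specs give bit-identical output.
* **Perturbation suite.** Base acquisition plus four camera-distance
  analogues (noise σ = 0.3 mm + 0.02 mm/cm at 20/25/30/35 cm — a
  documented linear stand-in for hardware-specific noise curves), three
  tilts (0/30/45° at 35 cm), and three 15 mm landmark misplacements
  (lateral, cranio-caudal, diagonal) that share one camera acquisition
  so only the landmark moves.

## Validation study design and problem sizes

The acceptance checks run, per seed: 100 random 32×32×8 volumes against
the flood-fill oracle (exact agreement required); the 48³ analytic
sphere (all vertices within half a voxel diagonal, watertight); the
default abdomen phantom at full and factor-2 resolution (Hausdorff at
most one coarse voxel diagonal); 50 pose-recovery trials (rotations up
to 20°, translations up to 50 mm, camera noise σ up to 1 mm, coverage
40–80%, requiring at least 95% of trials within 1° and 1 mm, with the
trimmed RMS monotone in every iteration); the misplacement study
(rotation change below 1°); 100 Hausdorff brute-force comparisons; the
colour-map and TRE anchors; and the 11-scenario perturbation table.

The recovery trials use two trunk-like phantoms (semi-axes 165/110/95
and 140/95/105 mm). This is a deliberate morphology choice: recovering a
pose to 1° from a frontal window requires the window to constrain all
three rotation axes. A plain ellipsoid whose anterior-posterior and
cranio-caudal semi-axes nearly coincide is almost rotationally symmetric
about the lateral axis, and on such shapes the rotation about that axis
is weakly observable *for any estimator* — exactly as the cylindrical
calibration phantom is the documented worst case for this class of
system. The near-symmetric shapes remain available in the generator, and
the 45° tilt scenario of the perturbation suite shows the same
degradation mechanism from the acquisition side (the tilted window sees
the smooth featureless flank; its TRE is an order of magnitude above all
other scenarios).

## Degenerate inputs and tie-breaks

* All four corner seeds at or above the iso-value: error naming the
  slice (padding prevents it in normal use).
* Empty or full segmentation mask: "no iso-surface" error.
* Sphere-like surfaces: PCA alignment refuses near-tied eigenvalues
  (1% relative gap).
* Vertices at exactly 90° to the anterior axis are excluded by the
  strict front-cut inequality.
* Colour-map rounding uses R's round-half-to-even; the 2.5 mm midpoint
  maps to (128, 0, 128).
* Landmarks further than 5 mm from their surface are rejected;
  registration inputs need at least 10 source points, and trimming that
  leaves fewer than 3 pairs is an error.

## Limitations

The synthetic studies validate the geometry and the estimator, not the
imaging physics: there are no bias fields, streak artefacts, partial
volume effects, or projective depth-camera distortions, the skin/air
margin is guaranteed by construction, and the phantoms are rigid —
breathing or posture change between CT/MR and the ultrasound exam, which
dominates error on real patients, is out of scope (rigid registration is
deliberate: the volume must not be deformed). Hausdorff distances are
vertex-based, so they include the sampling density of sparse clouds;
point-to-surface distances are used inside the ICP but not in the
reported metric, matching the k-d-tree formulation. Cold-start trimmed
ICP retains the known weakness of fraction trimming (it can stall a
degree or two off when started far from the optimum with the boundary
trimmed away); within the pipeline it always starts from the converged
full-trim stage, where the measured bias is negligible.
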