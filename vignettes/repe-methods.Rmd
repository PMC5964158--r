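---
title: "Methods: personalized tES electrodes on synthetic head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized tES electrodes on synthetic head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Transcranial electrical stimulation (tES) delivers weak currents through
scalp electrodes to modulate cortical excitability. When the target is one
cortical strip — here the primary somatosensory cortex S1, the postcentral
gyrus — a rectangular pad is a blunt instrument: the central sulcus (CS)
that separates S1 from the motor strip M1 curves across the scalp, so a
straight electrode inevitably straddles both banks. A *regional
personalized electrode* (RePE) is instead cut to the scalp projection of
the individual's central sulcus, so its anterior border can hug the S1/M1
boundary along its whole length.

This package implements the complete RePE workflow — shaping, positioning,
error evaluation, and electric-field dosimetry — and, because no imaging
data are deposited anywhere, a synthetic head phantom with exact ground
truth against which every stage is validated.

# Pipeline overview

1. **Phantom** (`generate_head_phantom`, `generate_template_pair`): layered
   head with a parametric CS groove; a "template" and an affinely warped
   "individual" with the warp known exactly.
2. **Segmentation + normalization** (`extract_brain_and_scalp`,
   `fit_affine`): brain/scalp masks from intensity, then the
   individual-to-template affine (TM).
3. **Shaping** (`map_template_sulcus`, `surface_from_mask`,
   `project_to_scalp`, `flatten_trace`, `build_electrode_outline`,
   `export_outline`): the 123 template sulcus points are mapped through
   TM^-1, projected to the scalp by minimal distance, unrolled to a plane,
   offset by 2 cm, and written as a true-scale SVG for printing.
4. **Positioning** (`compute_placement_sheet`, `repe_points`,
   `simulate_repositioning`, `positioning_error`): nasion/inion scalp
   distances that let an operator place the electrode with a flexible
   meter, and a simulation of repeated placements.
5. **Evaluation** (`trace_agreement`, `rm_anova`): nearest-point distances,
   ICC(2,1), and repeated-measures ANOVA for systematic displacement.
6. **Fields** (`conductivity_from_labels`, `place_anode`, `place_cathode`,
   `solve_potential`, `roi_dose`, `run_montage_study`): quasi-static
   volume-conductor solver and the 16-montage comparison.

# The phantom: a stated world

The head is a stack of nested shells — skin 4 mm, fat 3 mm, skull 6 mm,
CSF 4 mm, gray matter 4 mm, white matter inside — on outer semi-axes
70 x 85 x 80 mm, with a 28 mm-radius all-soft-tissue neck stub appended
inferiorly (the return path for extracephalic references). Two geometric
choices deserve explanation:

* **Tapered ovoid shells, not ellipsoids.** Real heads are egg-shaped;
  more importantly, an exact ellipsoid is invariant under a continuous
  three-parameter family of affines (whiten, rotate, unwhiten), so no
  mask-based registration can recover rotations from an ellipsoidal brain
  even in principle. The default taper (x semi-axis -6%, z +5% per unit of
  normalized anterior position) makes the shape affinely rigid and the
  registration problem well-posed.

* **Sulcus curvature 25 mm.** The groove's midline crosses the crown
  coronally and bows anteriorly by 25 mm toward its lateral ends. The
  parameter exists precisely to control how badly a straight strip
  electrode fails to follow the sulcus; a real CS scalp projection deviates
  2–3 cm from a straight coronal line. Below about the electrode width
  (20 mm) the personalized band and the straight strip become physically
  indistinguishable at phantom scale — smoothing by the conductive CSF
  erases sub-electrode-width shape detail — so a curvature in the realistic
  regime is what the RePE-vs-strip comparison is about.

Intensities are per-tissue means (air 0, skin 80, fat 110, skull 30, CSF
20, gray 60, white 90, arbitrary units) plus N(0, 5) noise: enough contrast
for threshold segmentation, with the skull/CSF trough separating brain from
scalp. All randomness is seeded; identical seeds give bit-identical
volumes. The phantom does **not** emulate MRI physics (bias fields,
sequence contrast), gyral anatomy beyond the one parametric sulcus, or
inter-subject variability beyond a 12-dof affine — so a green test
establishes algorithmic correctness on idealized geometry, not clinical
performance.

# Registration

`fit_affine` recovers the 12-parameter affine between brain masks in three
stages: moment matching (centroid plus symmetric square-root covariance
transport) for the initialization; a few point-to-point affine ICP
iterations with a closed-form least-squares update; then point-to-plane ICP
against normals of the smoothed fixed mask. Two details matter for
accuracy:

* Boundary samples are voxel centres Newton-projected onto the 0.5 level
  set of the Gaussian-smoothed mask (sigma 1.5 voxels). Raw boundary voxel
  centres carry a half-voxel phase bias that propagated into ~0.1 mm
  translation errors; the sub-voxel projection removes it.
* Point-to-point ICP alone stalls tangentially (matches slide along the
  surface), leaving rotation errors of the same size as the initialization;
  the point-to-plane stage resolves them.

A smoothed-overlap objective refined by Nelder–Mead was implemented first
and abandoned: at this problem size it was both slower (minutes) and less
accurate (~0.08 elementwise) than ICP (~1 s, <0.01). On the default
phantom pair the affine is recovered to well under 2% per element and the
mapped 123-point sulcus lands within half a voxel (mean) of ground truth.

# Surface, projection, geodesics

The scalp surface is extracted by marching **tetrahedra** (six tetrahedra
per cube, consistent face diagonals) on the Gaussian-smoothed mask at iso
level 0.5. Marching tetrahedra has no ambiguous cases, so the mesh is
always a closed 2-manifold; smoothing first puts interpolated vertices on
the underlying smooth surface, so areas converge (a voxelized ball's raw
staircase boundary area is ~50% high, the extracted mesh is within 0.1%).
Triangles are oriented outward using the generating tetrahedron's
inside/outside corners.

Nearest-point projection is the exact point-to-triangle distance (region
decomposition), brute force over candidate triangles with a vertex-kNN
pre-filter; ties break to the lowest triangle index, and the filtered
search is tested to be identical to the exhaustive one.

On-surface distances start from Dijkstra on the mesh edge graph and are
then *straightened*: the path is resampled, relaxed toward neighbour
midpoints, and reprojected onto the surface until its length converges.
The raw edge-graph metric overestimates geodesics by several percent and is
anisotropic (the tetrahedral split has a chirality, which showed up as a
~5 mm left/right asymmetry on a mirror-symmetric phantom); straightening
brings sphere great circles to ~0.2% and the symmetry to under 2 mm. The
N–I midline path is additionally restricted to a ±10 mm midsagittal
corridor above the fiducial plane, which is what a flexible meter laid over
the crown measures (and avoids the shorter under-the-chin path a shortest
path would otherwise take).

# Flattening and the outline

"Projecting to a plane" is realized as arc-length unrolling: point *i*
maps to (cumulative chord length, 0). This is the isometry along the trace
that a printed electrode wrapped onto the scalp needs — the planar trace
has exactly the 3D polyline length, and the 2 cm offset polygon has area
length x 20 mm exactly (35 cm^2 for the nominal 17.5 cm trace). An
orthogonal PCA-plane projection is available for comparison
(`flatten_trace(method = "pca")`) but foreshortens curved traces. The two
lateral closing segments are straight (the source procedure does not
specify the cap shape). The SVG is written at true scale (1 user unit =
1 mm) with a 100 mm calibration ruler.

# Positioning statistics

`simulate_repositioning` displaces the 27 marker points (centre ± 13 at
5 mm along the electrode edge) by seeded per-axis Gaussian noise plus an
optional per-repetition systematic shift, then re-snaps to the scalp.
`positioning_error` matches each marker to the *nearest* reference point
(not by index), reports per-repetition mean ± SD and per-axis deltas.
ICC uses the two-way random, absolute agreement, single-measure form
ICC(2,1), computed on matched coordinate pairs with the three axes pooled —
the natural agreement measure between two methods producing coordinates.
The repeated-measures ANOVA is the clean balanced one-way within-subject
F; no sphericity correction is applied (a documented limitation), and on
two conditions F equals the squared paired t exactly. The power check uses
a repetition-dependent drift (repetition *k* shifted by *k*·delta
anteriorly): a constant shift of all repetitions has no between-condition
variance, so a drift is the systematic displacement the ANOVA design can
see.

# The field solver

The quasi-static potential obeys div(sigma grad V) = 0 with no-flux walls
and injected currents at the electrodes. Discretization is a 7-point voxel
finite-volume stencil; face conductances use the harmonic mean (continuity
of normal current across tissue interfaces). Conductivities (S/m): gray
0.276, white 0.126, CSF 1.65, skull 0.01, air 1e-4 (excluded from the
domain), fat 0.025, skin 0.465, gel 0.3. The pure-Neumann system has a
constant nullspace; one node is pinned during the conjugate-gradient solve
(Jacobi-preconditioned, relative residual 1e-6) and the reported potential
is shifted to zero mean. The current of each electrode is divided over its
skin-contact voxels in proportion to their projected contact areas (the sum
of exposed-face areas projected on the local outward normal — an accurate
partition of the smooth patch area, where a raw face count would be up to
50% high); a 2-voxel gel layer grown by 6-connected dilation sits on top
as a passive conductor.

|E| is estimated from face current fluxes (E = J_face / sigma_voxel,
averaged over the two faces per axis) rather than central differences of
V: the normal current is continuous across interfaces, so this resolves
the field jump at conductivity boundaries, which matters in the
one-voxel-thin cortical sheet.

Validation: a homogeneous slab reproduces |E| = J/sigma to 1e-9; doubling
the current doubles V exactly and swapping the electrodes negates it; and a
three-shell concentric sphere (scalp/skull/brain = 0.465/0.01/0.276 S/m)
with a mirrored pair of 30-degree cap electrodes matches the analytic
Legendre-series solution to ~4.4% relative L2 in surface potential at 2 mm.
Two choices there are deliberate: caps rather than point electrodes (a
point source has an infinite analytic peak and is not resolvable on any
grid), and the cap axis along the grid diagonal — with the axis through a
grid pole the voxelized sphere presents a flat plateau exactly under the
electrode and the error triples, a staircase special case rather than a
generic property.

**Mesh independence.** Refining 4 mm to 2 mm leaves the S1/M1 dose ratio
stable to ~7%, but the raw voxel means of |E| in gray matter move by
20–30%: at 4 mm the cortex is one voxel thick and its voxel means carry
irreducible partial-volume error. The package therefore asserts ratio
stability (the quantity the montage comparison is about) and only bounds
the raw means loosely; sub-mm meshes, where the original tetrahedral
workflow demonstrated full mesh independence, are out of desk scale.

# Montages

The anode is either the personalized band (scalp voxels within 20 mm
posterior of the projected sulcus, optionally shifted 0/5/10/15 mm
anteriorly — shift 0 puts the anterior border on the CS projection) or a
straight constant-y strip of the same nominal 17.5 x 2 cm centred on the
footprint's mean anterior-posterior position. References: an occipital pad
of 70 cm^2 centred at 90% of the N–I midline arc, a neck band, a band at
the neck base standing in for "shoulders" (the phantom has none; labelled
an approximation), and a ring around the head at the ear plane. 10–10
positions on a phantom are defined by arc-length fractions of the N–I
midline (documented convention; there is no EEG cap on a phantom). The
16-montage study (4 references x 4 shifts at 1.5 mA) reproduces the
qualitative orderings: the occipital reference maximizes and best
discriminates the S1/M1 ratio; the ratio degrades monotonically as the
anode shifts anteriorly, with the 5 mm shift nearly equivalent to 0; and
the personalized band beats the straight strip under the occipital
reference.

# Numerical conventions

* World frame RAS, millimetres; voxel indices 0-based;
  world = affine x (i, j, k, 1).
* All transforms operate in world mm (the template-normalization matrix is
  stored as a FLIRT-style plain-text 4x4; the convention is documented in
  the README).
* Default grid 2 mm isotropic, 96^3; 1 mm available through
  `grid_params(n = 192, voxel = 1)`. Module tests and the montage study
  run at 4 mm (48^3) for speed, with contracts stated at 2 mm checked
  there.
* One global seed expands into per-stage seeds through a fixed counter
  scheme (`derive_seed`), so any stage is reproducible in isolation; all
  derived seeds stay below 2^31.
* Trace smoothing is off everywhere by default and in all tests.

# Known limitations

* Threshold-plus-morphology segmentation is tuned to the phantom's
  intensity model; it is a stand-in for a brain-extraction tool, conforming
  through its Dice contract, not a general segmenter.
* The edge-graph-plus-straightening geodesic is accurate to ~0.5% but is
  not an exact polyhedral geodesic.
* No sphericity correction in the RM-ANOVA; no Greenhouse–Geisser.
* The solver is quasi-static and isotropic; capacitive effects and
  anisotropic white matter are out of scope.
* Reported field magnitudes on the phantom are not comparable to values
  computed on a real segmented head; only orderings and ratios are.
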