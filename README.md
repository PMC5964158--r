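# repe — regional personalized electrodes for transcranial electrical stimulation

Transcranial electrical stimulation (tES/tDCS) injects weak currents
(~1.5 mA) through scalp electrodes to modulate cortical excitability. When
the target is a single cortical strip — primary somatosensory cortex S1,
the postcentral gyrus — a rectangular pad unavoidably straddles the central
sulcus (CS) and co-stimulates the motor strip M1, because the CS curves by
centimetres across the scalp. A **regional personalized electrode (RePE)**
is cut to the scalp projection of the *individual* central sulcus, so its
anterior border follows the S1/M1 boundary along its entire length.

`repe` implements the full RePE workflow in R, testable end-to-end on
synthetic head phantoms with exact ground truth (no imaging data needed):

* **Phantom**: layered tapered-ovoid head (skin/fat/skull/CSF/gray/white +
  neck stub) with a parametric, laterally curved CS groove; template /
  individual pairs linked by a known 12-dof affine.
* **Shaping**: segmentation, affine normalization `TM` (moment matching +
  point-to-plane ICP), mapping of the 123 template sulcus points through
  `TM⁻¹`, minimal-distance projection onto the triangulated scalp,
  arc-length flattening, and the printable 2 cm-wide outline exported as a
  true-scale SVG.
* **Positioning**: neuronavigation-free placement sheet — on-surface
  (geodesic) distances N–I, N–C, N–L, N–R from nasion/inion — plus a
  seeded simulator of repeated placements and its error report
  (27 marker points at 5 mm spacing).
* **Evaluation**: nearest-point trace agreement, ICC(2,1), and
  repeated-measures ANOVA for systematic displacement.
* **Fields**: quasi-static volume-conductor solver
  ∇·(σ∇V) = 0 (voxel finite-volume, harmonic-mean face conductivities,
  Jacobi-preconditioned CG to 1e-6) with patch electrodes, gel layer,
  ROI dosimetry and the 16-montage comparison
  (4 references × 4 anterior shifts at 1.5 mA).

The model core: tissue conductivities σ (S/m) gray 0.276, white 0.126,
CSF 1.65, skull 0.01, fat 0.025, skin 0.465, gel 0.3; electrode currents
applied as current density over the skin contact area; dose summarized as
the mean field magnitude EF_AVE per region and the selectivity ratio
EF_AVE(S1)/EF_AVE(M1).

## Worked example

```r
library(repe)

## template/individual phantom pair with a known affine
pair <- generate_template_pair(perturb = make_affine(
  scale = c(1.05, 0.97, 1.03), rot_deg = c(4, -3, 2),
  shear = c(0.03, 0.02, -0.02), trans = c(4, -3, 5)), seed = 1)

## segment, normalize, map the 123-point template sulcus, project, shape
seg  <- extract_brain_and_scalp(pair$individual$intensity)
segt <- extract_brain_and_scalp(pair$template$intensity)
tm   <- fit_affine(seg$iBrain, segt$iBrain)          # individual -> template
ics  <- map_template_sulcus(pair$template$sulcus, tm)
surf <- with_mesh_graph(surface_from_mask(seg$iScalp))
icss <- project_to_scalp(ics, surf)
out  <- build_electrode_outline(flatten_trace(icss), width_mm = 20,
                                scalp_points = icss$points)
out
#> <electrode_outline> 242 vertices, width 20.0 mm, area 49.6 cm^2

## placement sheet: what the operator measures with a flexible meter
compute_placement_sheet(surf, pair$individual$truth$fiducials,
                        out$scalp_footprint)
#> <placement_sheet> (scalp distances, mm)
#>   N-I     260.6
#>   N-C     151.7
#>   N-L     112.2
#>   N-R     110.0

## accuracy of the computed trace against the ground-truth projection
trace_agreement(icss, project_to_scalp(pair$individual$truth$sulcus_gt, surf))
#> <trace_agreement> 0.29 +/- 0.41 mm, ICC 1.0000
```

The electrode area exceeds the nominal 35 cm² because the full
Sylvian-to-Sylvian sulcus trace (~248 mm here) is longer than the 17.5 cm
nominal strip; `trace_length(icss)` × 20 mm is exact by construction. The
placement sheet (top) is the complete recipe for positioning the printed
electrode without neuronavigation: lay a flexible meter from nasion over
the crown to inion, mark the electrode centre at N–C, then orient it with
the N–L and N–R distances. The final line reports the computed scalp trace
landing 0.29 mm (mean) from the ground-truth projection.

The montage study (`run_montage_study`) at 4 mm reproduces the qualitative
dosimetry findings: an occipital (Oz) reference maximizes the S1/M1 ratio
(≈1.9 on the phantom vs ≈1.1 for neck/shoulders/ring); the ratio degrades
monotonically as the band shifts anteriorly, with a 5 mm shift nearly
equivalent to none; and the personalized band beats a straight strip of
identical size (1.91 vs 1.71) under the Oz reference.

## Command line

```
Rscript inst/cli/repe all --seed 1 --out run1/
```

runs phantom → segmentation → shaping → placement → evaluation → fields
and writes `electrode.svg`, `placement_sheet.json`, `dose_table.csv`,
NIfTI volumes, and a `manifest.json` with checksums (identical configs
give identical manifests). Configuration is YAML (`--config`); every stage
seed derives deterministically from the one global seed.

## Conventions

World coordinates are RAS millimetres with 0-based voxel indices
(`world = affine %*% c(i, j, k, 1)`); the normalization matrix is stored
as a FLIRT-style plain-text 4×4 acting on world mm. Default grid 2 mm
isotropic 96³ (1 mm available via `grid_params`). See
`vignettes/repe-methods.Rmd` for the model, numerical choices, and known
limitations.
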