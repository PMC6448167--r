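# dirqa — multiparametric QA for deformable image registration

Deformable image registration (DIR) maps each point of one CT study onto
the corresponding point of another; adaptive radiotherapy relies on it for
contour propagation and dose accumulation. Because commercial DIR engines
do not publish their cost functions, their accuracy has to be assessed
externally: register test objects with *known* deformations and measure how
well positions, volumes and shapes are recovered. `dirqa` is an R toolkit
for exactly that assessment, aimed at medical physicists validating a DIR
workflow:

* **Digital phantoms with ground truth.** A bending-stick phantom (clay
  stick with three 16 mm glass spheres and seven 2 mm grain markers,
  deformed by an analytic constant-curvature bend whose level is defined by
  the angle measured between the two extremity axes — study levels 8°, 16°,
  25°) and a head/neck-like shrinking-mass phantom (water-filled mass grown
  to 0/25/50 ml on the body surface, mandible-like bone, eight defect
  markers). Volumes, masks, landmarks and ground-truth displacement fields
  are generated in code and written as NIfTI-1 + CSV.
* **Contrast remapping.** The quadratic Hounsfield-unit transfer curve
  `q(v)` through three anchors (background fixed; clay→30/glass→1000,
  −100/40, 10/50 HU) used to create the muscle–bone, fat–muscle and
  soft-tissue contrast levels.
* **A stand-in DIR engine** (multi-resolution demons with fluid and
  elastic Gaussian regularization) plus box-based local-rigid refinement,
  so every protocol runs end to end; third-party engines are scored by
  importing their DVF.
* **The similarity-index suite.** For corresponding structures A, B:
  Dice coefficient `DSC = 2|A∩B|/(|A|+|B|)`, symmetric Hausdorff distance
  HD on surface voxels (mm), maximum-diameter difference
  `DD = |d_max(A) − d_max(B)|` (3D Feret), sphere-centroid distance R and
  marker distance RM (mm); self-registration *sensitivity* floors; spider
  (radar) summaries whose polygon area condenses HD/DD/R/RM (smaller =
  more accurate); paired exact Wilcoxon signed-rank comparison of refined
  vs unrefined registrations.

## Worked example

Register a 16°-bent phantom onto the straight reference and score it:

```r
library(dirqa)

ref  <- build_bending_phantom(bending_phantom_spec(angle_deg = 0,  spacing = c(2, 2, 2)))
bent <- build_bending_phantom(bending_phantom_spec(angle_deg = 16, spacing = c(2, 2, 2)))
measure_bend_angle(bent$volume)        # 16.0 degrees, by construction

remap   <- study_contrast_levels()[["30_1000"]]        # muscle/bone contrast
ref_ct  <- remap_contrast(add_noise(ref$volume, 10, seed = 1), remap)
bent_ct <- remap_contrast(add_noise(bent$volume, 10, seed = 2), remap)

anchors <- lapply(list(ref, bent), function(b)
  b$landmarks[b$landmarks$name %in% c("sphere1", "sphere3"), ])
init  <- rigid_align(mode = "landmark", anchors = anchors)
field <- deform_register(ref_ct, bent_ct, init, dir_params(iterations = c(40, 25, 10)))

registered <- resample(bent_ct, field)
ref_masks <- threshold_segment(ref_ct,     0.5, min_voxels = 40, labels = paste0("sphere", 1:3))
reg_masks <- threshold_segment(registered, 0.5, min_voxels = 40, labels = paste0("sphere", 1:3))
markers   <- invert_map_points(field, bent$landmarks)
evaluate_similarity(ref_masks, reg_masks, ref$landmarks, markers,
                    metadata = list(registration = "R2", refine = FALSE))
```

```
<dirqa_report> [registration=R2, refine=FALSE]
structures:
  structure    DSC HD     DD       R
1   sphere1 0.9695  2 0.6227 0.09118
2   sphere2 0.9817  2 0.2425 0.16394
3   sphere3 0.9799  2 0.0000 0.00000
...
summary:
  index    mean       sd  n
1   DSC 0.97702 0.006582  3
2    HD 2.00000 0.000000  3
3    DD 0.28841 0.313869  3
4     R 0.08504 0.082140  3
5    RM 0.55864 0.404042 10
```

Reading it: sphere overlap after DIR is high (mean DSC 0.977), residual
surface error is at the 2 mm slice-resolution floor, sphere centroids are
recovered to ≈0.1 mm, and the ten internal markers land within ≈0.6 mm of
their reference positions on average. Rising HD/DD and falling DSC across
8°→16°→25° quantify how this engine degrades with deformation size; the
study drivers (`run_bending_study()`, `run_contrast_study()`,
`run_shrinking_study()`, `compare_refinement()`, `export_report()`)
automate those sweeps, and `sensitivity_protocol()` supplies the floor
below which index differences are meaningless.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/scripts/dirqa`): `dirqa phantom bend --angle 25 --out out/`,
`dirqa register --ref a.nii --tgt b.nii --out dvf.nii`,
`dirqa study all --out results/`.

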