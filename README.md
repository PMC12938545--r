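# plugsim

Simulation of airway mucus plugs in CT volumes, with lesion-level
detection metrics.

Mucus plugs — inspissated secretions occluding bronchial lumina — are an
emerging CT biomarker in obstructive lung disease, but voxel-wise manual
annotation is slow, subjective, and dominated by small distal lesions.
`plugsim` implements an annotation-free alternative: it *synthesizes*
realistic plugs inside segmented airways of plug-free scans, so that a
segmentation model can be trained entirely on simulated lesions whose
ground truth is known by construction. The package also implements the
matching object-level evaluation protocol (overlap-based TP/FP/FN,
size-stratified sensitivity with score confidence intervals, false
positives per scan, paired comparisons), and a procedural airway/vessel
phantom generator so the whole pipeline runs and is testable without any
clinical data.

## The method

For a scan with segmented lung, airway lumen and vessel masks:

1. **Phenotype sampling.** Each plug draws a target length
   L ~ U(2, 20) mm, an occlusion ratio rho ~ U(0.35, 1.0) (plugged
   cross-sectional area / lumen cross-sectional area), and a host-airway
   caliber in 1–20 mm.
2. **Constrained region growing.** From a random seed voxel in an
   eligible airway lumen, a region grows within the lumen only, never
   crossing a bifurcation: longitudinally until the extent along the
   centerline reaches L, and in each one-voxel cross-section until the
   plugged area fraction reaches rho (grown mural-adherently from the
   seed-side wall).
3. **Signed distance fields.** SDF(x) = ±min-distance from voxel x to the
   compartment boundary (negative inside) is computed for the airway
   lumen and the vessel tree — here with an exact Euclidean distance
   transform.
4. **Depth-matched intensity transfer.** For each plug voxel P_airway, a
   voxel P_vessel of an adjacent, caliber-comparable vessel is chosen
   with SDF_vessel(P_vessel) ≈ SDF_airway(P_airway) (tolerance 0.5 mm),
   and its HU value is copied in. The plug inherits the vessel's
   depth-resolved attenuation profile, including partial-volume behaviour
   at the surface.
5. **Dataset building.** Volumes are resampled to 0.8 mm isotropic;
   mini-batches mix plug-positive and plug-negative patches at a fixed
   ratio; images + binary labels export as NIfTI with a JSON manifest.

Evaluation is lesion-level: a predicted component is a true positive if
it overlaps a ground-truth plug by **at least one voxel**; unmatched
predictions are false positives, unmatched ground-truth plugs false
negatives. Pixel-level agreement uses Dice, D(A,B) = 2|A∩B|/(|A|+|B|).
Sensitivity is stratified by plug length into (0,3), [3,6), [6,15),
[15,∞) mm bins with Wilson 95% CIs; FP/scan = total FPs / number of
scans; per-scan metrics are compared with paired two-sided t-tests.

## Worked example

```r
library(plugsim)

spec    <- phantom_spec(seed = 42)          # 80^3 voxels, 1 mm, 63 branches
anatomy <- generate_phantom(spec)
anatomy
#> <anatomy_model> 80 x 80 x 80 voxels, 63 airway branches
#>   lumen 2621 vox, wall+vessel 4495 vox, lumen fraction 0.512%

plugs <- populate_scan(anatomy, n_plugs = 50, seed = 42)
plugs
#> <plug_set> 50 plugs, 1578 labelled voxels
#>   length 0.8-15.0 mm (mean 5.3), occlusion 0.40-1.00, 40 truncated

tx <- texture_plugs(plugs, seed = 42)       # vessel-derived HU texture
head(plug_table(plugs)[, c("label_id", "branch", "length_mm", "occlusion")])
#>   label_id branch length_mm occlusion
#> 1        1     34 10.431733 1.0000000
#> 2        2      2  7.773402 0.7526455
#> ...

# score a (deliberately degraded) detector at the lesion level
pred <- detector_noisy_oracle(min_voxels = 3, miss_rate = 0.1, fp_rate = 2)(
  plugs$labels, anatomy)
m <- match_lesions(pred, plugs$labels)
m
#> <lesion_match_result> TP 45, FN 5, FP 2 (GT lesions 50, predictions 12)

lens <- setNames(plug_table(plugs)$length_mm, plug_table(plugs)$label_id)
stratify_and_summarize(list(m), list(lens))
#> <detection_report> 1 scans
#>   (0, 3)     sens 1.000 (8/8; 95% CI 0.676-1.000)  FP/scan 0 (0/1)
#>   [3, 6)     sens 0.821 (23/28; 95% CI 0.644-0.921)  FP/scan 2 (2/1)
#>   [6, 15)    sens 1.000 (13/13; 95% CI 0.772-1.000)  FP/scan 0 (0/1)
#>   [15, Inf)  sens 1.000 (1/1; 95% CI 0.207-1.000)  FP/scan 0 (0/1)
#>   all        sens 0.900 (45/50; 95% CI 0.786-0.957)  FP/scan 2 (2/1)
```

The numbers read exactly like a clinical report: per size bin, the
fraction of plugs detected (with the counts and CI behind it) and how
many spurious detections each scan would add. A perfect detector
(`detector_oracle()`) scores sensitivity 1.0 and 0 FP/scan.

A command-line front end (`inst/cli/plugforge`) wraps the same functions
as `phantom`, `simulate`, `build-dataset`, `evaluate` and `sweep`
subcommands; `run_density_sweep()` reproduces the augmentation-density
experiment (10–100 plugs/scan) against any detector callback.

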