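---
title: "Simulating airway mucus plugs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating airway mucus plugs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why simulate plugs

Mucus plugs appear on non-contrast CT as soft-tissue attenuation
(~30–50 HU) inside an airway lumen — nearly indistinguishable from the
pulmonary vessels that run alongside the airways. That resemblance is the
engine of this package: because a plug is essentially "vessel-like tissue
in an airway-shaped container", one can manufacture arbitrarily many
realistic plugs by (a) carving an anatomically constrained region out of
the airway lumen and (b) filling it with intensities borrowed from an
adjacent vessel at matched depth below the compartment surface. Ground
truth is then known by construction, so a segmentation model can be
trained with no manual annotation at all.

`plugsim` implements that synthesis pipeline end to end, plus the
object-level evaluation protocol used to score detectors, on top of a
procedural phantom generator that stands in for segmented clinical scans.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a CT-like volume containing a bifurcating
airway tree (air-filled lumen at −1000 HU wrapped in a −200 HU wall),
one companion vessel tube per branch at ~40 HU, parenchymal background
at −850 HU, and additive Gaussian acquisition noise (σ = 15 HU by
default). Rasterization produces the image *and* exact lung/airway/vessel
masks and the centerline tree with per-branch radii — the same inputs an
airway-segmentation toolchain would extract from a real scan.

Defaults (80³ voxels at 1 mm isotropic, 5 bifurcation generations, trunk
lumen radius 3 mm tapering by 0.78 per generation, bifurcation half-angle
32° with ±8% per-branch jitter) were chosen once, for two reasons:

* the lumen diameters span ~6 mm down to ~1.7 mm, so plugs occur across
  the eligible caliber range of 1–20 mm, with both multi-voxel and
  near-single-voxel cross-sections represented;
* the total centerline length (~400 mm) comfortably hosts the dense
  augmentation regime of 50 plugs per scan that the pipeline defaults
  to, mirroring the capacity of a real airway tree.

Companion vessels are modelled as one straight tube per branch at a fixed
8 mm centre-to-centre offset, with radius 0.75× the airway outer radius.
The offset *direction* is chosen per branch from 16 candidate
perpendicular directions by maximizing clearance from all other airway
tubes and already-placed vessels; a residual collision with any airway
lumen aborts rasterization with the branch named. This is the simplest
geometry satisfying the premise that a comparable-caliber vessel runs
adjacent to each airway.

The phantom deliberately does **not** emulate lobar anatomy, curved or
non-binary branching, cardiac/diaphragm structures, contrast enhancement,
bronchiectatic remodeling, air–fluid levels, or scanner-specific noise
spectra. Tests passing on phantoms therefore validate the *mechanics* of
synthesis and scoring — containment, parameter honoring, depth-matched
texture, metric arithmetic — not clinical realism of any absolute
performance number.

## Geometry

**Coordinates.** All geometry is computed in world millimetres. Arrays
use the native R/NIfTI (x, y, z) axis order with per-axis spacing
recorded explicitly; voxel (1,1,1) sits at the origin.

**Signed distance fields.** `signed_distance_field()` returns, for every
voxel, the signed distance to the mask's face boundary: exact Euclidean
distances between voxel centres (computed by a separable lower-envelope
distance transform in compiled code, anisotropic spacing respected),
shifted by half the smallest spacing so an inside/outside pair adjacent
across a face reads −h/2 / +h/2. Two consequences are tested: the sign
symmetry `sdf(mask) = -sdf(!mask)` is *exact*, and the field agrees with
an exhaustive nearest-boundary search to numerical precision. An exact
transform was preferred over a front-propagation (eikonal) solver: it is
deterministic to machine precision, has no causality-ordering error in
thin tubes, and the same O(N) cost in practice. The eikonal property
|∇SDF| ≈ 1 away from boundary and medial axis is verified empirically
(tolerance 0.2).

**Cross-sections.** A cross-section at a centerline point is the
one-voxel slab of lumen voxels whose centres fall within half a voxel of
the plane normal to the local tangent, restricted to the connected
component containing the point. The slab interval is half-open
([−h, h)) so a plane falling exactly midway between two voxel layers
still selects exactly one layer. Areas are voxel count × in-plane voxel
area (voxel volume / voxel extent along the tangent); for a 3 mm-radius
tube at 1 mm spacing the digitized area is within 10% of πr².

**Plug length** is the arc length between the extreme projections of the
plug's voxels onto its host centerline polyline. A single-voxel plug
reports one voxel spacing rather than zero so that every plug has a
well-defined length bin.

**Caliber validation.** The per-section caliber is estimated from the
slab *area* (d = 2√(A/π)) rather than from the centerline depth, because
the depth under-reads by up to half a voxel diagonal whenever the
centerline passes between voxel centres. On interior sections (one local
radius away from end caps and bifurcation junctions, where the merging
parent legitimately widens the section) the estimate tracks the
prescribed diameter within one voxel for ≳97% of sections, with rare
digitization outliers below 1.5 voxels — the tested contract.

## Plug synthesis

`sample_phenotype()` draws length, occlusion ratio and eligible caliber
independently and uniformly from the configured ranges (defaults
2–20 mm, 0.35–1.0, 1–20 mm). `select_seed()` draws a uniformly random
lumen voxel among those whose host-branch diameter is eligible and whose
cross-section is free of existing plugs. `grow_plug()` is deterministic
given (anatomy, seed, phenotype):

* the longitudinal window is ±L/2 around the seed's arc position,
  clipped to the contiguous run of plug-free cross-sections of the host
  branch — growth never crosses a bifurcation, which keeps "length along
  the centerline" single-valued per plug;
* each covered section receives the smallest voxel count whose area
  fraction reaches the target occlusion ratio (so the realized
  per-section ratio is always ≥ the target, hence ≥ 0.35), selected
  mural-adherently: voxels closest to the wall on the seed's side first
  (`geometry = "centered"` switches to growing from the axis outward);
* a connectivity pass keeps the 26-connected component containing the
  seed, refills any section that dropped below its quota from voxels
  adjacent to the plug, and drops sections that cannot be refilled, so
  the final voxel set is 26-connected and still honors the per-section
  floor.

**Saturation and truncation.** A plug whose free run is shorter than its
target length is truncated and flagged, rather than rejected. This is a
deliberate reading of the growth contract: requiring the full
target-length corridor to be free would make dense augmentation (50
plugs/scan) unattainable on desk-scale anatomies, and the pipeline
already defines truncation (branch shorter than target) and saturation
(fewer plugs with a warning) semantics. The strict behaviour is
available via `plug_config(corridor = "full")`. One consequence is that
realized length distributions on small phantoms skew below the sampled
targets; the sampled ranges, not the realized marginals, are the
contract.

`populate_scan()` repeats sample→seed→grow, resampling the phenotype
when no eligible site exists, until the requested count is reached or
the anatomy saturates (warning). Because each plug consumes its RNG
draws sequentially, a larger request reproduces the smaller request's
plugs as a prefix, and identical (config, seed) runs are bit-identical.

## Intensity transfer

`find_companion_vessel()` picks, among connected vessel components
within 20 mm of the host branch, the closest one whose estimated radius
is within ±50% of the airway's. "Comparable caliber" is not a quantified
notion in the field; ±50% is a band wide enough to tolerate the
half-voxel uncertainty of mask-based radius estimates yet narrow enough
to exclude vessels of a different generation. Failure raises a typed
condition and the plug falls back to nearest-depth sampling from the
whole vessel mask, flagged per voxel.

`transfer_intensities()` matches each plug voxel to a vessel voxel with
signed distance within 0.5 mm of its own (ties broken uniformly at
random under the run seed) and copies the HU. The 0.5 mm tolerance is
half a default voxel: digital grids rarely contain an exact depth match,
and a tighter tolerance would starve deep voxels of candidates. When the
airway is deeper than its vessel (wide lumen, narrow vessel), the deepest
plug voxels have no candidate within tolerance; they draw from the
vessel's deepest available pool and are flagged `fallback` in the
correspondence map, which is exportable for QC. Voxels outside the plug
are bit-identical to the input — tested across the whole volume.

The tested fidelity contract: on a noise-free, reconstruction-blurred
phantom, the two-sample KS distance between depth-stratified plug HU and
companion-vessel HU (1 mm depth bins, ≥40 samples a side, non-fallback
correspondences) stays below 0.35. The residual distance reflects the
±0.5 mm depth smear of the matching tolerance, not a bias.

`apply_augmentation()` draws a Gaussian smoothing σ (0–0.8 mm) and a
noise σ (0–10 HU) uniformly per call, emulating reconstruction-kernel
and dose variability; it is applied per patch at dataset-build time so
augmentation stays dynamic rather than baked into saved volumes.

## Dataset building

`resample_isotropic()` targets 0.8 mm isotropic spacing — the training
resolution the pipeline standardizes on — with trilinear interpolation
for images and nearest-neighbour for masks/labels (labels stay
integral). The output grid keeps the origin and preserves world extent
to within one voxel. Plug volume is preserved within 15% by resampling
for plugs ≥3 mm long in airways ≥3 mm caliber; thinner plugs are
quantization-limited (a one-voxel-thick structure cannot round-trip
through a 1.0→0.8 mm grid with bounded relative volume error), which is
a stated limitation rather than a defect.

`extract_balanced_patches()` samples patch batches at an exact
positive:negative ratio (1:1 default; the ratio is a free parameter of
the protocol, not a published constant), positives centred on plug
voxels, negatives on lumen-containing plug-free locations. The default
patch edge of 96 voxels at 0.8 mm (~77 mm) contains the largest plugs
(20 mm ≈ 25 voxels) with generous context. `export_dataset()` writes
NIfTI image/label pairs plus a JSON manifest and per-case plug CSVs;
round-trips are bit-exact.

## Evaluation protocol

* **Dice** 2|A∩B|/(|A|+|B|); both-empty is defined as 1.0 (perfect
  agreement on absence — the raw formula is 0/0) and flagged via an
  attribute.
* **Matching**: one voxel of overlap suffices for a true positive; a
  predicted component overlapping k ground-truth lesions credits each of
  the k (lesion-level recall semantics) while counting once itself;
  components use 26-connectivity, matching the growth connectivity.
  Matching is verified against brute-force pair enumeration on
  1000 random volumes.
* **Stratification**: length bins (0,3), [3,6), [6,15), [15,∞) mm.
  False positives have no ground-truth length, so they are binned by the
  predicted lesion's own principal-axis extent, each FP in exactly one
  bin. Sensitivity CIs use the Wilson score interval (via
  `prop.test(correct = FALSE)`; Clopper–Pearson available by config) —
  the score interval reproduces published interval widths at cohort
  scale (e.g. 1375/1643 → 0.818–0.854) and holds ≥93% empirical coverage
  across the operating points tested.
* **Paired comparison**: classical paired two-sided t-test per scan.
  Degenerate inputs are surfaced, not silently scored: identical vectors
  give t = 0, p = 1; nonzero constant differences return a flagged
  degenerate result. The test holds its nominal 5% type-I error in a
  10⁴-replicate null simulation at n = 98.

## The density-sweep harness

`run_density_sweep()` reruns the synthesis→detection→scoring loop for
plug counts 10–100 per scan against any detector callback. The package
ships a perfect oracle (returns ground truth; sensitivity 1.0, 0
FP/scan, an upper-bound sanity check) and a degraded oracle that misses
small and random lesions and injects spurious blobs, which exercises the
full metric path without any trained network. The harness reproduces the
*shape* of a density calibration; absolute values on phantoms are not
clinical results.

## Problem sizes and numerical choices

The test suite runs on 48³–80³ phantoms with 10–50 plugs per scan, 50
random masks ≤16³ for the distance-transform oracle, 10³ random volumes
for the matching oracle, and 10⁴ simulated t-tests — sizes chosen so the
full suite completes in about a minute while every contract is exercised
at meaningful scale. The cohort-count check runs the full 83 phantoms ×
50 plugs. Seeds are explicit everywhere; any function that consumes
randomness takes a `seed` argument and restores the caller's RNG state.

Known limitations: straight-branch phantoms only; one companion vessel
per branch; no sub-voxel surface model (all areas/volumes are voxel
counts); truncation skews realized plug lengths on small anatomies; and
CLI YAML configs expose only scalar/vector parameters, not per-branch
overrides.
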