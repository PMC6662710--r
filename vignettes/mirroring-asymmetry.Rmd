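---
title: "Quantifying 3D facial asymmetry by mirroring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D facial asymmetry by mirroring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`facesym` treats a craniofacial structure as a binary voxel mask on an
isotropic grid and measures its bilateral asymmetry about a reference
plane by mirroring. The procedure is:

1. binarize the Hounsfield-unit volume in a closed band (bone 320–520 HU,
   soft tissue −480 to −360 HU — inclusive at both ends, since the
   thresholds are printed as closed ranges);
2. fill interior holes (background components not 6-connected to the grid
   boundary) and apply a morphological closing with a spherical
   structuring element of radius 10 voxels, which seals the thin-walled
   condylar heads that open up under bone thresholding;
3. split the mask into two halves by the reference plane;
4. reflect the left half through that plane and superimpose it on the
   right half — no re-registration of any kind follows the reflection, so
   the statistic measures asymmetry *about the chosen plane*, not residual
   shape difference after optimal alignment;
5. report the Sørensen–Dice similarity index
   `SI = 2|A∩B| / (|A|+|B|)` and the non-overlapping volume
   `NOV = |A|+|B| − 2|A∩B|` (the symmetric difference), which satisfy
   `SI = 1 − NOV/(|A|+|B|)` exactly in integer voxel arithmetic.

Two reference planes are built from landmarks (`reference_planes()`): the
mandibular median plane (AMP) through menton, supramentale, and the genial
tubercle, capturing intrinsic structural asymmetry; and the facial
midsagittal plane (MSP) through nasion and sella perpendicular to the
Frankfort horizontal plane, additionally capturing displacement and
rotation of the mandible relative to the face. The non-overlap mask can be
further sectioned into ramus and body contributions by the plane through
the gonion midpoint and the lateral/medial junction points
(`segment_distribution()`).

### Orientation conventions

All plane normals are oriented deterministically so that signs carry
anatomical meaning: the MSP normal points toward the patient's left (the
left porion has positive signed distance), the FHP normal points
superiorly (nasion positive), the AMP normal is co-oriented with the MSP
normal, and each sectioning plane's normal points toward its condyle
(ramus positive). A positive signed distance of the menton therefore means
"deviates left", which makes the Dev-side determination a sign test
(`assess_deviation()`); subjects qualify for the asymmetry analysis when
the deviation strictly exceeds 4 mm (`>`, not `>=`). After
`reorientation_transform()` the world frame is +x patient-left,
+y anterior, +z superior, with nasion (which lies on the MSP by
construction) mapped to x = 0, y = 0.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| bone band | 320–520 | HU | closed interval; the upper bound excludes the densest cortical bone, implemented as printed |
| soft-tissue band | −480 to −360 | HU | closed interval |
| closing radius | 10 | voxels | discrete Euclidean ball {v : \|v\| ≤ r}; radius is in voxels, not mm |
| deviation threshold | 4 | mm | strict inequality for inclusion |
| surface mode | `face_count` | — | see below |
| mirroring interpolation | `nearest` | — | `linear` (trilinear + 0.5 threshold) available |
| voxel spacing | from the data | mm | isotropic only; anisotropic grids are rejected |

### Surface area: two estimators

The boundary-length-times-voxel-size formula used in the field is
dimensionally ambiguous, so two estimators are exposed. `face_count`
(default) counts foreground voxel faces adjacent to background and
multiplies by spacing²; it is a well-defined discrete surface measure and
equals `2(ab+bc+ca)·s²` on an a×b×c box. `slice_perimeter` sums the
per-axial-slice boundary length in voxel edges times spacing², the literal
reading of the formula; the slicing axis is assumed axial (z). When a mask
is produced by cutting a structure with a plane, the flat cut face is an
artifact of the sectioning, not anatomy; `exclude_cut_surface = TRUE`
(default) removes boundary faces whose centers lie within half a voxel of
the cutting plane and whose face normal aligns with the plane normal. The
exclusion is applied uniformly to hemi and segment surfaces — the source
protocol states it only for soft tissue, but leaving the cut face in
would inflate every bilateral surface comparison by the (identical) cut
area, so uniform exclusion is the package's default, with the flag to turn
it off.

## Numerical choices

- **Morphology by exact distance transform.** Dilation and erosion by the
  discrete ball are computed from an exact 3D squared Euclidean distance
  transform (Felzenszwalb–Huttenlocher, implemented in C++):
  `dilate(X) = {p : d²(p, X) ≤ r²}` and `erode(X) = {p : d²(p, Xᶜ) > r²}`.
  This is exact for integer radii — no ball rasterization or separable
  approximation — and is verified in the tests against brute-force
  set-arithmetic dilation/erosion. The grid is padded by 2r background
  voxels before closing and cropped afterwards, which makes the result
  identical to closing over an unbounded background (padding by r alone
  can overfill near the grid edge).
- **Splitting tie-break.** Voxels whose centers lie exactly on the
  splitting plane go to the positive side, making the partition
  deterministic; the two halves always partition the input exactly.
- **Mirroring.** Each output voxel center is reflected through the plane
  and the input is sampled with nearest-neighbor interpolation, which
  preserves binary values without a threshold choice. When the mirror
  plane is a grid mid-plane orthogonal to an axis the operation reduces to
  an exact index flip and is an exact involution; for oblique planes the
  resampling error is below 2 % in volume on a 40³ sphere (tested).
  Trilinear interpolation with a 0.5 threshold is available as an option.
- **Degenerate inputs.** Collinear plane-defining points, anchor
  directions parallel to the reference normal, non-perpendicular
  FHP/MSP pairs (tolerance 10⁻⁶ rad, far below landmark placement noise),
  inverted HU bands, anisotropic spacings, and empty masks all raise
  informative errors; an empty binarization result and an empty
  non-overlap mask warn instead of failing, and a structure lying entirely
  on one side of the reference plane yields SI = 0 with a warning.

## The phantom generator

`make_mandible_phantom()` emulates the inputs of a CBCT-based asymmetry
study: a horseshoe-shaped body (half-annulus slab, arc radius 34 mm) with
two vertical rami (height 42 mm) topped by spherical condylar knobs, a
soft-tissue shell grown by distance transform, HU values strictly inside
the binarization bands (bone 420, soft −420, background −1000; optional
Gaussian noise, default off so thresholding is exact), and landmarks
placed analytically from the parametric construction. The default grid is
108×66×68 voxels at 1 mm spacing, chosen so the full pipeline — including
the radius-10 closing — runs in about a second per scan; the midsagittal
plane falls on a grid mid-plane (no voxel centers on the plane), so a
symmetric phantom is *exactly* mirror-symmetric in voxel space and its
similarity index is exactly 1. The phantom is roughly half clinical scale
(ramal/body lengths ≈ 45/49 mm against typical adult values of ≈ 60/90 mm);
topology and landmark geometry, not anatomical realism, are the goal.

Asymmetry is parameterized and applied to the right side only, so ground
truth is unambiguous: a per-axis scale and a yaw about the vertical axis
deform the right hemi-mandible about the midline, and a whole-mandible
lateral shift displaces the menton off the MSP (the shift sign fixes the
Dev side a priori). Landmarks are transformed with the same affine map as
the voxel model. `make_cohort()` draws per-subject parameters — |shift| ~
U(4.5, 8) mm with random sign (every T1 subject exceeds the 4 mm
inclusion threshold), right vertical scale ~ U(0.78, 0.95), yaw ~
N(0, 2°) — and sets T2 = identity + (T1 − identity) × reduction
(default 0.5), emulating surgical correction that halves the asymmetry.

What the phantom does **not** emulate: partial-volume intensity gradients,
scanner noise texture and beam hardening, cortical/trabecular HU contrast,
dentition and maxilla, landmark placement error (landmarks are exact by
construction), and the seam that a scale discontinuity introduces at the
midline (cleaned up by the closing step). Tests passing on phantoms
therefore validate the geometry, morphology, and statistics of the
pipeline — not segmentation robustness on clinical scans.

## Statistics layer

`paired_t()` and `pearson_cor()` wrap the standard `stats` tests and are
cross-checked in the test suite against hand-computed formulas.
`icc_agreement()` implements the two-way random-effects,
absolute-agreement, single-measure intraclass correlation (ICC(2,1)):
the common choice for repeat-digitization reliability, adopted here as a
documented assumption since reliability protocols often omit the variant.
`build_cohort_tables()` reproduces the analysis pattern of a surgical
cohort: Dev vs N-Dev paired comparisons per timepoint, T1 vs T2 paired
comparisons of NOV and SI, and the SI × NOV correlation matrix. No
multiple-testing correction is applied by default (matching the analysis
pattern the package reproduces); `holm = TRUE` enables a Holm adjustment.
Normality screening is intentionally omitted: it gates nothing in the
synthetic setting.

Because `SI = 1 − NOV/(|A|+|B|)` per subject, the SI–NOV correlation is
exactly −1 whenever `|A|+|B|` is constant across a cohort, and remains
strongly negative (r < −0.9 in the tests) when the total volume varies by
less than about 5 %. When subjects' total volumes vary more — e.g. when
the asymmetry includes a volumetric scale component — the attenuation can
be substantial; this is a property of the index itself, worth keeping in
mind when comparing cohorts of heterogeneous size. Note also that cohort
*means* of SI and NOV need not satisfy the per-subject identity (a mean of
ratios is not a ratio of means), so published summary tables cannot be
inverted through the identity.

## Problem sizes and runtimes

The test suite runs phantoms at 72×46×48 with closing radius 3 (about
0.2 s per scan) and the full default geometry for the end-to-end checks;
the synthetic cohort used for the treatment-effect check is 20 subjects ×
2 timepoints at the default 108×66×68 grid with radius-10 closing, about
90 s total. Brute-force oracles (set-arithmetic morphology, per-voxel
overlap and face counting) run on grids up to 16³, where they are
feasible and exhaustive enough to pin down off-by-one errors.

## Known limitations

- Clinical cohort values from patient CBCT data are out of reach by
  construction; the package reproduces measurement *definitions* and
  qualitative cohort behavior on phantoms, not published clinical means.
- Mirroring about the AMP is sensitive to the plane's angle: small
  landmark perturbations of the three defining points can move the
  mirrored half considerably. This is a property of the method, not of
  the implementation.
- No mesh-based surface area (marching cubes); the face-count estimator
  overestimates the area of oblique surfaces by up to a factor √3.
- No landmark-free (voxel-based) median plane and no ICP re-registration
  after mirroring — both would change the statistic being computed.
- NRRD and DICOM-series input are not supported; convert to NIfTI first.
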