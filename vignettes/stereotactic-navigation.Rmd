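---
title: "Stereotactic coordinate navigation: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereotactic coordinate navigation: model, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereonav)
```

## The problem

A stereotactic procedure runs in four coordinate systems simultaneously.
Targets are planned in **anatomical** (mid-commissural) space, whose
origin is the midpoint of the segment joining the anterior and posterior
commissures (AC, PC), AP axis along PC→AC, midline plane at LAT = 0.
Imaging with an N-localizer yields the same landmarks in **frame** space.
The surgeon operates dials in **head-stage** space, whose axes rotate with
the ring and arc settings. Review happens in **atlas** coordinates, world
millimetres tied to screen pixels of printed sections. `stereonav` is the
geometry connecting them; it assumes landmarks are already localized
(no image processing) and that the frame is isocentric (target-centered).

## Conventions that carry everything

- **Storage order is `(AP, LAT, VERT)`**, signs + anterior / + right /
  + superior, because planning stations and the worked surgical records
  the package reproduces all print coordinates that way.
- **Rotation formulas use math order `x = LAT, y = AP, z = VERT`** (RAS).
  The permutation between the two orders is a self-inverse swap of the
  first two components (`to_math_order()`); rotation matrices move
  between orders by conjugation with that permutation.
- **Angles are degrees at the API**, radians internally. Elemental
  rotations place `+sin` above the diagonal — `R_x(90°)` maps math-order
  `(0, 1, 0)` to `(0, 0, −1)` — and this sign convention is load-bearing:
  it is what makes the printed worked examples reproduce.
- All spaces are metric millimetres, so rigid conversions carry no
  scaling. The only scaling in the package is the deliberate one-axis
  AP normalization for atlas overlay.

## The three-point registration

`build_3pt_transform()` constructs the frame↔anatomy rotation from AC,
PC, and a midline (falx) point. The AP basis vector is the unit vector
from the commissural midpoint to AC; LAT is the normalized cross product
with the midpoint→falx vector; VERT completes the right-handed triad.
Two design points:

- **Above/below detection is automatic.** Whether the midline point lies
  above or below the AC-PC line is judged by the VERT sign of its
  component perpendicular to the line *in frame coordinates*; if below,
  the cross-product order is swapped. Detecting this from the constructed
  basis itself is impossible — the completed triad always gives the falx
  a positive VERT image by construction — so the test must precede the
  choice of order. No user flag exists; the decision is recorded on the
  returned object (`falx_below`).
- **Direction labelling is explicit.** The printed 3×4 report form of a
  registration is the anatomy→frame map (linear `Rᵀ`, translation
  `P_M′`); `as_affine()` labels direction in the object and the CLI
  prints it, because transposed-direction mislabeling is the classic
  failure mode of these reports.

The least-squares alternative (`fit_affine_landmarks()`) is deliberately
an *unconstrained* per-axis OLS: the worked planning data show squared
row norms like 1.000711, proving the reference computation did not
constrain to a rotation. A rigid (orthogonal Procrustes) mode exists but
is not the default. Note the diagnostics report the **squared** row norm,
because that is the quantity such reports print (for a rigid map both are
exactly 1, so the distinction only matters for the OLS fit).

## Head-stage kinematics and targeting error

Dial conversion is frame-specific: on a CRW the ring dial is offset 90°
from the sagittal angle and the unsigned arc dial takes the sign of the
side (+ right, − left). The signed angles, not the dials, are canonical
in the API; `assembly_flipped` negates both for reversed apparatus
assemblies (default off — it matches all recorded examples). The
combined rotation `W = R·R_xy` gives the two workhorse operations
`X_n = X_c + W·Δ` and `Δ = Wᵀ·(X_t − X_c)`; frameless systems reuse the
same code path with `reg = NULL`, making `W = R_xyz` from anatomical
angles.

Printed dial angles carry 0.1° precision, which propagates to roughly
0.01–0.02 mm in recomputed head-stage deltas; the tests assert at
0.02 mm where dial-rounded inputs are involved and at 5×10⁻⁴ mm where
the angles happen to be near-exact. The Euclidean error is
dial-independent (rotations preserve norms) and is asserted tightly.

Radial/depth decomposition follows the head-stage axes: radial is the
in-plane `√(ΔAP² + ΔLAT²)`, depth the drive component `|ΔVERT|`. The
Pythagoras identity `radial² + depth² = euclidean²` is enforced as a
property test.

## Trajectory interpolation

Depth fractions `f = d/d_et` outside `[0, 1]` are allowed with a warning:
microdrives routinely overshoot past target, and nothing in the linear
interpolation forbids extrapolation. The inverse query
(`depth_of_closest_point()`) exists to compare a measured electrode point
against a planned line.

## Atlas mapping

Planes are stored with unit normals (offset rescaled), so the
point-to-plane distance has denominator 1 — a pure conditioning choice
with no effect on results. Equidistant slices tie-break to the first
slice in stack order, deterministically.

The 3×3 screen matrix `M = [U V 1]⁻¹·[x y z]` is singular whenever a
slice has a constant-zero world coordinate (an axial section at
VERT = 0). The fallback builds an orthonormal in-plane basis from the
world anchors and solves the 2D affine anchor↔screen map; it degrades to
exactly the same map when `M` is invertible, which is tested as a
property rather than assumed.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_case()` draws a rigid frame pose (tilt up to 15° from
anatomical alignment, mid-commissural origin within ±5 mm — typical
frame-placement misalignment), an AC-PC distance defaulting to 25 mm
(population average is close to 25 mm with ≈1.4 mm SD), canonical targets
at (−3, ±11.5, −3), and adds isotropic Gaussian noise to the frame-space
landmarks to emulate commissure-localization uncertainty on imaging
(default 0; property tests sweep 0–1 mm). It does **not** emulate
anisotropic imaging resolution, brain shift, frame flex, or systematic
localizer bias — so a green synthetic test establishes the geometry is
implemented correctly, not that any clinical accuracy claim holds. The
synthetic axial atlas stack (0.9 mm spacing, identity screen anchors)
emulates the sectioning geometry of a histological atlas only; it carries
no anatomical content.

## Numerical choices

- Collinearity rejection: cross product of the unit landmark vectors
  below 10⁻⁶; AC-PC separation must exceed 1 mm.
- Singularity thresholds: |det| ≤ 10⁻⁹ for affine linear parts and the
  screen matrix; line–plane intersection requires
  |normal·direction| > 10⁻⁹ and distinguishes line-in-plane (infinite
  intersections) from parallel-disjoint.
- Rotation checks: orthonormality within 10⁻¹⁰, norm preservation within
  10⁻⁹ — asserted across every rotation the package produces.
- Display rounding imitates surgical reports (2 decimals for errors,
  5–6 for computed targets); stored and serialized values keep full
  double precision (`digits = NA` in JSON).

## Known limitations

- Non-isocentric frames are out of scope; the frame-model registry
  handles dial sign/offset conventions only.
- The Leksell G entry is implemented from its published sign/offset
  conventions but no printed worked example exists to validate it
  end-to-end.
- A nonzero axial angle γ is supported in `R_xyz` but unexercised by any
  recorded example.
- Atlas navigation is slice-geometric: no volumetric or nonlinear
  atlas-to-brain warping, and no image rendering.
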