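# stereonav

Coordinate navigation for stereotactic neurosurgery in R.

Deep-brain-stimulation and lesioning procedures juggle several Cartesian
coordinate systems at once: the **anatomical** (mid-commissural) space
anchored on the anterior and posterior commissures, the **frame** space of
the rigid stereotactic apparatus fixed to the skull, the **head-stage**
space of the arc/XY-stage/drive platform whose axes rotate with the chosen
trajectory, and the **atlas** world-and-screen coordinates of printed brain
atlas sections. `stereonav` implements the rigid and affine geometry that
moves points, targets, and displacements among all of them, for surgeons,
neurophysiologists, and engineers building or auditing navigation
pipelines.

## The mathematics

All conversions are instances of the affine contract
`X = L·X′ + T` with millimetre units throughout (no scaling for rigid
frame conversions). The core pieces:

- **Three-point change of basis (3PT).** From AC, PC, and a midline falx
  point localized in frame space, the mid-commissural origin is
  `P_M′ = (P_AC′ + P_PC′)/2` and the anatomical basis in frame coordinates
  is `ĵ = v̂₁` (midpoint→AC), `î = v̂₁ × v̂₂` normalized (order swapped
  automatically when the midline point is below the AC-PC line),
  `k̂ = î × ĵ`, giving an orthonormal rotation `R` with
  `X = R·(X′ − P_M′)` and `X′ = Rᵀ·X + P_M′`.
- **Least-squares landmark fit.** With N ≥ 4 pairs, an unconstrained
  12-parameter affine is fit by ordinary least squares (per-axis normal
  equations); an orthogonal-Procrustes `mode = "rigid"` is available.
  Orthonormality/orthogonality diagnostics report the squared row norms
  and pairwise row dots of the fitted linear part.
- **Head-stage kinematics.** Ring/arc dials become signed sagittal and
  coronal angles (`φ = 90° − ring` on a CRW; arc sign follows the side);
  elemental rotations `R_x(φ)`, `R_y(ψ)`, `R_z(γ)` compose into `R_xy`
  (or `R_xyz`), and `W = R·R_xy` carries head-stage displacements straight
  into anatomy: `X_n = X_c + W·Δ`, `Δ = Wᵀ·(X_t − X_c)`. Targeting errors
  decompose into radial (`√(ΔAP² + ΔLAT²)`), depth (`|ΔVERT|`), and
  Euclidean parts.
- **Fixed trajectory.** Drive depth `d` along an entry→target line maps to
  `P = P_e + (d/d_et)·(P_t − P_e)`, plus the inverse closest-point query.
- **Atlas mapping.** Slices are planes `λx + μy + κz + σ = 0` with three
  3D↔2D anchor pairs; closest-slice selection by point-to-plane distance,
  orthogonal projection, line–plane intersection, and the 3×3 screen
  matrix `M = [U V 1]⁻¹·[x y z]` (with an in-plane 2D fallback when `M` is
  singular). A one-axis AP scaling normalizes patient to atlas by the
  AC-PC distance ratio.

Coordinates are stored `(AP, LAT, VERT)` — the order planning stations
print — and permuted internally to the rotation convention
`x = LAT, y = AP, z = VERT`.

## Worked example

The bundled case is a complete bilateral subthalamic-nucleus plan
(CRW frame) with AC `(14.2, 2.9, 2.4)`, PC `(−10.1, 2.1, 5.0)`, and
mid-falx `(9.3, 5.9, 54.2)` in frame space:

```r
library(stereonav)

case <- example_dbs_case()
reg <- build_3pt_transform(landmark_set(case$landmarks$ac_frame,
                                        case$landmarks$pc_frame,
                                        case$landmarks$falx_frame))

anatomy_to_frame(reg, point3(-3, 11.5, -3, "anatomical"))
#> <point3 frame> AP -1.69673  LAT 13.6752  VERT 0.334593

## the anatomical target sits 0.13 mm from the planning station's own value
sqrt(sum((as.numeric(anatomy_to_frame(reg, point3(-3, 11.5, -3, "anatomical")))
          - c(-1.8, 13.6, 0.3))^2))
#> [1] 0.1323705

## intraoperative imaging shows the left electrode here; how far to move?
cur <- frame_to_anatomy(reg, point3(-2.36385, -8.20936, 0.615163, "frame"))
W <- combined_transform_W(reg, crw_dials_to_angles(51.6, 10.1, "left"))
d <- anatomy_target_to_headstage_delta(cur, point3(-3, -11.5, -3, "anatomical"), W)
d
#> <headstage_delta> AP 0.529055  LAT -0.710424  VERT 2.02181 (mm)
targeting_error(d)$radial     #> 0.8857772  — nearly on the planned line,
targeting_error(d)$euclidean  #> 2.207334   — mostly short of depth
```

The first number says: move the stage 0.53 mm anterior, 0.71 mm left, and
advance 2.02 mm — the error is almost entirely along the trajectory.

A CLI wraps the same operations
(`system.file("cli", "stereonav", package = "stereonav")`):

```sh
stereonav fixtures --out case.json
stereonav adjust --case case.json --side left \
  --current -4.40882,-10.3171,-4.21997 --target -3,-11.5,-3
```

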