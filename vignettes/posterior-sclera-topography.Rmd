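---
title: "Posterior scleral topography: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior scleral topography: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleratopo)
```

## The model

`scleratopo` treats the posterior eye wall as a radial surface around a
reference point and asks two questions at every posterior surface point:
*how far is the wall from where the centre of a normal eye would be?* and
*how sharply is it bent locally?*

The reference point is the **hypothetical pre-elongation eye centre**. A
normal emmetropic eye has an axial length of about 24 mm, so its centre
sits about 12 mm behind the corneal vertex. In a myopic, elongated eye the
true globe centre migrates posteriorly with the elongation; placing the
origin 12 mm behind the vertex instead reconstructs where the centre *was*
before elongation, so every measurement reads as deviation from a normal
eye. For a surface point \(p\),

\[ D = \lVert p - o \rVert \quad [\mathrm{mm}], \qquad
   C = 1 / R_{\mathrm{fit}} \quad [\mathrm{mm}^{-1}], \]

where \(o\) is that origin and \(R_{\mathrm{fit}}\) is the radius of the
least-squares sphere through all surface points within 3 mm of \(p\).
\(D > 12\) mm flags elongation or bulging; large \(C\) flags a sharp local
bend; their product \(C \cdot D\) amplifies distance by local distortion
and equals 1 everywhere on a normal 24 mm eye
(\(D = 12\), \(C = 1/12\)).

### The coordinate frame

The pupillary–foveal axis is estimated without fitting the whole (possibly
deformed) surface: a **maximally inscribed sphere** is found inside the
eyeball, and the axis is the line from the corneal vertex (the anterior
surface point most distant from the sphere centre) through that centre.
The inscribed sphere is the key robustness device — a posterior
outpouching only adds volume far from the globe centre, so it cannot move
the sphere (for a prolate spheroid with semi-axes \(a < b\), an axis point
at distance \(y\) from the centre has boundary distance
\(a\sqrt{1 - y^2/(b^2-a^2)}\), uniquely maximal at the centre; a bump only
raises distances elsewhere). The suite verifies that 4 mm posterior bumps
leave the recovered axis unchanged to well under 1.5°.

Eye coordinates place the origin at \((0,0,0)\) with +Y posterior along
the axis, +X temporal (left eyes are mirrored in X so nasal/temporal
compare across laterality) and Z = X × Y (right-handed). All parameters
are computed over the posterior region spanning 120° about +Y, measured
from the origin.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `offset_mm` | 12 | mm | vertex-to-origin distance (normal-eye half axial length) |
| `span_deg` | 120 | deg | full angle of the posterior cone |
| `neighborhood_mm` | 3 | mm | Euclidean ball radius for the local sphere fit |
| `percentile` | 95 | — | robust "maximum" for `D_max`, `C_max`, `CD_max` |
| `target_spacing_mm` | 0.5 | mm | isotropic resampling grid |
| `smoothing_sigma_mm` | 1.25 | mm | Gaussian smoothing before isosurface extraction |
| `grid_res_deg` | 1 | deg | topography map cell size |

The first five are the method's defining constants. The smoothing sigma
deserves its own paragraph.

### Why sigma = 1.25 mm

Two discretisation errors pull in opposite directions. The isosurface of
a 0.5 mm binary mask smoothed with a one-voxel Gaussian still carries
lattice ripple of a few hundredths of a millimetre; that sounds
negligible, but the 3 mm sphere-fit neighbourhood has a sagitta of only
\(h^2/2R \approx 0.37\) mm on a 12 mm sphere, so ripple at a wavelength
comparable to the neighbourhood aliases directly into the fitted
curvature — on a voxelized 12 mm ball the 95th percentile of
\(C \cdot D\) lands at ≈ 1.08 instead of 1 with one-voxel smoothing.
Heavier smoothing suppresses the ripple but shrinks a convex surface
inward by roughly \(\sigma^2 \kappa\), and that bias enters the distance
twice (the posterior surface moves anteriorly *and* the vertex-derived
origin moves posteriorly). At \(\sigma = 1.25\) mm (2.5 voxels) both
errors sit comfortably inside their budgets: \(C \cdot D_{max} \approx
1.04\) on the voxelized ball, and the per-point distance stays within
half a voxel (≈ 0.45 mm worst case) of the analytic ground truth. Users
analysing finer grids can lower `sigma` proportionally.

## Numerical choices

- **Isosurface vertices.** The 0.5-level crossings of every grid edge of
  the smoothed field, linearly interpolated — the marching-cubes vertex
  set. Triangles are never needed: everything downstream consumes the
  point cloud. Normals come from the field gradient, oriented outward.
- **Resampling.** Masks are interpolated linearly on an isotropic target
  grid and re-thresholded at 0.5. Target cells tile the source extent from
  the same lower cell edge; with aligned grids a naive shared-origin
  convention puts half the boundary samples exactly at the 0.5 level and
  systematically dilates the mask (≈ +4 % volume on a 10 mm ball when
  downsampling 1 mm slices) — the cell-tiling convention avoids the ties
  and preserves volume to ≈ 0.5 %.
- **Inscribed sphere.** Exact squared Euclidean distance transform
  (separable lower-envelope sweeps, anisotropy-aware), then Nelder–Mead
  maximisation of the distance to the surface point cloud from the
  near-maximal plateau centroid. The radius is by construction the minimum
  distance from the centre to the surface cloud.
- **Corneal vertex.** On a smooth anterior surface (the phantoms have no
  corneal bulge) the distance-from-centre function is nearly flat near its
  maximum, so a plain argmax snaps to an arbitrary lattice point and
  flutters by half a voxel between discretisations — enough to swing the
  axis by ~3°. The estimator instead averages the near-maximal candidates
  (within 0.25 mm, half a voxel, of the maximum): the vertex is placed
  along their mean direction at their mean distance. On an exact-tie
  surface (a sphere) the anterior hint selects the hemisphere and the
  result is deterministic.
- **Sphere fit.** Algebraic (linearised) least squares, then Gauss–Newton
  on the orthogonal residuals iterated to convergence. The one-shot
  algebraic solution is catastrophically biased on shallow noisy caps
  (on a 3 mm cap of a 14 mm sphere with 0.1 mm noise it underestimates the
  radius by ~4 mm, i.e. overestimates curvature by ~30 %); the converged
  orthogonal fit is unbiased there. Neighbourhoods with fewer than 10
  points are flagged and excluded from every downstream statistic (never
  imputed); rank-deficient or larger-than-1000 mm fits are clamped to the
  1000 mm planarity cap and flagged.
- **Percentiles and variance.** Percentiles interpolate linearly between
  order statistics (R type 7); `D_var` uses the population (1/N)
  denominator — it is a shape descriptor, not an inferential estimate.
  Both are configurable.
- **Partial AUC.** The empirical ROC is integrated by trapezoids on its
  vertices over false-positive rate in \([0, 0.15]\) and divided by 0.15;
  ties enter as diagonal segments (Mann–Whitney ½ convention). The chance
  diagonal therefore scores exactly \(0.15^2/2 / 0.15 = 0.075\).

## The phantom generator

Validation runs on synthetic eyes with exact ground truth: a base
ellipsoid plus a Gaussian angular protrusion,

\[ r(u) = r_{\mathrm{ellipsoid}}(u) + A \exp\!\big(-\psi(u)^2 / 2\sigma_b^2\big), \]

with \(\psi\) the angle between direction \(u\) and the bump direction.
Directions are sampled on a Fibonacci lattice (quasi-uniform, so
spherical-cap fraction checks are tight); volumes are voxelized by inside
test. The default morphologies are: Type 0 — semi-axes
(11.5, 12.5, 11.5) mm, no bump; Type 1 — (11, 14.5, 11) mm with a 1.5 mm
posterior bump of 25° width; Type 2 — (11, 16, 11) mm with a 3 mm bump
25° temporal of the pole, 15° wide. Cohorts jitter semi-axes by ±5 % and
amplitude by ±20 % (seeded). Coordinate noise defaults to zero: the
voxelization pathway supplies realistic discretisation noise, and the
analytic pathway is meant to probe exact limits.

What the phantoms *do not* emulate: corneal curvature distinct from the
sclera, segmentation errors (holes, leaks), partial-volume intensity
effects, and multi-lobed or nasally-dragged staphylomas outside the
single-bump family. Passing tests therefore demonstrate correctness of
the geometry pipeline and the qualitative Type separation on idealised
globes, not clinical performance on real MRI.

## Desk-scale validation sizes

The test suite runs the full volume pathway at the reference 0.5 mm grid:
single phantoms use ~88³ volumes (~10⁴ surface points, ~3–4 × 10³
posterior points), the cohort experiment uses 30 phantoms (10 per type,
seed 42), and analytic-surface runs use 8–20 × 10³ points. These sizes
were chosen so every validation claim is exercised at the same spacing the
method is defined at while the whole suite stays desk-scale.

## Known limitations

- Curvature from a 3 mm cap is intrinsically noise-sensitive: with
  independent 0.1 mm point noise at realistic sampling density (~230
  points per cap) even an unbiased orthogonal fit has ~1 mm radius
  scatter on a 14 mm sphere. The smoothed-volume pathway keeps surface
  noise an order of magnitude below that, and the percentile-based maxima
  damp what remains; point clouds from other sources should arrive
  denoised.
- The corneal vertex assumes the segmentation includes the anterior
  globe; masks truncated at the equator will mis-place the axis.
- `D_var` and `CD_max` are anchored on the 12 mm offset; in eyes whose
  pre-myopic size differed substantially from 24 mm the normal-eye
  reference values (0 and 1) shift accordingly.
- The percentile-based tail statistics (`c_max`, `cd_max`) are the most
  grid-sensitive outputs: re-discretising a sharp protrusion on a
  different voxel grid moves them by a few percent while the means and
  `d_var` move by well under 1 %.
- Laterality cannot be inferred from the mask; supply it (`OD`/`OS`) when
  nasal/temporal asymmetry matters.
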