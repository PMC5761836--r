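---
title: "Methods: linear-static FEA of developing jaws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-static FEA of developing jaws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devFEA)
```

## The model

devFEA solves small-displacement linear elasticity on labeled tetrahedral
meshes: the equilibrium system `K d = P`, with `K` assembled from 4-node
constant-strain tetrahedra (TET4), `d` nodal displacements, and `P` the
muscle load vector. The linear-static idealization assumes linearly
elastic materials, negligibly small deflections, boundary conditions that
do not change under load, and time-invariant forces. All of these are
deliberate: the workflow's purpose is within-series comparison of forces,
orientations and stress locations across developmental stages, not
absolute prediction of deformation in any one specimen.

TET4 elements over-estimate stiffness relative to higher-order elements.
We accept this because every quantity the package reports is compared
within the method — between stages, between load conditions, between
geometries meshed the same way — mirroring the held-constant-properties
argument: if material properties and element type are identical across
the series, the locations and relative magnitudes of stress are
meaningful even where absolute values carry discretization bias.

Units are fixed package-wide at mm, N and MPa. This makes specific
tension (N·mm⁻²) and stress (MPa) share a unit and removes every
conversion from the stiffness assembly.

## Muscle loads

A muscle's maximal isometric force is `PCSA × specific tension`, with
2.5 N·mm⁻² the default specific tension (the literature value for
pharyngeal jaw muscles). For a bilateral pair the PCSA is averaged between
sides and the averaged magnitude applied to each side. The pull direction
is the unit vector from the insertion-area centroid to the origin-area
centroid; centroids are unweighted means of the member node coordinates
(the averaged-nodal-coordinates rule, taken literally). An area-weighted
variant would emphasise large facets, but attachment areas in segmented
larval meshes are small and nearly uniform, and the unweighted mean is
what the upstream segmentation workflow produces — so area weighting is
not applied. The total force is divided *equally* among the insertion
nodes (100 μN over 200 nodes → 0.5 μN per node). Distribution over the
full attachment area, rather than a single node, avoids spurious
deep-penetrating stress near the load — the package's
single-node-versus-distributed test demonstrates exactly this contrast,
with far-field stresses agreeing within 5% and near-field stresses
strictly exaggerated by the single-node load.

The sign convention is that muscles pull the structure toward their
origin (insertion → origin); the upstream description fixes only the
difference of centroids, not its sign, and the pulling convention is the
physically meaningful one for contraction.

Muscles that insert on structures outside the mesh (the lower-jaw sling:
levator externus 4 and levator posterior) are modeled as loads applied at
their contact areas on the meshed structure, fully transmitted during
biting.

## Orientation angles

The canonical anatomical frame is +x lateral (right), +y rostral,
+z dorsal. Nothing upstream fixes global axes; this choice makes the
three-axis angle conventions computable. With `l` the outward-lateral
component (+x for right and median structures, −x for left — folding the
bilateral mirror into the angles), `r` rostral and `d` dorsal:

* RCA = atan2(|d|, |l|), 0° lateral → 90° dorsal;
* MLA = atan2(d, r), 0° rostral, 90° dorsal, 180° caudal;
* DVA = atan2(r, |l|), +90° rostral, 0° lateral, −90° caudal.

Ventral-pointing directions give negative MLA (the range extends below
0°) rather than being reflected into [0°, 180°]; reported pharyngeal
muscle tables never need the extension, so the choice is documented here
rather than silently applied. Pair angles are computed per side and then
averaged component-wise; on an exactly mirrored pair the two sides agree
to round-off, so averaging is the identity there.

## Constraints, reactions, and the two-step analysis

The contact nodes shared with the neurocranium are fully fixed
(all three translations). Constraints are applied by row/column
elimination — the reduced system is solved and reactions recovered as
`K d − P` on the fixed freedoms — so reactions are exact rather than
penalty approximations, and the net model force (applied + reactions)
vanishes to solver precision.

Step one solves all muscles at full force and reports the neurocranium
reaction resultant, the bite force (the resultant magnitude of the
unreduced sling loads; no lever-arm geometry is available or assumed),
and the von Mises hotspot.

Step two removes anterior–posterior sliding. The net AP
(rostral-axis) reaction is affine in the scale `s` of the chosen muscle
pair, so two solves give the zeroing scale
`s* = −AP_without_pair / AP_pair` in closed form; a bisection on the
solved AP reaction confirms it to 1e-10 in the test suite. The literal
printed relation `X = (F_total − F_old)/F_old` is computed alongside on
the signed applied AP components. Global equilibrium makes the net AP
reaction equal minus the net applied AP force, hence `s* = −X`
identically: the literal relation and the verbal goal ("no
anterior–posterior sliding") cannot both be taken at face value, so the
pipeline applies `s*`, logs `X` beside it, and reports their residual
discrepancy rather than asserting either as the authors' intent. The
"anterior–posterior" axis is the frame's rostral axis (+y). Both the
patch-normal projection and the global dorsal projection of the reduced
contact force are reported, since the two coincide only for a flat dorsal
patch.

Bite force and the stress field are taken from the *unreduced* step-one
solution by contract: biting benefits from shearing and requires no
static compression.

## Hotspot rule

The reported stress hotspot is the maximum per-element von Mises stress
excluding all elements within one ring of the insertion and contact node
sets. This replaces case-by-case visual outlier screening with a
reproducible rule: elements directly under discrete nodal loads or fixed
nodes carry singular, mesh-dependent stress that is an artifact of
discrete load application, and one element ring is the smallest
neighbourhood that removes them. Stress is reported per element
(constant within a TET4); any nodal averaging is for visualization only
and never enters metrics.

## Numerical choices

* Sparse symmetric assembly (Matrix package), Cholesky factorization of
  the reduced system, factor reuse across the load combinations of the
  two-step analysis. At the package's phantom sizes (10³–10⁴ elements,
  ≤ 3×10⁴ freedoms) a direct solve is fastest and exact; iterative
  methods become attractive only far above this range.
* The admissible relative residual of a solve is 1e-8; the Cholesky
  route typically achieves 1e-12 or better, and a warning is raised if
  the tolerance is exceeded.
* Element volumes come from the signed determinant; non-positive volumes
  are reported as inverted elements and refuse to assemble. Duplicate
  nodes are flagged within 1e-9 mm. Meshes are never auto-repaired:
  validation reports, the user decides.
* Prescribed non-zero displacements are supported on constrained nodes
  (used by the uniform-strain patch test, which the TET4 implementation
  reproduces to 1e-8).
* Node indices are 1-based throughout, the native indexing of R; the
  VTK reader/writer translates that format's 0-based connectivity on
  ingest/export.
* Principal stresses use the symmetric eigensolver of base R per
  element; values are sorted descending with orthonormal direction
  triples.

Default materials are bone at 3670 MPa — the low end of the published
fish-bone range of 3.67–8.40 GPa, appropriate for juvenile, fully
bone-covered jaws — teeth at 70 GPa (young teeth), and Poisson's ratio
0.3 for both, all overridable per region tag.

## The phantoms and what they do (and do not) show

No scan data are deposited with the workflow, so the package ships
deterministic generators instead of fixtures:

* **Bars** (`make_bar`): structured prisms with end-face node sets, for
  analytic validation. The closed form δ = FL/(EA) assumes free lateral
  contraction, which a fully clamped end violates when ν > 0, so the
  analytic bar checks run with ν = 0 and area-consistent (tributary-area)
  end loads; under those conditions the linear field is exactly
  representable and the TET4 solution matches the closed form to
  round-off. The muscle-style equal division is used everywhere else.
* **Jaw phantom** (`make_jaw_phantom`): two tooth-capped lobes joined by
  a thinner midline bridge, a flat dorsal contact patch on the bridge
  roof, and three bilateral muscle pairs with explicit dorsal origin
  points. It is built as a half-domain and mirrored, so nodes *and*
  connectivity are exactly bilaterally symmetric (the FE mirror-symmetry
  tests rely on this). The bridge is the engineered weak zone: the load
  path from both lobes crosses its reduced section, so the
  excluded-zone hotspot lands there, the analogue of the inter-lobe
  junction of a real paired jaw. Default size 1.2 × 0.8 × 0.4 mm and
  placeholder PCSAs (0.010–0.016 mm² per muscle, 2.5 N·mm⁻² tension)
  put total loads near 0.2 N and contact forces in the 0.01–0.1 N range
  of larval jaws — physiologically plausible magnitudes, not a
  reproduction of any specimen. The retractor dorsalis pair pulls
  dorso-caudally against the dorso-rostral sling, giving the AP balance
  that the sliding-removal step needs (its zeroing scale is ≈ 0.71 at
  default settings).
* **Growth series** (`make_growth_series`): cumulative per-axis scaling
  of the base phantom, 1.26 per axis per stage by default (volume
  doubling per stage, the magnitude of early larval growth spurts).
  PCSA scales with the product of the two factors transverse to each
  muscle's line of action; "transverse" is resolved as the two axes
  orthogonal to the dominant component of the base-stage direction — a
  deterministic rule that reduces to the isotropic case exactly.
  Isotropic growth therefore changes no angles and no stresses
  (force/area is scale-free), giving a clean null baseline; anisotropic
  dorsal growth rotates every muscle monotonically toward dorsal.

What passing tests on these phantoms show: the solver, load model,
reduction step and reporting are correct on geometries where ground truth
is computable. What they do not show: realistic cichlid anatomy, real
attachment geometries, measured PCSAs, or the specimen-specific forces
and stresses of any published series — those require scan-derived meshes,
which users supply through the mesh readers.

Default problem sizes were chosen for desk-scale reproducibility: the
default jaw phantom has 13 824 elements (≈ 11 000 freedoms, ~3 s per
two-step analysis), and the test suite uses the 1 728-element variant
wherever full resolution adds nothing to the property under test.

## Known limitations

* TET4 stiffness over-estimation (see above); no higher-order elements.
* No contact mechanics at the joint: the contact patch is bonded
  (fixed), so tangential reactions are carried rather than slipping —
  the motivation for the sliding-removal step.
* No geometric or material nonlinearity, no transient dynamics, no
  muscle activation dynamics.
* Mesh I/O covers pragmatic dialects of MSH 4.1 / legacy VTK / INP
  (nodes, TET4 elements, region tags, node sets, scalar fields), not the
  full format specifications.
* PCSA is an input; the package does not measure it from images, and
  segmentation/meshing upstream of the readers is out of scope.
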