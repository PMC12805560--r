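---
title: "From SMILES to 3D models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From SMILES to 3D models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molforge)
```

`molforge` turns SMILES line notation into exportable 3D molecular models.
This vignette explains the science and the numerical choices behind each
stage, what the defaults mean, and where the package's documented
approximations lie.

## The molecular graph

SMILES encodes connectivity only: atoms, bonds, ring closures, branches,
charges. `parse_smiles()` builds that graph directly and **kekulizes on
parse**: aromatic systems are rewritten to alternating single/double bonds
by finding a perfect matching of double bonds over the aromatic atoms that
still have spare valence (pyrrole-type nitrogens, aromatic oxygen/sulfur
and atoms with exocyclic double bonds are excluded from the matching;
backtracking search is exponential in principle but trivial at
teaching-molecule scale). The rationale is that every downstream stage
draws *discrete* bonds — one stick per order unit — so a delocalized
aromatic order would have no renderable meaning here. A system with no
perfect matching (e.g. `c1ccc1`) is rejected as invalid input.

Implicit hydrogen counts follow standard organic-subset valences (B 3, C
4, N 3, O 2, halogens 1, ...), adjusted by formal charge (`[NH4+]` → N
with valence 4, `[O-]` → 1); bracket atoms use their explicit H count.
`add_hydrogens()` appends the hydrogens as real atoms after the heavy
atoms, a property the mesh and layout stages rely on; it is idempotent.

Stereo descriptors (`@`, `@@`, `/`, `\`) are parsed and stored but do not
constrain the embedding — the model generator shows *a* conformation, not
a specific enantiomer, and no wedge/hash rendering exists in a 3D mesh.
This is a documented limitation, not an oversight.

## Conformer embedding

SMILES deliberately contains no geometry, so coordinates are generated
randomly — re-generating the same molecule with a new seed shows a
different chair/twist or chain conformation, which is pedagogically
useful. The embedder is a seeded distance-geometry procedure:

1. **Initialization.** Topological (bond-count) distances, scaled by
   1.45 Å per bond, are embedded in 3D by classical multidimensional
   scaling (`cmdscale`). Gaussian jitter (σ = 0.25 Å, seeded) breaks the
   planarity of rings and chains, without which a flat ring is a saddle
   point of the refinement.
2. **Refinement.** L-BFGS-B minimizes a sum of pairwise harmonic terms:
   * bond lengths target the sum of Cordero covalent radii, scaled by
     1.00 / 0.87 / 0.78 for single/double/triple bonds (C–C 1.52 Å,
     C=C 1.32 Å; weight 100);
   * 1–3 distances encode ideal angles at each center — 109.47° for
     four-coordinate or saturated centers, 120° where a double bond or
     three neighbors make the center trigonal, 180° at triple bonds or
     cumulated doubles (weight 30);
   * one-sided repulsion keeps pairs three or more bonds apart at
     ≥ 0.7 × the sum of their van der Waals radii (weight 20).
3. **Orientation.** A seeded uniform random rotation, then translation of
   the centroid to the origin.

Equal `(graph, seed)` give bit-identical coordinates (the RNG state is
saved and restored, so embedding never perturbs the session); different
seeds give different conformations and orientations. A refined geometry is
accepted only if every bonded pair lies within 0.7–2.2 Å and every
non-bonded pair is > 0.5 Å apart; otherwise the embedder retries with
derived seeds (default 10) before raising an embedding failure. This is a
geometry *sketcher*, not a force field: bond lengths and angles are
chemically sensible, but torsional preferences (anti vs gauche, ring
pucker populations) are not Boltzmann-weighted, and chirality is not
enforced.

## Representations and meshes

All three representations share the same atom centers from the same
conformer, so a side-by-side display compares like with like:

| kind | atom radius | bonds |
|---|---|---|
| `building_kit` | 0.45 × (2 × covalent) | uniform light-gray sticks, r = 0.12 Å |
| `ball_and_stick` | 0.25 × vdW | element-colored half-sticks, r = 0.10 Å |
| `space_filling` | 1.00 × vdW | none |

Colors follow CPK conventions; radii are Bondi (vdW) and Cordero
(covalent). Elements outside the table render in a fallback pink with
generic radii and a warning — never an error, so one exotic atom cannot
kill a 300-model batch. Double/triple bonds become 2/3 parallel sticks
offset 0.20 Å perpendicular to the bond, in the plane of the first
non-collinear neighbor so rings keep their double bonds in-plane. The
exact look of a physical construction kit (peg-and-hole connectors, stick
lengths) is not reproduced; the building-kit style is a documented
approximation with kit-like proportions.

Atoms are UV spheres (default 12 latitude bands × 24 longitude segments,
i.e. 266 vertices / 528 triangles each) and bonds capped cylinders
(16 segments); every primitive is watertight with outward winding, checked
in the test suite by edge-pairing and signed volume. Spheres and sticks
interpenetrate rather than being boolean-unioned — the same choice the
original kit models make, and the reason printability relies on each
primitive being closed.

## Scene layout

Batches are placed on a grid of `ceiling(sqrt(k))` columns (columns along
+X, rows downward along −Y), in input order, with ≥ 2 Å clearance between
bounding boxes; a single model sits centered at the origin. A grid rather
than one long row keeps 100-model scenes viewable. Each model's input
string is drawn 0.5 Å below its bounding box at 1 Å capital height with a
built-in 14-segment stroke font facing +Z; characters without strokes
render as a box glyph. Labels are merged into the node's exported mesh
*and* recorded as node names, so viewers that ignore geometry still
identify molecules.

## Export formats

Geometry is modeled in Å; exports scale by 0.02 m/Å by default, making a
cyclohexane model ~10 cm across in AR. Everything is Y-up and
right-handed, matching the glTF mandate, and vertex colors (not textured
materials) carry the element coloring because they are the smallest
feature every target format supports. STL is colorless by design.

* **GLB / glTF**: one named mesh node per scene node, float32 positions
  and `COLOR_0`, uint32 indices, 4-byte-aligned chunks.
* **USDZ**: an uncompressed zip whose first entry is a `usda` text layer;
  every entry stored (method 0) with payloads aligned to 64 bytes, as the
  USDZ packaging rules require — the zip writer is built in because
  ordinary zip tools cannot guarantee the alignment. `metersPerUnit` set
  from the scale. Text rather than binary USD keeps archives inspectable;
  both are conformant.
* **OBJ / binary STL**: cross-platform meshes for modeling and printing.
* **PNG**: a built-in rasterizer — perspective camera auto-fitted to the
  scene's bounding sphere (default azimuth 25°, elevation 15°, margin
  1.15), painter's-algorithm depth sort, flat Lambert shading from one
  fixed light. No GPU and no external renderer, so identical input gives
  byte-identical files; world coordinates are taken relative to the scene
  center and quantized to 2⁻¹⁷ Å so translating a whole scene cannot
  change the image through floating-point rounding. Painter's sorting can
  misorder mutually intersecting triangles in rare views; for model
  inspection this is invisible and determinism was judged more valuable
  than a z-buffer.

Archive timestamps are fixed (2020-01-01) for reproducible bytes.

## The synthetic fixture generator

`batch_fixture()` produces deterministic batches of chemically trivial
SMILES (unbranched/lightly branched alkanes, primary alcohols, small
ethers and rings, a few alkenes/alkynes) — the scale of molecules the tool
is used with in teaching, and deliberately free of stereocenters and
charges so capacity runs measure pipeline robustness rather than embedder
corner cases. What passing 100- and 300-model batch tests shows is that
parsing, embedding, layout and export hold up at those scenes' sizes; it
does not certify embedding quality for macrocycles, fused polycyclics or
charged exotica beyond what the trivial-name dictionary (63 entries
including glucose, caffeine, aspirin, naphthalene) exercises.

## Problem sizes and determinism of the checks

The shipped tests run batches of 100 (inline, with GLB and zip-of-USDZ
export at default tessellation) and 300 (CSV, through the CLI), the alkane
series C₁–C₂₀ against closed-form valence counts, and a tessellation sweep
(lat 2–6, lon 3–8, segments 3–8) against brute-force UV-grid enumeration;
unit tests use coarse tessellation to stay fast. Independent cross-checks
come from ChemmineR/OpenBabel (graph parsing), `unzip` (USDZ packaging)
and trimesh (GLB geometry). All randomness is seed-derived; no test
depends on the session RNG state.
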