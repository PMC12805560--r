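# molforge

Chemistry educators need physical-looking 3D models of molecules — the kind
students know from classroom construction kits — that can be dropped into
augmented-reality apps, slide decks, Blender scenes or a 3D printer.
`molforge` generates them from [SMILES](https://en.wikipedia.org/wiki/Simplified_molecular-input_line-entry_system)
line notation, entirely offline: a SMILES string (or a trivial name such as
"ethanol", or a batch of several hundred strings) becomes a colored,
watertight triangle-mesh model in **building-kit**, **ball-and-stick** or
**space-filling (CPK)** style, laid out in a labeled scene and exported to
**USDZ**, **glTF/GLB**, **zip-of-USDZ**, **OBJ**, **STL** or a rendered
**PNG**.

## How it works

1. **Input** — trivial names resolve through a bundled offline dictionary;
   comma-separated lists and CSV files give batches.
2. **Graph** — a SMILES parser builds the hydrogen-explicit molecular graph
   (ring closures, branches, charges, dot-separated components); aromatic
   rings are kekulized to alternating single/double bonds so every bond has
   a discrete order to draw.
3. **Conformer** — SMILES carries no geometry, so coordinates are embedded
   by seeded distance geometry: classical MDS on topological distances,
   then refinement against bond-length targets (sums of Cordero covalent
   radii), ideal-angle 1–3 distances and non-bonded repulsion. The same
   seed always reproduces the same coordinates; different seeds show
   different conformations, which is itself a teaching point about freely
   rotatable bonds.
4. **Mesh** — UV-sphere atoms (CPK colors, Bondi vdW radii) and capped
   cylinder bonds, with double/triple bonds drawn as parallel sticks.
5. **Scene** — batches are placed on a `ceiling(sqrt(k))`-column grid with
   stroke-font labels under each model; one molecule can also be laid out
   in all three representations side by side.
6. **Export** — hand-written, spec-conformant writers: GLB/glTF 2.0 with
   vertex colors, USDZ (uncompressed zip, 64-byte-aligned entries, usda
   layer), OBJ, binary STL, and a deterministic software rasterizer for PNG.

## Worked example

```r
library(molforge)

g    <- add_hydrogens(parse_smiles("C1CCCCC1"))   # cyclohexane
g
#> <molecule_graph> C1CCCCC1: 18 atoms, 18 bonds
conf <- embed_conformer(g, seed = 7)
conf
#> <conformer> 18 atoms, seed 7
mesh <- build_model(g, conf, default_style("building_kit"))
mesh
#> <triangle_mesh> 5400 vertices, 10656 triangles
scene <- layout_grid(list(list(name = "C1CCCCC1", mesh = mesh)))
write_glb(scene, "cyclohexane.glb")    # AR/engine-ready, meters, Y-up
write_usdz(scene, "cyclohexane.usdz")  # Apple AR toolchain
```

The 18 atoms and 18 bonds are C6H12: six ring carbons (6 C–C bonds) plus
twelve hydrogens. The 5400 model vertices are 18 atom spheres of 266
vertices each (12x24 tessellation) plus 18 sticks of 34 vertices each.

From a shell, the same run plus a two-model labeled batch:

```sh
exec/molforge "C1CCCCC1" --format glb -o cyclohexane.glb
exec/molforge "CCO, CO" --format usdz-zip -o batch.zip   # ethanol + methanol
exec/molforge "COC" --representations all --format png -o ether.png
exec/molforge fixtures --count 100 --family mixed -o batch.csv
exec/molforge --csv batch.csv -o batch.glb
```

Each molecule logs one line (`CCO: 9 atoms, ok`); invalid SMILES abort the
batch with the offending input named (exit code 1), or are skipped with
`--skip-invalid`.

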