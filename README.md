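# spherevox

Residue-centered spherical voxelization of protein structures, in R.

## The problem

Convolutional models over 3D protein structure need a volumetric encoding,
and most pipelines use a single global Cartesian density grid. That loses
two things practitioners of residue-level tasks (mutation effect
prediction, binding-site analysis, microenvironment comparison) care
about: orientation normalization — the same local motif should encode
identically wherever the protein sits in space — and residue-level
granularity with explicit chemistry.

`spherevox` encodes each residue's microenvironment separately. For every
residue *r* with backbone atoms N, Cα, C it builds a local orthonormal
frame

- origin **o** = (N + Cα + C) / 3,
- x̂ = u/‖u‖ with u = Cα − N,
- ẑ = (u × v)/‖u × v‖ with v = C − Cα,
- ŷ = ẑ × x̂,

and maps every atom of the structure into it, **x**ₗₒ꜀ = R(**x** − **o**)
with R = (x̂, ŷ, ẑ)ᵀ. Atoms with ‖**x**ₗₒ꜀‖ ≤ B (the spherical
microenvironment of radius B; a Chebyshev box mask when spheres are
disabled) are assigned to the nearest cell of a cubic lattice spanning
−B…+B with spacing s (2B/s + 1 points per axis; with the default
B = 16 Å, s = 1 Å: 33). Occupancy is binary over 6 element channels
(H, C, N, O, P, S — simplified from TRIPOS SYBYL atom types,
e.g. C.3 → C, N.pl3 → N, O.co2 → O) crossed with a central-vs-neighbor
residue flag, giving a per-protein tensor of shape

```
(residues × n × n × n × 6 × 2)
```

plus a per-residue bond-feature matrix `(residues × 5)` counting single,
double, triple, aromatic and amide covalent bonds (from the MOL2 bond
table) whose both endpoints lie inside the environment. Because the frame
rides with the backbone, any proper rigid motion of the input leaves the
tensors exactly unchanged; reflections do not (chirality is preserved).

Inputs are paired files per protein: a PDB file (coordinates, chains,
residue identity) and a TRIPOS MOL2 file with matching atom order
(SYBYL types, covalent bonds). The pairing is cross-checked
coordinate-by-coordinate; structures with missing or inconsistent
annotations are excluded, and residues with incomplete backbones are
skipped and logged.

## Worked example

```r
library(spherevox)

toy   <- make_toy_peptide(toy_spec(n_residues = 3, residue_start = 106))
paths <- write_toy_pair(toy, "demo")
st    <- read_structure_pair(paths[["pdb"]], paths[["mol2"]])
st
#> <annotated_structure> toy
#>   atoms:    15 retained (C/N/O/S)
#>   bonds:    14
#>   residues: 3

vox <- voxelize_protein(st, box_size = 8, spacing = 1)
vox
#> <protein_voxelization> toy
#>   occupancy: (3 x 17 x 17 x 17 x 6 x 2)  [residues x grid^3 x 6 channels x 2 flags]
#>   bonds:     (3 x 5)  lattice: B = 8 A, s = 1 A, spherical mask

as.data.frame(glance(vox))
#>   protein_id n_residues n_skipped box_size spacing n_per_axis use_spheres
#> 1        toy          3         0        8       1         17        TRUE
#>   n_occupied single double triple aromatic amide
#> 1         41     24      8      0        0     6
```

Three residues give three environments on a 17-point lattice (B = 8 Å,
s = 1 Å). The 15 atoms set 41 occupancy cells across the three
environments (each atom occupies one cell in its own element/membership
channel, in each of the three frames it falls into), and the bond rows
total 24 single, 8 double and 6 amide counts over the three spheres.
`tidy(vox)` returns the occupied cells as a long tibble (one row per set
cell, with voxel indices, local coordinates, element and membership),
`autoplot(vox, box_index = 0)` draws one environment, and
`plot_bond_counts(vox)` profiles the bond matrix across box indices.

On disk (`write_voxelization(vox, out)` or the CLI below) each protein
becomes three parallel files:

```
out/
  output_vox_atoms/<id>.npy   # (R, n, n, n, 6, 2) binary occupancy
  output_vox_bonds/<id>.npy   # (R, 5) integer bond counts
  metadata/<id>.txt           # TSV: protein_id, box_index, residue_index, residue_label
```

The `.npy` files are standard NumPy arrays (`np.load` reads them
directly), so the tensors drop straight into Python training pipelines.

## Command line

```sh
Rscript inst/scripts/voxelize.R --input_dir structures/ --outdir out \
    --box_size 16 --spacing 1 --use_spheres 1
```

`--input_dir` is scanned for `<name>.pdb` / `<name>.mol2` pairs (or pass
explicit `--pdb`/`--mol2` lists). Per-structure failures are logged and
skipped without aborting the batch; `out/manifest.tsv` records every
input with its status and reason. Exit status is 0 when at least one
structure succeeded.

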