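---
title: "Residue-centered spherical voxelization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-centered spherical voxelization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherevox)
```

## The representation

`spherevox` encodes a protein as one voxelized microenvironment per
residue rather than a single global grid. The model has three parts.

**The residue frame.** Backbone atoms N, Cα, C define both position and
orientation of residue *r*: the frame origin is their unweighted
centroid, and the rotation is built by Gram–Schmidt from
u = Cα − N and v = C − Cα (x̂ along u, ẑ along u × v, ŷ = ẑ × x̂;
rotation rows are x̂, ŷ, ẑ). Every atom of the structure is mapped into
this frame by the rigid transformation xₗₒ꜀ = R(x − o). Two properties
follow and are enforced by tests: (i) any *proper* rigid motion of the
global coordinates cancels exactly, so the encoding of a motif does not
depend on where the protein sits in the crystal frame; (ii) reflections
do **not** cancel — the frame is right-handed, so chirality survives.
Full rotational *equivariance* is explicitly not a goal; the frame
normalizes orientation instead.

**The lattice and the masks.** A cubic lattice spans −B…+B per axis
with spacing s. We require 2B/s to be an integer and use
n = 2B/s + 1 points per axis, which pins one voxel exactly at the
centroid and one at each face — with B = 16 Å, s = 1 Å that is 33
points. Atoms are confined by the box mask (Chebyshev norm ≤ B) and, in
spherical mode (the default), additionally by the Euclidean ball
‖xₗₒ꜀‖ ≤ B; both boundaries are inclusive. Each retained atom is
assigned to the nearest lattice point per axis,
index = ⌊(coord + B)/s + ½⌋, i.e. round-half-up: an atom exactly midway
between two voxels deterministically takes the larger index. Ties are
measure-zero in real data but determinism matters for reproducible
tensors. Indices are 0-based, matching the on-disk layout.

**The feature channels.** Occupancy is *binary* over 6 element channels
(H, C, N, O, P, S) crossed with a 2-level membership flag (atom belongs
to the central residue vs. a neighboring one). Elements come from
simplifying the MOL2 SYBYL type — the substring before the first dot,
case-insensitively (C.3 → C, N.pl3 → N, O.co2 → O) — with a fallback to
the PDB element column when the SYBYL type is outside the six-element
vocabulary; atoms outside it even then (selenium, halogens, metals) are
dropped along with their bonds. Several same-channel atoms in one voxel
collapse to 1. A voxel holding both a central and a neighboring atom of
the same element sets both flags. In parallel, each environment gets a
5-vector of covalent bond counts (single, double, triple, aromatic,
amide, from MOL2 codes 1/2/3/ar/am; any other code is parsed but never
counted). A bond is counted iff *both* endpoints survived the mask, so
the vector summarizes the covalent topology *inside* the sphere; the
alternative (counting over the residue's atoms regardless of masking)
was rejected because it breaks the monotonicity of counts in B that the
local-topology reading implies, and which we test on nested spheres.

## Inputs and their validation

Each protein arrives as a PDB file plus a TRIPOS MOL2 file produced from
it with identical atom order. Atoms are paired by ordinal position
(i-th to i-th) and the pairing is verified by requiring every paired
Euclidean coordinate disagreement to stay within `coord_tolerance`
(default 0.01 Å — wide enough to absorb the formats' print precision,
PDB 3 decimals vs. MOL2 4, narrow enough to catch a genuinely shifted or
reordered conversion). Any violation, or a length mismatch, excludes the
whole structure as inconsistently annotated. Alternate locations keep
the first-listed conformer per atom name; HETATM records are dropped by
default (an `keep_hetero` switch exists). Hydrogens are used when
present and never added — a structure without explicit H simply leaves
the H channel empty. Residues are keyed by (chain, author index, name)
so multi-chain files cannot collide. A residue missing any of N, Cα, C
is skipped (its frame is undefined), logged, and box indices stay
consecutive over the residues actually processed — which is why
`box_index` is a 0-based ordinal rather than the author residue number.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `box_size` (B) | 16 | Å | sphere radius and lattice half-width; protein-scale microenvironments |
| `spacing` (s) | 1 | Å | voxel edge; 2B/s must be an integer |
| `use_spheres` | TRUE | — | Euclidean ball mask on top of the box |
| `coord_tolerance` | 0.01 | Å | PDB/MOL2 pairing cross-check |
| `keep_hetero` | FALSE | — | retain HETATM records |

Larger B widens context at O(n³) memory per environment; s controls
resolution against sparsity (at 1 Å nearly every occupied voxel holds a
single atom).

## The synthetic generator

`make_toy_peptide()` emits extended-chain peptides with explicit
N/Cα/C/O backbones, optional side chains (CB; CYS adds SG, SER adds OG,
PHE adds an aromatic six-ring bonded `ar`), optional amide hydrogens and
free-floating decorations for the P channel, as byte-deterministic
paired PDB/MOL2 text plus a ground-truth record. It emulates exactly
what the pipeline consumes — consistent paired annotation, SYBYL typing,
the five bond codes, multi-residue chains — and deliberately not what it
does not: no Ramachandran-plausible conformers, no rotamers, no crystal
artifacts, no missing density. Passing tests therefore demonstrate the
geometry, bookkeeping and serialization contracts, not robustness to the
messiness of real crystallographic files.

The geometry constants (`toy_geometry()`) are near-ideal extended-chain
values nudged within ~0.07 Å / ~5° of textbook geometry so that, in
every residue frame of the stock fixtures, local coordinates keep at
least 0.05 Å clearance from the voxel-assignment half-spacing boundaries
at s = 1 Å. This clearance is what lets the rigid-motion tests demand
*exact* tensor equality: a transformed fixture re-printed at PDB
precision perturbs coordinates by ≤ ~10⁻³ Å, far below the clearance, so
no atom can hop voxels. PHE-ring fixtures sit closer to boundaries and
are used for shape and bond coverage only.

## Numerical choices and degenerate inputs

* Frame degeneracy: collinear or coincident backbone atoms (cross-product
  norm < 10⁻⁸) raise a classed error; at protein scale this is a
  corrupt-input symptom, and the residue is skipped.
* Orthonormality of every frame is exact to ≤ 10⁻⁹ by construction and
  asserted in tests (det = +1).
* Lattice commensurability uses a 10⁻⁹ relative tolerance on 2B/s and the
  error message suggests the nearest valid B.
* Assignment tie-break is half-up (toward the larger index), fixed and
  documented; the oracle tests include exact half-spacing coordinates.
* Empty environments are legal (all-zero occupancy, zero bond row); a
  structure in which *no* residue has a complete backbone is an error.
* All serialization is deterministic: re-running a voxelization yields
  byte-identical NPY and TSV files, which the tests assert.

## On-disk format

Occupancy tensors `(R, n, n, n, 6, 2)` and bond matrices `(R, 5)` are
written as NumPy NPY v1.0 files (int32, Fortran order declared in the
header — NumPy reads these natively), metadata as a TSV with header
(`protein_id`, `box_index`, `residue_index`, `residue_label`), under the
fixed subdirectories `output_vox_atoms/`, `output_vox_bonds/` and
`metadata/`. The three outputs are index-aligned row by row. The NPY
writer/reader is implemented in the package and cross-checked against
NumPy itself in the test suite.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on generated peptides of
1–4 residues at B between 3 and 16 Å, 20 random rigid motions, 10⁴
random coordinates for the assignment oracle and clouds of a few
thousand points for the mask oracles — sizes chosen so the whole suite
exercises every contract in well under a minute while still covering the
default protein-scale lattice (33³ voxels).

## Known limitations

* The frame convention (which axes N→Cα→C maps to) is one fixed
  right-handed choice; any other fixed convention would be equally
  invariant but yields different voxel contents, so tensors are only
  comparable between runs of this package.
* Binary occupancy discards multiplicity within a voxel (a count mode is
  deliberately out of scope).
* No continuous densities, solvent accessibility, contact surfaces or
  interaction features; no mmCIF input; PDB→MOL2 conversion is the
  user's step — the package consumes, and cross-validates, the pair.
* Memory for the per-protein tensor grows as R·n³·12 int32 values;
  very large proteins at fine spacing are better processed residue-wise
  via `build_environment()`.
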