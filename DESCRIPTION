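Package: spherevox
Title: Residue-Centered Spherical Voxelization of Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein residue microenvironments as machine-learning-ready
    voxel tensors. For every residue, a local orthonormal coordinate frame is
    anchored at the centroid of the backbone N, C-alpha and C atoms and oriented
    by their geometry; all surrounding atoms are projected into that frame,
    confined to a sphere of radius B, and assigned to the nearest cell of a
    regular lattice with spacing s. Occupancy is recorded in six binary
    atom-type channels (H, C, N, O, P, S) crossed with a central-versus-neighbor
    residue flag, and covalent bond types (single, double, triple, aromatic,
    amide) are counted per environment from TRIPOS MOL2 annotations. Paired
    PDB/MOL2 inputs are parsed and cross-validated; results serialize to NumPy
    NPY arrays plus a plain-text metadata table, with tidy accessors and
    ggplot2 visualisations. Includes a generator of small synthetic paired
    PDB/MOL2 peptides for fully self-contained testing, and a command-line
    entry point for batch voxelization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
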