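# Shared fixture builders: everything is generated in code at test time.

fixture_structure <- function(spec = toy_spec(3), dir = NULL, name = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  toy <- make_toy_peptide(spec)
  paths <- write_toy_pair(toy, dir, name = name)
  list(toy = toy, paths = paths,
       structure = read_structure_pair(paths[["pdb"]], paths[["mol2"]]))
}

# Voxelize a PDB/MOL2 text pair (protein_id "toy") via temporary files.
voxelize_texts <- function(pdb_text, mol2_text, ...) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(sub("\n$", "", pdb_text), file.path(d, "toy.pdb"))
  writeLines(sub("\n$", "", mol2_text), file.path(d, "toy.mol2"))
  st <- read_structure_pair(file.path(d, "toy.pdb"), file.path(d, "toy.mol2"))
  suppressMessages(voxelize_protein(st, ...))
}

expect_binary <- function(arr) {
  expect_true(all(arr %in% c(0L, 1L)))
}
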