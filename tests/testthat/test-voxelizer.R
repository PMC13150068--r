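test_that("lattice construction spans -B..+B with the commensurability check", {
  lt <- build_lattice(16, 1)
  expect_equal(lt$n_per_axis, 33L)
  expect_equal(lt$axis_coords[1], -16)
  expect_equal(lt$axis_coords[33], 16)
  expect_equal(unique(round(diff(lt$axis_coords), 12)), 1)

  expect_equal(build_lattice(1, 1)$axis_coords, c(-1, 0, 1))
  expect_error(build_lattice(1, 0.3), class = "spherevox_config_error")
  expect_error(build_lattice(-2, 1), class = "spherevox_config_error")
  # half-spacing B is fine: 2B/s integer
  expect_equal(build_lattice(1.5, 1)$n_per_axis, 4L)
})

test_that("sphere and box masks equal brute-force norm filters", {
  set.seed(202)
  cloud <- tibble::tibble(x = runif(500, -10, 10), y = runif(500, -10, 10),
                          z = runif(500, -10, 10), atom_id = 1:500)
  b <- 8
  sph <- sphere_mask(cloud, b)
  box <- box_mask(cloud, b)
  # brute-force oracles, one atom at a time
  keep_sph <- vapply(seq_len(nrow(cloud)), function(i) {
    sqrt(cloud$x[i]^2 + cloud$y[i]^2 + cloud$z[i]^2) <= b
  }, logical(1))
  keep_box <- vapply(seq_len(nrow(cloud)), function(i) {
    max(abs(c(cloud$x[i], cloud$y[i], cloud$z[i]))) <= b
  }, logical(1))
  expect_equal(sph$atom_id, cloud$atom_id[keep_sph])
  expect_equal(box$atom_id, cloud$atom_id[keep_box])
  expect_true(all(sph$atom_id %in% box$atom_id))  # sphere within box
})

test_that("mask boundaries are inclusive and corner geometry differs", {
  b <- 5
  pts <- tibble::tibble(x = c(0, b, b + 1e-9, b, 0),
                        y = c(0, 0, 0, b, 0),
                        z = c(0, 0, 0, b, b + 1e-9),
                        atom_id = 1:5)
  expect_equal(sphere_mask(pts, b)$atom_id, c(1L, 2L))  # center + on-sphere
  expect_equal(box_mask(pts, b)$atom_id, c(1L, 2L, 4L)) # corner kept by box
})

test_that("nearest-voxel assignment matches exhaustive search with half-up ties", {
  lt <- build_lattice(16, 1)
  expect_equal(assign_voxel(c(0, 0, 0), lt)[1, ], c(ix = 16L, iy = 16L, iz = 16L))
  expect_equal(assign_voxel(c(0.4, -0.4, 0), lt)[1, ],
               c(ix = 16L, iy = 16L, iz = 16L))
  # exact half-spacing ties break toward the larger index
  expect_equal(assign_voxel(c(0.5, -0.5, 15.5), lt)[1, ],
               c(ix = 17L, iy = 16L, iz = 32L))

  # per-axis exhaustive argmin oracle on 1e4 random in-box coordinates
  set.seed(303)
  coords <- matrix(runif(3e4, -16, 16), ncol = 3)
  got <- assign_voxel(coords, lt)
  oracle_axis <- function(v) {
    d <- abs(lt$axis_coords - v)
    max(which(d == min(d))) - 1L   # tie -> larger index
  }
  want <- apply(coords, c(1, 2), oracle_axis)
  expect_identical(unname(got), unname(want))
  expect_true(all(got >= 0 & got <= lt$n_per_axis - 1))

  # full 3D exhaustive nearest-lattice-point search on a small grid
  lt9 <- build_lattice(4, 1)
  grid <- as.matrix(expand.grid(lt9$axis_coords, lt9$axis_coords,
                                lt9$axis_coords))
  set.seed(304)
  small <- matrix(runif(900, -4, 4), ncol = 3)
  got9 <- assign_voxel(small, lt9)
  for (i in seq_len(nrow(small))) {
    d2 <- colSums((t(grid) - small[i, ])^2)
    best <- grid[which.min(d2), ]
    expect_equal(lt9$axis_coords[got9[i, ] + 1L], unname(best))
  }
})

test_that("a single central atom occupies exactly the center voxel in its channel", {
  key <- list(chain_id = "A", residue_index = 1L, residue_name = "GLY")
  fr <- residue_frame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), key)
  at <- tibble::tibble(
    atom_id = 1L, atom_name = "CX", element_raw = "C",
    x = 2 / 3, y = 1 / 3, z = 0,   # the frame origin
    chain_id = "A", residue_name = "GLY", residue_index = 1L,
    element_category = "C"
  )
  st <- structure(list(atoms = at,
                       bonds = tibble::tibble(atom_a = integer(),
                                              atom_b = integer(),
                                              bond_code = character()),
                       protein_id = "one",
                       residue_order = at[, c("chain_id", "residue_index",
                                              "residue_name")]),
                  class = "annotated_structure")
  lt <- build_lattice(4, 1)
  env <- build_environment(st, fr, lt)
  expect_equal(sum(env$occupancy), 1L)
  expect_equal(env$occupancy[5, 5, 5, "C", "central"], 1L)
})

test_that("occupancy nonzeros match per-atom enumeration on a dipeptide", {
  fx <- fixture_structure(toy_spec(2, residue_names = c("ALA", "GLY")))
  vox <- suppressMessages(voxelize_protein(fx$structure, box_size = 8,
                                           spacing = 1))
  for (r in seq_len(nrow(vox$metadata))) {
    ra <- vox$retained_atoms[[r]]
    occ <- vox$occupancy[r, , , , , ]
    # enumerate expected cells atom by atom
    cells <- unique(tibble::tibble(
      i = ra$ix + 1L, j = ra$iy + 1L, k = ra$iz + 1L,
      c = match(ra$element_category, c("H", "C", "N", "O", "P", "S")),
      f = ifelse(ra$is_central, 1L, 2L)))
    expect_equal(sum(occ), nrow(cells))
    expect_true(all(occ[as.matrix(cells)] == 1L))
    expect_lte(sum(occ), nrow(ra))
  }
})

test_that("bond counting is restricted to fully retained bonds", {
  bonds <- tibble::tibble(
    atom_a = c(1L, 2L, 3L, 4L, 5L),
    atom_b = c(2L, 3L, 4L, 5L, 6L),
    bond_code = c("single", "single", "amide", "other", "double"))
  expect_equal(unlist(count_bonds(bonds, integer(0))),
               c(single = 0L, double = 0L, triple = 0L,
                 aromatic = 0L, amide = 0L))
  got <- count_bonds(bonds, 1:4)
  expect_equal(unlist(got), c(single = 2L, double = 0L, triple = 0L,
                              aromatic = 0L, amide = 1L))
  # "other"-coded bonds never counted even when fully retained
  expect_equal(sum(unlist(count_bonds(bonds, 1:6))), 4L)
})

test_that("a boundary-straddling bond drops exactly one count", {
  # CYS: the S-gamma sits ~2.8 A from CB; with a tight sphere around
  # residue 1 the CB-SG bond straddles the boundary
  fx <- fixture_structure(toy_spec(1, residue_names = "CYS"))
  st <- fx$structure
  whole <- suppressMessages(voxelize_protein(st, box_size = 8, spacing = 1))
  tight <- suppressMessages(voxelize_protein(st, box_size = 3, spacing = 1))
  ra <- tight$retained_atoms[[1]]
  sg_id <- st$atoms$atom_id[st$atoms$atom_name == "SG"]
  expect_false(sg_id %in% ra$atom_id)           # SG outside the 3 A sphere
  expect_true(st$atoms$atom_id[st$atoms$atom_name == "CB"] %in% ra$atom_id)
  expect_equal(unname(whole$bonds[1, "single"] - tight$bonds[1, "single"]),
               1L)
})

test_that("tripeptide voxelization has the documented tensor shapes", {
  fx <- fixture_structure(toy_spec(3))
  vox <- suppressMessages(voxelize_protein(fx$structure, box_size = 4,
                                           spacing = 1))
  expect_equal(dim(vox$occupancy), c(3L, 9L, 9L, 9L, 6L, 2L))
  expect_equal(dim(vox$bonds), c(3L, 5L))
  expect_equal(colnames(vox$bonds),
               c("single", "double", "triple", "aromatic", "amide"))
  expect_equal(vox$metadata$box_index, 0:2)
})

test_that("residues with incomplete backbones are skipped with consecutive box indices", {
  toy <- make_toy_peptide(toy_spec(3))
  broken <- corrupt(toy$pdb, toy$mol2, "drop_backbone_atom")
  vox <- voxelize_texts(broken$pdb, broken$mol2, box_size = 4, spacing = 1)
  expect_equal(nrow(vox$metadata), 2)
  expect_equal(dim(vox$occupancy)[1], 2L)
  expect_false(2L %in% vox$metadata$residue_index)
  expect_equal(vox$metadata$box_index, 0:1)     # consecutive over processed
  expect_equal(nrow(vox$skipped), 1)
  expect_match(vox$skipped$reason, "incomplete backbone")
})

test_that("voxelization fails cleanly when no residue has a complete backbone", {
  d <- withr::local_tempdir()
  pdb <- file.path(d, "t.pdb")
  mol2 <- file.path(d, "t.mol2")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.460   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  writeLines(c("@<TRIPOS>MOLECULE", "t", " 2 1 1", "SMALL", "NO_CHARGES", "",
               "@<TRIPOS>ATOM",
               "  1 N  0.0000 0.0 0.0 N.3 1 GLY1 0.0",
               "  2 CA 1.4600 0.0 0.0 C.3 1 GLY1 0.0",
               "@<TRIPOS>BOND", "  1 1 2 1"), mol2)
  st <- read_structure_pair(pdb, mol2)
  expect_error(voxelize_protein(st), class = "spherevox_empty_output_error")
})

test_that("occupancy is binary and sphere confinement holds for retained atoms", {
  fx <- fixture_structure(toy_spec(4, residue_names = c("ALA", "PHE", "SER",
                                                        "CYS")))
  vox <- suppressMessages(voxelize_protein(fx$structure, box_size = 6,
                                           spacing = 1))
  expect_binary(vox$occupancy)
  for (ra in vox$retained_atoms) {
    expect_true(all(sqrt(ra$x^2 + ra$y^2 + ra$z^2) <= 6))
  }
  # box mode confines by Chebyshev norm instead, and retains at least as much
  vox_box <- suppressMessages(voxelize_protein(fx$structure, box_size = 6,
                                               spacing = 1,
                                               use_spheres = FALSE))
  for (ra in vox_box$retained_atoms) {
    expect_true(all(pmax(abs(ra$x), abs(ra$y), abs(ra$z)) <= 6))
  }
  expect_gte(sum(vox_box$occupancy), sum(vox$occupancy))
})

test_that("bond counts conserve totals and are monotone in the sphere radius", {
  fx <- fixture_structure(toy_spec(3, with_hydrogens = TRUE))
  st <- fx$structure
  prev <- NULL
  for (b in c(3, 4, 6, 8)) {
    vox <- suppressMessages(voxelize_protein(st, box_size = b, spacing = 1))
    # conservation: each row equals the count of fully retained 5-type bonds
    for (r in seq_len(nrow(vox$metadata))) {
      ids <- vox$retained_atoms[[r]]$atom_id
      n_5type <- sum(st$bonds$atom_a %in% ids & st$bonds$atom_b %in% ids &
                       st$bonds$bond_code %in% c("single", "double", "triple",
                                                 "aromatic", "amide"))
      expect_equal(sum(vox$bonds[r, ]), n_5type)
    }
    if (!is.null(prev)) expect_true(all(vox$bonds >= prev))
    prev <- vox$bonds
  }
})

test_that("central-channel atoms are exactly the central residue's retained atoms", {
  fx <- fixture_structure(toy_spec(3))
  st <- fx$structure
  vox <- suppressMessages(voxelize_protein(st, box_size = 8, spacing = 1))
  for (r in seq_len(nrow(vox$metadata))) {
    ra <- vox$retained_atoms[[r]]
    res <- vox$metadata$residue_index[r]
    expect_setequal(ra$atom_id[ra$is_central],
                    intersect(ra$atom_id,
                              st$atoms$atom_id[st$atoms$residue_index == res]))
    # central channels contain at least one set voxel
    expect_gt(sum(vox$occupancy[r, , , , , 1]), 0)
  }
})

test_that("voxelization is rigid-motion invariant end to end (exact tensors)", {
  toy <- make_toy_peptide(toy_spec(3))
  ref <- voxelize_texts(toy$pdb, toy$mol2, box_size = 8, spacing = 1)
  set.seed(404)
  for (rep in 1:5) {
    tf <- random_rigid_transform()
    moved <- rigid_transform(toy$pdb, toy$mol2, tf$rotation, tf$translation)
    vox <- voxelize_texts(moved$pdb, moved$mol2, box_size = 8, spacing = 1)
    expect_identical(vox$occupancy, ref$occupancy)
    expect_identical(vox$bonds, ref$bonds)
    expect_equal(vox$metadata, ref$metadata)
  }
})

test_that("voxelizing the same fixture twice is bit-identical after serialization", {
  toy <- make_toy_peptide(toy_spec(2))
  v1 <- voxelize_texts(toy$pdb, toy$mol2, box_size = 4, spacing = 1)
  v2 <- voxelize_texts(toy$pdb, toy$mol2, box_size = 4, spacing = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_voxelization(v1, d1)
  write_voxelization(v2, d2)
  for (sub in c("output_vox_atoms/toy.npy", "output_vox_bonds/toy.npy",
                "metadata/toy.txt")) {
    expect_identical(readBin(file.path(d1, sub), "raw", 1e6),
                     readBin(file.path(d2, sub), "raw", 1e6))
  }
})
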