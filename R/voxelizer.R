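#' Build a cubic voxel lattice specification
#'
#' The lattice spans `-B ... +B` on each axis with uniform spacing `s`,
#' placing one grid point exactly at the frame origin and at both ends, so
#' `2B/s` must be an integer (to 1e-9 relative) and the number of points
#' per axis is `2B/s + 1`. With the default protein settings `B = 16`,
#' `s = 1` this gives 33 points per axis.
#'
#' @param box_size Half-width of the box and radius of the spherical mask,
#'   A (`B`).
#' @param spacing Voxel edge length, A (`s`).
#' @return A `lattice_spec`: list with `box_size`, `spacing`,
#'   `n_per_axis`, `axis_coords`.
#' @export
#' @examples
#' build_lattice(16, 1)$n_per_axis  # 33
build_lattice <- function(box_size, spacing) {
  if (!is.numeric(box_size) || length(box_size) != 1 || box_size <= 0 ||
      !is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    .sx_abort("`box_size` and `spacing` must be single positive numbers.",
              "spherevox_config_error")
  }
  ratio <- 2 * box_size / spacing
  if (abs(ratio - round(ratio)) > 1e-9 * max(1, ratio)) {
    suggested <- spacing * round(ratio) / 2
    .sx_abort(sprintf(
      paste0("2 * box_size / spacing = %.6g is not an integer; the lattice ",
             "cannot span -B..+B uniformly. Nearest valid box_size: %g A."),
      ratio, suggested),
      "spherevox_config_error")
  }
  n <- as.integer(round(ratio)) + 1L
  structure(
    list(box_size = box_size, spacing = spacing, n_per_axis = n,
         axis_coords = -box_size + spacing * (seq_len(n) - 1)),
    class = "lattice_spec"
  )
}

#' Spherical and box masks on local atom coordinates
#'
#' `sphere_mask()` retains atoms with Euclidean norm `|x| <= B` (boundary
#' inclusive); `box_mask()` retains atoms with Chebyshev norm
#' `max(|x|,|y|,|z|) <= B`. The sphere is a subset of the box, so sphere
#' mode alone confines atoms to the lattice; box masking is what applies
#' when spheres are disabled.
#'
#' @param atoms Data frame of local atom coordinates with columns `x`,
#'   `y`, `z` (e.g. from [project_atoms()]).
#' @param box_size Radius / half-width `B`, A.
#' @return The input tibble restricted to retained rows.
#' @export
sphere_mask <- function(atoms, box_size) {
  as_tibble(atoms)[sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2) <= box_size, ]
}

#' @rdname sphere_mask
#' @export
box_mask <- function(atoms, box_size) {
  as_tibble(atoms)[pmax(abs(atoms$x), abs(atoms$y), abs(atoms$z)) <= box_size, ]
}

#' Assign local coordinates to their nearest voxel
#'
#' Each coordinate maps to the nearest lattice point per axis,
#' `index = floor((coord + B) / s + 0.5)`, i.e. round-half-up: a
#' coordinate exactly midway between two grid points takes the larger
#' index. Indices are 0-based in `[0, n_per_axis - 1]`, matching the
#' on-disk tensor layout. Coordinates are assumed already masked (box or
#' sphere), which guarantees the indices are in range.
#'
#' @param coords Numeric length-3 vector, or an n x 3 matrix / data frame
#'   with columns `x`, `y`, `z`.
#' @param lattice A `lattice_spec` from [build_lattice()].
#' @return Integer matrix (n x 3) of 0-based voxel indices (a 1 x 3 matrix
#'   for a single coordinate).
#' @export
#' @examples
#' assign_voxel(c(0, 0, 0), build_lattice(16, 1))  # 16 16 16
assign_voxel <- function(coords, lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  idx <- floor((coords + lattice$box_size) / lattice$spacing + 0.5)
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("ix", "iy", "iz")
  idx
}

#' Voxelize one residue's local environment
#'
#' Projects the structure into the residue frame, confines atoms to the
#' lattice (always the box mask; additionally the spherical mask when
#' `use_spheres`), assigns each retained atom to its nearest voxel and
#' sets binary occupancy in the atom's element channel crossed with its
#' central/neighbor membership flag. Multiple same-channel atoms in one
#' voxel collapse to 1.
#'
#' @param structure An `annotated_structure`.
#' @param frame A `residue_frame`.
#' @param lattice A `lattice_spec`.
#' @param use_spheres Apply the spherical mask (`|x| <= B`)?
#' @return A `sphere_environment`: list with `residue_key`, `occupancy`
#'   (integer array `n x n x n x 6 x 2`, channel order H,C,N,O,P,S then
#'   central/neighbor), `retained` (tibble of retained atoms with local
#'   coordinates and 0-based voxel indices) and `lattice`.
#' @export
build_environment <- function(structure, frame, lattice, use_spheres = TRUE) {
  stopifnot(inherits(lattice, "lattice_spec"))
  loc <- project_atoms(structure, frame)
  loc <- box_mask(loc, lattice$box_size)
  if (use_spheres) loc <- sphere_mask(loc, lattice$box_size)
  n <- lattice$n_per_axis
  occ <- array(0L, dim = c(n, n, n, 6L, 2L),
               dimnames = list(NULL, NULL, NULL, .sx_elements,
                               c("central", "neighbor")))
  if (nrow(loc)) {
    idx <- assign_voxel(loc, lattice)
    loc$ix <- idx[, 1]; loc$iy <- idx[, 2]; loc$iz <- idx[, 3]
    occ[cbind(idx + 1L,
              match(loc$element_category, .sx_elements),
              ifelse(loc$is_central, 1L, 2L))] <- 1L
  } else {
    loc$ix <- integer(); loc$iy <- integer(); loc$iz <- integer()
  }
  structure(
    list(residue_key = frame$residue_key, occupancy = occ,
         retained = loc, lattice = lattice),
    class = "sphere_environment"
  )
}

#' Count covalent bond types within a residue environment
#'
#' Counts bonds whose both endpoints belong to the retained (masked) atom
#' set, binned into the five named MOL2 bond categories; bonds carrying
#' any other code are ignored.
#'
#' @param bonds Bond tibble (`atom_a`, `atom_b`, `bond_code`).
#' @param retained_atom_ids Atom ids retained in the environment.
#' @return One-row tibble with integer columns `single`, `double`,
#'   `triple`, `aromatic`, `amide`.
#' @export
count_bonds <- function(bonds, retained_atom_ids) {
  inside <- bonds$atom_a %in% retained_atom_ids &
    bonds$atom_b %in% retained_atom_ids
  code <- factor(bonds$bond_code[inside], levels = .sx_bond_types)
  counts <- table(code)
  as_tibble(as.list(vapply(.sx_bond_types, function(b)
    as.integer(counts[[b]]), integer(1))))
}

#' Voxelize every residue of a protein
#'
#' The full per-protein pipeline: one lattice is built once and reused;
#' for each residue of `residue_order` with a complete N/CA/C backbone, a
#' frame is built, the environment voxelized and its bond types counted.
#' Residues missing a backbone atom (or with degenerate geometry) are
#' skipped and logged; box indices stay consecutive over processed
#' residues.
#'
#' @param structure An `annotated_structure` from [merge_structure()] /
#'   [read_structure_pair()].
#' @param box_size Half-width / sphere radius `B`, A (default 16).
#' @param spacing Voxel spacing `s`, A (default 1).
#' @param use_spheres Apply the spherical mask (default TRUE)?
#' @return A `protein_voxelization`: list with `protein_id`, `lattice`,
#'   `occupancy` (integer array `R x n x n x n x 6 x 2`), `bonds`
#'   (integer matrix `R x 5`, columns single/double/triple/aromatic/amide),
#'   `metadata` (tibble: `protein_id`, `box_index` 0-based, `chain_id`,
#'   `residue_index`, `residue_label`), `retained_atoms` (list of
#'   per-environment retained-atom tibbles) and `skipped` (tibble of
#'   skipped residues with reasons).
#' @export
voxelize_protein <- function(structure, box_size = 16, spacing = 1,
                             use_spheres = TRUE) {
  stopifnot(inherits(structure, "annotated_structure"))
  lattice <- build_lattice(box_size, spacing)
  bf <- .sx_backbone_frames(structure)
  if (length(bf$frames) == 0) {
    .sx_abort(paste0("No residue with a complete N/CA/C backbone in ",
                     structure$protein_id, "; nothing to voxelize."),
              "spherevox_empty_output_error")
  }
  n <- lattice$n_per_axis
  r_count <- length(bf$frames)
  occupancy <- array(0L, dim = c(r_count, n, n, n, 6L, 2L))
  bond_rows <- vector("list", r_count)
  meta_rows <- vector("list", r_count)
  retained_atoms <- vector("list", r_count)
  for (r in seq_len(r_count)) {
    fr <- bf$frames[[r]]
    env <- build_environment(structure, fr, lattice,
                             use_spheres = use_spheres)
    occupancy[r, , , , , ] <- env$occupancy
    bond_rows[[r]] <- count_bonds(structure$bonds, env$retained$atom_id)
    meta_rows[[r]] <- tibble(
      protein_id = structure$protein_id,
      box_index = r - 1L,
      chain_id = fr$residue_key$chain_id,
      residue_index = as.integer(fr$residue_key$residue_index),
      residue_label = toupper(fr$residue_key$residue_name)
    )
    retained_atoms[[r]] <- env$retained
  }
  bonds <- as.matrix(bind_rows(bond_rows))
  storage.mode(bonds) <- "integer"
  rownames(bonds) <- NULL
  if (nrow(bf$skipped) > 0) {
    inform(sprintf("spherevox: skipped %d residue(s) in %s: %s",
                   nrow(bf$skipped), structure$protein_id,
                   paste(sprintf("%s/%s %s (%s)", bf$skipped$chain_id,
                                 bf$skipped$residue_index,
                                 bf$skipped$residue_name,
                                 bf$skipped$reason), collapse = "; ")))
  }
  structure(
    list(protein_id = structure$protein_id, lattice = lattice,
         occupancy = occupancy, bonds = bonds,
         metadata = bind_rows(meta_rows),
         retained_atoms = retained_atoms,
         skipped = bf$skipped,
         use_spheres = use_spheres),
    class = "protein_voxelization"
  )
}

#' @export
print.protein_voxelization <- function(x, ...) {
  d <- dim(x$occupancy)
  cat("<protein_voxelization> ", x$protein_id, "\n", sep = "")
  cat(sprintf("  occupancy: (%s)  [residues x grid^3 x 6 channels x 2 flags]\n",
              paste(d, collapse = " x ")))
  cat(sprintf("  bonds:     (%d x 5)  lattice: B = %g A, s = %g A, %s\n",
              nrow(x$bonds), x$lattice$box_size, x$lattice$spacing,
              if (isTRUE(x$use_spheres)) "spherical mask" else "box mask"))
  if (nrow(x$skipped)) cat("  skipped:  ", nrow(x$skipped), "residue(s)\n")
  invisible(x)
}
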