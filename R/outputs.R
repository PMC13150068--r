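#' Serialize a voxelization to the standard on-disk layout
#'
#' A voxelized protein is written as three parallel files under fixed
#' subdirectories of `out_dir`:
#'
#' * `output_vox_atoms/<protein_id>.npy` — binary occupancy tensor of
#'   shape `(R, n, n, n, 6, 2)`, channels (H,C,N,O,P,S) x
#'   (central, neighbor);
#' * `output_vox_bonds/<protein_id>.npy` — integer bond-count matrix
#'   `(R, 5)`, columns (single, double, triple, aromatic, amide);
#' * `metadata/<protein_id>.txt` — tab-separated table with header,
#'   columns `protein_id`, `box_index`, `residue_index`, `residue_label`,
#'   one row per environment, index-aligned with the array rows.
#'
#' @param voxelization A `protein_voxelization` from [voxelize_protein()].
#' @param out_dir Output directory (subdirectories are created).
#' @return The written file path, invisibly; `write_voxelization()`
#'   returns a named character vector of all three paths.
#' @name outputs
NULL

.sx_out_path <- function(out_dir, sub, file) {
  d <- file.path(out_dir, sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(d)) {
    .sx_abort(paste0("Cannot create output directory: ", d),
              "spherevox_io_error")
  }
  file.path(d, file)
}

.sx_check_vox <- function(voxelization) {
  if (!inherits(voxelization, "protein_voxelization")) {
    .sx_abort("Expected a `protein_voxelization` object.",
              "spherevox_input_error")
  }
  if (nrow(voxelization$metadata) == 0) {
    .sx_abort("Empty voxelization: no environments to write.",
              "spherevox_empty_output_error")
  }
}

#' @rdname outputs
#' @export
write_occupancy <- function(voxelization, out_dir) {
  .sx_check_vox(voxelization)
  path <- .sx_out_path(out_dir, "output_vox_atoms",
                       paste0(voxelization$protein_id, ".npy"))
  write_npy(voxelization$occupancy, path)
  invisible(path)
}

#' @rdname outputs
#' @export
write_bonds <- function(voxelization, out_dir) {
  .sx_check_vox(voxelization)
  path <- .sx_out_path(out_dir, "output_vox_bonds",
                       paste0(voxelization$protein_id, ".npy"))
  write_npy(voxelization$bonds, path)
  invisible(path)
}

#' @rdname outputs
#' @export
write_metadata <- function(voxelization, out_dir) {
  .sx_check_vox(voxelization)
  path <- .sx_out_path(out_dir, "metadata",
                       paste0(voxelization$protein_id, ".txt"))
  meta <- voxelization$metadata[, c("protein_id", "box_index",
                                    "residue_index", "residue_label")]
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' @rdname outputs
#' @export
write_voxelization <- function(voxelization, out_dir) {
  c(occupancy = write_occupancy(voxelization, out_dir),
    bonds = write_bonds(voxelization, out_dir),
    metadata = write_metadata(voxelization, out_dir))
}

#' Read a serialized voxelization back from disk
#'
#' Inverse of [write_voxelization()]; reads the three parallel files for
#' one protein from the fixed directory layout.
#'
#' @param out_dir Directory that holds `output_vox_atoms/`,
#'   `output_vox_bonds/` and `metadata/`.
#' @param protein_id Protein identifier (file basename).
#' @return List with `occupancy` (array), `bonds` (matrix) and `metadata`
#'   (tibble).
#' @export
read_voxelization <- function(out_dir, protein_id) {
  occ <- read_npy(file.path(out_dir, "output_vox_atoms",
                            paste0(protein_id, ".npy")))
  bonds <- read_npy(file.path(out_dir, "output_vox_bonds",
                              paste0(protein_id, ".npy")))
  meta_path <- file.path(out_dir, "metadata", paste0(protein_id, ".txt"))
  if (!file.exists(meta_path)) {
    .sx_abort(paste0("Metadata file not found: ", meta_path),
              "spherevox_io_error")
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  list(occupancy = occ, bonds = bonds, metadata = meta)
}

#' Wrap a voxelization in an indexable data handle
#'
#' An in-memory view over a `protein_voxelization` exposing the occupancy
#' tensor, bond matrix, metadata, lattice axis coordinates and
#' per-environment retained-atom tables, with lookup by box index or by
#' residue key. Iteration order equals metadata order.
#'
#' @param voxelization A `protein_voxelization`.
#' @return A `data_wrapper` list with fields `occupancy`, `bonds`,
#'   `metadata`, `axis_coords`, `retained_atoms`, `protein_id`, `lattice`.
#' @seealso [environment_at()] for lookups.
#' @export
wrap_results <- function(voxelization) {
  .sx_check_vox(voxelization)
  structure(
    list(
      protein_id = voxelization$protein_id,
      occupancy = voxelization$occupancy,
      bonds = voxelization$bonds,
      metadata = voxelization$metadata,
      axis_coords = voxelization$lattice$axis_coords,
      retained_atoms = voxelization$retained_atoms,
      lattice = voxelization$lattice
    ),
    class = "data_wrapper"
  )
}

#' Look up one residue environment in a data wrapper
#'
#' @param wrapper A `data_wrapper` from [wrap_results()].
#' @param box_index 0-based index of a processed residue, or `NULL` to
#'   look up by residue key instead.
#' @param chain_id,residue_index,residue_name Residue key components
#'   (used when `box_index` is `NULL`).
#' @return List with `metadata` (one-row tibble), `occupancy`
#'   (`n x n x n x 6 x 2` slice), `bonds` (one-row tibble) and `retained`
#'   (retained-atom tibble). Unknown keys raise a key error.
#' @export
environment_at <- function(wrapper, box_index = NULL, chain_id = NULL,
                           residue_index = NULL, residue_name = NULL) {
  stopifnot(inherits(wrapper, "data_wrapper"))
  meta <- wrapper$metadata
  if (!is.null(box_index)) {
    r <- which(meta$box_index == box_index)
  } else {
    r <- which(meta$chain_id == chain_id &
                 meta$residue_index == residue_index &
                 meta$residue_label == toupper(residue_name))
  }
  if (length(r) != 1) {
    .sx_abort(paste0(
      "No environment for ",
      if (!is.null(box_index)) paste0("box_index ", box_index) else
        paste(chain_id, residue_index, residue_name),
      " in ", wrapper$protein_id,
      " (the residue may have been skipped)."),
      "spherevox_key_error")
  }
  d <- dim(wrapper$occupancy)
  occ <- array(wrapper$occupancy[r, , , , , ], dim = d[-1])
  dimnames(occ) <- list(NULL, NULL, NULL, .sx_elements,
                        c("central", "neighbor"))
  list(
    metadata = meta[r, ],
    occupancy = occ,
    bonds = as_tibble(as.data.frame(t(wrapper$bonds[r, ]))),
    retained = wrapper$retained_atoms[[r]]
  )
}

#' @export
print.data_wrapper <- function(x, ...) {
  cat("<data_wrapper> ", x$protein_id, ": ", nrow(x$metadata),
      " residue environments\n", sep = "")
  invisible(x)
}
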