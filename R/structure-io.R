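#' Parse a PDB file into an atom table
#'
#' Reads ATOM/HETATM records (wwPDB v3.3 fixed-width layout, via
#' [bio3d::read.pdb()]) and applies the package's atom-acceptance policy:
#' alternate locations keep the first-listed altloc per atom name within a
#' residue, and HETATM records (waters included) are dropped unless
#' `keep_hetero = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param keep_hetero Keep HETATM records?
#' @return A tibble with one row per accepted atom, in file order:
#'   `serial` (1-based ordinal over accepted atoms), `pdb_serial` (the
#'   file's own serial column), `atom_name`, `element_raw` (element column,
#'   upper case), `x`, `y`, `z` (A), `chain_id`, `residue_name`,
#'   `residue_index` (author numbering), `altloc`, `is_hetero`.
#' @export
#' @examples
#' toy <- make_toy_peptide(toy_spec(n_residues = 1))
#' paths <- write_toy_pair(toy, tempfile("fix"))
#' parse_pdb(paths[["pdb"]])
parse_pdb <- function(path, keep_hetero = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    .sx_abort(paste0("PDB file not found: ", path[1]),
              "spherevox_input_error")
  }
  raw <- tryCatch(readLines(path, warn = FALSE),
                  error = function(e) .sx_abort(
                    paste0("Cannot read PDB file: ", conditionMessage(e)),
                    "spherevox_input_error"))
  if (!any(grepl("^(ATOM  |HETATM)", raw))) {
    .sx_abort(paste0("No ATOM/HETATM records in ", path),
              "spherevox_empty_structure_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) .sx_abort(
      paste0("Failed to parse PDB file: ", conditionMessage(e)),
      "spherevox_input_error"))
  at <- as_tibble(pdb$atom)
  at$insert <- at$insert %||% NA_character_
  atoms <- tibble(
    pdb_serial = as.integer(at$eleno),
    atom_name = as.character(at$elety),
    element_raw = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
    x = at$x, y = at$y, z = at$z,
    chain_id = ifelse(is.na(at$chain), "", as.character(at$chain)),
    residue_name = as.character(at$resid),
    residue_index = as.integer(at$resno),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    is_hetero = at$type == "HETATM"
  )
  if (!keep_hetero) atoms <- filter(atoms, !.data$is_hetero)
  if (nrow(atoms) == 0) {
    .sx_abort(paste0("No atoms retained from ", path,
                     " (all records are HETATM?)"),
              "spherevox_empty_structure_error")
  }
  # altloc policy: first-listed conformer per (residue, atom name)
  atoms <- atoms |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain_id, .data$residue_index, .data$residue_name,
             .data$atom_name) |>
    filter(.data$.ord == min(.data$.ord)) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    .sx_abort("Non-finite coordinates in PDB atom records.",
              "spherevox_input_error")
  }
  mutate(atoms, serial = row_number(), .before = 1)
}

#' Parse a TRIPOS MOL2 file into atom and bond tables
#'
#' Requires both `@<TRIPOS>ATOM` and `@<TRIPOS>BOND` sections. Bond type
#' codes `"1"`, `"2"`, `"3"`, `"ar"`, `"am"` map to
#' single/double/triple/aromatic/amide; any other code (e.g. `"un"`,
#' `"du"`, `"nc"`) becomes `"other"` and is carried but never counted.
#'
#' @param path Path to a TRIPOS MOL2 file.
#' @return List with `atoms` (tibble: `atom_id`, `atom_name`, `x`, `y`,
#'   `z`, `sybyl_type`) and `bonds` (tibble: `atom_a`, `atom_b`,
#'   `bond_code`).
#' @export
parse_mol2 <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    .sx_abort(paste0("MOL2 file not found: ", path[1]),
              "spherevox_input_error")
  }
  raw <- tryCatch(readLines(path, warn = FALSE),
                  error = function(e) .sx_abort(
                    paste0("Cannot read MOL2 file: ", conditionMessage(e)),
                    "spherevox_input_error"))
  for (sec in c("@<TRIPOS>ATOM", "@<TRIPOS>BOND")) {
    if (!any(raw == sec)) {
      .sx_abort(paste0("MOL2 file lacks required section ", sec, ": ", path),
                "spherevox_format_error")
    }
  }
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) .sx_abort(
                  paste0("Failed to parse MOL2 file: ", conditionMessage(e)),
                  "spherevox_format_error"))
  atoms <- tibble(
    atom_id = as.integer(m$atom$eleno),
    atom_name = as.character(m$atom$elena),
    x = m$atom$x, y = m$atom$y, z = m$atom$z,
    sybyl_type = as.character(m$atom$elety)
  )
  if (anyDuplicated(atoms$atom_id)) {
    .sx_abort("Duplicate atom_id in MOL2 ATOM section.",
              "spherevox_consistency_error")
  }
  if (any(!nzchar(atoms$sybyl_type)) || any(is.na(atoms$sybyl_type))) {
    .sx_abort("Empty SYBYL atom type in MOL2 ATOM section.",
              "spherevox_format_error")
  }
  bonds <- tibble(
    atom_a = as.integer(m$bond$origin),
    atom_b = as.integer(m$bond$target),
    bond_code = {
      code <- as.character(m$bond$type)
      out <- unname(.sx_bond_code_map[code])
      out[is.na(out)] <- "other"
      out
    }
  )
  bad <- !(bonds$atom_a %in% atoms$atom_id) | !(bonds$atom_b %in% atoms$atom_id)
  if (any(bad)) {
    .sx_abort(sprintf("%d bond(s) reference unknown atom ids.", sum(bad)),
              "spherevox_consistency_error")
  }
  if (any(bonds$atom_a == bonds$atom_b)) {
    .sx_abort("Bond with identical endpoints in MOL2 BOND section.",
              "spherevox_consistency_error")
  }
  list(atoms = atoms, bonds = bonds)
}

#' Simplify a SYBYL atom type to an element channel
#'
#' The element is the substring before the first `"."` (e.g. `C.3 -> C`,
#' `N.pl3 -> N`, `O.co2 -> O`), compared case-insensitively against the
#' six-channel vocabulary H, C, N, O, P, S. Anything outside it (halogens,
#' metals, selenium, dummy types) yields `NA`. Total and idempotent on its
#' own outputs.
#'
#' @param sybyl_type Character vector of SYBYL types.
#' @return Character vector over `c("H","C","N","O","P","S")` with `NA`
#'   for types outside the vocabulary.
#' @export
#' @examples
#' simplify_sybyl(c("C.3", "N.pl3", "O.co2", "H", "Se"))
simplify_sybyl <- function(sybyl_type) {
  el <- toupper(sub("\\..*$", "", as.character(sybyl_type)))
  ifelse(el %in% .sx_elements, el, NA_character_)
}

#' Merge paired PDB and MOL2 atom tables into an annotated structure
#'
#' Atoms are paired by ordinal position (i-th PDB atom to i-th MOL2 atom);
#' the pairing is cross-checked by requiring every paired Euclidean
#' coordinate disagreement to be at most `coord_tolerance`. Each atom gets
#' an element category via [simplify_sybyl()], falling back to the PDB
#' element column when the SYBYL type is outside the vocabulary; atoms
#' with no category are dropped together with their bonds.
#'
#' @param pdb_atoms Atom tibble from [parse_pdb()].
#' @param mol2_atoms Atom tibble from [parse_mol2()] (`$atoms`).
#' @param bonds Bond tibble from [parse_mol2()] (`$bonds`).
#' @param coord_tolerance Maximum allowed PDB/MOL2 coordinate disagreement
#'   per atom (A). The default 0.01 A absorbs format rounding (PDB prints 3
#'   decimals, MOL2 4) while catching genuinely inconsistent conversions.
#' @param protein_id Identifier stored with the structure.
#' @return An `annotated_structure`: list with `atoms` (tibble, one row
#'   per retained atom, with `element_category` and `sybyl_type`), `bonds`
#'   (endpoints guaranteed retained), `protein_id` and `residue_order`
#'   (tibble of `(chain_id, residue_index, residue_name)` in first-appearance
#'   order).
#' @export
merge_structure <- function(pdb_atoms, mol2_atoms, bonds,
                            coord_tolerance = 0.01,
                            protein_id = "protein") {
  if (nrow(pdb_atoms) == 0 || nrow(mol2_atoms) == 0) {
    .sx_abort("Both atom tables must be non-empty.",
              "spherevox_empty_structure_error")
  }
  if (nrow(pdb_atoms) != nrow(mol2_atoms)) {
    .sx_abort(sprintf(
      "Inconsistent annotation: %d PDB atoms vs %d MOL2 atoms; structure excluded.",
      nrow(pdb_atoms), nrow(mol2_atoms)),
      "spherevox_inconsistent_error")
  }
  dev <- sqrt((pdb_atoms$x - mol2_atoms$x)^2 +
                (pdb_atoms$y - mol2_atoms$y)^2 +
                (pdb_atoms$z - mol2_atoms$z)^2)
  if (any(dev > coord_tolerance)) {
    worst <- which.max(dev)
    .sx_abort(sprintf(
      paste0("Inconsistent annotation: paired coordinates disagree by up to ",
             "%.4f A (atom ordinal %d) at tolerance %g A; structure excluded."),
      max(dev), worst, coord_tolerance),
      "spherevox_inconsistent_error")
  }
  category <- simplify_sybyl(mol2_atoms$sybyl_type)
  fallback <- is.na(category) & pdb_atoms$element_raw %in% .sx_elements
  category[fallback] <- pdb_atoms$element_raw[fallback]

  atoms <- pdb_atoms |>
    mutate(atom_id = mol2_atoms$atom_id,
           sybyl_type = mol2_atoms$sybyl_type,
           element_category = category)
  retained <- filter(atoms, !is.na(.data$element_category))
  keep_bond <- bonds$atom_a %in% retained$atom_id &
    bonds$atom_b %in% retained$atom_id
  structure(
    list(
      atoms = retained,
      bonds = bonds[keep_bond, ],
      protein_id = protein_id,
      residue_order = distinct(retained, .data$chain_id,
                               .data$residue_index, .data$residue_name)
    ),
    class = "annotated_structure"
  )
}

#' Read and merge a paired PDB/MOL2 structure in one call
#'
#' @param pdb_path,mol2_path File paths.
#' @param protein_id Defaults to the shared file basename.
#' @inheritParams merge_structure
#' @inheritParams parse_pdb
#' @return An `annotated_structure` (see [merge_structure()]).
#' @export
read_structure_pair <- function(pdb_path, mol2_path,
                                protein_id = NULL,
                                coord_tolerance = 0.01,
                                keep_hetero = FALSE) {
  protein_id <- protein_id %||% sub("\\.pdb$", "", basename(pdb_path),
                                    ignore.case = TRUE)
  pdb_atoms <- parse_pdb(pdb_path, keep_hetero = keep_hetero)
  m <- parse_mol2(mol2_path)
  merge_structure(pdb_atoms, m$atoms, m$bonds,
                  coord_tolerance = coord_tolerance,
                  protein_id = protein_id)
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat("<annotated_structure> ", x$protein_id, "\n", sep = "")
  cat("  atoms:    ", nrow(x$atoms), " retained (",
      paste(names(table(x$atoms$element_category)), collapse = "/"), ")\n",
      sep = "")
  cat("  bonds:    ", nrow(x$bonds), "\n", sep = "")
  cat("  residues: ", nrow(x$residue_order), "\n", sep = "")
  invisible(x)
}
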