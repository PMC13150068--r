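#' Specification for a synthetic toy peptide
#'
#' Describes a small, fully synthetic peptide from which [make_toy_peptide()]
#' emits a paired PDB / TRIPOS MOL2 fixture with known ground truth. The
#' backbone is an idealized extended chain (N-CA 1.46 A, CA-C 1.52 A,
#' C-N 1.33 A, C=O 1.23 A, tetrahedral/trigonal angles) laid out in the
#' xy-plane; side chains extend out of plane so residue frames are chiral.
#'
#' Supported residue names: `"GLY"` (backbone only), `"ALA"` (+CB),
#' `"CYS"` (+CB, SG), `"SER"` (+CB, OG), `"PHE"` (+CB and an aromatic
#' six-ring bonded with MOL2 code `"ar"`).
#'
#' @param n_residues Number of residues (>= 1).
#' @param residue_names Character vector of residue names, recycled to
#'   `n_residues`. Defaults to `c("ALA", "GLY", "CYS")` recycled, so the
#'   default tripeptide exercises the C, N, O and S channels.
#' @param chain_id Single-character chain identifier.
#' @param residue_start Author numbering of the first residue.
#' @param with_hydrogens Add one amide hydrogen per residue (element H,
#'   SYBYL type `"H"`, bonded to backbone N)?
#' @param extra_atoms Optional list of decorations; each element is a list
#'   with fields `element` (PDB element symbol), `sybyl` (SYBYL type),
#'   `residue` (1-based residue ordinal the atom attaches to) and `offset`
#'   (3-vector, A, relative to that residue's CA). Decorations are emitted
#'   as additional atoms bonded (MOL2 code `"1"`) to their residue's CA.
#' @param protein_id Identifier used in metadata and output file names.
#' @param backbone_geometry Named list overriding the idealized geometry
#'   constants (bond lengths in A, angles in degrees); see
#'   [toy_geometry()] for the defaults and their names. The defaults are
#'   tuned so that, in every residue frame of the stock fixtures, local
#'   coordinates stay clear of the voxel-assignment boundaries at the
#'   default spacing of 1 A (rigid-motion tests can then compare tensors
#'   exactly).
#' @param seed Integer seed; reserved for randomized placement options
#'   (the default construction is fully deterministic).
#'
#' @return A `toy_spec` list, validated.
#' @export
toy_spec <- function(n_residues = 3,
                     residue_names = NULL,
                     chain_id = "A",
                     residue_start = 1L,
                     with_hydrogens = FALSE,
                     extra_atoms = NULL,
                     protein_id = "toy",
                     backbone_geometry = NULL,
                     seed = 1L) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues < 1) {
    .sx_abort("`n_residues` must be a single integer >= 1.",
              "spherevox_config_error")
  }
  n_residues <- as.integer(n_residues)
  residue_names <- rep_len(residue_names %||% c("ALA", "GLY", "CYS"),
                           n_residues)
  known <- c("GLY", "ALA", "CYS", "SER", "PHE")
  if (!all(residue_names %in% known)) {
    .sx_abort(
      paste0("Unsupported residue name(s): ",
             paste(setdiff(residue_names, known), collapse = ", "),
             ". Supported: ", paste(known, collapse = ", "), "."),
      "spherevox_config_error"
    )
  }
  if (!is.null(extra_atoms)) {
    ok <- vapply(extra_atoms, function(e) {
      is.list(e) && all(c("element", "sybyl", "residue", "offset") %in% names(e)) &&
        length(e$offset) == 3 && all(is.finite(e$offset)) &&
        e$residue >= 1 && e$residue <= n_residues
    }, logical(1))
    if (!all(ok)) {
      .sx_abort("Each extra_atoms entry needs element, sybyl, residue and a finite 3-vector offset.",
                "spherevox_config_error")
    }
  }
  geo <- toy_geometry()
  if (!is.null(backbone_geometry)) {
    bad <- setdiff(names(backbone_geometry), names(geo))
    if (length(bad)) {
      .sx_abort(paste0("Unknown backbone_geometry field(s): ",
                       paste(bad, collapse = ", ")),
                "spherevox_config_error")
    }
    geo[names(backbone_geometry)] <- backbone_geometry
  }
  structure(
    list(n_residues = n_residues, residue_names = residue_names,
         chain_id = chain_id, residue_start = as.integer(residue_start),
         with_hydrogens = isTRUE(with_hydrogens), extra_atoms = extra_atoms,
         protein_id = protein_id, geometry = geo, seed = as.integer(seed)),
    class = "toy_spec"
  )
}

#' Default geometry constants for the toy-peptide generator
#'
#' Idealized extended-chain values: bond lengths in Angstrom
#' (`n_ca`, `ca_c`, `c_n`, `c_o`, `cb_len`, `sg_len`, `og_len`, `h_len`,
#' `cg_len`, `ring_r`), backbone angles in degrees (`ang_n_ca_c`,
#' `ang_ca_c_n`, `ang_c_n_ca`) and out-of-plane offsets (`cb_z`,
#' `branch_z`, `h_z`).
#'
#' @return Named list of geometry constants.
#' @export
toy_geometry <- function() {
  # near-ideal extended-chain values, adjusted within ~0.07 A / ~5 degrees
  # of textbook geometry so stock fixtures keep a >= 0.05 A clearance from
  # voxel-assignment boundaries at spacing 1 A
  list(
    n_ca = 1.474, ca_c = 1.45, c_n = 1.30, c_o = 1.287,
    ang_n_ca_c = 119.7, ang_ca_c_n = 119.4, ang_c_n_ca = 115.9,
    cb_len = 1.508, cb_z = 1.196,
    sg_len = 1.744, og_len = 1.435, branch_z = 0.438,
    h_len = 1.018, h_z = -0.722,
    cg_len = 1.51, ring_r = 1.39
  )
}

.sx_unit <- function(v) v / sqrt(sum(v * v))

# Turtle construction of an extended backbone in the xy-plane.
.sx_toy_backbone <- function(n_res, geo) {
  d2r <- pi / 180
  step <- function(p, phi, l) p + l * c(cos(phi), sin(phi), 0)
  pos <- c(0, 0, 0); phi <- 0; sgn <- 1
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    n_at <- pos
    pos <- step(pos, phi, geo$n_ca); ca <- pos
    phi <- phi + sgn * (180 - geo$ang_n_ca_c) * d2r; sgn <- -sgn
    pos <- step(pos, phi, geo$ca_c); c_at <- pos
    phi <- phi + sgn * (180 - geo$ang_ca_c_n) * d2r; sgn <- -sgn
    n_next <- step(c_at, phi, geo$c_n)
    bis <- -(.sx_unit(ca - c_at) + .sx_unit(n_next - c_at))
    o_at <- c_at + geo$c_o * .sx_unit(bis)
    out[[i]] <- list(N = n_at, CA = ca, C = c_at, O = o_at)
    pos <- n_next
    phi <- phi + sgn * (180 - geo$ang_c_n_ca) * d2r; sgn <- -sgn
  }
  out
}

# Side-chain atoms and intra-residue bonds for one residue.
.sx_side_chain <- function(resname, n_at, ca, c_at, geo) {
  if (resname == "GLY") return(list(atoms = list(), bonds = list()))
  u_n <- .sx_unit(n_at - ca); u_c <- .sx_unit(c_at - ca)
  cb <- ca + geo$cb_len * .sx_unit(-(u_n + u_c) + c(0, 0, geo$cb_z))
  atoms <- list(list(name = "CB", element = "C", sybyl = "C.3", xyz = cb))
  bonds <- list(list(a = "CA", b = "CB", code = "1"))
  if (resname == "CYS") {
    sg <- cb + geo$sg_len * .sx_unit(cb - ca + c(0, 0, geo$branch_z))
    atoms <- c(atoms, list(list(name = "SG", element = "S", sybyl = "S.3", xyz = sg)))
    bonds <- c(bonds, list(list(a = "CB", b = "SG", code = "1")))
  } else if (resname == "SER") {
    og <- cb + geo$og_len * .sx_unit(cb - ca + c(0, 0, geo$branch_z))
    atoms <- c(atoms, list(list(name = "OG", element = "O", sybyl = "O.3", xyz = og)))
    bonds <- c(bonds, list(list(a = "CB", b = "OG", code = "1")))
  } else if (resname == "PHE") {
    d <- .sx_unit(cb - ca)
    e0 <- c(0, 0, 1) - sum(c(0, 0, 1) * d) * d
    if (sqrt(sum(e0^2)) < 1e-6) e0 <- c(1, 0, 0) - sum(c(1, 0, 0) * d) * d
    e <- .sx_unit(e0)
    ctr <- cb + (geo$cg_len + geo$ring_r) * d
    ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    th <- (0:5) * 60 * pi / 180
    for (k in 1:6) {
      v <- ctr + geo$ring_r * (cos(th[k]) * (-d) + sin(th[k]) * e)
      atoms <- c(atoms, list(list(name = ring[k], element = "C",
                                  sybyl = "C.ar", xyz = v)))
    }
    bonds <- c(bonds, list(list(a = "CB", b = "CG", code = "1")))
    for (k in 1:6) {
      bonds <- c(bonds, list(list(a = ring[k], b = ring[k %% 6 + 1], code = "ar")))
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' Generate a paired PDB/MOL2 toy peptide with ground truth
#'
#' Emits a synthetic peptide as PDB text and TRIPOS MOL2 text with identical
#' atom order and coordinates (PDB rounded to 3 decimals, MOL2 to 4), plus a
#' `ground_truth` record for oracle-style tests.
#'
#' @param spec A [toy_spec()].
#' @return A list with elements `pdb` (single string), `mol2` (single
#'   string) and `truth` (list: `atoms` tibble, `bonds` tibble with MOL2
#'   code and mapped `bond_code`, `residue_order` tibble, `protein_id`).
#' @export
#' @examples
#' toy <- make_toy_peptide(toy_spec(n_residues = 2))
#' cat(substr(toy$pdb, 1, 80))
make_toy_peptide <- function(spec) {
  if (!inherits(spec, "toy_spec")) spec <- do.call(toy_spec, as.list(spec))
  bb <- .sx_toy_backbone(spec$n_residues, spec$geometry)

  rows <- list(); bonds <- list()
  serial <- 0L
  key_of <- function(res_i, name) paste0(res_i, ":", name)
  id_by_key <- new.env(parent = emptyenv())

  add_atom <- function(res_i, name, element, sybyl, xyz) {
    serial <<- serial + 1L
    rows[[serial]] <<- tibble(
      serial = serial, atom_name = name, element = element,
      sybyl_type = sybyl, chain_id = spec$chain_id,
      residue_index = spec$residue_start + res_i - 1L,
      residue_name = spec$residue_names[res_i],
      x = round(xyz[1], 4), y = round(xyz[2], 4), z = round(xyz[3], 4)
    )
    assign(key_of(res_i, name), serial, envir = id_by_key)
    serial
  }
  add_bond <- function(res_a, name_a, res_b, name_b, code) {
    bonds[[length(bonds) + 1L]] <<- tibble(
      atom_a = get(key_of(res_a, name_a), envir = id_by_key),
      atom_b = get(key_of(res_b, name_b), envir = id_by_key),
      code = code
    )
  }

  for (i in seq_len(spec$n_residues)) {
    g <- bb[[i]]
    resname <- spec$residue_names[i]
    add_atom(i, "N", "N", if (i == 1) "N.3" else "N.am", g$N)
    add_atom(i, "CA", "C", "C.3", g$CA)
    add_atom(i, "C", "C", "C.2", g$C)
    add_atom(i, "O", "O", "O.2", g$O)
    sc <- .sx_side_chain(resname, g$N, g$CA, g$C, spec$geometry)
    for (a in sc$atoms) add_atom(i, a$name, a$element, a$sybyl, a$xyz)
    if (spec$with_hydrogens) {
      h <- g$N + spec$geometry$h_len *
        .sx_unit(-.sx_unit(g$CA - g$N) + c(0, 0, spec$geometry$h_z))
      add_atom(i, "H", "H", "H", h)
    }
    add_bond(i, "N", i, "CA", "1")
    add_bond(i, "CA", i, "C", "1")
    add_bond(i, "C", i, "O", "2")
    for (b in sc$bonds) add_bond(i, b$a, i, b$b, b$code)
    if (spec$with_hydrogens) add_bond(i, "N", i, "H", "1")
    if (i > 1) add_bond(i - 1, "C", i, "N", "am")
  }

  if (!is.null(spec$extra_atoms)) {
    for (k in seq_along(spec$extra_atoms)) {
      e <- spec$extra_atoms[[k]]
      ca <- bb[[e$residue]]$CA
      nm <- e$name %||% paste0("X", k)
      add_atom(e$residue, nm, e$element, e$sybyl, ca + e$offset)
      add_bond(e$residue, nm, e$residue, "CA", "1")
    }
  }

  atoms <- bind_rows(rows)
  bond_tbl <- if (length(bonds)) bind_rows(bonds) else
    tibble(atom_a = integer(), atom_b = integer(), code = character())
  bond_tbl$bond_code <- unname(.sx_bond_code_map[bond_tbl$code])
  bond_tbl$bond_code[is.na(bond_tbl$bond_code)] <- "other"

  truth <- list(
    atoms = atoms,
    bonds = bond_tbl,
    residue_order = distinct(atoms, .data$chain_id, .data$residue_index,
                             .data$residue_name),
    protein_id = spec$protein_id
  )
  list(pdb = .sx_emit_pdb(atoms), mol2 = .sx_emit_mol2(atoms, bond_tbl,
                                                       spec$protein_id),
       truth = truth)
}

.sx_pdb_name_field <- function(name) {
  # element symbols of one character start in column 14
  ifelse(nchar(name) < 4, sprintf(" %-3s", name), name)
}

.sx_emit_pdb <- function(atoms) {
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, .sx_pdb_name_field(atoms$atom_name), atoms$residue_name,
    atoms$chain_id, atoms$residue_index,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element
  )
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

.sx_emit_mol2 <- function(atoms, bonds, name) {
  head <- c(
    "@<TRIPOS>MOLECULE", name,
    sprintf("%5d %5d %5d", nrow(atoms), nrow(bonds), 1L),
    "SMALL", "NO_CHARGES", ""
  )
  atom_lines <- sprintf(
    "%7d %-8s %9.4f %9.4f %9.4f %-9s %3d %-8s %9.4f",
    atoms$serial, atoms$atom_name, atoms$x, atoms$y, atoms$z,
    atoms$sybyl_type, atoms$residue_index,
    paste0(atoms$residue_name, atoms$residue_index), 0
  )
  bond_lines <- if (nrow(bonds)) sprintf("%6d %5d %5d %4s",
                                         seq_len(nrow(bonds)), bonds$atom_a,
                                         bonds$atom_b, bonds$code) else character()
  paste0(paste(c(head, "@<TRIPOS>ATOM", atom_lines,
                 "@<TRIPOS>BOND", bond_lines), collapse = "\n"), "\n")
}

#' Write a toy peptide pair to disk
#'
#' @param toy Output of [make_toy_peptide()] (or a [toy_spec()], which is
#'   generated first).
#' @param dir Directory (created if needed).
#' @param name Basename for `<name>.pdb` / `<name>.mol2`; defaults to the
#'   spec's `protein_id`.
#' @return Named character vector with elements `pdb` and `mol2` (paths).
#' @export
write_toy_pair <- function(toy, dir, name = NULL) {
  if (inherits(toy, "toy_spec")) toy <- make_toy_peptide(toy)
  name <- name %||% toy$truth$protein_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  mol2_path <- file.path(dir, paste0(name, ".mol2"))
  writeLines(sub("\n$", "", toy$pdb), pdb_path)
  writeLines(sub("\n$", "", toy$mol2), mol2_path)
  c(pdb = pdb_path, mol2 = mol2_path)
}

# Minimal parser for the generator's own emitted dialect (corrupt/transform
# round-trip through this; it is not a general PDB/MOL2 reader).
.sx_parse_toy_pair <- function(pdb_text, mol2_text) {
  plines <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  al <- grepl("^(ATOM|HETATM)", plines)
  p <- plines[al]
  atoms <- tibble(
    serial = as.integer(substr(p, 7, 11)),
    atom_name = trimws(substr(p, 13, 16)),
    residue_name = trimws(substr(p, 18, 20)),
    chain_id = trimws(substr(p, 22, 22)),
    residue_index = as.integer(substr(p, 23, 26)),
    x = as.numeric(substr(p, 31, 38)),
    y = as.numeric(substr(p, 39, 46)),
    z = as.numeric(substr(p, 47, 54)),
    element = trimws(substr(p, 77, 78))
  )
  mlines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  sec <- grep("^@<TRIPOS>", mlines)
  sec_name <- mlines[sec]
  take <- function(which) {
    i <- match(which, sec_name)
    if (is.na(i)) return(character())
    from <- sec[i] + 1L
    to <- if (i < length(sec)) sec[i + 1L] - 1L else length(mlines)
    out <- mlines[seq(from, to)]
    out[nzchar(trimws(out))]
  }
  mol_head <- take("@<TRIPOS>MOLECULE")
  a <- take("@<TRIPOS>ATOM")
  af <- strsplit(trimws(a), "\\s+")
  matoms <- tibble(
    atom_id = as.integer(vapply(af, `[`, "", 1)),
    atom_name = vapply(af, `[`, "", 2),
    x = as.numeric(vapply(af, `[`, "", 3)),
    y = as.numeric(vapply(af, `[`, "", 4)),
    z = as.numeric(vapply(af, `[`, "", 5)),
    sybyl_type = vapply(af, `[`, "", 6),
    residue_index = as.integer(vapply(af, `[`, "", 7))
  )
  b <- take("@<TRIPOS>BOND")
  bf <- strsplit(trimws(b), "\\s+")
  mbonds <- if (length(bf)) tibble(
    atom_a = as.integer(vapply(bf, `[`, "", 2)),
    atom_b = as.integer(vapply(bf, `[`, "", 3)),
    code = vapply(bf, `[`, "", 4)
  ) else tibble(atom_a = integer(), atom_b = integer(), code = character())
  list(atoms = atoms, matoms = matoms, bonds = mbonds,
       mol_name = mol_head[1])
}

.sx_reemit_pair <- function(parsed, drop_bond_section = FALSE) {
  atoms <- parsed$atoms
  atoms$sybyl_type <- parsed$matoms$sybyl_type
  # re-emit from merged table so both files stay index-aligned
  pdb <- .sx_emit_pdb(atoms)
  bonds <- parsed$bonds
  m_atoms <- atoms
  m_atoms$x <- parsed$matoms$x; m_atoms$y <- parsed$matoms$y
  m_atoms$z <- parsed$matoms$z
  mol2 <- .sx_emit_mol2(m_atoms, bonds, parsed$mol_name)
  if (drop_bond_section) {
    mol2 <- sub("(?s)@<TRIPOS>BOND.*$", "", mol2, perl = TRUE)
  }
  list(pdb = pdb, mol2 = mol2)
}

#' Inject a single targeted defect into a toy peptide pair
#'
#' Used to exercise the exclusion/skip behaviour of the parsing and
#' voxelization pipeline: structures with missing or inconsistent
#' annotations must be excluded, residues with incomplete backbones
#' skipped, and atoms outside the H/C/N/O/P/S vocabulary dropped.
#'
#' Modes: `"drop_backbone_atom"` removes the CA of the second residue (the
#' first if only one) from both files; `"shift_mol2_atom"` displaces one
#' MOL2 atom by +0.5 A in x so PDB/MOL2 coordinates disagree;
#' `"drop_bond_section"` deletes the `@<TRIPOS>BOND` section;
#' `"add_selenium"` appends a selenium atom (bonded to the last atom) to
#' both files.
#'
#' @param pdb_text,mol2_text Texts as produced by [make_toy_peptide()].
#' @param mode One of the four modes above.
#' @return List with modified `pdb` and `mol2` texts.
#' @export
corrupt <- function(pdb_text, mol2_text,
                    mode = c("drop_backbone_atom", "shift_mol2_atom",
                             "drop_bond_section", "add_selenium")) {
  mode <- tryCatch(match.arg(mode), error = function(e)
    .sx_abort(paste0("Unknown corruption mode: ", mode[1]),
              "spherevox_config_error"))
  p <- .sx_parse_toy_pair(pdb_text, mol2_text)
  if (mode == "drop_backbone_atom") {
    res <- unique(p$atoms$residue_index)
    target_res <- if (length(res) >= 2) res[2] else res[1]
    i <- which(p$atoms$atom_name == "CA" &
                 p$atoms$residue_index == target_res)[1]
    if (is.na(i)) .sx_abort("No CA atom found to drop.",
                            "spherevox_config_error")
    p$atoms <- p$atoms[-i, ]
    p$matoms <- p$matoms[-i, ]
    keep <- p$bonds$atom_a != i & p$bonds$atom_b != i
    p$bonds <- p$bonds[keep, ]
    remap <- function(v) ifelse(v > i, v - 1L, v)
    p$bonds$atom_a <- remap(p$bonds$atom_a)
    p$bonds$atom_b <- remap(p$bonds$atom_b)
    p$atoms$serial <- seq_len(nrow(p$atoms))
    p$matoms$atom_id <- seq_len(nrow(p$matoms))
    .sx_reemit_pair(p)
  } else if (mode == "shift_mol2_atom") {
    i <- min(3L, nrow(p$matoms))
    p$matoms$x[i] <- p$matoms$x[i] + 0.5
    .sx_reemit_pair(p)
  } else if (mode == "drop_bond_section") {
    .sx_reemit_pair(p, drop_bond_section = TRUE)
  } else { # add_selenium
    last <- nrow(p$atoms)
    new <- p$atoms[last, ]
    new$serial <- last + 1L
    new$atom_name <- "SE"
    new$element <- "SE"
    new$x <- new$x + 1.95
    p$atoms <- bind_rows(p$atoms, new)
    mnew <- p$matoms[last, ]
    mnew$atom_id <- last + 1L
    mnew$atom_name <- "SE"
    mnew$sybyl_type <- "Se"
    mnew$x <- mnew$x + 1.95
    p$matoms <- bind_rows(p$matoms, mnew)
    p$bonds <- bind_rows(p$bonds,
                         tibble(atom_a = last, atom_b = last + 1L, code = "1"))
    .sx_reemit_pair(p)
  }
}

#' Apply a proper rigid motion to a toy peptide pair
#'
#' Every coordinate in both files is mapped `x -> R x + t`; everything else
#' is unchanged (an identity transform reproduces the input byte for byte).
#' Only proper rotations are accepted: reflections would silently change
#' the chirality the residue frames encode.
#'
#' @param pdb_text,mol2_text Texts as produced by [make_toy_peptide()].
#' @param rotation 3x3 proper orthonormal matrix (checked to 1e-9).
#' @param translation Length-3 numeric vector, A.
#' @return List with transformed `pdb` and `mol2` texts.
#' @export
rigid_transform <- function(pdb_text, mol2_text, rotation,
                            translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    .sx_abort("`rotation` must be a proper orthonormal 3x3 matrix (det +1).",
              "spherevox_config_error")
  }
  p <- .sx_parse_toy_pair(pdb_text, mol2_text)
  tr <- function(df) {
    xyz <- t(rotation %*% t(as.matrix(df[, c("x", "y", "z")])) + translation)
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  p$atoms <- tr(p$atoms)
  p$matoms <- tr(p$matoms)
  .sx_reemit_pair(p)
}

#' Draw a random proper rigid motion
#'
#' @param max_translation Translations are drawn uniformly in
#'   `[-max_translation, max_translation]` per axis.
#' @return List with `rotation` (3x3, det +1) and `translation` (length 3).
#'   Uses the current RNG state; call `set.seed()` beforehand for
#'   reproducibility.
#' @export
random_rigid_transform <- function(max_translation = 20) {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- diag(sign(diag(qr.R(qr_dec))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q,
       translation = stats::runif(3, -max_translation, max_translation))
}
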