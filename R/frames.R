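#' Build a residue-centered backbone coordinate frame
#'
#' The frame is anchored at the unweighted centroid of the backbone N,
#' C-alpha and C atoms and oriented by their geometry: with `u = CA - N`
#' and `v = C - CA`, the local x axis is `u / |u|`, the local z axis is
#' `(u x v) / |u x v|`, and y completes the right-handed triad. The
#' rotation matrix rows are (x, y, z), so it maps global to local
#' coordinates. Projecting the backbone into its own frame puts N -> CA
#' along +x with the N/CA/C plane as the local xy-plane; this normalizes
#' away global position and orientation (but not reflections).
#'
#' @param n_coord,ca_coord,c_coord Global coordinates (length-3, A) of the
#'   residue's N, C-alpha and C atoms.
#' @param residue_key List or named vector with `chain_id`,
#'   `residue_index`, `residue_name` identifying the residue.
#' @return A `residue_frame`: list with `origin` (centroid), `rotation`
#'   (3x3 orthonormal, det +1) and `residue_key`.
#' @export
#' @examples
#' fr <- residue_frame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
#'                     list(chain_id = "A", residue_index = 1,
#'                          residue_name = "GLY"))
#' fr$origin    # (2/3, 1/3, 0)
#' fr$rotation  # identity
residue_frame <- function(n_coord, ca_coord, c_coord, residue_key) {
  coords <- rbind(n_coord, ca_coord, c_coord)
  if (!is.numeric(coords) || ncol(coords) != 3 || !all(is.finite(coords))) {
    .sx_abort("Backbone coordinates must be three finite 3-vectors.",
              "spherevox_input_error")
  }
  u <- as.numeric(ca_coord - n_coord)
  v <- as.numeric(c_coord - ca_coord)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(w^2)) < 1e-8) {
    .sx_abort("Degenerate residue frame: backbone N/CA/C collinear or coincident.",
              "spherevox_degenerate_frame_error")
  }
  x_hat <- u / sqrt(sum(u^2))
  z_hat <- w / sqrt(sum(w^2))
  y_hat <- c(z_hat[2] * x_hat[3] - z_hat[3] * x_hat[2],
             z_hat[3] * x_hat[1] - z_hat[1] * x_hat[3],
             z_hat[1] * x_hat[2] - z_hat[2] * x_hat[1])
  structure(
    list(
      origin = as.numeric(n_coord + ca_coord + c_coord) / 3,
      rotation = rbind(x_hat, y_hat, z_hat, deparse.level = 0),
      residue_key = as.list(residue_key)
    ),
    class = "residue_frame"
  )
}

#' Project a structure's atoms into a residue frame
#'
#' Applies `local = rotation %*% (global - origin)` to every retained atom
#' of the structure (a rigid map: pairwise distances are preserved), and
#' flags atoms of the frame's own residue as central.
#'
#' @param structure An `annotated_structure` from [merge_structure()].
#' @param frame A `residue_frame` from [residue_frame()].
#' @return Tibble with one row per atom: `atom_id`, local `x`, `y`, `z`
#'   (A), `element_category`, `is_central`.
#' @export
project_atoms <- function(structure, frame) {
  stopifnot(inherits(structure, "annotated_structure"),
            inherits(frame, "residue_frame"))
  at <- structure$atoms
  g <- as.matrix(at[, c("x", "y", "z")])
  loc <- sweep(g, 2, frame$origin) %*% t(frame$rotation)
  key <- frame$residue_key
  tibble(
    atom_id = at$atom_id,
    x = loc[, 1], y = loc[, 2], z = loc[, 3],
    element_category = at$element_category,
    is_central = at$chain_id == key$chain_id &
      at$residue_index == key$residue_index &
      at$residue_name == key$residue_name
  )
}

# Backbone lookup: frames for every residue with a complete N/CA/C set.
# Returns frames plus a log of skipped residues (missing atoms or
# degenerate geometry).
.sx_backbone_frames <- function(structure) {
  at <- structure$atoms
  res <- structure$residue_order
  frames <- list()
  skipped <- list()
  for (i in seq_len(nrow(res))) {
    key <- list(chain_id = res$chain_id[i],
                residue_index = res$residue_index[i],
                residue_name = res$residue_name[i])
    rows <- at[at$chain_id == key$chain_id &
                 at$residue_index == key$residue_index &
                 at$residue_name == key$residue_name, ]
    pick <- function(nm) {
      hit <- rows[rows$atom_name == nm, c("x", "y", "z")]
      if (nrow(hit) == 0) NULL else as.numeric(hit[1, ])
    }
    n_c <- pick("N"); ca_c <- pick("CA"); c_c <- pick("C")
    if (is.null(n_c) || is.null(ca_c) || is.null(c_c)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(!!!key, reason = "incomplete backbone (missing N, CA or C)")
      next
    }
    fr <- tryCatch(residue_frame(n_c, ca_c, c_c, key),
                   spherevox_degenerate_frame_error = function(e) NULL)
    if (is.null(fr)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(!!!key, reason = "degenerate backbone geometry")
      next
    }
    frames[[length(frames) + 1L]] <- fr
  }
  list(
    frames = frames,
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(chain_id = character(), residue_index = integer(),
             residue_name = character(), reason = character())
  )
}

#' @export
print.residue_frame <- function(x, ...) {
  k <- x$residue_key
  cat(sprintf("<residue_frame> %s/%s %s  origin (%.3f, %.3f, %.3f)\n",
              k$chain_id, k$residue_index, k$residue_name,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}
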