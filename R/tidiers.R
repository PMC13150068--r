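#' Tidy a protein voxelization into a long tibble of occupied voxels
#'
#' One row per set occupancy cell, joining in the residue metadata and the
#' lattice axis coordinates of the voxel center.
#'
#' @param x A `protein_voxelization`.
#' @param ... Unused.
#' @return Tibble with columns `box_index`, `residue_index`,
#'   `residue_label`, `ix`, `iy`, `iz` (0-based voxel indices), `x`, `y`,
#'   `z` (voxel-center coordinates in the residue frame, A), `element`,
#'   `membership` (`"central"` / `"neighbor"`).
#' @export
tidy.protein_voxelization <- function(x, ...) {
  hits <- which(x$occupancy == 1L, arr.ind = TRUE)
  ax <- x$lattice$axis_coords
  meta <- x$metadata
  r <- hits[, 1]
  tibble(
    box_index = meta$box_index[r],
    residue_index = meta$residue_index[r],
    residue_label = meta$residue_label[r],
    ix = hits[, 2] - 1L, iy = hits[, 3] - 1L, iz = hits[, 4] - 1L,
    x = ax[hits[, 2]], y = ax[hits[, 3]], z = ax[hits[, 4]],
    element = factor(.sx_elements[hits[, 5]], levels = .sx_elements),
    membership = factor(c("central", "neighbor")[hits[, 6]],
                        levels = c("central", "neighbor"))
  ) |>
    arrange(.data$box_index, .data$ix, .data$iy, .data$iz,
            .data$element, .data$membership)
}

#' One-row summary of a protein voxelization
#'
#' @param x A `protein_voxelization`.
#' @param ... Unused.
#' @return One-row tibble: `protein_id`, `n_residues` (processed),
#'   `n_skipped`, `box_size`, `spacing`, `n_per_axis`, `use_spheres`,
#'   `n_occupied` (set occupancy cells) and total counts per bond type.
#' @export
glance.protein_voxelization <- function(x, ...) {
  totals <- colSums(x$bonds)
  tibble(
    protein_id = x$protein_id,
    n_residues = nrow(x$metadata),
    n_skipped = nrow(x$skipped),
    box_size = x$lattice$box_size,
    spacing = x$lattice$spacing,
    n_per_axis = x$lattice$n_per_axis,
    use_spheres = isTRUE(x$use_spheres),
    n_occupied = sum(x$occupancy),
    !!!as.list(totals)
  )
}

#' Plot one residue environment's occupied voxels
#'
#' A 2D projection of the occupied voxels of one residue-centered sphere
#' onto the local xy-plane (depth along z mapped to point size), coloured
#' by element channel and faceted by central/neighbor membership —
#' a flat rendering of the per-channel panels a voxel browser would show.
#'
#' @param object A `protein_voxelization`.
#' @param box_index Which environment to show (0-based; default 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_voxelization <- function(object, box_index = 0, ...) {
  td <- tidy(object)
  td <- filter(td, .data$box_index == !!box_index)
  if (nrow(td) == 0) {
    .sx_abort(paste0("No occupied voxels for box_index ", box_index, "."),
              "spherevox_key_error")
  }
  lab <- sprintf("%s — residue %d (%s), B = %g A, s = %g A",
                 object$protein_id, td$residue_index[1], td$residue_label[1],
                 object$lattice$box_size, object$lattice$spacing)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$element,
                                   size = .data$z)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~membership) +
    ggplot2::coord_equal() +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(title = lab, x = "local x (Å)", y = "local y (Å)",
                  colour = "element", size = "local z (Å)") +
    ggplot2::theme_minimal()
}

#' Plot bond-type counts across residue environments
#'
#' Line profile of the five covalent bond-type counts against box index,
#' the per-protein view of the bond feature matrix.
#'
#' @param voxelization A `protein_voxelization`.
#' @return A ggplot object.
#' @export
plot_bond_counts <- function(voxelization) {
  stopifnot(inherits(voxelization, "protein_voxelization"))
  df <- as_tibble(as.data.frame(voxelization$bonds))
  df$box_index <- voxelization$metadata$box_index
  long <- tidyr::pivot_longer(df, -"box_index",
                              names_to = "bond_type", values_to = "count")
  long$bond_type <- factor(long$bond_type, levels = .sx_bond_types)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$box_index, y = .data$count,
                                     colour = .data$bond_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = paste0(voxelization$protein_id,
                                 ": covalent bond types per environment"),
                  x = "box index", y = "bond count", colour = "bond type") +
    ggplot2::theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
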