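#' Voxelize a surface mesh into a binary occupancy grid
#'
#' Converts a watertight triangulated surface into an isotropic 3D binary
#' occupancy grid.  The surface is first rasterized into a voxel shell;
#' the exterior is then flood-filled (6-connectivity) from the padded grid
#' boundary, which classifies all off-surface voxels robustly.  Voxels on
#' the one-voxel-thick surface shell, whose centers may fall either side
#' of the surface, are resolved by a parity ray test on their centers, so
#' the filled grid contains exactly the voxels whose centers lie inside
#' the closed surface.
#'
#' @param mesh a `surface_mesh`; must be watertight when `fill = TRUE`.
#' @param spacing isotropic voxel edge h (mm).  Default 0.25 mm, suited to
#'   vessels of 3-4 mm baseline diameter.
#' @param fill if `TRUE` (default) return the solid interior; if `FALSE`
#'   return only the rasterized surface shell.
#' @param pad number of empty voxels guaranteed around the mesh (>= 1).
#' @return A `voxel_grid`: list with `occupancy` (3D logical array, axis
#'   order x, y, z), `origin` (mm coordinates of the center of voxel
#'   `[1,1,1]`), `spacing` (mm) and `dims`.
#' @export
voxelize_mesh <- function(mesh, spacing = 0.25, fill = TRUE, pad = 2L) {
  if (spacing <= 0) stop("spacing must be positive")
  pad <- max(1L, as.integer(pad))
  if (fill && !is_watertight(mesh))
    stop("mesh is not watertight: cannot fill interior")
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  # generic (golden-ratio) sub-voxel offset: avoids the degenerate case of
  # mesh features lying exactly on voxel centers, which biases center-inside
  # counting on aligned analytic shapes
  origin <- unname(lo - (pad + 0.38196601125) * spacing)
  dims <- as.integer(ceiling((hi - origin) / spacing)) + pad + 1L
  shell <- cpp_mark_shell(mesh$vertices, mesh$faces, origin, spacing, dims)
  ext <- cpp_flood_exterior(shell, dims)
  if (fill) {
    occ <- !ext & !shell
    shell_ids <- which(shell) - 1L
    if (length(shell_ids)) {
      ins <- cpp_inside_parity(mesh$vertices, mesh$faces, origin, spacing,
                               dims, shell_ids)
      occ[shell_ids[ins] + 1L] <- TRUE
    }
  } else {
    occ <- shell
  }
  occ <- array(occ, dim = dims)
  if (!any(occ)) stop("voxelization produced an empty grid")
  min_d <- 2 * min_mesh_radius_estimate(mesh)
  if (is.finite(min_d) && min_d / spacing < 4)
    warning(sprintf("spacing %.3g mm is coarse: fewer than 4 voxels across the minimum diameter (%.3g mm)",
                    spacing, min_d))
  structure(list(occupancy = occ, origin = origin, spacing = spacing,
                 dims = dims),
            class = "voxel_grid")
}

# crude lower bound on the local diameter used only for the resolution
# warning: twice the smallest distance from the volume centroid-axis; we
# simply use the smallest bbox extent / 10 as a cheap heuristic floor.
min_mesh_radius_estimate <- function(mesh) {
  ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
  min(ext) / 2
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d at h = %.3g mm, %d occupied (%.1f mm^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, sum(x$occupancy),
              sum(x$occupancy) * x$spacing^3))
  invisible(x)
}

#' Volume represented by an occupancy grid
#' @param grid a `voxel_grid`.
#' @return Occupied voxel count times h^3 (mm^3).
#' @export
grid_volume <- function(grid) sum(grid$occupancy) * grid$spacing^3

#' World coordinates of occupied voxel centers
#' @param grid a `voxel_grid`.
#' @return `n x 3` matrix of mm coordinates.
#' @export
grid_points <- function(grid) {
  idx <- which(grid$occupancy, arr.ind = TRUE)
  sweep((idx - 1) * grid$spacing, 2, grid$origin, "+")
}

#' Number of connected components of the occupied set
#' @param grid a `voxel_grid`.
#' @param conn connectivity, 6 or 26.
#' @return Component count.
#' @export
grid_components <- function(grid, conn = 26) {
  lab <- cpp_label_components(as.logical(grid$occupancy), grid$dims,
                              as.integer(conn))
  max(lab)
}

#' Dump a grid as flat binary + JSON-style header (debugging aid)
#' @param grid a `voxel_grid`.
#' @param path output path prefix; writes `<path>.bin` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
dump_grid <- function(grid, path) {
  writeBin(as.integer(grid$occupancy), paste0(path, ".bin"), size = 1)
  hdr <- sprintf(
    '{"dims": [%d, %d, %d], "origin": [%g, %g, %g], "spacing": %g, "order": "x-fastest"}',
    grid$dims[1], grid$dims[2], grid$dims[3],
    grid$origin[1], grid$origin[2], grid$origin[3], grid$spacing)
  writeLines(hdr, paste0(path, ".json"))
  invisible(path)
}
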