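#' Export a mesh (and optional solution) as a legacy ASCII VTK file
#'
#' Writes the reference mesh as a VTK unstructured grid with the layer tag
#' as cell data and, when a displacement vector is supplied, the
#' displacement as point data (so the deformed configuration can be warped
#' in ParaView or similar). Cross-section meshes are written as
#' biquadratic quads, volume meshes as hexahedra.
#'
#' @param mesh A `bilayer_mesh`.
#' @param file Output path.
#' @param u Optional nodal displacement vector.
#' @export
write_vtk <- function(mesh, file, u = NULL) {
  stopifnot(inherits(mesh, "bilayer_mesh"))
  d <- mesh$dim
  n <- nrow(mesh$coords)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("morphowrinkle bilayer mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  pts <- if (d == 2L) cbind(mesh$coords[, 1], mesh$coords[, 2], 0)
         else mesh$coords
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 12),
                                             collapse = " ")), con)
  ne <- nrow(mesh$conn)
  if (d == 2L) {
    # VTK biquadratic quad (28): corners, edge mids, centre
    ord <- c(1L, 3L, 9L, 7L, 2L, 6L, 8L, 4L, 5L)
    cells <- cbind(9L, mesh$conn[, ord, drop = FALSE] - 1L)
    ctype <- 28L
  } else {
    ord <- c(1L, 2L, 4L, 3L, 5L, 6L, 8L, 7L)
    cells <- cbind(8L, mesh$conn[, ord, drop = FALSE] - 1L)
    ctype <- 12L
  }
  wl("CELLS ", ne, " ", length(cells))
  writeLines(apply(cells, 1, paste, collapse = " "), con)
  wl("CELL_TYPES ", ne)
  writeLines(as.character(rep(ctype, ne)), con)
  wl("CELL_DATA ", ne)
  wl("SCALARS layer int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(mesh$layer), con)
  if (!is.null(u)) {
    um <- matrix(u, ncol = d, byrow = TRUE)
    if (d == 2L) um <- cbind(um[, 1], um[, 2], 0)
    wl("POINT_DATA ", n)
    wl("VECTORS displacement double")
    writeLines(apply(um, 1, function(p) paste(format(p, digits = 12),
                                              collapse = " ")), con)
  }
  invisible(file)
}

#' Write the per-step pattern summary of a run as CSV
#'
#' @param sim A `wrinkle_sim` from [run_quasistatic()].
#' @param file Output path.
#' @export
write_summary_csv <- function(sim, file) {
  stopifnot(inherits(sim, "wrinkle_sim"))
  write.csv(sim$summary, file, row.names = FALSE)
  invisible(file)
}
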