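#' Export a labeled grid (and optional cell fields) as legacy VTK
#'
#' Writes an ASCII `STRUCTURED_POINTS` file with the region labels as cell
#' data, plus any additional scalar fields (e.g. a temperature array) and an
#' optional flow field as cell-centered vectors — convenient for visual
#' inspection in ParaView.
#'
#' @param grid a [voxelize()] grid
#' @param path output `.vtk` file path
#' @param fields named list of arrays with the grid's dims (scalar cell data)
#' @param flow optional `flow_field` exported as a `velocity` vector array
#' @return `path`, invisibly
#' @export
write_vtk_grid <- function(grid, path, fields = list(), flow = NULL) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cryovessel labeled voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1, d[2] + 1, d[3] + 1),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("CELL_DATA %d", prod(d)),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(grid$labels), collapse = "\n"), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(format(as.numeric(fields[[nm]]), digits = 7),
                     collapse = "\n"), con)
  }
  if (!is.null(flow)) {
    vel <- cell_velocity(flow, grid)
    writeLines("VECTORS velocity float", con)
    writeLines(paste(format(vel[, 1], digits = 7),
                     format(vel[, 2], digits = 7),
                     format(vel[, 3], digits = 7)), con)
  }
  invisible(path)
}
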