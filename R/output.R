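# Trajectory output writers: per-sample node CSVs, spatially averaged
# summary traces, cell records, and an optional legacy-ASCII VTK series for
# external viewers.

#' Write a trajectory as CSV files
#'
#' Writes one `nodes_<k>.csv` per sample (node id, x, y, one column per
#' species), a `summary_traces.csv` of per-sample spatial statistics
#' (mean, min, max, quartiles per species) and, for cell-coupled runs, a
#' `cell_records.csv`.
#'
#' @param traj An `rd_trajectory`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_trajectory_csv <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(traj$values)[1]
  for (k in seq_along(traj$times)) {
    df <- data.frame(node = seq_len(n),
                     x = traj$mesh$coords[, 1],
                     y = traj$mesh$coords[, 2])
    for (s in seq_along(traj$species))
      df[[traj$species[s]]] <- traj$values[, s, k]
    utils::write.csv(df, file.path(dir, sprintf("nodes_%05d.csv", k - 1L)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(spatial_summary(traj),
                   file.path(dir, "summary_traces.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(traj$cell_records))
    utils::write.csv(traj$cell_records, file.path(dir, "cell_records.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write a trajectory as a legacy-ASCII VTK snapshot series
#'
#' One `<basename>_<k>.vtk` unstructured-grid file per sample with a point
#' scalar field per species, readable by standard VTK viewers.
#'
#' @param traj An `rd_trajectory`.
#' @param dir Output directory.
#' @param basename File name stem.
#' @return The directory path, invisibly.
#' @export
write_vtk_series <- function(traj, dir, basename = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- traj$mesh
  n <- nrow(mesh$coords)
  ne <- nrow(mesh$elements)
  header <- c("# vtk DataFile Version 3.0", "rdcell field snapshot",
              "ASCII", "DATASET UNSTRUCTURED_GRID")
  pts <- sprintf("%g %g 0", mesh$coords[, 1], mesh$coords[, 2])
  cells <- sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                   mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L)
  for (k in seq_along(traj$times)) {
    out <- c(header,
             sprintf("POINTS %d float", n), pts,
             sprintf("CELLS %d %d", ne, 4L * ne), cells,
             sprintf("CELL_TYPES %d", ne), rep("5", ne),
             sprintf("POINT_DATA %d", n))
    for (s in seq_along(traj$species)) {
      out <- c(out,
               sprintf("SCALARS %s float 1", traj$species[s]),
               "LOOKUP_TABLE default",
               sprintf("%g", traj$values[, s, k]))
    }
    writeLines(out, file.path(dir, sprintf("%s_%05d.vtk", basename, k - 1L)))
  }
  invisible(dir)
}
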