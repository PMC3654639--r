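# Legacy-VTK structured-points export for label fields and nodal scalar
# fields, for visualisation in ParaView and friends.

#' Write arrays as a legacy VTK structured-points file
#'
#' @param path Output path (`.vtk`).
#' @param field A `label_field` providing grid dimensions, origin and
#'   spacing.
#' @param arrays Named list of arrays to write as scalar point data; each
#'   must match the grid dimensions. If empty, the label array itself is
#'   written as `labels`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, field, arrays = list()) {
  stopifnot(inherits(field, "label_field"))
  d <- dim(field$lab)
  if (!length(arrays)) arrays <- list(labels = field$lab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bidecg structured points export",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", field$origin[1] + field$dx / 2,
                       field$origin[2] + field$dx / 2,
                       field$origin[3] + field$dx / 2),
               sprintf("SPACING %g %g %g", field$dx, field$dx, field$dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    stopifnot(all(dim(a) == d))
    isint <- is.integer(a)
    writeLines(c(sprintf("SCALARS %s %s 1", nm,
                         if (isint) "int" else "float"),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(a), trim = TRUE,
                            digits = if (isint) NULL else 7),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Expand a nodal vector to a grid array
#'
#' Places a per-conducting-node vector (e.g. the potential from a
#' `field_state`) back on the full voxel grid, with `NA` outside the body.
#'
#' @param sys A `discrete_system`.
#' @param v Numeric vector over all conducting nodes, or over heart nodes
#'   (length `sys$nh`).
#' @return A 3D array matching the label grid.
#' @export
node_array <- function(sys, v) {
  out <- array(NA_real_, dim(sys$field$lab))
  if (length(v) == sys$n) out[sys$cond] <- v
  else if (length(v) == sys$nh) out[sys$hvox] <- v
  else stop("length of v matches neither all nodes nor heart nodes",
            call. = FALSE)
  out
}
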