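# Electrode placement: named fractional positions on the torso bounding box
# snapped to the nearest torso-surface voxel.

#' Default electrode layout
#'
#' Fractional positions (in the torso bounding box; 0-1 per axis) of the
#' four limb electrodes at the torso corners (VR, VL, VF, VGND), the six
#' precordial electrodes V1-V6 along an anterior arc at heart level, and the
#' seven Frank electrodes (A, C, E, I anterior/lateral, M posterior, H at
#' the neck, F at the left leg). Axes: x toward the subject's left,
#' y anterior, z cranial.
#'
#' @return Named list of length-3 fraction vectors.
#' @export
default_electrode_layout <- function() {
  list(
    VR   = c(0.03, 0.50, 0.97),
    VL   = c(0.97, 0.50, 0.97),
    VF   = c(0.85, 0.50, 0.03),
    VGND = c(0.15, 0.50, 0.03),
    V1   = c(0.44, 0.88, 0.58),
    V2   = c(0.56, 0.88, 0.58),
    V3   = c(0.64, 0.84, 0.54),
    V4   = c(0.72, 0.78, 0.52),
    V5   = c(0.80, 0.68, 0.52),
    V6   = c(0.88, 0.55, 0.52),
    A    = c(0.97, 0.50, 0.55),
    C    = c(0.80, 0.82, 0.55),
    E    = c(0.50, 0.97, 0.55),
    F    = c(0.62, 0.50, 0.03),
    H    = c(0.50, 0.30, 0.97),
    I    = c(0.03, 0.50, 0.55),
    M    = c(0.50, 0.03, 0.55)
  )
}

#' Place electrodes on the torso surface
#'
#' Snaps each named fractional position to the nearest conducting voxel that
#' touches the outside of the body, and reports the snapping distance.
#'
#' @param field A `label_field`.
#' @param layout Named list of fractional positions (each in `[0,1]^3`),
#'   e.g. [default_electrode_layout()].
#' @return An `electrode_set` data frame with columns `name`, `voxel`
#'   (linear voxel index), `x`, `y`, `z` (snapped coordinates, m) and
#'   `snap_dist` (m).
#' @export
place_electrodes <- function(field, layout = default_electrode_layout()) {
  stopifnot(inherits(field, "label_field"))
  bad <- vapply(layout, function(f)
    length(f) != 3 || any(!is.finite(f)) || any(f < 0 | f > 1), logical(1))
  if (any(bad))
    stop("electrode fraction(s) outside [0,1]: ",
         paste(names(layout)[bad], collapse = ", "), call. = FALSE)
  lab <- field$lab
  surf <- which(lab > 0L & .adjacent_to(lab, 0L))
  if (!length(surf)) stop("no surface voxels in field", call. = FALSE)
  ax <- .axis_coords(field)
  d <- dim(lab)
  kk <- (surf - 1L) %/% (d[1] * d[2])
  jj <- (surf - 1L - kk * d[1] * d[2]) %/% d[1]
  ii <- surf - 1L - kk * d[1] * d[2] - jj * d[1]
  sx <- ax[[1]][ii + 1L]; sy <- ax[[2]][jj + 1L]; sz <- ax[[3]][kk + 1L]

  cond <- which(lab > 0L)
  ck <- (cond - 1L) %/% (d[1] * d[2])
  cj <- (cond - 1L - ck * d[1] * d[2]) %/% d[1]
  ci <- cond - 1L - ck * d[1] * d[2] - cj * d[1]
  bb_min <- c(min(ax[[1]][ci + 1L]), min(ax[[2]][cj + 1L]),
              min(ax[[3]][ck + 1L]))
  bb_max <- c(max(ax[[1]][ci + 1L]), max(ax[[2]][cj + 1L]),
              max(ax[[3]][ck + 1L]))

  res <- lapply(names(layout), function(nm) {
    tgt <- bb_min + layout[[nm]] * (bb_max - bb_min)
    d2 <- (sx - tgt[1])^2 + (sy - tgt[2])^2 + (sz - tgt[3])^2
    i <- which.min(d2)
    data.frame(name = nm, voxel = surf[i], x = sx[i], y = sy[i], z = sz[i],
               snap_dist = sqrt(d2[i]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  maxsnap <- max(4 * field$dx, 0.1 * sqrt(sum((bb_max - bb_min)^2)))
  far <- out$snap_dist > maxsnap
  if (any(far))
    stop("electrode(s) too far from the torso surface (interior or outside ",
         "target): ", paste(out$name[far], collapse = ", "), call. = FALSE)
  dup <- duplicated(out$voxel) | duplicated(out$voxel, fromLast = TRUE)
  if (any(dup))
    warning("electrodes snapped to a shared node: ",
            paste(out$name[dup], collapse = ", "), call. = FALSE)
  class(out) <- c("electrode_set", "data.frame")
  out
}
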