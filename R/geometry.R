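# Parametric voxel geometry: torso and lungs extruded from ellipses, a
# cavity in the lung field holding a spherical two-chamber heart divided
# into the seven electrophysiological regions, with an insulating
# atrioventricular gap bridged only by the His bundle in the septum.

.label_table <- c(outside = 0L, torso = 1L, lungs = 2L, blood = 3L,
                  SAN = 4L, atria = 5L, AVN = 6L, His = 7L, BNL = 8L,
                  Purkinje = 9L, ventricles = 10L)

# heart-region label <-> region name
.region_label <- c(SAN = 4L, Atria = 5L, AVN = 6L, His = 7L, BNL = 8L,
                   Purkinje = 9L, Ventricles = 10L)

#' Heart region labels
#' @return Named integer vector mapping all geometry labels to label codes.
#' @export
label_table <- function() .label_table

#' Geometry configuration
#'
#' Parametric description of the torso, lungs, heart and conduction-system
#' geometry on a regular voxel grid. Axes: x lateral (+x toward the
#' subject's left), y antero-posterior (+y anterior), z caudo-cranial
#' (+z cranial); origin at the torso centre. All lengths in metres.
#'
#' @param dx Grid spacing (m).
#' @param type `"torso"` for the full torso-embedded heart or `"strip"` for a
#'   one-region conduction-velocity strip.
#' @param torso List with semi-axes `rx`, `ry` and half-height `hz` of the
#'   extruded torso ellipse.
#' @param lungs List with semi-axes `rx`, `ry` and `zmin`, `zmax` of the
#'   extruded lung field.
#' @param cavity_radius Radius (m) of the spherical cavity carved out of the
#'   lung field around the heart.
#' @param heart List with `center` (xyz, m), outer `radius`, wall thicknesses
#'   `wall_ventricles` and `wall_atria`, the atrioventricular isolation gap
#'   `av_gap`, septum thickness `septum`, the fractional height
#'   `av_plane_frac` of the AV plane above the heart centre, and
#'   `atrial_floor`, the thickness of the myocardial floor of the atria.
#' @param san List with unit direction `dir` (from the heart centre to the
#'   sinoatrial patch in the right atrial wall) and patch `radius`.
#' @param avn List with `radius` of the atrioventricular-node cylinder carved
#'   from the atrial floor at the septum.
#' @param his List with `radius` of the His-bundle column crossing the AV gap.
#' @param bnl List with `apex_frac` (how far towards the apex, as a fraction
#'   of the heart radius, the bundle branches descend).
#' @param strip List describing the strip geometry (used when
#'   `type = "strip"`): `region`, `length` (m), `cross` (voxels across),
#'   `dx` override.
#' @return A `geometry_config` object.
#' @export
geometry_config <- function(dx = 0.004,
                            type = c("torso", "strip"),
                            torso = list(rx = 0.175, ry = 0.125, hz = 0.30),
                            lungs = list(rx = 0.150, ry = 0.102,
                                         zmin = -0.16, zmax = 0.24),
                            cavity_radius = 0.085,
                            heart = list(center = c(0.01, -0.01, 0.02),
                                         radius = 0.060,
                                         wall_ventricles = 0.012,
                                         wall_atria = 0.009,
                                         av_gap = 0.008,
                                         septum = 0.012,
                                         av_plane_frac = 0.25,
                                         atrial_floor = 0.009),
                            san = list(dir = c(-0.65, -0.35, 0.67),
                                       radius = 0.012),
                            avn = list(radius = 0.009),
                            his = list(radius = 0.004),
                            bnl = list(apex_frac = 0.70),
                            strip = list(region = "Ventricles",
                                         length = 0.06, cross = 3,
                                         dx = 0.002)) {
  type <- match.arg(type)
  cfg <- list(dx = dx, type = type, torso = torso, lungs = lungs,
              cavity_radius = cavity_radius, heart = heart, san = san,
              avn = avn, his = his, bnl = bnl, strip = strip)
  class(cfg) <- "geometry_config"
  if (type == "torso") validate_geometry_config(cfg)
  cfg
}

validate_geometry_config <- function(cfg) {
  h <- cfg$heart
  dx <- cfg$dx
  if (!is.numeric(dx) || dx <= 0) stop("dx must be positive", call. = FALSE)
  thick <- c(ventricular_wall = h$wall_ventricles, atrial_wall = h$wall_atria,
             av_gap = h$av_gap, septum = h$septum,
             atrial_floor = h$atrial_floor)
  bad <- names(thick)[thick < 2 * dx]
  if (length(bad))
    stop("region(s) not resolvable at dx = ", dx, " (need >= 2*dx): ",
         paste(bad, collapse = ", "), call. = FALSE)
  hc <- h$center
  if (h$radius >= cfg$cavity_radius)
    stop("heart must fit strictly inside the lung cavity", call. = FALSE)
  room <- min(cfg$torso$rx - abs(hc[1]), cfg$torso$ry - abs(hc[2]),
              cfg$torso$hz - abs(hc[3]))
  if (cfg$cavity_radius > room)
    stop("lung cavity must fit inside the torso", call. = FALSE)
  if (cfg$lungs$rx >= cfg$torso$rx || cfg$lungs$ry >= cfg$torso$ry)
    stop("lungs must fit strictly inside the torso", call. = FALSE)
  invisible(cfg)
}

# face-connected voxel walk between two index triples (L-shaped: x, y, z legs)
.voxel_walk <- function(a, b) {
  path <- list(a)
  cur <- a
  for (axis in 1:3) {
    while (cur[axis] != b[axis]) {
      cur[axis] <- cur[axis] + sign(b[axis] - cur[axis])
      path[[length(path) + 1L]] <- cur
    }
  }
  do.call(rbind, path)
}

#' Build the voxelised geometry
#'
#' Rasterises the parametric geometry onto a regular grid. Each voxel takes
#' the label of the region covering its centre. The heart is a sphere split
#' by the atrioventricular (AV) plane: a ventricular shell with a septum and
#' blood below, an atrial shell with a myocardial floor and blood above, and
#' an insulating gap between them crossed only by the His-bundle column. The
#' conduction chain SAN - atria - AVN - His - bundle branches - Purkinje -
#' ventricles is face-connected by construction, and bundle-branch voxels are
#' ensheathed in Purkinje-labelled tissue so that ventricular myocardium is
#' reached through the Purkinje layer.
#'
#' @param cfg A [geometry_config()].
#' @return A `label_field` object: a list with the integer label array `lab`,
#'   `origin`, `dx`, the label table and the generating config.
#' @export
build_geometry <- function(cfg = geometry_config()) {
  stopifnot(inherits(cfg, "geometry_config"))
  if (cfg$type == "strip") return(.build_strip(cfg))
  validate_geometry_config(cfg)
  dx <- cfg$dx
  tor <- cfg$torso
  h <- cfg$heart
  hc <- h$center

  # grid with a one-voxel outside margin
  nx <- ceiling(2 * tor$rx / dx) + 2L
  ny <- ceiling(2 * tor$ry / dx) + 2L
  nz <- ceiling(2 * tor$hz / dx) + 2L
  origin <- c(-nx, -ny, -nz) / 2 * dx
  xc <- origin[1] + (seq_len(nx) - 0.5) * dx
  yc <- origin[2] + (seq_len(ny) - 0.5) * dx
  zc <- origin[3] + (seq_len(nz) - 0.5) * dx

  lab <- array(0L, dim = c(nx, ny, nz))

  ell2 <- function(rx, ry) outer((xc / rx)^2, (yc / ry)^2, "+")
  zin <- function(zmin, zmax) zc >= zmin & zc <= zmax
  expand_z <- function(mask2, zmask) {
    m <- array(FALSE, dim = c(nx, ny, nz))
    m[, , which(zmask)] <- mask2
    m
  }

  lab[expand_z(ell2(tor$rx, tor$ry) <= 1, zin(-tor$hz, tor$hz))] <- 1L
  lab[expand_z(ell2(cfg$lungs$rx, cfg$lungs$ry) <= 1,
               zin(cfg$lungs$zmin, cfg$lungs$zmax)) & lab == 1L] <- 2L

  r2 <- outer(outer((xc - hc[1])^2, (yc - hc[2])^2, "+"), (zc - hc[3])^2, "+")
  lab[r2 <= cfg$cavity_radius^2 & lab == 2L] <- 1L   # pericardial cavity

  R <- h$radius
  in_heart <- r2 <= R^2 & lab > 0L
  zarr <- array(rep(zc, each = nx * ny), dim = dim(lab))
  xarr <- array(rep(xc, ny * nz), dim = dim(lab))
  z_av <- hc[3] + h$av_plane_frac * R
  g2 <- h$av_gap / 2

  vent_part <- in_heart & zarr <= z_av - g2
  atr_part <- in_heart & zarr > z_av + g2
  gap_part <- in_heart & !vent_part & !atr_part

  lab[gap_part] <- 1L                                   # insulating AV gap
  # ventricles: outer wall shell plus septum; blood elsewhere
  wall_v <- vent_part & r2 > (R - h$wall_ventricles)^2
  sept <- vent_part & r2 <= (R - h$wall_ventricles)^2 &
    abs(xarr - hc[1]) <= h$septum / 2
  lab[vent_part] <- 3L
  lab[wall_v | sept] <- 10L
  # atria: outer wall shell plus myocardial floor; blood elsewhere
  wall_a <- atr_part & r2 > (R - h$wall_atria)^2
  floor_a <- atr_part & zarr <= z_av + g2 + h$atrial_floor
  lab[atr_part] <- 3L
  lab[wall_a | floor_a] <- 5L

  # Purkinje layer: ventricular voxels facing chamber blood
  lab[lab == 10L & .adjacent_to(lab, 3L)] <- 9L

  vx <- function(p) pmin(pmax(1L, as.integer(floor((p - origin) / dx)) + 1L),
                         dim(lab))

  # sinoatrial patch in the atrial wall
  sdir <- cfg$san$dir / sqrt(sum(cfg$san$dir^2))
  sc <- hc + sdir * (R - h$wall_atria / 2)
  s2 <- outer(outer((xc - sc[1])^2, (yc - sc[2])^2, "+"), (zc - sc[3])^2, "+")
  san_m <- s2 <= cfg$san$radius^2 & lab == 5L
  if (!any(san_m))
    stop("SAN patch not resolvable at dx = ", dx, call. = FALSE)
  lab[san_m] <- 4L
  # interdigitated sinoatrial exit: an atrial tongue into the patch, so that
  # the weakly conducting node can ignite the atrial myocardium (the real
  # SAN-atrial junction is likewise interdigitated)
  tdir <- c(-sdir[2], sdir[1], 0)
  if (sum(tdir^2) < 1e-12) tdir <- c(1, 0, 0)
  tdir <- tdir / sqrt(sum(tdir^2))
  tong <- .voxel_walk(vx(sc + tdir * cfg$san$radius), vx(sc))
  for (i in seq_len(nrow(tong))) {
    v <- tong[i, ]
    if (lab[v[1], v[2], v[3]] == 4L) lab[v[1], v[2], v[3]] <- 5L
  }

  # AV node: cylinder carved from the atrial floor at the septal edge
  # (over the cavity, so the His bundle can continue into a subendocardial,
  # blood-insulated bundle branch)
  x_j <- hc[1] + h$septum / 2 + 0.6 * dx
  rho2 <- outer((xc - x_j)^2, (yc - hc[2])^2, "+")
  avn_m <- expand_z(rho2 <= cfg$avn$radius^2,
                    zc > z_av + g2 & zc <= z_av + g2 + h$atrial_floor) &
    lab == 5L
  if (!any(avn_m))
    stop("AVN not resolvable at dx = ", dx, call. = FALSE)
  lab[avn_m] <- 6L

  # His bundle: column through the gap, originating inside the AVN block
  # (the bundle penetrates the node, so its uppermost voxels are surrounded
  # by nodal tissue, which lets the weakly conducting node ignite it)
  his_r <- max(cfg$his$radius, 0.51 * dx)
  his_m <- expand_z(rho2 <= his_r^2,
                    zc > z_av - g2 & zc <= z_av + g2 + h$atrial_floor / 2) &
    (lab == 1L | lab == 6L) & r2 <= R^2
  if (!any(his_m))
    stop("His bundle not resolvable at dx = ", dx, call. = FALSE)
  lab[his_m] <- 7L

  # bundle branch: a subendocardial strip running from under the His column
  # down the septal surface towards the apex, through chamber-blood voxels
  # (blood-insulated, like the fibrous sheath of the real branches), so its
  # only myocardial contacts are the Purkinje layer
  ij <- vx(c(x_j, hc[2], 0))[1:2]
  iz_his <- vx(c(x_j, hc[2], z_av - g2 + 0.51 * dx))[3]
  iz_bot <- iz_his
  while (iz_bot > 1 && lab[ij[1], ij[2], iz_bot] %in% c(1L, 7L))
    iz_bot <- iz_bot - 1L                     # first voxel below the gap
  z_apex <- hc[3] - cfg$bnl$apex_frac * R
  iz_apex <- max(1L, vx(c(x_j, hc[2], z_apex))[3])
  nb <- 0L
  for (iz in seq(iz_bot, iz_apex, by = -1L)) {
    if (lab[ij[1], ij[2], iz] != 3L) break
    lab[ij[1], ij[2], iz] <- 8L
    nb <- nb + 1L
  }
  if (nb == 0L)
    stop("bundle branches not resolvable at dx = ", dx, call. = FALSE)

  structure(list(lab = lab, origin = origin, dx = dx,
                 labels = .label_table, type = "torso", config = cfg),
            class = "label_field")
}

# strip geometry: a single-region bar in a one-voxel passive jacket
.build_strip <- function(cfg) {
  s <- cfg$strip
  dx <- if (!is.null(s$dx)) s$dx else cfg$dx
  nzc <- ceiling(s$length / dx)
  cr <- s$cross
  nx <- cr + 4L; ny <- cr + 4L; nz <- nzc + 4L
  lab <- array(0L, dim = c(nx, ny, nz))
  lab[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] <- 1L
  reg <- .region_label[[match_region(s$region)]]
  lab[3:(cr + 2), 3:(cr + 2), 3:(nzc + 2)] <- reg
  origin <- -c(nx, ny, nz) / 2 * dx
  structure(list(lab = lab, origin = origin, dx = dx,
                 labels = .label_table, type = "strip", config = cfg),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  cat(sprintf("<label_field %s: %d x %d x %d voxels, dx = %g m>\n",
              x$type, dim(x$lab)[1], dim(x$lab)[2], dim(x$lab)[3], x$dx))
  tab <- table(factor(x$lab, levels = .label_table,
                      labels = names(.label_table)))
  print(tab[tab > 0])
  invisible(x)
}

# logical array: voxels with >= 1 face neighbour carrying label `lev`
.adjacent_to <- function(lab, lev) {
  d <- dim(lab)
  out <- array(FALSE, d)
  tgt <- lab == lev
  out[-d[1], , ] <- out[-d[1], , ] | tgt[-1, , ]
  out[-1, , ] <- out[-1, , ] | tgt[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | tgt[, -1, ]
  out[, -1, ] <- out[, -1, ] | tgt[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | tgt[, , -1]
  out[, , -1] <- out[, , -1] | tgt[, , -d[3]]
  out
}

# index pairs (rows of voxel indices) of face-adjacent voxels with labels la, lb
.adjacency_pairs <- function(lab, la, lb) {
  d <- dim(lab)
  res <- NULL
  for (axis in 1:3) {
    n <- d[axis]
    idxA <- switch(axis, lab[-n, , ], lab[, -n, ], lab[, , -n])
    idxB <- switch(axis, lab[-1, , ], lab[, -1, ], lab[, , -1])
    hit <- (idxA == la & idxB == lb) | (idxA == lb & idxB == la)
    if (any(hit)) {
      dd <- d; dd[axis] <- dd[axis] - 1L
      w <- which(array(hit, dd), arr.ind = TRUE)
      res <- rbind(res, cbind(w, axis = axis))
    }
  }
  res
}

#' Validate a label field
#'
#' Reports per-label voxel counts and runs the structural checks: presence of
#' all seven heart regions, face-connectivity of every link in the conduction
#' chain SAN - atria - AVN - His - bundle branches - Purkinje - ventricles,
#' and atrioventricular isolation (no direct atria-ventricle contact).
#'
#' @param field A `label_field`.
#' @return A `geometry_report` list with `counts`, a data frame `checks`
#'   (check, pass, detail) and `all_pass`.
#' @export
validate_geometry <- function(field) {
  stopifnot(inherits(field, "label_field"))
  lab <- field$lab
  counts <- table(factor(lab, levels = .label_table,
                         labels = names(.label_table)))
  checks <- data.frame(check = character(), pass = logical(),
                       detail = character(), stringsAsFactors = FALSE)
  add <- function(check, pass, detail = "") {
    checks[nrow(checks) + 1L, ] <<- list(check, pass, detail)
  }
  if (field$type == "torso") {
    present <- vapply(.region_label, function(l) any(lab == l), logical(1))
    add("seven heart regions present", all(present),
        if (all(present)) "" else paste("missing:",
          paste(names(.region_label)[!present], collapse = ", ")))
    chain <- c("SAN", "Atria", "AVN", "His", "BNL", "Purkinje", "Ventricles")
    for (i in seq_len(length(chain) - 1L)) {
      la <- .region_label[[chain[i]]]; lb <- .region_label[[chain[i + 1L]]]
      prs <- .adjacency_pairs(lab, la, lb)
      add(sprintf("conduction link %s-%s", chain[i], chain[i + 1L]),
          !is.null(prs) && nrow(prs) > 0,
          if (is.null(prs)) sprintf("broken link %s-%s", chain[i], chain[i + 1L])
          else sprintf("%d contact faces", nrow(prs)))
    }
    iso <- .adjacency_pairs(lab, .region_label[["Atria"]],
                            .region_label[["Ventricles"]])
    add("AV isolation (no atria-ventricle contact)", is.null(iso),
        if (is.null(iso)) "" else paste("contact at voxel",
          paste(iso[1, 1:3], collapse = ",")))
  } else {
    hl <- unique(lab[lab %in% .region_label])
    add("single heart region present", length(hl) == 1L,
        paste(length(hl), "heart labels"))
  }
  structure(list(counts = counts, checks = checks,
                 all_pass = all(checks$pass)),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Voxel counts:\n")
  print(x$counts[x$counts > 0])
  cat("\nChecks:\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s %s\n",
                if (x$checks$pass[i]) "ok" else "FAIL", x$checks$check[i],
                if (nzchar(x$checks$detail[i]))
                  paste0("(", x$checks$detail[i], ")") else ""))
  cat(if (x$all_pass) "\nAll checks passed.\n" else "\nSome checks FAILED.\n")
  invisible(x)
}

# voxel-centre coordinates along each axis
.axis_coords <- function(field) {
  d <- dim(field$lab)
  lapply(1:3, function(a) field$origin[a] + (seq_len(d[a]) - 0.5) * field$dx)
}
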