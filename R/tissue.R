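# Conductivity maps, the tissue model (per-voxel parameter and initial-value
# fields) and myocardial-infarction lesions.

#' Per-voxel conductivity maps
#'
#' Expands region parameters and passive-tissue conductivities onto the voxel
#' grid. Intracellular conductivity is zero outside the myocardium, which at
#' the discrete level enforces the zero-flux condition for the intracellular
#' potential on the heart boundary (harmonic face averaging yields zero
#' coupling across any face with a zero-conductivity side).
#'
#' @param field A `label_field`.
#' @param params Named list of [cell_parameters] per region, as from
#'   [region_defaults_all()].
#' @param passive Named conductivities (S/m) for the passive labels
#'   `torso`, `lungs`, `blood`.
#' @return List of 3D arrays `sigma_i`, `sigma_e`, `sigma_o` (S/m).
#' @export
conductivity_maps <- function(field, params = region_defaults_all(),
                              passive = c(torso = 0.2, lungs = 0.04,
                                          blood = 0.7)) {
  stopifnot(inherits(field, "label_field"))
  lab <- field$lab
  miss <- setdiff(names(.region_label)[vapply(.region_label, function(l)
    any(lab == l), logical(1))], names(params))
  if (length(miss))
    stop("missing cell parameters for region(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- dim(lab)
  sig_i <- array(0, d); sig_e <- array(0, d); sig_o <- array(0, d)
  for (r in names(.region_label)) {
    l <- .region_label[[r]]
    if (!any(lab == l)) next
    sig_i[lab == l] <- params[[r]]$sigma_i / 1000   # mS/m -> S/m
    sig_e[lab == l] <- params[[r]]$sigma_e / 1000
  }
  for (nm in c("torso", "lungs", "blood")) {
    l <- .label_table[[nm]]
    if (any(lab == l)) {
      if (is.na(passive[nm]))
        stop("missing passive conductivity for label: ", nm, call. = FALSE)
      sig_o[lab == l] <- passive[[nm]]
    }
  }
  list(sigma_i = sig_i, sigma_e = sig_e, sigma_o = sig_o)
}

#' Build a tissue model
#'
#' Combines a label field with region parameters into per-voxel conductivity,
#' rate-constant and initial-value fields. Lesions applied with
#' [apply_infarct()] modify these fields locally.
#'
#' @inheritParams conductivity_maps
#' @return A `tissue_model` object.
#' @export
tissue_model <- function(field, params = region_defaults_all(),
                         passive = c(torso = 0.2, lungs = 0.04,
                                     blood = 0.7)) {
  maps <- conductivity_maps(field, params, passive)
  lab <- field$lab
  d <- dim(lab)
  karr <- array(0, d)
  vm0 <- array(0, d)   # volts; Vm = Vi - Ve with tabulated Ve = 0
  for (r in names(.region_label)) {
    l <- .region_label[[r]]
    if (!any(lab == l)) next
    karr[lab == l] <- params[[r]]$k
    vm0[lab == l] <- .region_init_Vi[[match_region(r)]] / 1000
  }
  structure(list(field = field, params = params, passive = passive,
                 sigma_i = maps$sigma_i, sigma_e = maps$sigma_e,
                 sigma_o = maps$sigma_o, sigma_i_op = maps$sigma_i,
                 k = karr, init_vm = vm0, init_ve = array(0, d),
                 frozen = array(FALSE, d), border_coupling = 0.5,
                 lesions = list()),
            class = "tissue_model")
}

#' Specify an infarct lesion
#'
#' @param name Lesion name (e.g. `"anterior-MI"`).
#' @param center Lesion centre (xyz, m).
#' @param radii Semi-axes (m) of the ellipsoid, or half-widths of the box.
#' @param shape `"ellipsoid"` or `"box"`.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(name, center, radii, shape = c("ellipsoid", "box")) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3, length(radii) == 3, all(radii >= 0))
  structure(list(name = name, center = center, radii = radii, shape = shape),
            class = "lesion_spec")
}

#' Preset infarct lesions
#'
#' Apically positioned transmural lesions spanning epicardium, midmyocardium
#' and endocardium: `"anterior-MI"` on the anterior ventricular wall near the
#' apex and `"inferior-MI"` on the inferior (diaphragmatic) wall at the apex.
#'
#' @param name `"anterior-MI"` or `"inferior-MI"`.
#' @param geometry The [geometry_config()] the lesion is positioned in.
#' @return A [lesion_spec()].
#' @export
lesion_preset <- function(name, geometry = geometry_config()) {
  h <- geometry$heart
  hc <- h$center
  R <- h$radius
  switch(name,
    "anterior-MI" = lesion_spec(name,
      center = hc + c(0, 0.72, -0.55) / sqrt(0.72^2 + 0.55^2) * (R - h$wall_ventricles / 2),
      radii = c(0.55, 0.45, 0.5) * R),
    "inferior-MI" = lesion_spec(name,
      center = hc + c(0, -0.25, -0.97) / sqrt(0.25^2 + 0.97^2) * (R - h$wall_ventricles / 2),
      radii = c(0.55, 0.5, 0.45) * R),
    stop("unknown lesion preset: ", name, call. = FALSE))
}

.lesion_mask <- function(field, lesion) {
  ax <- .axis_coords(field)
  ctr <- lesion$center; rad <- lesion$radii
  if (lesion$shape == "ellipsoid") {
    q <- outer(outer(((ax[[1]] - ctr[1]) / rad[1])^2,
                     ((ax[[2]] - ctr[2]) / rad[2])^2, "+"),
               ((ax[[3]] - ctr[3]) / rad[3])^2, "+")
    q <= 1
  } else {
    m1 <- abs(ax[[1]] - ctr[1]) <= rad[1]
    m2 <- abs(ax[[2]] - ctr[2]) <= rad[2]
    m3 <- abs(ax[[3]] - ctr[3]) <= rad[3]
    outer(outer(m1, m2, "&"), m3, "&")
  }
}

#' Apply an infarct lesion to a tissue model
#'
#' Within the lesioned myocardium the intracellular conductivity and the rate
#' constant `k` are set to zero, so the tissue neither activates nor conducts
#' intracellular current, and the initial intracellular and extracellular
#' potentials are set to -60 mV and -20 mV. Voxels outside the lesion mask
#' are untouched. A lesion with a zero radius is a no-op; a lesion whose mask
#' contains no myocardial voxel is rejected.
#'
#' @param model A [tissue_model()].
#' @param lesion A [lesion_spec()].
#' @return The modified `tissue_model`.
#' @export
apply_infarct <- function(model, lesion) {
  stopifnot(inherits(model, "tissue_model"), inherits(lesion, "lesion_spec"))
  if (any(lesion$radii == 0)) return(model)
  field <- model$field
  mask <- .lesion_mask(field, lesion)
  heart <- array(field$lab %in% .region_label, dim(field$lab))
  sel <- mask & heart
  if (!any(sel))
    stop("lesion '", lesion$name, "' lies outside the heart", call. = FALSE)
  model$sigma_i[sel] <- 0
  model$k[sel] <- 0
  model$init_vm[sel] <- (-0.060) - (-0.020)  # Vm = Vi - Ve
  model$init_ve[sel] <- -0.020
  # Lesion nodes are frozen at their injury potential. The solver's
  # intracellular operator keeps the regional conductivity on lesion faces
  # (the equipotential interior carries no current; the interface coupling
  # is what makes the frozen injury potential a persistent extracellular
  # source, reproducing the diastolic injury current of a transmural MI).
  model$frozen[sel] <- TRUE
  model <- .close_lesion(model)
  # Stunned border zone. Injury coupling across the lesion boundary is
  # retained only between working-myocardium voxels (atria, ventricles; see
  # assemble()); infarcted conduction-system tissue is plain scar and is
  # decoupled. The two-voxel shell of surviving working myocardium around
  # the coupled core is unexcitable (k = 0) but keeps its conductivities
  # and a dynamic membrane potential: it smooths the standing injury
  # gradient so healthy tissue stays safely subthreshold, while the injury
  # dipole (sigma_i times the core-to-rest potential difference) survives.
  lab <- model$field$lab
  work <- array(lab == .region_label[["Atria"]] |
                  lab == .region_label[["Ventricles"]], dim(lab))
  fzw <- model$frozen & work
  rim <- work & !model$frozen & .face_count(fzw) > 0L
  rim <- rim | (work & !model$frozen & .face_count(rim) > 0L)
  model$k[rim] <- 0
  # safety: an excitable working voxel mostly surrounded by unexcitable
  # tissue is itself stunned, so no sliver is slowly driven over threshold
  repeat {
    exc <- work & model$k > 0
    nstun <- .face_count(work & model$k == 0)
    nexc <- .face_count(exc)
    add <- exc & (nstun >= 3L | (nstun >= 2L & nexc <= 1L) | nexc == 0L)
    if (!any(add)) break
    model$k[add] <- 0
  }
  model$lesions <- c(model$lesions, list(lesion))
  model
}

# 6-neighbour face count of a logical mask
.face_count <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  out[-d[1], , ] <- out[-d[1], , ] + mask[-1, , ]
  out[-1, , ] <- out[-1, , ] + mask[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] + mask[, -1, ]
  out[, -1, ] <- out[, -1, ] + mask[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] + mask[, , -1]
  out[, , -1] <- out[, , -1] + mask[, , -d[3]]
  out
}

# morphological closing of the lesion: a surviving myocardial voxel mostly
# surrounded by infarct (>= 3 lesion faces, or none of its myocardial
# neighbours surviving) is absorbed into the lesion, so no isolated sliver
# is slowly re-excited by the injury potential
.close_lesion <- function(model) {
  lab <- model$field$lab
  heart <- array(lab %in% .region_label, dim(lab))
  repeat {
    nfz <- .face_count(model$frozen)
    nact <- .face_count(heart & !model$frozen)
    add <- heart & !model$frozen & (nfz >= 3L | (nfz >= 1L & nact == 0L))
    if (!any(add)) break
    model$sigma_i[add] <- 0
    model$k[add] <- 0
    model$init_vm[add] <- (-0.060) - (-0.020)
    model$init_ve[add] <- -0.020
    model$frozen[add] <- TRUE
  }
  model
}
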