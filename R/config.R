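# Run configuration: a serialisable key tree with tabulated defaults for
# every omitted key, YAML load/save, and the test fixtures.

#' Default run configuration
#'
#' The full default configuration: tabulated region parameters, default
#' torso geometry and electrode layout, no lesions, 1 s simulated at a
#' 0.05 ms step with 1 ms output resolution.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    mode = "torso",                  # "torso" (PDE) or "cell" (single cell)
    geometry = geometry_config(),
    regions = list(),                # per-region parameter overrides
    passive = list(torso = 0.2, lungs = 0.04, blood = 0.7, heart = 0.05),
    electrodes = default_electrode_layout(),
    lesions = list(),                # lesion_spec lists or preset names
    solver = list(dt = 5e-5, duration = 1.0, output_interval = 1e-3),
    cell = list(region = "SAN", duration = 2, dt = 1e-4, stimulate = FALSE),
    output = list(electrodes = "electrodes.csv", leads = "leads.csv",
                  features = NULL, vtk = NULL),
    seed = 1L,
    verbose = FALSE
  ), class = "run_config")
}

# recursive merge of a user tree into the default tree, rejecting unknown
# keys with their dotted path
.merge_config <- function(base, user, path = character()) {
  if (is.null(user)) return(base)
  if (!is.list(user) || !is.list(base)) return(user)
  open_keys <- c("regions", "electrodes", "lesions")  # free-form subtrees
  for (nm in names(user)) {
    p <- c(path, nm)
    if (!nm %in% names(base) && !(length(path) &&
                                  path[length(path)] %in% open_keys))
      stop("unknown configuration key: ", paste(p, collapse = "."),
           call. = FALSE)
    if (length(path) && path[length(path)] %in% open_keys) {
      base[[nm]] <- user[[nm]]
    } else if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
               !(nm %in% open_keys)) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], p)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  sv <- cfg$solver
  if (!is.numeric(sv$dt) || length(sv$dt) != 1 || sv$dt <= 0)
    stop("invalid value at solver.dt: must be a positive number",
         call. = FALSE)
  if (!is.numeric(sv$duration) || sv$duration < sv$dt)
    stop("invalid value at solver.duration: must be >= solver.dt",
         call. = FALSE)
  if (!is.numeric(sv$output_interval) || sv$output_interval < sv$dt)
    stop("invalid value at solver.output_interval", call. = FALSE)
  if (!cfg$mode %in% c("torso", "cell"))
    stop("invalid value at mode: must be 'torso' or 'cell'", call. = FALSE)
  if (!is.null(cfg$cell$dt) && cfg$cell$dt <= 0)
    stop("invalid value at cell.dt: must be positive", call. = FALSE)
  for (r in names(cfg$regions))
    match_region(r)
  invisible(cfg)
}

#' Coerce to a run configuration
#'
#' @param x A `run_config`, or a plain list of overrides to the defaults.
#' @return A validated `run_config`.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(.validate_config(x))
  stopifnot(is.list(x))
  base <- default_config()
  geom <- x$geometry
  x$geometry <- NULL
  cfg <- .merge_config(unclass(base), x)
  if (!is.null(geom)) {
    if (inherits(geom, "geometry_config")) cfg$geometry <- geom
    else cfg$geometry <- do.call(geometry_config,
                                 .merge_list_args(geometry_config, geom))
  }
  class(cfg) <- "run_config"
  .validate_config(cfg)
}

# merge user geometry keys into geometry_config() formals defaults
.merge_list_args <- function(fun, user) {
  fx <- formals(fun)
  args <- lapply(names(fx), function(nm) eval(fx[[nm]]))
  names(args) <- names(fx)
  args$type <- eval(fx$type)[1]
  bad <- setdiff(names(user), names(args))
  if (length(bad))
    stop("unknown configuration key: ",
         paste(paste0("geometry.", bad), collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(args[[nm]]) && is.list(user[[nm]])) {
      sub <- setdiff(names(user[[nm]]), names(args[[nm]]))
      if (length(sub))
        stop("unknown configuration key: geometry.", nm, ".", sub[1],
             call. = FALSE)
      args[[nm]][names(user[[nm]])] <- user[[nm]]
      args[[nm]] <- lapply(args[[nm]], function(v)
        if (is.list(v)) unlist(v) else v)
    } else {
      args[[nm]] <- if (is.list(user[[nm]])) unlist(user[[nm]]) else user[[nm]]
    }
  }
  args
}

#' Load a run configuration from YAML
#'
#' Reads a structured-text (YAML) configuration and fills every omitted key
#' with its tabulated default. Unknown keys are rejected with their key
#' path.
#'
#' @param path YAML file path. An empty file yields the full default
#'   (normal-heart) configuration.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_run_config(user)
}

#' Save a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$geometry <- unclass(x$geometry)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Coerce a config entry to a lesion
#'
#' @param x A [lesion_spec()], a preset name (`"anterior-MI"`,
#'   `"inferior-MI"`), or a list with `preset` or full lesion fields.
#' @param geometry The geometry the lesion is positioned in.
#' @return A `lesion_spec`.
#' @export
as_lesion <- function(x, geometry = geometry_config()) {
  if (inherits(x, "lesion_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(lesion_preset(x, geometry))
  if (is.list(x) && !is.null(x$preset)) return(lesion_preset(x$preset, geometry))
  if (is.list(x) && all(c("name", "center", "radii") %in% names(x)))
    return(lesion_spec(x$name, unlist(x$center), unlist(x$radii),
                       shape = if (is.null(x$shape)) "ellipsoid" else x$shape))
  stop("cannot interpret lesion specification", call. = FALSE)
}

#' Test fixtures
#'
#' Small, fast-solving configurations exercising every code path:
#' * `"tiny-3d"`: a coarse (8 mm, under 24^3 voxels) torso with a complete
#'   7-region heart, solving 1 s of activity in desk time;
#' * `"strip-1d"`: a single-region conduction-velocity strip;
#' * `"cell-only"`: a single-cell run with no PDE.
#'
#' @param kind One of `"tiny-3d"`, `"strip-1d"`, `"cell-only"`.
#' @return A `run_config`.
#' @export
make_fixture <- function(kind = c("tiny-3d", "strip-1d", "cell-only")) {
  kind <- match.arg(kind)
  cfg <- default_config()
  if (kind == "tiny-3d") {
    cfg$geometry <- geometry_config(
      dx = 0.008,
      torso = list(rx = 0.088, ry = 0.072, hz = 0.086),
      lungs = list(rx = 0.076, ry = 0.062, zmin = -0.078, zmax = 0.080),
      cavity_radius = 0.066,
      heart = list(center = c(0.004, -0.004, 0), radius = 0.055,
                   wall_ventricles = 0.016, wall_atria = 0.016,
                   av_gap = 0.016, septum = 0.016, av_plane_frac = 0.25,
                   atrial_floor = 0.016),
      san = list(dir = c(-0.65, -0.35, 0.67), radius = 0.020),
      avn = list(radius = 0.014),
      his = list(radius = 0.005),
      bnl = list(apex_frac = 0.70))
  } else if (kind == "strip-1d") {
    cfg$geometry <- geometry_config(type = "strip")
    cfg$solver$duration <- 0.12
  } else {
    cfg$mode <- "cell"
  }
  cfg
}
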