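# Region parameter registry: kinetic and conductivity constants for the seven
# heart regions. Potentials are carried in mV and conductivities in mS/m at
# the user surface (the solver converts to SI internally).

.region_names <- c("SAN", "Atria", "AVN", "His", "BNL", "Purkinje", "Ventricles")

.region_table <- data.frame(
  region  = .region_names,
  a       = c(-0.60, 0.13, 0.13, 0.13, 0.13, 0.13, 0.13),
  b       = c(-0.30, 0, 0, 0, 0, 0, 0),
  c1      = c(1000, 2.6, 2.6, 2.6, 2.6, 2.6, 2.6),
  c2      = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
  d       = c(0, 1, 1, 1, 1, 1, 1),
  e       = c(0.0660, 0.0132, 0.0132, 0.0050, 0.0022, 0.0047, 0.0060),
  A       = c(33, 140, 140, 140, 140, 140, 140),       # mV
  B       = c(-22, -85, -85, -85, -85, -85, -85),      # mV
  k       = c(1000, 1000, 1000, 1000, 1000, 1000, 1000), # 1/s
  sigma_e = c(0.5, 8, 0.5, 10, 15, 35, 8),             # mS/m
  sigma_i = c(0.5, 8, 0.5, 10, 15, 35, 8),             # mS/m
  stringsAsFactors = FALSE
)

# Initial values per region: Vi in mV (Ve = 0, u = 0 everywhere).
.region_init_Vi <- c(SAN = -60, Atria = -85, AVN = -85, His = -85,
                     BNL = -85, Purkinje = -85, Ventricles = -85)

match_region <- function(region) {
  if (length(region) != 1L || !is.character(region))
    stop("'region' must be a single region name", call. = FALSE)
  i <- match(tolower(region), tolower(.region_names))
  if (is.na(i))
    stop(sprintf("unknown region '%s'; valid regions are: %s",
                 region, paste(.region_names, collapse = ", ")), call. = FALSE)
  .region_names[i]
}

#' Region names of the heart model
#'
#' @return Character vector of the seven heart region names, ordered along
#'   the normal activation pathway.
#' @export
region_names <- function() .region_names

#' Construct a set of cell parameters
#'
#' Bundles the kinetic and conductivity constants of one heart region for the
#' modified FitzHugh-Nagumo membrane model. The sinoatrial node (SAN) uses a
#' self-oscillatory ionic-current variant; all other regions use the excitable
#' variant whose recovery current scales with `Vm - B`.
#'
#' @param region Region name (one of [region_names()]).
#' @param a Dimensionless excitation threshold.
#' @param b Dimensionless recovery offset.
#' @param c1,c2 Excitation and recovery-coupling coefficients
#'   (A s V^-1 m^-3 in the model's unit system).
#' @param d Dimensionless recovery decay.
#' @param e Dimensionless rate scale; mainly sets action potential duration.
#' @param A Action potential amplitude (mV).
#' @param B Resting potential (mV).
#' @param k Rate constant (1/s).
#' @param sigma_e,sigma_i Extracellular and intracellular conductivities (mS/m).
#' @return An object of class `cell_parameters`.
#' @export
cell_parameters <- function(region, a, b, c1, c2, d, e, A, B, k,
                            sigma_e, sigma_i) {
  region <- match_region(region)
  p <- list(region = region, a = a, b = b, c1 = c1, c2 = c2, d = d, e = e,
            A = A, B = B, k = k, sigma_e = sigma_e, sigma_i = sigma_i)
  num <- vapply(p[-1], function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all cell parameters must be finite numeric scalars; bad: ",
         paste(names(num)[!num], collapse = ", "), call. = FALSE)
  if (p$A <= 0) stop("amplitude A must be positive", call. = FALSE)
  for (nm in c("k", "c1", "c2", "sigma_e", "sigma_i"))
    if (p[[nm]] < 0) stop(sprintf("parameter %s must be non-negative", nm),
                          call. = FALSE)
  structure(p, class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("<cell_parameters: %s>\n", x$region))
  v <- unlist(x[-1])
  print(noquote(format(v, digits = 4)))
  invisible(x)
}

#' Default cell parameters for a heart region
#'
#' Returns the tabulated parameter set of one of the seven heart regions.
#'
#' @param region Region name (case-insensitive); see [region_names()].
#' @param override Optional named list of parameter overrides.
#' @return A [cell_parameters] object.
#' @examples
#' region_defaults("SAN")
#' region_defaults("Ventricles")$A  # 140 mV
#' @export
region_defaults <- function(region, override = NULL) {
  region <- match_region(region)
  row <- .region_table[.region_table$region == region, , drop = FALSE]
  p <- as.list(row)
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(p))
    if (length(bad))
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(override)] <- override
  }
  do.call(cell_parameters, p)
}

#' Default parameters for all regions
#'
#' @param overrides Named list (by region) of parameter override lists.
#' @return Named list of [cell_parameters], one per region.
#' @export
region_defaults_all <- function(overrides = NULL) {
  out <- lapply(.region_names, function(r)
    region_defaults(r, override = overrides[[r]]))
  names(out) <- .region_names
  out
}

#' Initial state of a cell in a given region
#'
#' Tabulated initial values: `Vi` is -60 mV in the SAN and -85 mV elsewhere;
#' `Ve` and the recovery variable `u` start at zero, so `Vm = Vi`.
#'
#' @param region Region name.
#' @return A list with elements `Vi_mV`, `Ve_mV`, `Vm_mV` and `u`.
#' @export
initial_state <- function(region) {
  region <- match_region(region)
  vi <- .region_init_Vi[[region]]
  list(Vi_mV = vi, Ve_mV = 0, Vm_mV = vi, u = 0)
}
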