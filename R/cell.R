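# Membrane kinetics: the modified FitzHugh-Nagumo currents and a single-cell
# integrator. All user-facing potentials are in mV; internally the model
# works in volts with the membrane capacitance / surface-to-volume product
# normalised to one, so the ionic current is expressed in V/s.

#' Ionic membrane current
#'
#' Evaluates the modified FitzHugh-Nagumo ionic current
#' `i_ion = k c1 (Vm - B) (a - v)(1 - v) + recovery`, with the normalised
#' excitation `v = (Vm - B)/A`. The recovery term is `k c2 u` in the
#' sinoatrial node and `k c2 u (Vm - B)` in all other regions.
#'
#' @param vm Transmembrane potential (mV); vectorised.
#' @param u Recovery variable (dimensionless); recycled against `vm`.
#' @param p A [cell_parameters] object.
#' @return Ionic current in model units (V/s once the unit membrane scaling
#'   is applied); positive values repolarise the membrane
#'   (`dVm/dt = -i_ion` for an isolated cell).
#' @examples
#' iion(-85, 0, region_defaults("Ventricles"))  # 0 at rest
#' @export
iion <- function(vm, u, p) {
  stopifnot(inherits(p, "cell_parameters"))
  w <- (vm - p$B) / 1000                     # volts above rest
  v <- (vm - p$B) / p$A                      # dimensionless excitation
  cur <- p$k * p$c1 * w * (p$a - v) * (1 - v)
  if (p$region == "SAN") cur + p$k * p$c2 * u else cur + p$k * p$c2 * u * w
}

#' Recovery-variable rate
#'
#' Evaluates `du/dt = k e ((Vm - B)/A - d u - b)` (1/s).
#'
#' @inheritParams iion
#' @return Rate of change of `u` (1/s).
#' @export
du_dt <- function(vm, u, p) {
  stopifnot(inherits(p, "cell_parameters"))
  p$k * p$e * ((vm - p$B) / p$A - p$d * u - p$b)
}

#' Roots of the ionic-current cubic
#'
#' Finds the three real transmembrane potentials at which the ionic current
#' vanishes for `u = 0`. Analytically these are `B`, `B + a A` and `B + A`;
#' the roots are located numerically from the cubic's coefficients.
#'
#' @param p A [cell_parameters] object with `c1 > 0` and `A != 0`.
#' @return Numeric vector of the three roots (mV), sorted ascending.
#' @examples
#' cubic_roots(region_defaults("Ventricles"))  # -85, -66.8, 55
#' @export
cubic_roots <- function(p) {
  stopifnot(inherits(p, "cell_parameters"))
  if (p$c1 <= 0 || p$A == 0)
    stop("no cubic: c1 must be positive and A non-zero", call. = FALSE)
  # i_ion(Vm, 0) = k c1 [ a w - (1+a) w^2 / A + w^3 / A^2 ], w = Vm - B (mV)
  r <- polyroot(c(0, p$a, -(1 + p$a) / p$A, 1 / p$A^2))
  if (any(abs(Im(r)) > 1e-8 * (1 + abs(Re(r)))))
    stop("cubic has complex roots; degenerate parameter set", call. = FALSE)
  sort(Re(r)) + p$B
}

# RK4 stability-based internal step for the stiff membrane kinetics. The
# bound scans the Jacobian of (dVm/dt, du/dt) over the physiological range
# of the normalised excitation and adds the cross-coupling scale.
.cell_rate_bound <- function(p) {
  v <- seq(-1.7, 1.7, by = 0.01)
  vm <- p$B + v * p$A
  cur <- iion(vm, 0, p)
  dvm <- diff(vm) / 1000                     # volts
  lam_v <- max(abs(diff(cur) / dvm))         # |d i_ion / d Vm|, 1/s
  lam_u <- p$k * p$e * max(p$d, 1)
  cross <- sqrt(p$k * p$c2 * p$k * p$e / abs(p$A / 1000))
  lam_v + lam_u + cross
}

.cell_substeps <- function(p, dt) {
  max(1L, as.integer(ceiling(dt * .cell_rate_bound(p) / 2)))
}

#' Default suprathreshold stimulus for a single cell
#'
#' A 1 ms rectangular current pulse sized to lift the membrane just above
#' the excitation threshold `B + a A`.
#'
#' @param p A [cell_parameters] object.
#' @param t_on Pulse onset time (s).
#' @param duration Pulse duration (s).
#' @param margin Overdrive factor applied to the threshold excursion.
#' @return A stimulus list with elements `t_on`, `duration` and `amplitude`
#'   (model units, V/s).
#' @export
default_stimulus <- function(p, t_on = 0.05, duration = 1e-3, margin = 1.6) {
  amp <- margin * abs(p$a) * (p$A / 1000) / duration
  list(t_on = t_on, duration = duration, amplitude = amp)
}

#' Integrate a single cell
#'
#' Integrates the isolated-cell limit of the membrane model,
#' `dVm/dt = -i_ion + i_stim` and `du/dt` as in [du_dt()], with a
#' fixed-step fourth-order Runge-Kutta scheme. The requested `dt` is the
#' output sampling interval; internally each step is subdivided as needed to
#' keep the scheme inside its stability region for the region's rate
#' constants (the sinoatrial parameter set is much stiffer than the others).
#'
#' @param p A [cell_parameters] object.
#' @param duration Total simulated time (s).
#' @param dt Output sampling interval (s); default 0.1 ms.
#' @param stimulus Optional stimulus list as returned by
#'   [default_stimulus()], or `NULL` for none.
#' @param init Optional initial state list with `Vm_mV` and `u`; defaults to
#'   [initial_state()] for the region.
#' @return A `cell_trace` data frame with columns `time_s`, `Vm_mV`, `u`.
#' @examples
#' tr <- integrate_cell(region_defaults("SAN"), duration = 2)
#' range(tr$Vm_mV)
#' @export
integrate_cell <- function(p, duration, dt = 1e-4, stimulus = NULL,
                           init = NULL) {
  stopifnot(inherits(p, "cell_parameters"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be at least dt", call. = FALSE)
  if (is.null(init)) init <- initial_state(p$region)
  if (is.null(stimulus)) stimulus <- list(t_on = 0, duration = 0, amplitude = 0)
  nsub <- .cell_substeps(p, dt)
  m <- cell_rk4(p$a, p$b, p$c1, p$c2, p$d, p$e, p$k,
                p$A / 1000, p$B / 1000, p$region == "SAN",
                init$Vm_mV / 1000, init$u, duration, dt, nsub,
                stimulus$t_on, stimulus$duration, stimulus$amplitude)
  out <- data.frame(time_s = m[, 1], Vm_mV = m[, 2] * 1000, u = m[, 3])
  structure(out, class = c("cell_trace", "data.frame"),
            params = p, dt = dt, substeps = nsub)
}

#' Action potential duration from a cell trace
#'
#' Measures the duration between the upstroke crossing and the repolarisation
#' crossing of a fractional threshold between resting and peak potential.
#'
#' @param trace A `cell_trace` from [integrate_cell()].
#' @param frac Repolarisation fraction (default 0.9 for APD90).
#' @return Duration in seconds, or `NA` if no action potential is found.
#' @export
apd <- function(trace, frac = 0.9) {
  vm <- trace$Vm_mV
  t <- trace$time_s
  rest <- vm[1]
  peak <- max(vm)
  if (peak - rest < 10) return(NA_real_)     # no excursion worth measuring
  thr <- peak - frac * (peak - rest)
  above <- vm > thr
  up <- which(diff(above) == 1L)
  down <- which(diff(above) == -1L)
  if (!length(up) || !length(down)) return(NA_real_)
  down <- down[down > up[1]]
  if (!length(down)) return(NA_real_)
  t[down[1]] - t[up[1]]
}

#' Write a single-cell trace to CSV
#'
#' @param trace A `cell_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_trace <- function(trace, path) {
  write.csv(as.data.frame(trace)[, c("time_s", "Vm_mV", "u")],
            path, row.names = FALSE)
  invisible(path)
}
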