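# The lead calculus: Einthoven, Goldberger-augmented and precordial (Wilson)
# leads, the Frank orthogonal X/Y/Z system, and RMS / signal-averaged
# curves. All operations are per-sample linear combinations of electrode
# potentials in mV.

.check_equal_length <- function(...) {
  n <- vapply(list(...), length, integer(1))
  if (length(unique(n)) != 1L)
    stop("trace length mismatch: ", paste(n, collapse = ", "), call. = FALSE)
  invisible(n[1])
}

#' Einthoven limb leads
#'
#' `I = VL - VR`, `II = VF - VR`, `III = VF - VL` per sample; the Einthoven
#' identity `II = I + III` holds exactly.
#'
#' @param VL,VR,VF Electrode potential traces (mV), equal length.
#' @return Data frame with columns `lead_I`, `lead_II`, `lead_III`.
#' @export
einthoven <- function(VL, VR, VF) {
  .check_equal_length(VL, VR, VF)
  data.frame(lead_I = VL - VR, lead_II = VF - VR, lead_III = VF - VL)
}

#' Goldberger-augmented limb leads
#'
#' `aVR = (2 VR - VL - VF)/2`, `aVL = (2 VL - VR - VF)/2`,
#' `aVF = (2 VF - VR - VL)/2`; the three sum to zero per sample.
#'
#' @inheritParams einthoven
#' @return Data frame with columns `aVR`, `aVL`, `aVF`.
#' @export
augmented <- function(VL, VR, VF) {
  .check_equal_length(VL, VR, VF)
  data.frame(aVR = (2 * VR - VL - VF) / 2,
             aVL = (2 * VL - VR - VF) / 2,
             aVF = (2 * VF - VR - VL) / 2)
}

#' Precordial (Wilson) chest leads
#'
#' Each precordial electrode referenced to the Wilson central terminal
#' `(VL + VR + VF)/3`.
#'
#' @param V1,V2,V3,V4,V5,V6 Precordial electrode traces (mV).
#' @inheritParams einthoven
#' @return Data frame with columns `lead_V1` .. `lead_V6`.
#' @export
precordial <- function(V1, V2, V3, V4, V5, V6, VL, VR, VF) {
  .check_equal_length(V1, V2, V3, V4, V5, V6, VL, VR, VF)
  wct <- (VL + VR + VF) / 3
  data.frame(lead_V1 = V1 - wct, lead_V2 = V2 - wct, lead_V3 = V3 - wct,
             lead_V4 = V4 - wct, lead_V5 = V5 - wct, lead_V6 = V6 - wct)
}

#' Frank-lead orthogonal X, Y, Z
#'
#' The orthogonal vectorcardiographic leads from the seven Frank
#' electrodes:
#' `X = 0.610 A + 0.171 C - 0.781 I`,
#' `Y = 0.655 F + 0.345 M - 1.000 H`,
#' `Z = 0.133 A + 0.736 M - 0.264 I - 0.374 E - 0.231 C`.
#' Each coefficient set sums to zero, so a common-mode offset on all
#' electrodes cancels.
#'
#' @param A,C,E,F,H,I,M Frank electrode traces (mV), equal length.
#' @return Data frame with columns `X`, `Y`, `Z`.
#' @export
frank_xyz <- function(A, C, E, F, H, I, M) {
  .check_equal_length(A, C, E, F, H, I, M)
  data.frame(X = 0.610 * A + 0.171 * C - 0.781 * I,
             Y = 0.655 * F + 0.345 * M - 1.000 * H,
             Z = 0.133 * A + 0.736 * M - 0.264 * I - 0.374 * E - 0.231 * C)
}

#' RMS curve of three leads
#'
#' `sqrt((a^2 + b^2 + c^2)/3)` per sample: applied to leads I, II, III this
#' is the RMS ECG curve; applied to the Frank X, Y, Z leads it is the
#' signal-averaged ECG (SAECG) curve.
#'
#' @param a,b,c Lead traces (mV), equal length.
#' @return Numeric vector (mV), non-negative.
#' @export
rms_curve <- function(a, b, c) {
  .check_equal_length(a, b, c)
  sqrt((a^2 + b^2 + c^2) / 3)
}

.standard_electrodes <- c("VR", "VL", "VF", "VGND", paste0("V", 1:6))
.frank_electrodes <- c("A", "C", "E", "F", "H", "I", "M")
.channel_order <- c("time_s", .standard_electrodes, .frank_electrodes,
                    "lead_I", "lead_II", "lead_III", "aVR", "aVL", "aVF",
                    paste0("lead_V", 1:6), "X", "Y", "Z", "VRMS", "VSAECG")

#' Derive the full lead set from electrode traces
#'
#' Computes the 12 standard leads, the Frank X/Y/Z leads and the RMS and
#' SAECG curves from raw electrode potentials.
#'
#' @param traces A data frame with a `time_s` column and one column per
#'   electrode (mV), or a `simulation_result`.
#' @return A `lead_traces` data frame with the full fixed channel set, with
#'   the sampling interval in attribute `interval`.
#' @export
derive_leads <- function(traces) {
  if (inherits(traces, "simulation_result")) traces <- traces$traces
  stopifnot(is.data.frame(traces))
  need <- c("time_s", .standard_electrodes, .frank_electrodes)
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("missing electrode channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  w <- traces
  out <- cbind(
    w[need],
    einthoven(w$VL, w$VR, w$VF),
    augmented(w$VL, w$VR, w$VF),
    precordial(w$V1, w$V2, w$V3, w$V4, w$V5, w$V6, w$VL, w$VR, w$VF),
    frank_xyz(w$A, w$C, w$E, w$F, w$H, w$I, w$M))
  ein <- einthoven(w$VL, w$VR, w$VF)
  out$VRMS <- rms_curve(ein$lead_I, ein$lead_II, ein$lead_III)
  fr <- frank_xyz(w$A, w$C, w$E, w$F, w$H, w$I, w$M)
  out$VSAECG <- rms_curve(fr$X, fr$Y, fr$Z)
  out <- out[.channel_order]
  iv <- if (nrow(out) > 1) stats::median(diff(out$time_s)) else NA_real_
  structure(out, class = c("lead_traces", "data.frame"), interval = iv)
}

#' Write lead traces to CSV
#'
#' @param x A `lead_traces` (or any trace data frame with `time_s`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lead_traces <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read trace CSV
#'
#' @param path CSV with a `time_s` column and one column per channel.
#' @param require Optional channel names that must be present.
#' @return A `lead_traces` data frame.
#' @export
read_lead_traces <- function(path, require = NULL) {
  x <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(x))
    stop("trace file lacks a time_s column: ", path, call. = FALSE)
  miss <- setdiff(require, names(x))
  if (length(miss))
    stop("missing channel(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  iv <- if (nrow(x) > 1) stats::median(diff(x$time_s)) else NA_real_
  structure(x, class = c("lead_traces", "data.frame"), interval = iv)
}
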