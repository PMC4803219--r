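## End-inspiratory occlusion analysis: cannula correction, flow integration,
## occlusion detection, inflection-point measurement, elastance summary.

#' Analysis configuration for the occlusion method
#'
#' @param flow_zero_frac flow-zero threshold as a fraction of the peak
#'   inspiratory flow (default 0.02)
#' @param min_occlusion_s minimum sustained zero-flow duration accepted as
#'   an occlusion, s. The default (1 s) is longer than the near-zero flow
#'   tail of a passive expiration at typical murine time constants.
#' @param fast_phase_s span of the piecewise-linear inflection fit after
#'   occlusion onset, s
#' @param plateau_window_s averaging window for the plateau pressure, ending
#'   5 s after onset, s
#' @param plateau_at_s time after onset at which the plateau is read, s
#' @return a named list of class `ventmech_config`
#' @export
ventmech_config <- function(flow_zero_frac = 0.02, min_occlusion_s = 1,
                            fast_phase_s = 0.5, plateau_window_s = 0.2,
                            plateau_at_s = 5) {
  structure(list(flow_zero_frac = flow_zero_frac,
                 min_occlusion_s = min_occlusion_s,
                 fast_phase_s = fast_phase_s,
                 plateau_window_s = plateau_window_s,
                 plateau_at_s = plateau_at_s),
            class = "ventmech_config")
}

#' Remove the cannula pressure drop from a recording
#'
#' Subtracts the calibrated nonlinear cannula pressure-flow contribution
#' `k1*V' + k2*V'*|V'|` from tracheal pressure; flow is unchanged.
#'
#' @param rec a [vent_recording()] whose metadata carries `cannula_k1`,
#'   `cannula_k2`
#' @return the corrected [vent_recording()] (metadata flag
#'   `cannula_corrected` set)
#' @export
correct_cannula <- function(rec) {
  stopifnot(inherits(rec, "vent_recording"))
  k1 <- rec$meta$cannula_k1
  k2 <- rec$meta$cannula_k2
  if (is.null(k1) || is.null(k2))
    stop_config("cannula coefficients missing from recording metadata")
  rec$ptr <- rec$ptr - (k1 * rec$flow + k2 * rec$flow * abs(rec$flow))
  rec$meta$cannula_corrected <- TRUE
  rec
}

#' Integrate flow to volume with per-breath drift re-zeroing
#'
#' Trapezoidal cumulative integration of flow; the volume is re-zeroed at
#' each detected inspiration onset (flow rising through a threshold after a
#' non-inspiratory interval) to suppress integration drift while keeping the
#' tidal excursion exact.
#'
#' @param rec a [vent_recording()]
#' @param onset_frac inspiration-onset flow threshold as fraction of peak
#'   inspiratory flow
#' @return numeric vector of volumes, ml, same length as the recording
#' @export
integrate_flow <- function(rec, onset_frac = 0.05) {
  stopifnot(inherits(rec, "vent_recording"))
  dt <- 1 / rec$meta$fs
  f <- rec$flow
  v <- cumsum(c(0, (f[-1] + f[-length(f)]) / 2 * dt))
  thr <- onset_frac * max(f, 0)
  if (thr > 0) {
    rising <- which(f[-1] > thr & f[-length(f)] <= thr) + 1L
    for (i in rising) v[i:length(v)] <- v[i:length(v)] - v[i]
  }
  v
}

#' Detect end-inspiratory occlusion windows
#'
#' An occlusion is a maximal run of samples with |flow| below a threshold
#' (fraction of peak inspiratory flow) sustained at least `min_occlusion_s`.
#' Each window is checked to begin at end-inspiration: the integrated volume
#' at onset must be close to the metadata tidal volume; windows failing the
#' check are flagged, not dropped.
#'
#' @param rec a (cannula-corrected) [vent_recording()]
#' @param config a [ventmech_config()]
#' @return a data.frame with columns `onset`, `end` (sample indices),
#'   `duration_s`, `end_inspiratory` (logical); zero rows if none found
#' @export
detect_occlusions <- function(rec, config = ventmech_config()) {
  stopifnot(inherits(rec, "vent_recording"))
  fs <- rec$meta$fs
  peak <- max(rec$flow, 0)
  thr <- config$flow_zero_frac * peak
  zero <- if (peak > 0) abs(rec$flow) < thr else rep(TRUE, length(rec$flow))
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_occlusion_s * fs
  if (!any(keep))
    return(data.frame(onset = integer(0), end = integer(0),
                      duration_s = numeric(0), end_inspiratory = logical(0)))
  onset <- starts[keep]
  end <- ends[keep]
  v <- integrate_flow(rec)
  vt <- rec$meta$VT
  ei <- if (peak > 0) v[onset] > 0.5 * vt else rep(FALSE, length(onset))
  data.frame(onset = onset, end = end,
             duration_s = (end - onset + 1L) / fs, end_inspiratory = ei)
}

#' Measure one end-inspiratory occlusion
#'
#' From the occluded pressure trace: the plateau pressure `Pel` is the mean
#' over the last `plateau_window_s` before `plateau_at_s` (5 s) after onset;
#' the inflection pressure `Pi` separating the fast resistive drop from the
#' slow viscoelastic decay is located as the breakpoint of a continuous
#' two-segment piecewise-linear least-squares fit spanning the last
#' pre-occlusion sample through `fast_phase_s` after onset, and `Pi` is the
#' recorded pressure at the breakpoint sample (the fitted chord value is
#' biased low on a convex viscoelastic decay). Then `dP1` = pre-occlusion pressure
#' minus `Pi`, `dP2` = `Pi - Pel`, `Est = (Pel - PEEP)/VT` and
#' `Edyn = (Pi - PEEP)/VT`.
#'
#' @param rec a cannula-corrected [vent_recording()]
#' @param window one row of [detect_occlusions()] output (or a list with
#'   `onset` and `end` sample indices)
#' @param config a [ventmech_config()]
#' @return an object of class `occlusion_measures`
#' @export
measure_occlusion <- function(rec, window, config = ventmech_config()) {
  stopifnot(inherits(rec, "vent_recording"))
  fs <- rec$meta$fs
  onset <- as.integer(window$onset)
  end <- as.integer(window$end)
  if ((end - onset + 1L) / fs < config$plateau_at_s - 1e-9)
    stop_analysis("occlusion window shorter than ", config$plateau_at_s,
                  " s; cannot read the plateau")
  i5 <- onset + round(config$plateau_at_s * fs) - 1L
  i5 <- min(i5, end)
  ip <- i5 - round(config$plateau_window_s * fs) + 1L
  Pel <- mean(rec$ptr[ip:i5])

  pre_idx <- max(onset - 1L, 1L)
  P_pre <- rec$ptr[pre_idx]
  fit_idx <- pre_idx:min(onset + round(config$fast_phase_s * fs), end)
  pw <- piecewise_linear_fit(rec$t[fit_idx], rec$ptr[fit_idx])
  Pi <- rec$ptr[fit_idx[pw$index]]

  dP1 <- P_pre - Pi
  dP2 <- Pi - Pel
  vt <- rec$meta$VT
  peep <- rec$meta$PEEP
  warn <- character(0)
  if (dP2 < -0.02 * max(abs(dP1), 1e-9))
    warn <- c(warn, "negative slow-phase pressure drop (dP2 < 0)")
  structure(list(onset_idx = onset, dP1 = dP1, dP2 = dP2, Pi = Pi,
                 Pel = Pel, P_pre = P_pre,
                 Est = (Pel - peep) / vt, Edyn = (Pi - peep) / vt,
                 breakpoint_s = pw$breakpoint, warnings = warn),
            class = "occlusion_measures")
}

#' @export
print.occlusion_measures <- function(x, ...) {
  cat(sprintf("<occlusion_measures> onset sample %d\n", x$onset_idx))
  cat(sprintf("  dP1 %.3f  dP2 %.3f  Pi %.3f  Pel %.3f cmH2O\n",
              x$dP1, x$dP2, x$Pi, x$Pel))
  cat(sprintf("  Est %.2f  Edyn %.2f cmH2O/ml\n", x$Est, x$Edyn))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Elastances of a recording by the occlusion method
#'
#' Runs the full occlusion analysis on a recording: cannula correction (if
#' not yet applied), occlusion detection, per-occlusion measurement, and
#' averaging across occlusions (the per-animal estimate is the mean of the
#' end-inspiratory occlusions found).
#'
#' @param rec a [vent_recording()]
#' @param config a [ventmech_config()]
#' @return an object of class `elastance_result` with fields `Est_mean`,
#'   `Edyn_mean`, `ratio_dyn_st`, `per_occlusion` (list of
#'   `occlusion_measures`), `compartment_label`
#' @export
compute_elastances <- function(rec, config = ventmech_config()) {
  stopifnot(inherits(rec, "vent_recording"))
  if (!isTRUE(rec$meta$cannula_corrected) &&
      !is.null(rec$meta$cannula_k1)) rec <- correct_cannula(rec)
  occ <- detect_occlusions(rec, config)
  occ <- occ[occ$end_inspiratory, , drop = FALSE]
  if (!nrow(occ))
    stop_analysis("no end-inspiratory occlusion found in recording")
  meas <- lapply(seq_len(nrow(occ)), function(i)
    measure_occlusion(rec, occ[i, ], config))
  est <- vapply(meas, `[[`, 0, "Est")
  edyn <- vapply(meas, `[[`, 0, "Edyn")
  structure(list(Est_mean = mean(est), Edyn_mean = mean(edyn),
                 ratio_dyn_st = mean(edyn) / mean(est),
                 per_occlusion = meas,
                 n_occlusions = length(meas),
                 compartment_label = rec$meta$compartment_label %||% "total"),
            class = "elastance_result")
}

#' @export
print.elastance_result <- function(x, ...) {
  cat(sprintf("<elastance_result> %s compartment, %d occlusion(s)\n",
              x$compartment_label, x$n_occlusions))
  cat(sprintf("  Est  %.2f cmH2O/ml\n  Edyn %.2f cmH2O/ml\n  Edyn/Est %.3f\n",
              x$Est_mean, x$Edyn_mean, x$ratio_dyn_st))
  invisible(x)
}

#' @export
coef.elastance_result <- function(object, ...) {
  c(Est = object$Est_mean, Edyn = object$Edyn_mean,
    ratio = object$ratio_dyn_st)
}

#' Chest-wall elastances by subtraction
#'
#' Chest-wall static and dynamic elastances are the element-wise difference
#' between the total respiratory system result and the lung (open-chest)
#' result of the same animal.
#'
#' @param total an `elastance_result` labelled `total`
#' @param lung an `elastance_result` labelled `lung`
#' @return an `elastance_result` labelled `chest_wall`
#' @export
chest_wall_elastance <- function(total, lung) {
  stopifnot(inherits(total, "elastance_result"),
            inherits(lung, "elastance_result"))
  if (identical(total$compartment_label, lung$compartment_label))
    stop_config("expected a 'total' and a 'lung' result, got two '",
                total$compartment_label, "'")
  est <- total$Est_mean - lung$Est_mean
  edyn <- total$Edyn_mean - lung$Edyn_mean
  structure(list(Est_mean = est, Edyn_mean = edyn,
                 ratio_dyn_st = if (est != 0) edyn / est else NA_real_,
                 per_occlusion = list(), n_occlusions = 0L,
                 compartment_label = "chest_wall"),
            class = "elastance_result")
}
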