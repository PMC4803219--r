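## Synthetic ventilation waveforms: single-compartment linear lung with one
## Maxwell viscoelastic body, volume-controlled ventilation with constant
## inspiratory flow and passive expiration, end-inspiratory occlusions.

#' Mechanical parameters of the simulated lung
#'
#' Bundles the parameters of the single-compartment viscoelastic lung model
#' used by [simulate_ventilation()]: tracheal pressure is
#' \deqn{P_{tr} = PEEP + R_{aw} V' + E_{st} V + P_{ve},}
#' where the Maxwell-body pressure obeys
#' \eqn{dP_{ve}/dt = E_2 V' - P_{ve}/\tau} with \eqn{\tau = R_2/E_2}.
#' After an end-inspiratory occlusion (\eqn{V' = 0}) the resistive term
#' vanishes instantly (the fast drop) and \eqn{P_{ve}} decays exponentially
#' to the plateau \eqn{P_{el} = PEEP + E_{st} V_T} (the slow drop).
#'
#' @param Est static elastance, cmH2O/ml (> 0)
#' @param Raw airway (Newtonian) resistance, cmH2O.s/ml (>= 0)
#' @param E2 viscoelastic (Maxwell) elastance, cmH2O/ml (>= 0)
#' @param R2 viscoelastic resistance, cmH2O.s/ml (>= 0)
#' @param PEEP end-expiratory pressure, cmH2O
#' @param noise_sd additive Gaussian pressure noise, cmH2O
#' @param seed integer RNG seed used by the generator
#' @return an object of class `lung_model_params`
#' @export
lung_model_params <- function(Est = 22.4, Raw = 0.5, E2 = 0, R2 = 0,
                              PEEP = 0, noise_sd = 0, seed = 1L) {
  check_number(Est, "Est", 0, strict_lower = TRUE)
  check_number(Raw, "Raw", 0)
  check_number(E2, "E2", 0)
  check_number(R2, "R2", 0)
  check_number(PEEP, "PEEP")
  check_number(noise_sd, "noise_sd", 0)
  structure(list(Est = Est, Raw = Raw, E2 = E2, R2 = R2, PEEP = PEEP,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "lung_model_params")
}

#' Ventilation maneuver specification
#'
#' Describes the volume-controlled ventilation pattern and the
#' end-inspiratory occlusion maneuvers to simulate. Inspiration is a
#' constant-flow ramp occupying `duty_insp` of the breath; expiration is
#' passive (first-order decay with time constant `Raw/Est`). The simulated
#' cannula adds a nonlinear pressure drop `k1*V' + k2*V'*|V'|` to tracheal
#' pressure so that the correction stage of the analysis is exercised.
#'
#' @param VT tidal volume, ml (> 0)
#' @param rate respiratory rate, breaths/min
#' @param fs sampling rate, Hz
#' @param n_breaths_before_occlusion breaths of regular ventilation preceding
#'   each occlusion (default 100, i.e. one minute at 100 breaths/min)
#' @param occlusion_duration occlusion hold, s (>= 5 s for a plateau read)
#' @param n_occlusions number of end-inspiratory occlusions
#' @param cannula_k1 linear cannula coefficient, cmH2O.s/ml
#' @param cannula_k2 quadratic cannula coefficient, cmH2O.s^2/ml^2
#' @param duty_insp inspiratory fraction of the breath cycle
#' @return an object of class `maneuver_spec`
#' @export
maneuver_spec <- function(VT = 0.30, rate = 100, fs = 100,
                          n_breaths_before_occlusion = 100L,
                          occlusion_duration = 5, n_occlusions = 2L,
                          cannula_k1 = 0.2, cannula_k2 = 0.05,
                          duty_insp = 1 / 3) {
  check_number(VT, "VT", 0, strict_lower = TRUE)
  check_number(rate, "rate", 0, strict_lower = TRUE)
  check_number(fs, "fs", 0, strict_lower = TRUE)
  check_number(occlusion_duration, "occlusion_duration", 0,
               strict_lower = TRUE)
  check_number(duty_insp, "duty_insp", 0, 1, strict_lower = TRUE)
  if (n_occlusions < 1L) stop_invalid("n_occlusions must be >= 1")
  structure(list(VT = VT, rate = rate, fs = fs,
                 n_breaths_before_occlusion = as.integer(n_breaths_before_occlusion),
                 occlusion_duration = occlusion_duration,
                 n_occlusions = as.integer(n_occlusions),
                 cannula_k1 = cannula_k1, cannula_k2 = cannula_k2,
                 duty_insp = duty_insp),
            class = "maneuver_spec")
}

#' Construct a ventilation recording
#'
#' Container for a sampled flow + tracheal pressure recording with its
#' maneuver metadata, as read from disk or produced by the generator.
#'
#' @param t time, s (uniform grid)
#' @param flow ventilatory flow, ml/s
#' @param ptr tracheal pressure, cmH2O
#' @param meta named list with at least `VT`, `PEEP`, `fs`; optionally
#'   `cannula_k1`, `cannula_k2`, `compartment_label`
#' @return an object of class `vent_recording`
#' @export
vent_recording <- function(t, flow, ptr, meta) {
  if (length(t) != length(flow) || length(t) != length(ptr))
    stop_invalid("t, flow and ptr must have equal length")
  if (is.null(meta$fs) || meta$fs <= 0) stop_invalid("meta$fs must be > 0")
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - 1 / meta$fs)) > 1e-6 / meta$fs))
    stop_invalid("t must be strictly increasing with constant step 1/fs")
  if (is.null(meta$compartment_label)) meta$compartment_label <- "total"
  structure(list(t = t, flow = flow, ptr = ptr, meta = meta),
            class = "vent_recording")
}

#' @export
print.vent_recording <- function(x, ...) {
  cat(sprintf("<vent_recording> %d samples at %g Hz (%.1f s), %s compartment\n",
              length(x$t), x$meta$fs, length(x$t) / x$meta$fs,
              x$meta$compartment_label))
  cat(sprintf("  VT %g ml, PEEP %g cmH2O, cannula k1=%g k2=%g\n",
              x$meta$VT, x$meta$PEEP,
              x$meta$cannula_k1 %||% NA, x$meta$cannula_k2 %||% NA))
  occ <- attr(x, "occlusion_onsets")
  if (!is.null(occ))
    cat("  ground-truth occlusion onsets at samples:",
        paste(occ, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vent_recording <- function(x, ...) {
  data.frame(time_s = x$t, flow_ml_s = x$flow, ptr_cmH2O = x$ptr)
}

#' @export
plot.vent_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t, x$flow, type = "l", xlab = "time (s)", ylab = "flow (ml/s)", ...)
  plot(x$t, x$ptr, type = "l", xlab = "time (s)",
       ylab = expression(P[tr] ~ (cmH[2] * O)), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Exact per-sample update of the Maxwell-body pressure for piecewise-constant
## flow over one sampling step.
pve_step <- function(pve, flow, E2, tau, dt) {
  if (E2 <= 0 || tau <= 0) return(0)
  target <- E2 * flow * tau
  target + (pve - target) * exp(-dt / tau)
}

#' Simulate a volume-controlled ventilation recording with occlusions
#'
#' Forward model: constant-flow inspiration to `VT`, passive expiration,
#' `n_occlusions` end-inspiratory occlusions each preceded by
#' `n_breaths_before_occlusion` regular breaths. During occlusion flow is
#' exactly zero, volume is held at `VT` and the Maxwell pressure decays
#' exponentially, so pressure falls from the pre-occlusion value through an
#' inflection to the plateau `PEEP + Est*VT`. The emitted tracheal pressure
#' includes the cannula drop `k1*V' + k2*V'*|V'|` (to be removed by
#' [correct_cannula()]) and, if `noise_sd > 0`, additive Gaussian noise.
#'
#' Ground truth is attached as attributes: `occlusion_onsets` (sample index
#' of the first occluded sample of each maneuver, 1-based), `Pve_at_onset`
#' (Maxwell pressure then), and `params`.
#'
#' @param params a [lung_model_params()] object
#' @param spec a [maneuver_spec()] object
#' @return a [vent_recording()] with ground-truth attributes
#' @export
simulate_ventilation <- function(params, spec) {
  stopifnot(inherits(params, "lung_model_params"),
            inherits(spec, "maneuver_spec"))
  fs <- spec$fs
  dt <- 1 / fs
  Tb <- 60 / spec$rate
  n_insp <- max(2L, round(spec$duty_insp * Tb * fs))
  n_exp <- max(2L, round(Tb * fs) - n_insp)
  flow_insp <- spec$VT / (n_insp * dt)
  tau_exp <- max(params$Raw / params$Est, 2 * dt)
  tau_ve <- if (params$E2 > 0) params$R2 / params$E2 else 0
  n_occl <- max(1L, round(spec$occlusion_duration * fs))

  ## segment plan: (breaths x n) then inspiration + occlusion + expiration,
  ## repeated n_occlusions times
  segs <- list()
  for (j in seq_len(spec$n_occlusions)) {
    for (b in seq_len(spec$n_breaths_before_occlusion))
      segs[[length(segs) + 1L]] <- "breath"
    segs[[length(segs) + 1L]] <- "occlusion"
  }

  flow <- numeric(0)
  vol <- numeric(0)
  onsets <- integer(0)
  pve_onset <- numeric(0)

  breath_flow <- c(rep(flow_insp, n_insp),
                   -spec$VT / tau_exp * exp(-(seq_len(n_exp) - 1L) * dt / tau_exp))
  breath_vol <- c(flow_insp * dt * seq_len(n_insp),
                  spec$VT * exp(-(seq_len(n_exp) - 1L) * dt / tau_exp))

  for (s in segs) {
    if (s == "breath") {
      flow <- c(flow, breath_flow)
      vol <- c(vol, breath_vol)
    } else {
      flow <- c(flow, rep(flow_insp, n_insp), rep(0, n_occl),
                -spec$VT / tau_exp * exp(-(seq_len(n_exp) - 1L) * dt / tau_exp))
      vol <- c(vol, flow_insp * dt * seq_len(n_insp), rep(spec$VT, n_occl),
               spec$VT * exp(-(seq_len(n_exp) - 1L) * dt / tau_exp))
      onsets <- c(onsets, length(vol) - n_occl - n_exp + 1L)
    }
  }

  n <- length(flow)
  pve <- numeric(n)
  p <- 0
  for (i in seq_len(n)) {
    p <- pve_step(p, flow[i], params$E2, tau_ve, dt)
    pve[i] <- p
  }
  pve_onset <- pve[pmax(onsets - 1L, 1L)]  # state entering the occlusion

  ptr <- params$PEEP + params$Raw * flow + params$Est * vol + pve +
    spec$cannula_k1 * flow + spec$cannula_k2 * flow * abs(flow)
  if (params$noise_sd > 0)
    ptr <- ptr + with_seed(params$seed, rnorm(n, 0, params$noise_sd))

  rec <- vent_recording(
    t = (seq_len(n) - 1L) * dt, flow = flow, ptr = ptr,
    meta = list(VT = spec$VT, PEEP = params$PEEP, fs = fs,
                cannula_k1 = spec$cannula_k1, cannula_k2 = spec$cannula_k2,
                compartment_label = "total"))
  attr(rec, "occlusion_onsets") <- onsets
  attr(rec, "Pve_at_onset") <- pve_onset
  attr(rec, "params") <- params
  rec
}

#' Calibrate Maxwell-body parameters for a target dynamic/static ratio
#'
#' Chooses `E2` (at a fixed time constant `tau = R2/E2`) so that the Maxwell
#' pressure at occlusion onset equals `(ratio - 1) * Est * VT`, i.e. the
#' analyzed Edyn/Est ratio of a noiseless recording approaches `ratio`.
#' The Maxwell pressure at onset is linear in `E2` for fixed `tau`, so a
#' single noiseless probe simulation determines the scale factor.
#'
#' @param params baseline [lung_model_params()] (its E2/R2 are replaced)
#' @param spec a [maneuver_spec()]
#' @param ratio target Edyn/Est ratio (> 1)
#' @param tau Maxwell time constant R2/E2, s (should be << 5 s)
#' @return a `lung_model_params` object with calibrated `E2`, `R2`
#' @export
calibrate_viscoelastance <- function(params, spec, ratio = 1.15, tau = 0.3) {
  check_number(ratio, "ratio", 1, strict_lower = TRUE)
  check_number(tau, "tau", 0, strict_lower = TRUE)
  probe <- lung_model_params(Est = params$Est, Raw = params$Raw,
                             E2 = 1, R2 = tau, PEEP = params$PEEP,
                             noise_sd = 0, seed = params$seed)
  sim <- simulate_ventilation(probe, spec)
  gain <- attr(sim, "Pve_at_onset")[1]  # Pve per unit E2
  target <- (ratio - 1) * params$Est * spec$VT
  E2 <- target / gain
  lung_model_params(Est = params$Est, Raw = params$Raw, E2 = E2,
                    R2 = tau * E2, PEEP = params$PEEP,
                    noise_sd = params$noise_sd, seed = params$seed)
}

#' Cohort specification for group-level simulations
#'
#' @param n_per_group animals per group (>= 1)
#' @param group_means named list of [lung_model_params()] objects, one per
#'   group, giving the group-mean mechanical parameters
#' @param between_animal_cv lognormal coefficient of variation of Est (and
#'   proportionally of E2/R2) across animals
#' @param maneuver a [maneuver_spec()] shared by all animals
#' @param seed integer seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group, group_means, between_animal_cv = 0.05,
                        maneuver = maneuver_spec(), seed = 1L) {
  if (n_per_group < 1L) stop_invalid("n_per_group must be >= 1")
  check_number(between_animal_cv, "between_animal_cv", 0)
  if (!length(names(group_means)) ||
      !all(vapply(group_means, inherits, TRUE, "lung_model_params")))
    stop_invalid("group_means must be a named list of lung_model_params")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_means = group_means,
                 between_animal_cv = between_animal_cv,
                 maneuver = maneuver, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of ventilation recordings
#'
#' Per-animal true static elastances are drawn lognormally around each
#' group mean with the stated between-animal CV (lognormal keeps parameters
#' positive); the viscoelastic parameters scale with Est so the Edyn/Est
#' ratio is preserved across animals. Returns the recordings plus a ground
#' truth table.
#'
#' @param spec a [cohort_spec()]
#' @return list with `recordings` (list of [vent_recording()]) and `truth`
#'   (data.frame: animal, group, Est_true, E2_true, R2_true, seed)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cv <- spec$between_animal_cv
  sdlog <- sqrt(log(1 + cv^2))
  groups <- names(spec$group_means)
  recs <- list()
  truth <- list()
  idx <- 0L
  draws <- with_seed(spec$seed, {
    lapply(seq_along(groups), function(g)
      rlnorm(spec$n_per_group, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  })
  for (g in seq_along(groups)) {
    gm <- spec$group_means[[g]]
    for (a in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      mult <- draws[[g]][a]
      seed_a <- (spec$seed * 1000L + idx) %% .Machine$integer.max
      pa <- lung_model_params(Est = gm$Est * mult, Raw = gm$Raw,
                              E2 = gm$E2 * mult, R2 = gm$R2 * mult,
                              PEEP = gm$PEEP, noise_sd = gm$noise_sd,
                              seed = seed_a)
      recs[[idx]] <- simulate_ventilation(pa, spec$maneuver)
      truth[[idx]] <- data.frame(
        animal = idx, group = groups[g], Est_true = pa$Est,
        E2_true = pa$E2, R2_true = pa$R2, seed = seed_a)
    }
  }
  list(recordings = recs, truth = do.call(rbind, truth))
}
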