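#' Initial single-myocyte state
#'
#' Resting state of the human atrial myocyte model: membrane potential (mV),
#' 12 voltage-dependent gates plus the calcium-release gates (all in [0,1]),
#' and intracellular Na+/K+/Ca2+ with the two sarcoplasmic-reticulum calcium
#' compartments (mM).
#'
#' @return Named numeric vector of length 21, class `myocyte_state`.
#' @export
cell_state <- function() {
  structure(crn_default_state(), class = "myocyte_state")
}

validate_state <- function(state) {
  if (length(state) != 21) abort("myocyte state must have 21 elements")
  s <- unclass(state)
  if (any(!is.finite(s))) {
    bad <- names(s)[!is.finite(s)][1]
    abort(paste0("non-finite state variable: ", bad))
  }
  gates <- s[2:16]
  if (any(gates < -1e-12 | gates > 1 + 1e-12)) {
    bad <- names(gates)[gates < -1e-12 | gates > 1 + 1e-12][1]
    abort(paste0("gating variable out of [0,1]: ", bad))
  }
  conc <- s[17:21]
  if (any(conc <= 0)) {
    bad <- names(conc)[conc <= 0][1]
    abort(paste0("non-positive concentration: ", bad))
  }
  invisible(state)
}

#' Membrane currents of a myocyte state
#'
#' Evaluates all 13 currents of the ionic model (pA/pF) for a given state
#' and conductance scaling, plus their sum `i_ion` as consumed by the
#' propagation equation.
#'
#' @param state A [cell_state()] (or any valid 21-element state).
#' @param scaling A [conductance_scaling()].
#' @param ach_um Acetylcholine concentration (micromolar) activating IKACh;
#'   default 0 (current present but silent).
#' @return One-row tibble with the 13 named currents and `i_ion`.
#' @export
ionic_currents <- function(state, scaling = conductance_scaling(), ach_um = 0) {
  validate_state(state)
  g <- as_scaling_vector(scaling)
  out <- crn_ionic_currents(as.numeric(unclass(state)), g, ach_um)
  res <- as_tibble(as.list(out[CHANNELS]))
  res$i_ion <- out[["Iion"]]
  res
}

#' Advance a single myocyte by explicit time stepping
#'
#' Integrates the cell model (Rush-Larsen gates, forward-Euler
#' concentrations and potential) for `n_steps` steps of `dt_ms` under a
#' constant stimulus current.
#'
#' @param state Starting state.
#' @param scaling A [conductance_scaling()].
#' @param i_stim Stimulus current density (pA/pF), positive depolarizing.
#' @param dt_ms Time step (ms); must lie within the stability bound
#'   (0, 0.11].
#' @param n_steps Number of steps.
#' @param ach_um Acetylcholine concentration (micromolar).
#' @return Updated `myocyte_state`.
#' @export
step_cell <- function(state, scaling = conductance_scaling(), i_stim = 0,
                      dt_ms = 0.02, n_steps = 1, ach_um = 0) {
  validate_state(state)
  g <- as_scaling_vector(scaling)
  stim <- if (i_stim != 0) matrix(c(0, n_steps * dt_ms, i_stim), 1, 3)
          else matrix(numeric(0), 0, 3)
  r <- crn_cell_run(as.numeric(unclass(state)), g, stim,
                    t_end = n_steps * dt_ms, dt = dt_ms, rec_dt = 0,
                    ach = ach_um)
  structure(r$state, class = "myocyte_state")
}

#' Pace a single myocyte to steady state and record its action potentials
#'
#' Delivers `n_beats` stimuli at a fixed cycle length and records the
#' membrane-potential trace together with per-beat activation events
#' (activation time, APD90, peak upstroke velocity).
#'
#' @param scaling A [conductance_scaling()].
#' @param cl_ms Pacing cycle length (ms).
#' @param n_beats Number of beats (20 pre-beats plus measurement beats by
#'   default).
#' @param state Starting state (defaults to rest).
#' @param dt_ms Integration step (ms).
#' @param rec_dt_ms Trace sampling interval (ms).
#' @param stim_amp Stimulus amplitude (pA/pF, depolarizing).
#' @param stim_dur_ms Stimulus duration (ms).
#' @param tail_ms Extra quiescent time after the last beat (ms).
#' @param ach_um Acetylcholine concentration (micromolar).
#' @return A `cell_trace` object: list with `trace` (tibble time_ms, vm_mV),
#'   `events` (tibble of per-beat measurements), `state` (final state) and
#'   the pacing metadata.
#' @export
pace_cell <- function(scaling = conductance_scaling(), cl_ms = 500,
                      n_beats = 22, state = cell_state(), dt_ms = 0.02,
                      rec_dt_ms = 0.1, stim_amp = 20, stim_dur_ms = 2,
                      tail_ms = 500, ach_um = 0) {
  validate_state(state)
  g <- as_scaling_vector(scaling)
  onsets <- 10 + (seq_len(n_beats) - 1) * cl_ms
  stim <- cbind(onsets, stim_dur_ms, stim_amp)
  t_end <- max(onsets) + cl_ms + tail_ms
  r <- crn_cell_run(as.numeric(unclass(state)), g, stim, t_end = t_end,
                    dt = dt_ms, rec_dt = rec_dt_ms, ach = ach_um)
  structure(list(
    trace = tibble(time_ms = r$time_ms, vm_mV = r$vm_mV),
    events = as_tibble(r$events)[-1],
    state = structure(r$state, class = "myocyte_state"),
    cl_ms = cl_ms, n_beats = n_beats, dt_ms = dt_ms,
    stim_amp = stim_amp, stim_onsets = onsets),
    class = "cell_trace")
}

#' @export
tidy.cell_trace <- function(x, ...) x$events

#' Measure action-potential metrics from a voltage trace
#'
#' Works on the last complete beat of a uniformly sampled trace: activation
#' time is the time of maximal dV/dt, amplitude is peak minus take-off
#' potential, and APD90 is the interval from activation to 90%
#' repolarization of that amplitude.
#'
#' @param trace Data frame with columns `time_ms` and `vm_mV` (a
#'   `cell_trace` is also accepted).
#' @param cl_ms Pacing cycle length used (ms), for locating the last beat.
#' @param upstroke_threshold_mV Membrane potential a beat must exceed to
#'   count as an action potential.
#' @return One-row tibble: `apd90_ms`, `dvdt_max_Vps`, `amplitude_mV`,
#'   `v_rest_mV`, `captured`. When no beat is detected `captured` is FALSE
#'   and the metrics are NA (an explicit "no action potential" result).
#' @export
measure_ap <- function(trace, cl_ms = 500, upstroke_threshold_mV = -10) {
  if (inherits(trace, "cell_trace")) trace <- trace$trace
  t <- trace$time_ms
  v <- trace$vm_mV
  if (length(t) < 10) abort("trace too short")
  no_ap <- tibble(apd90_ms = NA_real_, dvdt_max_Vps = NA_real_,
                  amplitude_mV = NA_real_, v_rest_mV = NA_real_,
                  captured = FALSE)
  if (max(v) < upstroke_threshold_mV) return(no_ap)
  dt <- t[2] - t[1]
  dv <- diff(v) / dt
  # activation candidates: local upstrokes crossing the threshold
  up <- which(v[-1] >= upstroke_threshold_mV & v[-length(v)] < upstroke_threshold_mV)
  if (length(up) == 0) return(no_ap)
  # last beat with room for repolarization
  last_up <- up[length(up)]
  beat_start <- max(1, last_up - round(20 / dt))
  seg <- seg_end <- length(v)
  act_rel <- which.max(dv[beat_start:(min(last_up + round(5 / dt), length(dv)))])
  i_act <- beat_start + act_rel - 1
  t_act <- t[i_act]
  v_takeoff <- min(v[beat_start:i_act])
  seg_idx <- i_act:seg_end
  v_peak <- max(v[seg_idx])
  amplitude <- v_peak - v_takeoff
  v90 <- v_peak - 0.9 * amplitude
  i_peak <- seg_idx[which.max(v[seg_idx])]
  below <- which(v[i_peak:seg_end] <= v90)
  if (length(below) == 0) return(no_ap)
  i90 <- i_peak + below[1] - 1
  # linear interpolation of the crossing time
  if (i90 > 1 && v[i90 - 1] > v90) {
    frac <- (v[i90 - 1] - v90) / (v[i90 - 1] - v[i90])
    t90 <- t[i90 - 1] + frac * dt
  } else t90 <- t[i90]
  tibble(apd90_ms = t90 - t_act,
         dvdt_max_Vps = max(dv[beat_start:min(i_peak, length(dv))]),
         amplitude_mV = amplitude,
         v_rest_mV = v_takeoff,
         captured = TRUE)
}

#' Single-cell dose-response of action-potential metrics
#'
#' Paces one myocyte to steady state at each drug concentration (Hill
#' blockade applied on top of the supplied base scaling) and reports the
#' AP metrics of the last beat per concentration.
#'
#' @param drug A [drug_spec()].
#' @param concentrations_um Ascending drug concentrations (micromolar).
#' @param cl_ms Pacing cycle length (ms).
#' @param base_scaling Scaling applied before the drug (default: unmodified
#'   control cell).
#' @param n_prebeats Conditioning beats before the measured beats.
#' @param n_measure Measured beats.
#' @param ... Passed to [pace_cell()].
#' @return Tibble: one row per concentration with the [measure_ap()]
#'   metrics; rows that lose capture are flagged `captured = FALSE`, never
#'   dropped.
#' @export
dose_response_cell <- function(drug, concentrations_um = dose_presets()$concentration_um,
                               cl_ms = 500, base_scaling = conductance_scaling(),
                               n_prebeats = 20, n_measure = 2, ...) {
  if (is.unsorted(concentrations_um))
    abort("concentrations_um must be sorted ascending")
  purrr::map_dfr(concentrations_um, function(conc) {
    g <- apply_drug(base_scaling, hill_blockade(drug, conc))
    tr <- pace_cell(g, cl_ms = cl_ms, n_beats = n_prebeats + n_measure, ...)
    m <- measure_ap(tr, cl_ms = cl_ms)
    dplyr::bind_cols(tibble(concentration_um = conc), m)
  })
}
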