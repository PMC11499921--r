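#' Pacing protocols
#'
#' `constant`: fixed 500-ms cycle-length pacing. `ramp`: the AF-induction
#' ramp — cycle length starting at 200 ms, decreasing by 10 ms per stage to
#' a floor of 120 ms, 8 beats per stage; the 9 stages sum to exactly
#' 11.52 s of pacing (8 x (200 + 190 + ... + 120) ms), which is enforced as
#' an invariant.
#'
#' @param kind `"constant"` or `"ramp"`.
#' @param cl_ms Cycle length for `constant` (ms).
#' @param n_beats Number of beats for `constant`.
#' @param start_ms Time of the first stimulus (ms).
#' @param ramp_start_ms,ramp_floor_ms,ramp_step_ms,beats_per_cl Ramp
#'   parameters.
#' @return A `pacing_protocol`: tibble of stimulus onset times with
#'   metadata attributes.
#' @export
pacing_protocol <- function(kind = c("constant", "ramp"), cl_ms = 500,
                            n_beats = 10, start_ms = 10,
                            ramp_start_ms = 200, ramp_floor_ms = 120,
                            ramp_step_ms = 10, beats_per_cl = 8) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    onsets <- start_ms + (seq_len(n_beats) - 1) * cl_ms
    cls <- rep(cl_ms, n_beats)
  } else {
    stages <- seq(ramp_start_ms, ramp_floor_ms, by = -ramp_step_ms)
    cls <- rep(stages, each = beats_per_cl)
    onsets <- start_ms + cumsum(c(0, cls[-length(cls)]))
    span <- sum(cls)
    stopifnot(abs(span - beats_per_cl * sum(stages)) < 1e-9)
  }
  structure(tibble(beat = seq_along(onsets), t_on_ms = onsets, cl_ms = cls),
            class = c("pacing_protocol", class(tibble())),
            kind = kind, pacing_end_ms = max(onsets) + cls[length(cls)])
}

#' Earliest activation site
#'
#' Returns the node with the earliest recorded activation; ties are broken
#' by the lowest node index.
#'
#' @param events Activation events tibble (`node`, `t_act`) from a
#'   [run_tissue()] trace (a `simulation_trace` is also accepted).
#' @return Integer node id.
#' @export
find_eas <- function(events) {
  if (inherits(events, "simulation_trace")) events <- events$events
  if (nrow(events) == 0) abort("no activation found: cannot locate an EAS")
  tmin <- min(events$t_act)
  cand <- events$node[events$t_act <= tmin + 1e-9]
  min(cand)
}

#' Automatic stimulus strength search
#'
#' Finds the diastolic capture threshold for a pacing site by bisection on
#' short test runs (capture = any activation at least 2 mm from the site),
#' then returns twice the threshold.
#'
#' @param grid A `tissue_grid`.
#' @param scaling Scaling (vector or field).
#' @param site_nodes Stimulated node set.
#' @param stim_dur_ms Pulse duration (ms).
#' @param amp_range Bracket for the search (pA/pF).
#' @return Stimulus amplitude (pA/pF).
#' @export
find_stim_threshold <- function(grid, scaling, site_nodes, stim_dur_ms = 2,
                                amp_range = c(2, 80)) {
  site_xy <- c(mean(grid$nodes$x_mm[site_nodes]), mean(grid$nodes$y_mm[site_nodes]))
  far <- sqrt((grid$nodes$x_mm - site_xy[1])^2 +
              (grid$nodes$y_mm - site_xy[2])^2) > 2
  captures <- function(amp) {
    tr <- run_tissue(grid, scaling, stimulus(site_nodes, 2, stim_dur_ms, amp),
                     t_end_ms = 40)
    any(far[tr$events$node])
  }
  lo <- amp_range[1]; hi <- amp_range[2]
  if (!captures(hi)) abort("no capture even at the maximum test amplitude")
  if (captures(lo)) return(2 * lo)
  for (i in 1:6) {
    mid <- sqrt(lo * hi)
    if (captures(mid)) hi <- mid else lo <- mid
  }
  2 * hi
}

#' Run a pacing protocol on tissue and observe the outcome window
#'
#' Delivers the protocol's stimuli at the pacing site and integrates until
#' `observe_until_ms`. Runs that fall silent after pacing are ended early
#' (the termination classification is unaffected: quiescence is exactly
#' what the early stop detects).
#'
#' @param grid A `tissue_grid`.
#' @param scaling Scaling (vector or field matrix).
#' @param protocol A [pacing_protocol()].
#' @param site_nodes Pacing node set (EAS neighborhood).
#' @param observe_until_ms End of observation (ms). Must extend past the
#'   pacing span.
#' @param stim_amp Stimulus amplitude (pA/pF) or `"auto"` for a threshold
#'   search.
#' @param stim_dur_ms Stimulus pulse width (ms).
#' @param df_window_ms Optional all-node recording window for spectral
#'   analysis, `c(t0, t1)` in ms.
#' @param early_stop Allow early termination of quiescent runs.
#' @param ... Passed to [run_tissue()].
#' @return A `simulation_trace`.
#' @export
run_protocol <- function(grid, scaling, protocol, site_nodes,
                         observe_until_ms, stim_amp = 30, stim_dur_ms = 2,
                         df_window_ms = NULL, early_stop = TRUE, ...) {
  pac_end <- attr(protocol, "pacing_end_ms")
  if (observe_until_ms < pac_end)
    abort(paste0("observe_until_ms (", observe_until_ms,
                 ") ends before the pacing span (", pac_end, " ms)"))
  if (identical(stim_amp, "auto"))
    stim_amp <- find_stim_threshold(grid, scaling, site_nodes, stim_dur_ms)
  stim <- stimulus(list(site_nodes), protocol$t_on_ms, stim_dur_ms, stim_amp)
  run_tissue(grid, scaling, stim, t_end_ms = observe_until_ms,
             window_ms = df_window_ms,
             quiet_stop_ms = if (early_stop) 500 else 0,
             quiet_from_ms = if (early_stop) pac_end + 500 else 0, ...)
}

#' Classify the rhythm at the end of the observation window
#'
#' Termination: no node crosses the activation threshold during the final
#' detection window. Otherwise the pooled activation cycle lengths over the
#' analysis window decide between regular atrial tachycardia (coefficient
#' of variation below `at_cv_threshold` with a dominant cycle length above
#' `min_cl_ms`) and atrial fibrillation.
#'
#' @param trace A `simulation_trace` covering the window end.
#' @param window_end_ms End of observation (default: the trace's horizon).
#' @param quiet_window_ms Final detection window for termination (ms).
#' @param analysis_window_ms Span before the window end over which cycle
#'   lengths are pooled (ms).
#' @param at_cv_threshold Regularity limit for an AT call.
#' @param min_cl_ms Minimum dominant cycle length for AT (ms).
#' @return One-row tibble (`rhythm_outcome`): `label` (AF/AT/termination),
#'   `t_termination_ms`, `mean_cl_ms`, `cl_cv`, `n_active_nodes`.
#' @export
classify_rhythm <- function(trace, window_end_ms = NULL,
                            quiet_window_ms = 500, analysis_window_ms = 2000,
                            at_cv_threshold = 0.1, min_cl_ms = 120) {
  window_end_ms <- window_end_ms %||% trace$t_end_ms
  if (trace$completed && trace$t_stop < window_end_ms - 1e-6)
    abort("trace ends before the observation window")
  ev <- trace$events
  if (!trace$completed) {
    # run ended early because activity ceased
    t_term <- if (nrow(ev) > 0) max(ev$t_act) else NA_real_
    return(tibble(label = "termination", t_termination_ms = t_term,
                  mean_cl_ms = NA_real_, cl_cv = NA_real_,
                  n_active_nodes = 0L))
  }
  final <- ev[ev$t_act >= window_end_ms - quiet_window_ms, ]
  if (nrow(final) == 0) {
    t_term <- if (nrow(ev) > 0) max(ev$t_act) else NA_real_
    return(tibble(label = "termination", t_termination_ms = t_term,
                  mean_cl_ms = NA_real_, cl_cv = NA_real_,
                  n_active_nodes = 0L))
  }
  win <- ev[ev$t_act >= window_end_ms - analysis_window_ms, ]
  cls <- win %>% group_by(node) %>%
    summarise(cl = list(diff(sort(t_act))), .groups = "drop")
  cl <- unlist(cls$cl)
  cl <- cl[cl > 50]  # discard double-detections
  if (length(cl) < 3) {
    lab <- "AT"  # sparse, slow but persistent activation
    return(tibble(label = lab, t_termination_ms = NA_real_,
                  mean_cl_ms = if (length(cl)) mean(cl) else NA_real_,
                  cl_cv = 0, n_active_nodes = length(unique(final$node))))
  }
  cv <- stats::sd(cl) / mean(cl)
  dom <- median(cl)
  lab <- if (cv < at_cv_threshold && dom > min_cl_ms) "AT" else "AF"
  tibble(label = lab, t_termination_ms = NA_real_, mean_cl_ms = mean(cl),
         cl_cv = cv, n_active_nodes = length(unique(final$node)))
}

#' Virtual drug test on one patient model
#'
#' Runs the AF-induction protocol at every dose of the preset grid on a
#' calibrated patient model, classifies each outcome, and applies the
#' grouping rule: Effective if AF terminated at at least one therapeutic
#' dose (low or high), otherwise Ineffective. A baseline (no-drug) run
#' that does not sustain AF is flagged as a calibration failure and
#' excluded from grouping.
#'
#' @param model A calibrated patient model from [build_patient_model()] /
#'   [tune_for_baseline_af()].
#' @param drug A [drug_spec()], default [amiodarone()].
#' @param doses Dose grid, see [dose_presets()].
#' @param observe_after_pacing_ms Observation window after the pacing ramp
#'   (ms).
#' @param ach_um Acetylcholine tone of the AF substrate (micromolar).
#' @param ... Passed to [run_protocol()].
#' @return A `drug_verdict`: list with `outcomes` (tibble dose x label),
#'   `group`, `calibration_failure`.
#' @export
virtual_drug_test <- function(model, drug = amiodarone(),
                              doses = dose_presets(),
                              observe_after_pacing_ms = 10000,
                              ach_um = 0.01, ...) {
  proto <- pacing_protocol("ramp")
  t_end <- attr(proto, "pacing_end_ms") + observe_after_pacing_ms
  run_dose <- function(conc) {
    blk <- if (conc > 0) hill_blockade(drug, conc) else NULL
    scal <- make_scaling_field(model$substrate, blockade = blk,
                               af_remodeling = TRUE,
                               remodeling = model$remodeling)
    tr <- run_protocol(model$grid, scal, proto, model$eas_nodes, t_end,
                       stim_amp = model$stim_amp, ach_um = ach_um, ...)
    classify_rhythm(tr, window_end_ms = t_end)
  }
  outcomes <- purrr::map_dfr(seq_len(nrow(doses)), function(i) {
    out <- run_dose(doses$concentration_um[i])
    dplyr::bind_cols(tibble(dose = doses$label[i],
                            concentration_um = doses$concentration_um[i],
                            therapeutic = doses$therapeutic[i]), out)
  })
  baseline <- outcomes$label[outcomes$concentration_um == 0]
  calib_fail <- length(baseline) > 0 && baseline[1] == "termination"
  therapeutic <- outcomes$label[outcomes$therapeutic]
  group <- if (calib_fail) NA_character_
           else if (any(therapeutic == "termination")) "Effective"
           else "Ineffective"
  structure(list(outcomes = outcomes, group = group,
                 calibration_failure = calib_fail),
            class = "drug_verdict")
}

#' Grouping rule for the virtual drug test
#'
#' Pure function of the two therapeutic-dose outcomes: Effective when
#' at least one is `"termination"`.
#'
#' @param low_label,high_label Rhythm labels at the low and high dose.
#' @return `"Effective"` or `"Ineffective"`.
#' @export
verdict_group <- function(low_label, high_label) {
  ifelse(low_label == "termination" | high_label == "termination",
         "Effective", "Ineffective")
}

#' @export
tidy.drug_verdict <- function(x, ...) {
  out <- x$outcomes
  out$group <- x$group
  out
}

#' @export
print.drug_verdict <- function(x, ...) {
  cat("<drug_verdict> group:", x$group, "\n")
  print(x$outcomes[, c("label", "concentration_um")])
  invisible(x)
}
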