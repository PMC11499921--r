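#' Run the full virtual drug-test pipeline
#'
#' Executes the whole workflow on a synthetic cohort: cohort generation,
#' substrate construction, vein-hole/PVI lesions, sustained-AF diffusion
#' calibration, ramp-pacing induction at every drug dose, rhythm
#' classification, Smax/DF biomarker maps and the per-patient
#' effective/ineffective verdicts. Per-patient failures are recorded and
#' the pipeline continues with the remaining patients.
#'
#' @param config A [load_config()] configuration (default: package
#'   defaults).
#' @param out_dir Output directory for the CSV tables, or NULL to skip
#'   writing.
#' @param doses Dose labels to run (default: all four presets).
#' @param biomarkers Compute Smax and DF maps per run.
#' @param progress Print per-patient progress lines.
#' @return List: `verdicts` tibble, `cohort_summary` tibble, `biomarkers`
#'   tibble (if requested), `models` (calibrated patient models),
#'   `excluded` tibble of patients failing calibration, `config_hash`.
#' @export
run_pipeline <- function(config = load_config(), out_dir = NULL,
                         doses = c("none", "low", "high", "toxic"),
                         biomarkers = TRUE, progress = interactive()) {
  hash <- config_hash(config)
  cfgc <- config$cohort
  drug <- if (is.null(config$drug$table)) amiodarone()
          else drug_spec(config$drug$name, config$drug$table)
  dose_tab <- dose_presets()
  dose_tab <- dose_tab[dose_tab$label %in% doses, ]
  dose_tab$concentration_um <-
    unlist(config$drug$doses_um[dose_tab$label])
  proto <- pacing_protocol("ramp",
                           ramp_start_ms = config$protocol$ramp_start_ms,
                           ramp_floor_ms = config$protocol$ramp_floor_ms,
                           ramp_step_ms = config$protocol$ramp_step_ms,
                           beats_per_cl = config$protocol$beats_per_cl)
  pac_end <- attr(proto, "pacing_end_ms")
  t_end <- pac_end + config$protocol$observe_after_pacing_ms
  df_win <- c(max(pac_end, t_end - config$biomarkers$df_window_s * 1000), t_end)

  cohort <- make_cohort(cohort_spec(
    n_patients = cfgc$n_patients, master_seed = cfgc$master_seed,
    nx = cfgc$nx, ny = cfgc$ny, spacing_um = cfgc$spacing_um,
    n_points = cfgc$n_points))

  remodeling <- unlist(config$model$af_remodeling)

  results <- list()
  excluded <- list()
  biom <- list()
  models <- list()
  run_patient <- function(i) {
    pid <- cohort$manifest$patient_id[i]
    model <- build_patient_model(
      cohort$patients[[i]], stim_amp = config$protocol$stim_amp,
      remodeling = remodeling,
      radius_mm = config$substrate$idw_radius_mm,
      power = config$substrate$idw_power)
    model <- tune_for_baseline_af(
      model, observe_after_pacing_ms = config$protocol$observe_after_pacing_ms,
      bracket = cfgc$calibration_bracket, dt_ms = config$solver$dt_ms)
    if (!model$calibrated) {
      return(list(excluded = tibble(
        patient_id = pid, reason = "calibration failed",
        scales_tried = paste(round(model$calibration_runs$scale, 3),
                             collapse = ";"))))
    }
    biom_rows <- list()
    per_dose <- purrr::map_dfr(seq_len(nrow(dose_tab)), function(k) {
      conc <- dose_tab$concentration_um[k]
      lab <- dose_tab$label[k]
      if (conc == 0) {
        tr <- model$baseline_trace
        out <- model$baseline_outcome
      } else {
        blk <- hill_blockade(drug, conc)
        scal <- make_scaling_field(model$substrate, blockade = blk,
                                   remodeling = remodeling)
        tr <- run_protocol(model$grid, scal, proto, model$eas_nodes,
                           t_end, stim_amp = model$stim_amp,
                           ach_um = config$model$ach_um,
                           df_window_ms = if (biomarkers) df_win else NULL,
                           dt_ms = config$solver$dt_ms)
        out <- classify_rhythm(tr, window_end_ms = t_end)
      }
      if (biomarkers) {
        sm_nodes <- seq(1, model$grid$n_nodes,
                        by = config$biomarkers$smax_node_stride)
        sm <- smax_map(tr, model$substrate, nodes = sm_nodes,
                       window_ms = c(0, pac_end + 500))
        dfv <- if (out$label %in% c("AF", "AT") &&
                   length(tr$window_time_ms) > 8)
          glance(df_map(tr, model$substrate,
                        band_hz = config$biomarkers$df_band_hz))$mean
        else NA_real_
        biom_rows[[length(biom_rows) + 1]] <<- tibble(
          patient_id = pid, dose = lab, concentration_um = conc,
          mean_smax = sm$regional$mean,
          delta_regional_smax = sm$regional$delta_regional,
          mean_df_hz = dfv)
      }
      tibble(patient_id = pid, dose = lab, concentration_um = conc,
             label = out$label, diffusion_scale = model$diffusion_scale)
    })
    list(model = model, outcomes = per_dose, biomarkers = bind_rows(biom_rows))
  }

  for (i in seq_along(cohort$patients)) {
    pid <- cohort$manifest$patient_id[i]
    res <- tryCatch(run_patient(i), error = function(e) {
      list(excluded = tibble(patient_id = pid,
                             reason = conditionMessage(e),
                             scales_tried = NA_character_))
    })
    if (!is.null(res$excluded)) {
      excluded[[length(excluded) + 1]] <- res$excluded
      if (progress) message("patient ", pid, ": excluded (",
                            res$excluded$reason[1], ")")
    } else {
      models[[as.character(pid)]] <- res$model
      results[[length(results) + 1]] <- res$outcomes
      if (!is.null(res$biomarkers) && nrow(res$biomarkers) > 0)
        biom[[length(biom) + 1]] <- res$biomarkers
      if (progress)
        message("patient ", pid, ": ",
                paste(res$outcomes$dose, res$outcomes$label,
                      sep = "=", collapse = " "))
    }
  }

  outcomes <- bind_rows(results)
  verdicts <- if (nrow(outcomes) > 0) {
    outcomes %>% group_by(patient_id) %>%
      summarise(
        outcome_none = label[dose == "none"][1],
        outcome_low = if (any(dose == "low")) label[dose == "low"][1] else NA,
        outcome_high = if (any(dose == "high")) label[dose == "high"][1] else NA,
        outcome_toxic = if (any(dose == "toxic")) label[dose == "toxic"][1] else NA,
        .groups = "drop") %>%
      mutate(group = dplyr::case_when(
        is.na(outcome_low) & is.na(outcome_high) ~ NA_character_,
        outcome_none == "termination" ~ NA_character_,
        TRUE ~ verdict_group(outcome_low %||% "AF", outcome_high %||% "AF")))
  } else tibble()
  cohort_summary <- if (nrow(outcomes) > 0) {
    outcomes %>% group_by(dose, concentration_um) %>%
      summarise(n = n(), n_AF = sum(label == "AF"), n_AT = sum(label == "AT"),
                n_term = sum(label == "termination"), .groups = "drop") %>%
      arrange(concentration_um)
  } else tibble()

  out <- list(verdicts = verdicts, cohort_summary = cohort_summary,
              outcomes = outcomes,
              biomarkers = if (biomarkers) bind_rows(biom) else NULL,
              models = models, excluded = bind_rows(excluded),
              manifest = cohort$manifest, config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(d) { d$config_hash <- hash; d }
    utils::write.csv(stamp(out$manifest), file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(out$outcomes), file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(out$verdicts), file.path(out_dir, "verdicts.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(out$cohort_summary),
                     file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
    if (!is.null(out$biomarkers))
      utils::write.csv(stamp(out$biomarkers),
                       file.path(out_dir, "biomarkers.csv"), row.names = FALSE)
    if (nrow(out$excluded) > 0)
      utils::write.csv(stamp(out$excluded), file.path(out_dir, "excluded.csv"),
                       row.names = FALSE)
  }
  out
}
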