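#' Virtual-patient specification
#'
#' Parameters of one synthetic patient: sheet geometry, an
#' electroanatomical-map-like voltage point cloud (dense background of
#' healthy voltages with low-voltage fibrotic patches), fiber field, the
#' vein-hole/ablation template and the pacing site. The seed fixes
#' everything downstream.
#'
#' @param seed RNG seed.
#' @param nx,ny,spacing_um Sheet geometry, see [make_sheet()].
#' @param n_points Number of map points (>= 500 emulating clinical density).
#' @param bg_mean_mv,bg_sd_mv Background bipolar voltage distribution (mV),
#'   truncated at 0.
#' @param n_patches Number of low-voltage patches.
#' @param patch_r_mm `c(min, max)` patch radius range (mm).
#' @param patch_mean_mv,patch_sd_mv Patch voltage distribution (mV).
#' @param patch_box Region holding the patch centers, as fractions of the
#'   sheet extent `c(x0, x1, y0, y1)`; the default keeps the low-voltage
#'   patches on the wall opposite the vein pair (posterior-type scar) so
#'   the peri-antral conduction corridors stay patent.
#' @param fiber_mode,fiber_angle_deg Fiber field, see [build_fiber_field()].
#' @param eas `c(x, y)` pacing-site location as fractions of the sheet
#'   extent.
#' @return A `patient_spec` list.
#' @export
patient_spec <- function(seed, nx = 64, ny = 64, spacing_um = 250,
                         n_points = 600, bg_mean_mv = 1.45, bg_sd_mv = 0.45,
                         n_patches = 2, patch_r_mm = c(1.5, 2.5),
                         patch_mean_mv = 0.45, patch_sd_mv = 0.15,
                         patch_box = c(0.06, 0.38, 0.25, 0.76),
                         fiber_mode = "uniform", fiber_angle_deg = 0,
                         eas = c(0.94, 0.5)) {
  if (n_points < 1) abort("n_points must be >= 1")
  if (bg_mean_mv < 0 || patch_mean_mv < 0) abort("voltages must be >= 0")
  structure(as.list(environment()), class = "patient_spec")
}

#' Generate one virtual patient
#'
#' Samples the voltage point cloud (background Gaussian truncated at zero,
#' overridden inside circular low-voltage patches by the patch Gaussian)
#' at random in-domain locations, together with the sheet, fiber
#' parameters and the vein-hole/ablation template. Deterministic per seed.
#'
#' @param spec A [patient_spec()].
#' @return A `virtual_patient`: list with `sheet`, `cloud`, `patches`,
#'   `lesion_template`, `spec`.
#' @export
make_patient <- function(spec) {
  stopifnot(inherits(spec, "patient_spec"))
  sheet <- make_sheet(spec$nx, spec$ny, spec$spacing_um)
  xr <- range(sheet$x_mm)
  yr <- range(sheet$y_mm)
  bx <- xr[1] + spec$patch_box[1:2] * diff(xr)
  by <- yr[1] + spec$patch_box[3:4] * diff(yr)
  dat <- with_seed(spec$seed, {
    px <- runif(spec$n_patches, bx[1], bx[2])
    py <- runif(spec$n_patches, by[1], by[2])
    pr <- runif(spec$n_patches, spec$patch_r_mm[1], spec$patch_r_mm[2])
    cx <- runif(spec$n_points, xr[1], xr[2])
    cy <- runif(spec$n_points, yr[1], yr[2])
    v_bg <- pmax(rnorm(spec$n_points, spec$bg_mean_mv, spec$bg_sd_mv), 0)
    v_patch <- pmax(rnorm(spec$n_points, spec$patch_mean_mv, spec$patch_sd_mv), 0)
    list(px = px, py = py, pr = pr, cx = cx, cy = cy,
         v_bg = v_bg, v_patch = v_patch)
  })
  in_patch <- rep(FALSE, spec$n_points)
  if (spec$n_patches > 0) {
    for (k in seq_len(spec$n_patches)) {
      d <- sqrt((dat$cx - dat$px[k])^2 + (dat$cy - dat$py[k])^2)
      in_patch <- in_patch | d <= dat$pr[k]
    }
  }
  if (all(in_patch) && spec$n_patches > 0)
    warn("low-voltage patches cover the whole mapped domain")
  v <- ifelse(in_patch, dat$v_patch, dat$v_bg)
  cloud <- voltage_cloud(dat$cx, dat$cy, v)
  cloud$in_patch <- in_patch
  structure(list(
    sheet = sheet, cloud = cloud,
    patches = tibble(x_mm = dat$px, y_mm = dat$py, r_mm = dat$pr),
    lesion_template = pvi_lesion_template(sheet),
    spec = spec),
    class = "virtual_patient")
}

#' Assemble the simulation model of a patient
#'
#' Builds substrate, grid and pacing-site metadata for a generated
#' patient: the full substrate path (interpolation, fibrosis,
#' conductivity, regions), the monodomain grid with the vein holes and
#' PVI rings applied, and the EAS pacing neighborhood.
#'
#' @param patient A [make_patient()] result.
#' @param diffusion_scale Initial global diffusion scale.
#' @param stim_amp Pacing stimulus amplitude (pA/pF).
#' @param remodeling Optional AF-remodeling override profile.
#' @param ... Passed to [build_substrate()].
#' @return A `patient_model` list: `substrate`, `grid`, `eas_nodes`,
#'   `stim_amp`, `remodeling`, `patient`.
#' @export
build_patient_model <- function(patient, diffusion_scale = 1, stim_amp = 30,
                                remodeling = NULL, ...) {
  spec <- patient$spec
  substrate <- build_substrate(
    patient$sheet, patient$cloud, seed = spec$seed + 1000L,
    fiber_mode = spec$fiber_mode, fiber_angle_deg = spec$fiber_angle_deg,
    lesion_template = patient$lesion_template, ...)
  grid <- build_grid(substrate, diffusion_scale = diffusion_scale)
  xr <- range(substrate$x_mm)
  yr <- range(substrate$y_mm)
  eas_xy <- c(xr[1] + spec$eas[1] * diff(xr), yr[1] + spec$eas[2] * diff(yr))
  eas_nodes <- disc_nodes(grid, eas_xy[1], eas_xy[2], radius_mm = 0.8)
  if (length(eas_nodes) == 0) abort("pacing site has no conducting nodes")
  structure(list(substrate = substrate, grid = grid, eas_nodes = eas_nodes,
                 stim_amp = stim_amp, remodeling = remodeling,
                 patient = patient),
            class = "patient_model")
}

#' Cohort specification
#'
#' Number of patients plus per-patient parameter ranges; patient i is
#' reproducible from (master seed, i).
#'
#' @param n_patients Cohort size.
#' @param master_seed Master RNG seed.
#' @param bg_mean_mv_range,patch_mean_mv_range,n_patches_range,fiber_angle_range
#'   Ranges from which per-patient parameters are drawn.
#' @param ... Fixed arguments forwarded to every [patient_spec()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10, master_seed = 20240101,
                        bg_mean_mv_range = c(1.3, 1.45),
                        patch_mean_mv_range = c(0.3, 0.6),
                        n_patches_range = c(1L, 3L),
                        fiber_angle_range = c(-12, 12), ...) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  structure(c(as.list(environment()), list(fixed = list(...))),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List: `patients` (list of `virtual_patient`), `manifest` tibble
#'   of per-patient parameters.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- with_seed(spec$master_seed, {
    tibble(
      patient_id = seq_len(spec$n_patients),
      seed = sample.int(2^30, spec$n_patients),
      bg_mean_mv = runif(spec$n_patients, spec$bg_mean_mv_range[1],
                         spec$bg_mean_mv_range[2]),
      patch_mean_mv = runif(spec$n_patients, spec$patch_mean_mv_range[1],
                            spec$patch_mean_mv_range[2]),
      n_patches = {
        pool <- seq(spec$n_patches_range[1], spec$n_patches_range[2])
        pool[sample.int(length(pool), spec$n_patients, replace = TRUE)]
      },
      fiber_angle_deg = runif(spec$n_patients, spec$fiber_angle_range[1],
                              spec$fiber_angle_range[2]))
  })
  patients <- purrr::map(seq_len(spec$n_patients), function(i) {
    args <- c(list(seed = draws$seed[i], bg_mean_mv = draws$bg_mean_mv[i],
                   patch_mean_mv = draws$patch_mean_mv[i],
                   n_patches = draws$n_patches[i],
                   fiber_angle_deg = draws$fiber_angle_deg[i]),
              spec$fixed)
    make_patient(do.call(patient_spec, args))
  })
  list(patients = patients, manifest = draws)
}

#' Calibrate a patient model for sustained baseline AF
#'
#' Wraps [calibrate_diffusion()] with the sustained-AF target: the global
#' diffusion scale is reduced from the upper bracket until drug-free
#' ramp-pacing induction leaves AF (or AT) still active at the end of the
#' observation window. Patients that cannot be calibrated inside the
#' bracket are flagged (`calibrated = FALSE`) with the attempted scales
#' reported; callers exclude them from cohort statistics.
#'
#' @param model A [build_patient_model()] result.
#' @param observe_after_pacing_ms Observation window after the ramp (ms).
#' @param bracket Diffusion-scale search interval.
#' @param descend_factor Geometric reduction per failed attempt.
#' @param ach_um Acetylcholine tone of the AF substrate (micromolar).
#' @param max_attempts Cap on calibration attempts per patient.
#' @param ... Passed to [run_protocol()].
#' @return The model with `$grid` rescaled and fields `calibrated`,
#'   `diffusion_scale`, `calibration_runs`, `baseline_trace`,
#'   `baseline_outcome` added.
#' @export
tune_for_baseline_af <- function(model, observe_after_pacing_ms = 10000,
                                 bracket = c(0.9, 1), descend_factor = 0.985,
                                 ach_um = 0.01, max_attempts = 1, ...) {
  proto <- pacing_protocol("ramp")
  t_end <- attr(proto, "pacing_end_ms") + observe_after_pacing_ms
  scal <- make_scaling_field(model$substrate, af_remodeling = TRUE,
                             remodeling = model$remodeling)
  last_trace <- NULL
  pac_end <- attr(proto, "pacing_end_ms")
  sustain_test <- function(g) {
    tr <- run_protocol(g, scal, proto, model$eas_nodes, t_end,
                       stim_amp = model$stim_amp, ach_um = ach_um, ...)
    last_trace <<- tr
    list(ok = classify_rhythm(tr, window_end_ms = t_end)$label %in% c("AF", "AT"),
         near = tr$t_stop > pac_end + 1000)
  }
  cal <- calibrate_diffusion(model$grid, scal, sustain_test = sustain_test,
                             bracket = bracket, max_iter = max_attempts,
                             descend_factor = descend_factor)
  model$calibrated <- isTRUE(cal$achieved)
  model$diffusion_scale <- cal$scale
  model$calibration_runs <- cal$runs
  if (model$calibrated) {
    model$grid <- rescale_grid(model$grid, cal$scale)
    model$baseline_trace <- last_trace
    model$baseline_outcome <- classify_rhythm(last_trace, window_end_ms = t_end)
  } else {
    model$baseline_trace <- NULL
    model$baseline_outcome <- NULL
  }
  model
}
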