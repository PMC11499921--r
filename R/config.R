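#' Default pipeline configuration
#'
#' Nested configuration with every tunable of the pipeline; all physical
#' quantities carry their unit in the key name. [load_config()] fills
#' missing keys from these defaults and rejects unknown ones.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    model = list(
      af_remodeling = list(ICaL = 0.3, Ito = 0.5, IKur = 0.5, IK1 = 2.0),
      ach_um = 0.01
    ),
    drug = list(
      name = "amiodarone",
      table = NULL,            # NULL = packaged amiodarone table
      doses_um = list(none = 0, low = 1.6, high = 3.9, toxic = 8.0)
    ),
    substrate = list(
      idw_radius_mm = 10,
      idw_power = 2,
      fibrosis_seed_offset = 1000
    ),
    solver = list(
      dt_ms = 0.1,
      cell_dt_ms = 0.02,
      k_sigma = 0.65
    ),
    protocol = list(
      constant_cl_ms = 500,
      ramp_start_ms = 200,
      ramp_floor_ms = 120,
      ramp_step_ms = 10,
      beats_per_cl = 8,
      observe_after_pacing_ms = 10000,
      stim_amp = 30,
      stim_dur_ms = 2
    ),
    biomarkers = list(
      df_band_hz = c(1, 20),
      df_window_s = 6,
      at_cv_threshold = 0.1,
      smax_node_stride = 12
    ),
    cohort = list(
      n_patients = 10,
      master_seed = 20240101,
      nx = 64, ny = 64, spacing_um = 250,
      n_points = 600,
      calibration_bracket = c(0.9, 1)
    )
  )
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills unset keys from [default_config()]
#' and rejects unknown keys and out-of-range values with messages naming
#' the offending key. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return Validated nested list with attribute `hash`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste("config file not found:", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_config(default_config(), user, prefix = NULL)
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

merge_config <- function(base, user, prefix = NULL) {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(base))
  if (length(extra) > 0) {
    key <- paste(c(prefix, extra[1]), collapse = ".")
    abort(paste0("unknown config key: ", key))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], prefix = c(prefix, k))
    } else if (is.null(user[[k]])) {
      base[k] <- list(NULL)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  check <- function(ok, key, msg) {
    if (!ok) abort(paste0("config ", key, ": ", msg))
  }
  check(cfg$solver$dt_ms > 0 && cfg$solver$dt_ms <= 0.11, "solver.dt_ms",
        "must be in (0, 0.11] ms")
  check(cfg$solver$cell_dt_ms > 0 && cfg$solver$cell_dt_ms <= 0.11,
        "solver.cell_dt_ms", "must be in (0, 0.11] ms")
  check(cfg$solver$k_sigma > 0, "solver.k_sigma", "must be > 0")
  check(cfg$substrate$idw_radius_mm > 0, "substrate.idw_radius_mm", "must be > 0")
  check(cfg$substrate$idw_power > 0, "substrate.idw_power", "must be > 0")
  check(cfg$protocol$observe_after_pacing_ms > 0,
        "protocol.observe_after_pacing_ms", "must be > 0")
  check(cfg$protocol$stim_amp > 0, "protocol.stim_amp", "must be > 0")
  check(cfg$cohort$n_patients >= 1, "cohort.n_patients", "must be >= 1")
  check(all(unlist(cfg$drug$doses_um) >= 0), "drug.doses_um", "must be >= 0")
  invisible(cfg)
}

#' Configuration hash
#'
#' Stable content hash recorded in every pipeline output for provenance.
#'
#' @param cfg A configuration list.
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  # canonicalize numeric storage modes so YAML round trips hash identically
  canon <- rapply(cfg, function(x) if (is.numeric(x)) as.numeric(x) else x,
                  how = "replace")
  rlang::hash(canon)
}

#' Save a configuration to YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
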