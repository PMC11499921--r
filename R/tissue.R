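#' Assemble a monodomain tissue grid from a substrate map
#'
#' Builds the anisotropic diffusion operator on the sheet: each node gets
#' the 2x2 tensor D = Dt I + (Dl - Dt) f f' from its conductivities and
#' fiber direction, discretized on an 8-neighbor stencil whose cross-term
#' is carried by one diagonal pair (sign of Dxy), with per-edge harmonic
#' averaging of the neighboring node coefficients. Rows of the operator
#' sum to zero (no-flux boundaries); lesion and removed nodes are
#' decoupled.
#'
#' Conductivities (S/m) are converted to diffusion coefficients (mm^2/ms)
#' as D = diffusion_scale * k_sigma * sigma, where k_sigma lumps membrane
#' capacitance and surface-to-volume ratio into a single calibration
#' constant.
#'
#' @param substrate A [build_substrate()] map.
#' @param diffusion_scale Global multiplier on all diffusion coefficients
#'   (the quantity tuned by [calibrate_diffusion()]).
#' @param k_sigma Conductivity-to-diffusion conversion, (mm^2/ms)/(S/m).
#' @return A `tissue_grid` object.
#' @export
build_grid <- function(substrate, diffusion_scale = 1, k_sigma = 0.65) {
  h <- attr(substrate, "spacing_mm")
  nx <- attr(substrate, "nx")
  ny <- attr(substrate, "ny")
  if (is.null(h) || h <= 0) abort("substrate lacks a positive spacing")
  N <- nrow(substrate)
  alive <- !(substrate$removed | substrate$lesion)

  Dl <- k_sigma * substrate$sigma_l
  Dt <- k_sigma * substrate$sigma_t
  fx <- substrate$fx
  fy <- substrate$fy
  a <- Dt + (Dl - Dt) * fx^2          # Dxx
  b <- Dt + (Dl - Dt) * fy^2          # Dyy
  cc <- (Dl - Dt) * fx * fy           # Dxy
  ac <- abs(cc)
  wE <- pmax(a - ac, 0) / h^2         # E/W axial coefficient
  wN <- pmax(b - ac, 0) / h^2         # N/S axial
  wP <- pmax(cc, 0) / h^2             # NE/SW diagonal (c > 0)
  wM <- pmax(-cc, 0) / h^2            # NW/SE diagonal (c < 0)

  ix <- substrate$ix
  iy <- substrate$iy
  id <- function(i, j) (j - 1L) * nx + i
  harm <- function(x, y) ifelse(x > 0 & y > 0, 2 * x * y / (x + y), 0)

  rows <- integer(0); cols <- integer(0); wts <- numeric(0)
  add_dir <- function(di, dj, coefs) {
    i2 <- ix + di; j2 <- iy + dj
    ok <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ny
    me <- id(ix, iy)[ok]; nb <- id(i2, j2)[ok]
    keep <- alive[me] & alive[nb]
    me <- me[keep]; nb <- nb[keep]
    w <- harm(coefs[me], coefs[nb])
    nz <- w > 0
    rows <<- c(rows, me[nz]); cols <<- c(cols, nb[nz]); wts <<- c(wts, w[nz])
  }
  add_dir(1L, 0L, wE);  add_dir(-1L, 0L, wE)
  add_dir(0L, 1L, wN);  add_dir(0L, -1L, wN)
  add_dir(1L, 1L, wP);  add_dir(-1L, -1L, wP)           # NE / SW
  add_dir(-1L, 1L, wM); add_dir(1L, -1L, wM)            # NW / SE

  o <- order(rows, cols)
  rows <- rows[o]; cols <- cols[o]; wts <- wts[o]
  row_ptr <- c(0L, cumsum(tabulate(rows, N)))
  diag <- numeric(N)
  rs <- tapply(wts, factor(rows, levels = seq_len(N)), sum)
  diag <- -ifelse(is.na(rs), 0, as.numeric(rs))

  comp <- grid_components(N, rows, cols, alive)
  if (comp$n > 1)
    warn(paste0("non-lesion tissue is disconnected: ",
                comp$n, " components"))

  structure(list(
    row_ptr = as.integer(row_ptr), col = as.integer(cols - 1L), w = wts,
    diag = diag, alive = alive, n_nodes = N, nx = nx, ny = ny,
    spacing_mm = h, k_sigma = k_sigma, diffusion_scale = diffusion_scale,
    nodes = tibble(node = substrate$node, x_mm = substrate$x_mm,
                   y_mm = substrate$y_mm),
    substrate = substrate),
    class = "tissue_grid")
}

grid_components <- function(N, rows, cols, alive) {
  # union-find over coupled alive nodes
  parent <- seq_len(N)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(rows)) {
    a <- find(as.integer(rows[k])); b <- find(as.integer(cols[k]))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(as.integer(which(alive)), function(i) as.integer(find(i)), integer(1))
  list(n = length(unique(roots)))
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid> ", x$nx, "x", x$ny, " nodes (", sum(x$alive),
      " conducting), spacing ", x$spacing_mm, " mm, diffusion scale ",
      x$diffusion_scale, "\n", sep = "")
  invisible(x)
}

#' Rescale the global diffusion coefficient of a grid
#'
#' @param grid A `tissue_grid`.
#' @param diffusion_scale New global scale.
#' @return Rescaled grid.
#' @export
rescale_grid <- function(grid, diffusion_scale) {
  f <- diffusion_scale / grid$diffusion_scale
  grid$w <- grid$w * f
  grid$diag <- grid$diag * f
  grid$diffusion_scale <- diffusion_scale
  grid
}

#' Add ablation lesions to a built grid
#'
#' Marks the nodes inside the given ring footprints non-conducting
#' (decoupled from all neighbors and clamped at rest). An empty lesion
#' specification returns the grid unchanged.
#'
#' @param grid A `tissue_grid`.
#' @param rings Tibble with `cx_mm`, `cy_mm`, `r_in_mm`, `r_out_mm`.
#' @return Updated grid.
#' @export
apply_lesions <- function(grid, rings) {
  if (is.null(rings) || nrow(rings) == 0) return(grid)
  lesioned <- rep(FALSE, grid$n_nodes)
  for (i in seq_len(nrow(rings))) {
    r <- rings[i, ]
    d <- sqrt((grid$nodes$x_mm - r$cx_mm)^2 + (grid$nodes$y_mm - r$cy_mm)^2)
    lesioned <- lesioned | (d >= r$r_in_mm & d <= r$r_out_mm)
  }
  if (all(lesioned | !grid$alive)) abort("lesions cover all conducting tissue")
  grid$alive <- grid$alive & !lesioned
  # zero couplings touching dead nodes, restore zero row sums
  keep_node <- grid$alive
  row_of <- rep(seq_len(grid$n_nodes), diff(grid$row_ptr))
  dead_edge <- !keep_node[row_of] | !keep_node[grid$col + 1L]
  grid$w[dead_edge] <- 0
  rs <- tapply(grid$w, factor(row_of, levels = seq_len(grid$n_nodes)), sum)
  grid$diag <- -ifelse(is.na(rs), 0, as.numeric(rs))
  grid
}

#' Per-node conductance scaling field
#'
#' Expands fibrosis-dependent scaling plus an optional drug blockade into
#' the 13 x n_nodes matrix consumed by the solver: non-fibrotic nodes get
#' the (optionally AF-remodeled) profile, fibrotic nodes additionally the
#' fibrotic current reductions.
#'
#' @param substrate A [build_substrate()] map.
#' @param blockade Optional [hill_blockade()] tibble.
#' @param af_remodeling Apply chronic-AF remodeling (default TRUE for AF
#'   substrates).
#' @param remodeling Optional override profile, see [conductance_scaling()].
#' @return 13 x n_nodes numeric matrix.
#' @export
make_scaling_field <- function(substrate, blockade = NULL,
                               af_remodeling = TRUE, remodeling = NULL) {
  g_n <- conductance_scaling(af_remodeling = af_remodeling, fibrotic = FALSE,
                             blockade = blockade, remodeling = remodeling)
  g_f <- conductance_scaling(af_remodeling = af_remodeling, fibrotic = TRUE,
                             blockade = blockade, remodeling = remodeling)
  out <- matrix(as_scaling_vector(g_n), 13, nrow(substrate))
  out[, substrate$fibrotic] <- as_scaling_vector(g_f)
  out
}

#' Nodes within a disc
#'
#' @param grid A `tissue_grid` (or any object with `$nodes`).
#' @param x_mm,y_mm Disc center (mm).
#' @param radius_mm Disc radius (mm).
#' @param alive_only Restrict to conducting nodes.
#' @return Integer node ids.
#' @export
disc_nodes <- function(grid, x_mm, y_mm, radius_mm = 0.75, alive_only = TRUE) {
  d <- sqrt((grid$nodes$x_mm - x_mm)^2 + (grid$nodes$y_mm - y_mm)^2)
  ids <- which(d <= radius_mm)
  if (alive_only) ids <- ids[grid$alive[ids]]
  ids
}

#' Stimulus event table
#'
#' @param nodes Integer node ids (or list of id vectors, one per event).
#' @param t_on_ms Onset time(s), ms.
#' @param duration_ms Pulse duration(s), ms (> 0).
#' @param amplitude Current density (pA/pF), depolarizing positive (> 0).
#' @return Tibble with a `nodes` list-column.
#' @export
stimulus <- function(nodes, t_on_ms, duration_ms = 2, amplitude = 30) {
  if (!is.list(nodes)) nodes <- list(nodes)
  out <- tibble(t_on_ms = t_on_ms, duration_ms = duration_ms,
                amplitude = amplitude)
  if (any(out$duration_ms <= 0)) abort("stimulus duration must be > 0")
  if (any(out$amplitude <= 0)) abort("stimulus amplitude must be > 0")
  out$nodes <- rep_len(nodes, nrow(out))
  out
}

#' Run a monodomain tissue simulation
#'
#' Integrates the reaction-diffusion system on the grid with the given
#' per-node conductance scaling and stimulus schedule. Activation
#' (upstroke crossing of `vthresh_mV`) and 90%-repolarization events are
#' detected online at every node; membrane-potential traces are recorded
#' for a chosen node subset and, optionally, for all nodes inside a time
#' window (for spectral analysis). Fully deterministic for a given
#' configuration.
#'
#' @param grid A `tissue_grid`.
#' @param scaling A `conductance_scaling` (applied everywhere) or a
#'   13 x n_nodes matrix from [make_scaling_field()].
#' @param stimuli A [stimulus()] tibble.
#' @param t_end_ms Simulated duration (ms).
#' @param dt_ms Shared reaction/diffusion time step (ms), default 0.1.
#' @param rec_nodes Node ids to record (default: none).
#' @param rec_dt_ms Sampling interval for `rec_nodes` (ms).
#' @param window_ms Optional `c(t0, t1)` all-node recording window (ms).
#' @param window_dt_ms Sampling interval inside the window (ms).
#' @param quiet_stop_ms If > 0, end the run early once no node has
#'   activated for this long (checked after `quiet_from_ms`); used to
#'   abbreviate runs that have terminated.
#' @param quiet_from_ms Earliest time at which the quiet criterion applies
#'   (normally the end of pacing).
#' @param ach_um Acetylcholine concentration (micromolar).
#' @param vthresh_mV Activation detection threshold (mV).
#' @param init_state Optional 21 x n_nodes state matrix to start from.
#' @return A `simulation_trace` object.
#' @export
run_tissue <- function(grid, scaling, stimuli, t_end_ms, dt_ms = 0.1,
                       rec_nodes = integer(0), rec_dt_ms = 1,
                       window_ms = NULL, window_dt_ms = 8,
                       quiet_stop_ms = 0, quiet_from_ms = 0,
                       ach_um = 0, vthresh_mV = -40, init_state = NULL) {
  if (is.matrix(scaling)) {
    if (nrow(scaling) != 13 || ncol(scaling) != grid$n_nodes)
      abort("scaling matrix must be 13 x n_nodes")
    scal <- scaling
  } else {
    scal <- matrix(as_scaling_vector(scaling), 13, grid$n_nodes)
  }
  if (nrow(stimuli) > 0 && !all(c("t_on_ms", "duration_ms", "amplitude", "nodes")
                                %in% names(stimuli)))
    abort("stimuli must come from stimulus()")
  spar <- if (nrow(stimuli) > 0)
    cbind(stimuli$t_on_ms, stimuli$duration_ms, stimuli$amplitude)
  else matrix(numeric(0), 0, 3)
  snodes <- lapply(stimuli$nodes %||% list(), function(v) as.integer(v) - 1L)
  w0 <- if (is.null(window_ms)) c(0, 0) else window_ms
  wdt <- if (is.null(window_ms)) 0 else window_dt_ms

  r <- crn_tissue_run(
    as.numeric(cell_state()), grid$row_ptr, grid$col, grid$w, grid$diag,
    as.integer(grid$alive), scal, snodes, spar, t_end_ms, dt_ms,
    if (length(rec_nodes) > 0) rec_dt_ms else 0,
    as.integer(rec_nodes) - 1L, w0[1], w0[2], wdt, ach_um, vthresh_mV,
    quiet_stop_ms, quiet_from_ms, init_state)

  ev <- as_tibble(r$events)
  ev$node <- as.integer(ev$node)
  structure(list(
    time_ms = r$time_ms, vm = r$vm, rec_nodes = rec_nodes,
    window_time_ms = r$time2_ms, window_vm = r$vm2,
    events = ev, t_stop = r$t_stop, completed = !r$stopped_early,
    t_end_ms = t_end_ms, dt_ms = dt_ms, n_nodes = grid$n_nodes,
    state_final = r$state_final,
    config_hash = rlang::hash(list(grid$w, grid$diag, scal, spar,
                                   t_end_ms, dt_ms, ach_um))),
    class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace> ", x$n_nodes, " nodes, ",
      round(x$t_stop), "/", x$t_end_ms, " ms simulated, ",
      nrow(x$events), " activation events\n", sep = "")
  invisible(x)
}

#' @export
tidy.simulation_trace <- function(x, ...) x$events

#' @export
glance.simulation_trace <- function(x, ...) {
  tibble(t_end_ms = x$t_end_ms, t_stop_ms = x$t_stop,
         completed = x$completed, n_events = nrow(x$events),
         n_nodes = x$n_nodes, dt_ms = x$dt_ms)
}

#' Measure conduction velocity along a planar wave
#'
#' Paces one full edge of the sheet to launch a planar wave and regresses
#' activation time on distance along the propagation axis over the central
#' band of the sheet.
#'
#' @param grid A `tissue_grid`.
#' @param scaling Scaling (vector or field matrix).
#' @param direction `"x"` (stimulate the left edge) or `"y"` (bottom edge).
#' @param stim_amp Stimulus amplitude (pA/pF).
#' @param dt_ms Time step (ms).
#' @return One-row tibble: `cv_mps`, `n_nodes`, `propagated`.
#' @export
measure_cv <- function(grid, scaling = conductance_scaling(), direction = "x",
                       stim_amp = 40, dt_ms = 0.1) {
  nd <- grid$nodes
  h <- grid$spacing_mm
  band <- max(h / 2, 0.5)  # stimulated edge band >= 0.5 mm (capture margin)
  if (direction == "x") {
    edge <- which(nd$x_mm <= band)
    axis <- nd$x_mm
    span <- max(nd$x_mm)
  } else {
    edge <- which(nd$y_mm <= band)
    axis <- nd$y_mm
    span <- max(nd$y_mm)
  }
  edge <- edge[grid$alive[edge]]
  # generous horizon: slowest plausible CV ~0.05 m/s
  t_end <- min(span / 0.05 + 50, 2000)
  tr <- run_tissue(grid, scaling, stimulus(edge, 5, 2, stim_amp), t_end, dt_ms)
  ev <- tr$events
  first <- ev %>% group_by(node) %>% summarise(t_act = min(t_act), .groups = "drop")
  if (nrow(first) < 0.5 * sum(grid$alive))
    return(tibble(cv_mps = NA_real_, n_nodes = nrow(first), propagated = FALSE))
  d <- axis[first$node]
  # exclude the stimulated margin and the far boundary
  keep <- d > 0.15 * span & d < 0.9 * span
  fit <- stats::lm(t_act ~ d, data = tibble(t_act = first$t_act, d = d)[keep, ])
  slope <- coef(fit)[["d"]]                 # ms per mm
  tibble(cv_mps = 1 / slope, n_nodes = nrow(first), propagated = TRUE)
}

#' Calibrate the global diffusion scale
#'
#' Two calibration targets are supported. A conduction-velocity target is
#' met by bisection on the scale (CV grows monotonically with diffusion).
#' A sustained-AF target follows the baseline-tailoring procedure: starting
#' from the upper bracket, the scale is reduced geometrically until the
#' supplied induction test reports sustained AF over the observation
#' window; reducing diffusion shortens the excitation wavelength, which is
#' what permits reentry on a bounded sheet.
#'
#' @param grid A `tissue_grid`.
#' @param scaling Scaling used during calibration runs.
#' @param target_cv_mps Target conduction velocity (m/s), or NULL.
#' @param sustain_test Function(grid) -> logical (TRUE when AF sustained),
#'   used when `target_cv_mps` is NULL.
#' @param bracket `c(lo, hi)` search interval for the scale.
#' @param tol_mps CV tolerance (m/s).
#' @param descend_factor Geometric step for the sustained-AF search.
#' @param max_iter Iteration cap.
#' @param futility_stop Sustained-AF search only: abandon after this many
#   initial attempts in which induction produced no post-pacing activity
#'   at all (the test may return `list(ok, near)`; attempts with `near =
#'   TRUE` — transient reentry — disable the futility rule). Substrates
#'   whose wavefront timing is close to reentry flip with small scale
#'   changes, which is why the search uses fine steps; substrates that
#'   never show any reentrant transient are not rescued by further scale
#'   reduction.
#' @return List: `scale`, `mode`, `achieved`, `runs` (tibble of attempts).
#' @export
calibrate_diffusion <- function(grid, scaling = conductance_scaling(),
                                target_cv_mps = NULL, sustain_test = NULL,
                                bracket = c(0.9, 1), tol_mps = 0.01,
                                descend_factor = 0.985, max_iter = 12,
                                futility_stop = 2) {
  if (!is.null(target_cv_mps)) {
    lo <- bracket[1]; hi <- bracket[2]
    cv_at <- function(s) measure_cv(rescale_grid(grid, s), scaling)$cv_mps
    runs <- tibble(scale = numeric(0), cv_mps = numeric(0))
    cv_lo <- cv_at(lo); cv_hi <- cv_at(hi)
    runs <- bind_rows(runs, tibble(scale = c(lo, hi), cv_mps = c(cv_lo, cv_hi)))
    if (is.na(cv_lo) || is.na(cv_hi) ||
        target_cv_mps < cv_lo - tol_mps || target_cv_mps > cv_hi + tol_mps)
      abort(paste0("target CV ", target_cv_mps, " m/s unreachable in bracket: ",
                   "achieved [", round(cv_lo, 3), ", ", round(cv_hi, 3), "] m/s"))
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      cv <- cv_at(mid)
      runs <- bind_rows(runs, tibble(scale = mid, cv_mps = cv))
      if (abs(cv - target_cv_mps) <= tol_mps)
        return(list(scale = mid, mode = "cv", achieved = cv, runs = runs))
      if (cv < target_cv_mps) lo <- mid else hi <- mid
    }
    mid <- sqrt(lo * hi)
    cv <- cv_at(mid)
    return(list(scale = mid, mode = "cv", achieved = cv,
                runs = bind_rows(runs, tibble(scale = mid, cv_mps = cv))))
  }
  if (is.null(sustain_test))
    abort("supply either target_cv_mps or sustain_test")
  s <- bracket[2]
  runs <- tibble(scale = numeric(0), sustained = logical(0), near = logical(0))
  any_near <- FALSE
  for (i in seq_len(max_iter)) {
    res <- sustain_test(rescale_grid(grid, s))
    ok <- if (is.list(res)) isTRUE(res$ok) else isTRUE(res)
    near <- if (is.list(res)) isTRUE(res$near) else ok
    any_near <- any_near || near
    runs <- bind_rows(runs, tibble(scale = s, sustained = ok, near = near))
    if (ok)
      return(list(scale = s, mode = "sustained_af", achieved = TRUE, runs = runs))
    if (!any_near && nrow(runs) >= futility_stop) break
    s <- s * descend_factor
    if (s < bracket[1] - 1e-9) break
  }
  list(scale = NA_real_, mode = "sustained_af", achieved = FALSE, runs = runs)
}
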