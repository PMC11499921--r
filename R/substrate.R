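#' Regular 2D tissue sheet
#'
#' Node set of a regular nx-by-ny sheet at a given internode spacing,
#' the desk-scale stand-in for a triangulated atrial surface. Coordinates
#' are in mm; node ids are 1-based row-major (x fastest).
#'
#' @param nx,ny Nodes per side.
#' @param spacing_um Internode spacing (micrometers), default 250 matching
#'   the clinical mesh density.
#' @return Tibble (`sheet_mesh`) with columns `node`, `ix`, `iy`, `x_mm`,
#'   `y_mm` and attributes `nx`, `ny`, `spacing_mm`.
#' @export
make_sheet <- function(nx = 64, ny = 64, spacing_um = 250) {
  if (nx < 2 || ny < 2 || spacing_um <= 0) abort("invalid sheet dimensions")
  h <- spacing_um / 1000
  out <- tibble(node = seq_len(nx * ny),
                ix = rep(seq_len(nx), ny),
                iy = rep(seq_len(ny), each = nx))
  out$x_mm <- (out$ix - 1) * h
  out$y_mm <- (out$iy - 1) * h
  structure(out, class = c("sheet_mesh", class(out)),
            nx = nx, ny = ny, spacing_mm = h)
}

#' Sparse bipolar-voltage point cloud
#'
#' Validated container for an electroanatomical-map-like point set:
#' coordinates (mm) with non-negative bipolar voltages (mV).
#'
#' @param x_mm,y_mm Point coordinates (mm).
#' @param voltage_mv Bipolar voltage (mV), >= 0.
#' @return Tibble of class `voltage_cloud`.
#' @export
voltage_cloud <- function(x_mm, y_mm, voltage_mv) {
  if (length(x_mm) < 1) abort("a voltage cloud needs at least one point")
  if (length(unique(c(length(x_mm), length(y_mm), length(voltage_mv)))) != 1)
    abort("x_mm, y_mm, voltage_mv must have equal length")
  if (any(!is.finite(voltage_mv)) || any(voltage_mv < 0))
    abort("voltages must be finite and >= 0")
  structure(tibble(x_mm = x_mm, y_mm = y_mm, voltage_mv = voltage_mv),
            class = c("voltage_cloud", class(tibble())))
}

#' Inverse-distance-weighted interpolation of sparse voltages
#'
#' Interpolates cloud voltages onto mesh nodes with normalized
#' inverse-distance weights w_i = d_i^-a over the cloud points within
#' `radius_mm` of each node. A node coincident with a sample point returns
#' that sample's value exactly. Nodes with no sample within the radius are
#' flagged uncovered and filled from their nearest sample.
#'
#' @param nodes A [make_sheet()] result (or data frame with `x_mm`, `y_mm`).
#' @param cloud A [voltage_cloud()].
#' @param radius_mm Search radius (mm), default 10.
#' @param power IDW exponent a, default 2.
#' @return `nodes` with added columns `voltage_mv` and `covered`.
#' @export
idw_interpolate <- function(nodes, cloud, radius_mm = 10, power = 2) {
  if (nrow(cloud) < 1) abort("empty voltage cloud")
  if (radius_mm <= 0 || power <= 0) abort("radius_mm and power must be > 0")
  d2 <- outer(nodes$x_mm, cloud$x_mm, "-")^2 + outer(nodes$y_mm, cloud$y_mm, "-")^2
  d <- sqrt(d2)
  inr <- d <= radius_mm
  # exact hits dominate: snap to sample value
  v <- numeric(nrow(nodes))
  covered <- rowSums(inr) > 0
  w <- ifelse(inr, 1 / pmax(d, 1e-12)^power, 0)
  hit <- d < 1e-9
  has_hit <- rowSums(hit) > 0
  v <- as.numeric(w %*% cloud$voltage_mv) / pmax(rowSums(w), .Machine$double.xmin)
  if (any(has_hit)) {
    first_hit <- apply(hit[has_hit, , drop = FALSE], 1, which.max)
    v[has_hit] <- cloud$voltage_mv[first_hit]
  }
  if (any(!covered)) {
    nearest <- apply(d[!covered, , drop = FALSE], 1, which.min)
    v[!covered] <- cloud$voltage_mv[nearest]
  }
  nodes$voltage_mv <- v
  nodes$covered <- covered
  nodes
}

#' Probability of fibrosis from bipolar voltage
#'
#' Piecewise map from bipolar voltage V (mV) to fibrosis probability:
#' 1 below 0 mV; the cubic (1/100)(-40 V^3 + 155 V^2 - 206 V + 99.8) on
#' [0, 1.74], clamped to [0, 1] (the raw cubic is slightly negative at the
#' 1.74 mV boundary); 0 above 1.74 mV.
#'
#' @param v_mv Bipolar voltage(s), mV.
#' @return Probabilities in [0, 1].
#' @export
#' @examples
#' fibrosis_probability(c(-0.5, 0, 0.5, 1.74, 2))
fibrosis_probability <- function(v_mv) {
  if (any(!is.finite(v_mv))) abort("voltage must be finite")
  p <- (-40 * v_mv^3 + 155 * v_mv^2 - 206 * v_mv + 99.8) / 100
  p <- pmin(pmax(p, 0), 1)
  p[v_mv < 0] <- 1
  p[v_mv > 1.74] <- 0
  p
}

#' Stochastic fibrosis assignment
#'
#' Marks each node fibrotic when a uniform(0,1) draw falls below its
#' fibrosis probability; reproducible under a fixed seed.
#'
#' @param voltage_mv Per-node bipolar voltage (mV).
#' @param seed RNG seed.
#' @return Logical vector.
#' @export
assign_fibrosis <- function(voltage_mv, seed) {
  if (missing(seed)) abort("a seed is required for reproducible assignment")
  p <- fibrosis_probability(voltage_mv)
  with_seed(seed, runif(length(p)) < p)
}

#' Myocardial fiber direction field
#'
#' Unit in-plane fiber vectors: `uniform` (constant angle), `circular`
#' (tangential around a center, emulating circumferential atrial bundles)
#' or `parametric` (angle varying linearly across the sheet, an atlas-like
#' smooth field). Deterministic given its parameters.
#'
#' @param nodes Data frame with `x_mm`, `y_mm`.
#' @param mode One of `"uniform"`, `"circular"`, `"parametric"`.
#' @param angle_deg Fiber angle for `uniform` (from +x axis) and the base
#'   angle for `parametric`.
#' @param center `c(x, y)` (mm) for `circular` (default: sheet centroid).
#' @param twist_deg_per_mm Angle gradient along y for `parametric`.
#' @return `nodes` with unit-vector columns `fx`, `fy`.
#' @export
build_fiber_field <- function(nodes, mode = c("uniform", "circular", "parametric"),
                              angle_deg = 0, center = NULL,
                              twist_deg_per_mm = 5) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    a <- angle_deg * pi / 180
    nodes$fx <- rep(cos(a), nrow(nodes))
    nodes$fy <- rep(sin(a), nrow(nodes))
  } else if (mode == "circular") {
    if (is.null(center)) center <- c(mean(nodes$x_mm), mean(nodes$y_mm))
    dx <- nodes$x_mm - center[1]
    dy <- nodes$y_mm - center[2]
    r <- sqrt(dx^2 + dy^2)
    # tangential: orthogonal to the radius; arbitrary direction at the center
    fx <- ifelse(r > 1e-9, -dy / r, 1)
    fy <- ifelse(r > 1e-9, dx / r, 0)
    nodes$fx <- fx
    nodes$fy <- fy
  } else {
    a <- (angle_deg + twist_deg_per_mm * (nodes$y_mm - min(nodes$y_mm))) * pi / 180
    nodes$fx <- cos(a)
    nodes$fy <- sin(a)
  }
  nodes
}

#' Default conductivity table (S/m)
#'
#' Longitudinal and transverse conductivities for non-fibrotic and fibrotic
#' tissue.
#'
#' @return Named list with `nonfibrotic_l`, `fibrotic_l`, `nonfibrotic_t`,
#'   `fibrotic_t`.
#' @export
conductivity_table <- function() {
  list(nonfibrotic_l = 0.1264, fibrotic_l = 0.0546,
       nonfibrotic_t = 0.0252, fibrotic_t = 0.0068)
}

#' Assign anisotropic conductivities per node
#'
#' Non-fibrotic nodes get (0.1264, 0.0252) S/m and fibrotic nodes
#' (0.0546, 0.0068) S/m (longitudinal, transverse), unless overridden.
#'
#' @param fibrotic Logical per-node fibrosis flags.
#' @param table Conductivity table, see [conductivity_table()].
#' @return Tibble with `sigma_l`, `sigma_t` (S/m).
#' @export
assign_conductivity <- function(fibrotic, table = conductivity_table()) {
  req <- c("nonfibrotic_l", "fibrotic_l", "nonfibrotic_t", "fibrotic_t")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    abort(paste("conductivity table missing:", paste(miss, collapse = ", ")))
  tibble(sigma_l = ifelse(fibrotic, table$fibrotic_l, table$nonfibrotic_l),
         sigma_t = ifelse(fibrotic, table$fibrotic_t, table$nonfibrotic_t))
}

#' Six-region labels
#'
#' @return Character vector of the extra-pulmonary-vein region scheme.
#' @export
region_labels <- function() {
  c("septum", "anterior_wall", "appendage",
    "lateral_isthmus", "posterior_wall", "posterior_inferior_wall")
}

#' Segment a sheet into the six-region scheme
#'
#' On synthetic sheets the anatomical segmentation is replaced by a fixed
#' 3 x 2 template of contiguous rectangular patches (columns split at 1/3
#' and 2/3 of the x extent, rows at 1/2 of the y extent): bottom row
#' left-to-right = lateral isthmus, posterior-inferior wall, posterior
#' wall; top row = appendage, anterior wall, septum. Lesion and removed
#' nodes are unlabeled (NA).
#'
#' @param nodes Data frame with `x_mm`, `y_mm`.
#' @param lesion Logical: nodes excluded from the region scheme (lesions,
#'   vein holes); default none.
#' @return Factor of region labels (NA for excluded nodes).
#' @export
segment_regions <- function(nodes, lesion = rep(FALSE, nrow(nodes))) {
  xr <- range(nodes$x_mm)
  yr <- range(nodes$y_mm)
  cx <- pmin(2L, pmax(0L, floor(3 * (nodes$x_mm - xr[1]) / (xr[2] - xr[1] + 1e-9))))
  cy <- pmin(1L, pmax(0L, floor(2 * (nodes$y_mm - yr[1]) / (yr[2] - yr[1] + 1e-9))))
  template <- matrix(c("lateral_isthmus", "posterior_inferior_wall", "posterior_wall",
                       "appendage", "anterior_wall", "septum"),
                     nrow = 2, byrow = TRUE)
  lab <- template[cbind(cy + 1, cx + 1)]
  lab[lesion] <- NA
  lab <- factor(lab, levels = region_labels())
  present <- table(lab)
  if (any(present == 0))
    abort(paste("degenerate geometry: empty region",
                names(present)[present == 0][1]))
  lab
}

#' Virtual pulmonary-vein isolation template for a sheet
#'
#' Two circular "vein" holes on the posterior half of the sheet, each
#' encircled by a 2-mm-wide non-conducting ablation ring at the antral
#' level.
#'
#' The default places the vein pair at 60% of the sheet width so closed
#' conduction corridors remain on all sides of the antral obstacle, as
#' around real PV antra.
#'
#' @param sheet A [make_sheet()] result.
#' @param hole_radius_mm Vein-hole radius.
#' @param ring_width_mm Lesion ring width (default 2 mm).
#' @param ring_gap_mm Gap between hole edge and ring inner edge.
#' @return List with `holes` and `rings` tibbles (cx_mm, cy_mm, r_mm /
#'   r_in_mm, r_out_mm).
#' @export
pvi_lesion_template <- function(sheet, hole_radius_mm = 1.2,
                                ring_width_mm = 2, ring_gap_mm = 0.3) {
  xr <- range(sheet$x_mm)
  yr <- range(sheet$y_mm)
  cx <- xr[1] + 0.6 * diff(xr)
  cys <- yr[1] + c(0.3, 0.7) * diff(yr)
  holes <- tibble(cx_mm = cx, cy_mm = cys, r_mm = hole_radius_mm)
  rings <- tibble(cx_mm = cx, cy_mm = cys,
                  r_in_mm = hole_radius_mm + ring_gap_mm,
                  r_out_mm = hole_radius_mm + ring_gap_mm + ring_width_mm)
  list(holes = holes, rings = rings)
}

apply_lesion_template <- function(nodes, template) {
  removed <- rep(FALSE, nrow(nodes))
  lesion <- rep(FALSE, nrow(nodes))
  if (!is.null(template)) {
    for (i in seq_len(nrow(template$holes))) {
      h <- template$holes[i, ]
      d <- sqrt((nodes$x_mm - h$cx_mm)^2 + (nodes$y_mm - h$cy_mm)^2)
      removed <- removed | d <= h$r_mm
    }
    for (i in seq_len(nrow(template$rings))) {
      r <- template$rings[i, ]
      d <- sqrt((nodes$x_mm - r$cx_mm)^2 + (nodes$y_mm - r$cy_mm)^2)
      lesion <- lesion | (d >= r$r_in_mm & d <= r$r_out_mm)
    }
  }
  nodes$removed <- removed
  nodes$lesion <- lesion & !removed
  nodes
}

#' Build the complete per-node electrophysiological substrate
#'
#' Runs the full substrate path: IDW voltage interpolation, probabilistic
#' fibrosis assignment, fiber field, conductivity assignment, optional
#' vein-hole/lesion template, and region segmentation.
#'
#' @param sheet A [make_sheet()].
#' @param cloud A [voltage_cloud()].
#' @param seed RNG seed for fibrosis assignment.
#' @param fiber_mode,fiber_angle_deg Fiber-field parameters, see
#'   [build_fiber_field()].
#' @param lesion_template Optional [pvi_lesion_template()] output.
#' @param cond_table See [assign_conductivity()].
#' @param radius_mm,power IDW parameters.
#' @return `substrate_map` tibble: one row per node with voltage, fibrosis,
#'   fiber, conductivity, lesion and region columns.
#' @export
build_substrate <- function(sheet, cloud, seed, fiber_mode = "uniform",
                            fiber_angle_deg = 0, lesion_template = NULL,
                            cond_table = conductivity_table(),
                            radius_mm = 10, power = 2) {
  nodes <- idw_interpolate(sheet, cloud, radius_mm = radius_mm, power = power)
  nodes$p_fibrosis <- fibrosis_probability(nodes$voltage_mv)
  nodes$fibrotic <- assign_fibrosis(nodes$voltage_mv, seed = seed)
  nodes <- build_fiber_field(nodes, mode = fiber_mode, angle_deg = fiber_angle_deg)
  nodes <- dplyr::bind_cols(nodes, assign_conductivity(nodes$fibrotic, cond_table))
  nodes <- apply_lesion_template(nodes, lesion_template)
  nodes$fibrotic[nodes$removed | nodes$lesion] <- FALSE
  nodes$region <- segment_regions(nodes, lesion = nodes$removed | nodes$lesion)
  structure(nodes, class = c("substrate_map", class(tibble())),
            seed = seed, spacing_mm = attr(sheet, "spacing_mm"),
            nx = attr(sheet, "nx"), ny = attr(sheet, "ny"))
}
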