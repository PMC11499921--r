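# small uniform-voltage substrates for solver tests
solver_substrate <- function(nx, ny, spacing_um = 250, fibrotic = FALSE,
                             angle = 0, isotropic = FALSE) {
  sheet <- make_sheet(nx, ny, spacing_um)
  v <- if (fibrotic) 0 else 5
  cloud <- voltage_cloud(range(sheet$x_mm), range(sheet$y_mm), c(v, v))
  sub <- build_substrate(sheet, cloud, seed = 1, fiber_angle_deg = angle)
  if (fibrotic) {
    sub$fibrotic <- TRUE
    ct <- assign_conductivity(rep(TRUE, nrow(sub)))
    sub$sigma_l <- ct$sigma_l
    sub$sigma_t <- ct$sigma_t
  }
  if (isotropic) sub$sigma_t <- sub$sigma_l
  sub
}

test_that("the diffusion operator conserves charge and respects symmetry", {
  sub <- solver_substrate(16, 16, isotropic = TRUE)
  g <- build_grid(sub)
  # zero row sums everywhere (no-flux boundaries)
  rows <- rep(seq_len(g$n_nodes), diff(g$row_ptr))
  rs <- tapply(g$w, factor(rows, levels = seq_len(g$n_nodes)), sum)
  rs[is.na(rs)] <- 0
  expect_lt(max(abs(g$diag + as.numeric(rs))), 1e-12)

  # rotating fibers by 90 degrees swaps the principal axes
  gx <- build_grid(solver_substrate(12, 12, angle = 0))
  gy <- build_grid(solver_substrate(12, 12, angle = 90))
  # E-W coupling of x-aligned fibers equals N-S coupling of y-aligned ones
  pick_w <- function(g, from, to) {
    idx <- which(rep(seq_len(g$n_nodes), diff(g$row_ptr)) == from &
                 g$col + 1L == to)
    if (length(idx)) g$w[idx] else 0
  }
  ctr <- 6 + 5 * 12  # interior node
  expect_equal(pick_w(gx, ctr, ctr + 1L), pick_w(gy, ctr, ctr + 12L),
               tolerance = 1e-12)
  expect_equal(pick_w(gx, ctr, ctr + 12L), pick_w(gy, ctr, ctr + 1L),
               tolerance = 1e-12)
})

test_that("lesions decouple nodes and an empty specification is identity", {
  sub <- solver_substrate(20, 20)
  g <- build_grid(sub)
  g0 <- apply_lesions(g, tibble::tibble(cx_mm = numeric(0), cy_mm = numeric(0),
                                        r_in_mm = numeric(0), r_out_mm = numeric(0)))
  expect_identical(g0$w, g$w)

  ring <- tibble::tibble(cx_mm = 2.375, cy_mm = 2.375, r_in_mm = 0.7, r_out_mm = 1.6)
  gl <- apply_lesions(g, ring)
  lesioned <- which(!gl$alive & g$alive)
  expect_gt(length(lesioned), 0)
  rows <- rep(seq_len(gl$n_nodes), diff(gl$row_ptr))
  expect_true(all(gl$w[rows %in% lesioned] == 0))
  expect_true(all(gl$w[(gl$col + 1L) %in% lesioned] == 0))

  expect_error(apply_lesions(g, tibble::tibble(cx_mm = 2.375, cy_mm = 2.375,
                                               r_in_mm = 0, r_out_mm = 99)),
               "cover all")
})

test_that("a 2-mm ring at clinical spacing is at least 8 nodes thick", {
  sheet <- make_sheet(64, 64, 235)
  tpl <- pvi_lesion_template(sheet)
  nodes <- apply_lesion_template_for_test(sheet, tpl)
  ring1 <- tpl$rings[1, ]
  row_y <- sheet$y_mm[which.min(abs(sheet$y_mm - ring1$cy_mm))]
  on_row <- nodes$lesion & abs(nodes$y_mm - row_y) < 1e-9 &
    nodes$x_mm > ring1$cx_mm
  expect_gte(sum(on_row), 8)
})

test_that("an unstimulated grid stays at rest and runs are deterministic", {
  sub <- solver_substrate(16, 16)
  g <- build_grid(sub)
  tr <- run_tissue(g, conductance_scaling(), stimulus(1, 1, 1, 1)[0, ],
                   t_end_ms = 2000, rec_nodes = c(1, 120), rec_dt_ms = 10)
  expect_lt(max(abs(tr$vm - tr$vm[1, 1])), 0.5)
  expect_equal(nrow(tr$events), 0)

  st <- stimulus(which(sub$ix <= 2), 5, 2, 40)
  t1 <- run_tissue(g, conductance_scaling(), st, 60, rec_nodes = 1:8)
  t2 <- run_tissue(g, conductance_scaling(), st, 60, rec_nodes = 1:8)
  expect_identical(t1$vm, t2$vm)
  expect_identical(t1$events, t2$events)
})

test_that("a point stimulus on an isotropic sheet gives circular isochrones", {
  sub <- solver_substrate(48, 48, isotropic = TRUE)
  g <- build_grid(sub)
  ctr <- c(mean(sub$x_mm), mean(sub$y_mm))
  site <- disc_nodes(g, ctr[1], ctr[2], 0.6)
  tr <- run_tissue(g, conductance_scaling(), stimulus(site, 5, 2, 40), 60)
  ev <- tr$events %>% dplyr::group_by(node) %>%
    dplyr::summarise(t_act = min(t_act), .groups = "drop")
  d <- sqrt((sub$x_mm[ev$node] - ctr[1])^2 + (sub$y_mm[ev$node] - ctr[2])^2)
  ang <- atan2(sub$y_mm[ev$node] - ctr[2], sub$x_mm[ev$node] - ctr[1])
  # radius of the 10 ms isochrone along axes vs diagonals
  sel <- abs(ev$t_act - 10) < 1 & d > 1
  r_axis <- mean(d[sel & (abs(cos(2 * ang)) > 0.9)])
  r_diag <- mean(d[sel & (abs(cos(2 * ang)) < 0.3)])
  ecc <- max(r_axis, r_diag) / min(r_axis, r_diag)
  expect_lt(ecc, 1.1)
})

test_that("conduction velocity scales with the square root of diffusion", {
  # fine spacing so the wavefront stays resolved across the diffusion range
  subf <- solver_substrate(100, 8, spacing_um = 125)
  gf <- build_grid(subf)
  cvs <- vapply(c(1, 2, 4), function(s)
    measure_cv(rescale_grid(gf, s), conductance_scaling(), dt_ms = 0.01)$cv_mps,
    numeric(1))
  expect_lt(abs(cvs[3] / cvs[1] - 2), 0.1)        # 4x diffusion -> 2x CV
  expect_lt(abs(cvs[2] / cvs[1] - sqrt(2)), 0.05 * sqrt(2))
  sub <- solver_substrate(60, 14)
  g <- build_grid(sub)
  cvs[3] <- measure_cv(g, conductance_scaling())$cv_mps
  # anisotropy: along fibers faster than across
  sub_t <- solver_substrate(14, 60)
  cv_across <- measure_cv(build_grid(sub_t), conductance_scaling(), "y")
  expect_gt(cvs[3], cv_across$cv_mps)
  # fibrotic tissue conducts more slowly
  cv_fib <- measure_cv(build_grid(solver_substrate(60, 14, fibrotic = TRUE)),
                       conductance_scaling(fibrotic = TRUE))
  expect_lt(cv_fib$cv_mps, cvs[3])
})

test_that("a closed lesion ring blocks conduction to its interior", {
  sub <- solver_substrate(40, 40)
  g <- build_grid(sub)
  ctr <- c(mean(sub$x_mm), mean(sub$y_mm))
  g <- apply_lesions(g, tibble::tibble(cx_mm = ctr[1], cy_mm = ctr[2],
                                       r_in_mm = 1.5, r_out_mm = 2.6))
  edge <- which(sub$ix <= 2)
  tr <- suppressWarnings(
    run_tissue(g, conductance_scaling(), stimulus(edge, 5, 2, 40), 120))
  inside <- which(sqrt((sub$x_mm - ctr[1])^2 + (sub$y_mm - ctr[2])^2) < 1.5)
  expect_gt(length(inside), 10)
  expect_false(any(tr$events$node %in% inside))
  # tissue outside the ring still activates
  expect_gt(length(unique(tr$events$node)), 0.7 * sum(g$alive))
})

test_that("halving the time step shifts activation times by under 1 ms", {
  sub <- solver_substrate(48, 10)
  g <- build_grid(sub)
  edge <- which(sub$ix <= 2)
  st <- stimulus(list(edge, edge, edge, edge), c(5, 505, 1005, 1505), 2, 40)
  act_last <- function(dt) {
    tr <- run_tissue(g, conductance_scaling(), st, 2000, dt_ms = dt)
    ev <- tr$events[tr$events$t_act > 1500, ]
    ev <- ev[order(ev$node), ]
    stats::setNames(ev$t_act, ev$node)
  }
  a1 <- act_last(0.1)
  a2 <- act_last(0.05)
  common <- intersect(names(a1), names(a2))
  expect_gt(length(common), 400)
  expect_lt(max(abs(a1[common] - a2[common])), 1)
})

test_that("instability and stability-bound violations are rejected loudly", {
  sub <- solver_substrate(12, 12)
  g <- build_grid(sub)
  expect_error(run_tissue(rescale_grid(g, 6), conductance_scaling(),
                          stimulus(1, 1, 2, 10), 10),
               "stability")
  expect_error(run_tissue(g, conductance_scaling(), stimulus(1, 1, 2, 10), 10,
                          dt_ms = 0.5), "stability")
})

test_that("diffusion calibration meets a conduction-velocity target", {
  sub <- solver_substrate(48, 10)
  g <- build_grid(sub)
  cv1 <- measure_cv(g, conductance_scaling())$cv_mps
  # fixed point: target equal to the scale-1 velocity returns ~1
  cal <- calibrate_diffusion(g, conductance_scaling(), target_cv_mps = cv1,
                             bracket = c(0.5, 2), tol_mps = 0.005)
  expect_lt(abs(cal$scale - 1), 0.1)
  expect_lt(abs(cal$achieved - cv1), 0.005 + 1e-9)
  # a lower target is met within tolerance by bisection
  cal2 <- calibrate_diffusion(g, conductance_scaling(),
                              target_cv_mps = 0.75 * cv1,
                              bracket = c(0.25, 1.5), tol_mps = 0.01)
  expect_lt(abs(cal2$achieved - 0.75 * cv1), 0.01 + 1e-9)
  # unreachable target reports the achieved extremes
  expect_error(calibrate_diffusion(g, conductance_scaling(),
                                   target_cv_mps = 10, bracket = c(0.5, 1)),
               "unreachable")
})
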