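fake_trace <- function(events, t_end = 10000, completed = TRUE) {
  structure(list(events = events, t_end_ms = t_end, t_stop = t_end,
                 completed = completed, n_nodes = max(c(events$node, 1))),
            class = "simulation_trace")
}

test_that("the induction ramp delivers 72 beats spanning exactly 11.52 s", {
  p <- pacing_protocol("ramp")
  expect_equal(nrow(p), 9 * 8)
  expect_equal(unique(p$cl_ms), seq(200, 120, -10))
  expect_true(all(table(p$cl_ms) == 8))
  expect_equal(sum(p$cl_ms), 11520)
  expect_equal(attr(p, "pacing_end_ms") - p$t_on_ms[1], 11520)
  expect_equal(diff(p$t_on_ms), p$cl_ms[-nrow(p)])

  cst <- pacing_protocol("constant", cl_ms = 500, n_beats = 10)
  expect_true(all(diff(cst$t_on_ms) == 500))
})

test_that("earliest-activation-site selection breaks ties by node index", {
  ev <- tibble::tibble(node = c(9L, 4L, 2L), t_act = c(3, 1, 1))
  expect_equal(find_eas(ev), 2L)
  expect_equal(find_eas(tibble::tibble(node = 5L, t_act = 0.5)), 5L)
  expect_error(find_eas(tibble::tibble(node = integer(0), t_act = numeric(0))),
               "no activation")
})

test_that("EAS of a planar wave lies on the stimulated edge", {
  sheet <- make_sheet(24, 12, 400)
  cloud <- voltage_cloud(range(sheet$x_mm), range(sheet$y_mm), c(5, 5))
  sub <- build_substrate(sheet, cloud, seed = 1)
  g <- build_grid(sub)
  edge <- which(sub$ix == 1)
  tr <- run_tissue(g, conductance_scaling(), stimulus(edge, 5, 2, 40), 80)
  expect_true(find_eas(tr) %in% edge)
})

test_that("rhythm classification distinguishes termination, AT and AF", {
  # all nodes silent over the final window -> termination
  quiet <- fake_trace(tibble::tibble(node = 1:50, t_act = runif(50, 0, 9000)))
  out <- classify_rhythm(quiet, window_end_ms = 10000)
  expect_equal(out$label, "termination")
  expect_equal(out$t_termination_ms, max(quiet$events$t_act))

  # perfectly periodic activation -> AT
  at_ev <- tidyr::expand_grid(node = 1:20, beat = 0:39) %>%
    dplyr::mutate(t_act = 150 + beat * 250 + node * 2) %>%
    dplyr::select(node, t_act)
  at <- classify_rhythm(fake_trace(at_ev), window_end_ms = 10000)
  expect_equal(at$label, "AT")
  expect_equal(at$mean_cl_ms, 250)
  expect_lt(at$cl_cv, 1e-9)

  # irregular cycle lengths drawn uniform(120, 220) -> AF
  set.seed(8)
  af_ev <- purrr::map_dfr(1:20, function(nd) {
    cls <- runif(60, 120, 220)
    tibble::tibble(node = nd, t_act = cumsum(c(runif(1, 0, 200), cls)))
  })
  af <- classify_rhythm(fake_trace(af_ev), window_end_ms = 10000)
  expect_equal(af$label, "AF")
  expect_gt(af$cl_cv, 0.1)

  # determinism of the classifier
  expect_identical(classify_rhythm(fake_trace(af_ev), window_end_ms = 10000), af)

  # early-stopped runs are terminations by construction
  early <- fake_trace(at_ev[at_ev$t_act < 4000, ], completed = FALSE)
  early$t_stop <- 4500
  expect_equal(classify_rhythm(early, window_end_ms = 10000)$label,
               "termination")

  short <- fake_trace(at_ev, t_end = 10000)
  short$t_stop <- 8000
  expect_error(classify_rhythm(short, window_end_ms = 10000), "before")
})

test_that("the effective/ineffective grouping rule is a pure two-dose function", {
  expect_equal(verdict_group("termination", "AF"), "Effective")
  expect_equal(verdict_group("AF", "termination"), "Effective")
  expect_equal(verdict_group("termination", "termination"), "Effective")
  expect_equal(verdict_group("AT", "AF"), "Ineffective")
  expect_equal(verdict_group("AT", "AT"), "Ineffective")
})

test_that("protocol preconditions and stimulus validation hold", {
  sheet <- make_sheet(12, 12, 400)
  cloud <- voltage_cloud(range(sheet$x_mm), range(sheet$y_mm), c(5, 5))
  g <- build_grid(build_substrate(sheet, cloud, seed = 1))
  expect_error(run_protocol(g, conductance_scaling(), pacing_protocol("ramp"),
                            1:3, observe_until_ms = 5000),
               "before the pacing span")
  expect_error(stimulus(1:3, 10, duration_ms = 0), "duration")
  expect_error(stimulus(1:3, 10, amplitude = -1), "amplitude")
})

test_that("the automatic stimulus strength search captures at twice threshold", {
  sheet <- make_sheet(24, 12, 400)
  cloud <- voltage_cloud(range(sheet$x_mm), range(sheet$y_mm), c(5, 5))
  sub <- build_substrate(sheet, cloud, seed = 1)
  g <- build_grid(sub)
  site <- disc_nodes(g, 1, 2.2, 0.9)
  amp <- find_stim_threshold(g, conductance_scaling(), site)
  expect_gt(amp, 2)
  expect_lt(amp, 160)
  # the returned amplitude does capture
  tr <- run_tissue(g, conductance_scaling(), stimulus(site, 5, 2, amp), 80)
  expect_gt(length(unique(tr$events$node)), 0.5 * nrow(sub))
})
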