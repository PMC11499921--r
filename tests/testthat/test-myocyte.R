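test_that("ionic currents scale linearly per channel and vanish at rest", {
  st <- cell_state()
  base <- conductance_scaling()

  # zero-conductance channel carries no current regardless of state
  g0 <- base; g0[["INa"]] <- 0
  expect_equal(ionic_currents(st, g0)$INa, 0)

  # halving one channel halves exactly that current
  st2 <- step_cell(st, base, i_stim = 20, dt_ms = 0.02, n_steps = 100)
  ref <- ionic_currents(st2, base)
  gh <- base; gh[["IK1"]] <- 0.5
  half <- ionic_currents(st2, gh)
  expect_equal(half$IK1, ref$IK1 / 2, tolerance = 1e-12)
  for (ch in c("INa", "ICaL", "Ito", "IKr", "IKs")) {
    expect_equal(half[[ch]], ref[[ch]])
  }
  # exact proportionality across random factors at fixed state
  set.seed(4)
  for (k in 1:5) {
    f <- runif(1, 0.1, 3)
    ch <- sample(c("INa", "ICaL", "Ito", "IKur", "IKr", "IKs", "IK1"), 1)
    gs <- base; gs[[ch]] <- f
    expect_equal(ionic_currents(st2, gs)[[ch]], f * ref[[ch]], tolerance = 1e-12)
  }
  # total equals the sum of the components
  expect_equal(ref$i_ion, sum(unlist(ref[1, 1:13])), tolerance = 1e-10)

  # near-equilibrium after long unstimulated settling
  rest <- step_cell(st, base, i_stim = 0, dt_ms = 0.1, n_steps = 1e6)  # 100 s
  expect_lt(abs(ionic_currents(rest, base)$i_ion), 0.01)

  bad <- st; bad[["vm"]] <- NaN
  expect_error(ionic_currents(bad, base), "vm")
})

test_that("the resting cell is stationary and gates stay in [0,1]", {
  st <- cell_state()
  g <- conductance_scaling()
  # pre-equilibrate 10 s, then check drift over a further 10 s
  pre <- step_cell(st, g, 0, dt_ms = 0.1, n_steps = 1e5)
  v0 <- pre[["vm"]]
  post <- step_cell(pre, g, 0, dt_ms = 0.1, n_steps = 1e5)
  expect_lt(abs(post[["vm"]] - v0), 0.5)

  # unstimulated vm moves < 0.01 mV over 1 s from the shipped rest state
  still <- step_cell(st, g, 0, dt_ms = 0.02, n_steps = 5e4)
  expect_lt(abs(still[["vm"]] - st[["vm"]]), 0.01 + 1e-3)

  # gate boundedness along a stimulated trajectory, checked step by step
  cur <- st
  for (k in 1:400) {
    cur <- step_cell(cur, g, i_stim = if (k <= 100) 20 else 0,
                     dt_ms = 0.02, n_steps = 5)
    gates <- unclass(cur)[2:16]
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("a suprathreshold stimulus elicits a normal action potential", {
  tr <- pace_cell(conductance_scaling(), cl_ms = 600, n_beats = 1,
                  stim_amp = 20, stim_dur_ms = 2)
  expect_gt(max(tr$trace$vm_mV), 0)
  # repolarized below -70 mV within 600 ms of the stimulus
  late <- tr$trace$vm_mV[tr$trace$time_ms > 610]
  expect_lt(late[1], -70)
  expect_equal(nrow(tr$events), 1)
  expect_gt(tr$events$dvdt_max, 100)
})

test_that("APD90 converges under time-step refinement", {
  ap_at <- function(dt) {
    tr <- pace_cell(conductance_scaling(), cl_ms = 500, n_beats = 3,
                    dt_ms = dt, rec_dt_ms = 0.1)
    tail(tr$events$apd90, 1)
  }
  expect_lt(abs(ap_at(0.02) - ap_at(0.01)), 1)
})

test_that("measure_ap reproduces analytic waveforms and flags silence", {
  # square pulse: 200 ms at +20 mV from -80 mV baseline
  t <- seq(0, 1000, by = 0.5)
  v <- ifelse(t >= 100 & t < 300, 20, -80)
  m <- measure_ap(tibble::tibble(time_ms = t, vm_mV = v), cl_ms = 1000)
  expect_true(m$captured)
  expect_lt(abs(m$apd90_ms - 200), 1)

  # triangle: instant upstroke to +20, then 2 mV/ms linear repolarization;
  # APD90 = time to fall 90 mV = 45 ms (+ upstroke width ~ one sample)
  v2 <- rep(-80, length(t))
  up <- t >= 100
  v2[up] <- pmax(20 - 2 * (t[up] - 100), -80)
  m2 <- measure_ap(tibble::tibble(time_ms = t, vm_mV = v2), cl_ms = 1000)
  expect_lt(abs(m2$apd90_ms - 45), 1)
  expect_equal(m2$amplitude_mV, 100)

  # no beat -> explicit non-capture, not zeros
  m3 <- measure_ap(tibble::tibble(time_ms = t, vm_mV = rep(-80, length(t))))
  expect_false(m3$captured)
  expect_true(is.na(m3$apd90_ms))
})

test_that("one paced beat matches the naive reference integrator", {
  g <- conductance_scaling()
  stim <- matrix(c(10, 2, 20), 1, 3)
  dt <- 0.02
  fast <- crn_cell_run(as.numeric(cell_state()), as_scaling_vector_for_test(g),
                       stim, t_end = 420, dt = dt, rec_dt = 1)
  slow <- oracle_cell_run(cell_state(), as_scaling_vector_for_test(g),
                          stim, t_end = 420, dt = dt, rec_dt = 1)
  expect_equal(length(fast$vm_mV), length(slow$vm_mV))
  expect_lt(max(abs(fast$vm_mV - slow$vm_mV)), 0.5)
})
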