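test_that("APD/DI pairs follow from activation and repolarization times", {
  # synthetic steady train: APD 200 ms at CL 500 -> DI = 300 ms
  ev <- tibble::tibble(node = 1L, t_act = seq(0, 4500, 500), apd90 = 200,
                       dvdt_max = 150, v_peak = 20, v_takeoff = -80)
  pairs <- extract_apd_di(ev)
  expect_true(all(pairs$di_ms == 300))
  expect_true(all(pairs$apd90_ms == 200))

  # 2:1 block: a missed beat doubles the interval
  ev2 <- tibble::tibble(node = 1L, t_act = c(0, 500, 1500, 2000), apd90 = 150)
  p2 <- extract_apd_di(ev2)
  expect_equal(p2$di_ms, c(350, 850, 350))

  # monotone CL ramp gives non-increasing DI for constant APD
  cls <- rep(seq(300, 180, -30), each = 3)
  t_act <- cumsum(c(0, cls[-length(cls)]))
  ev3 <- tibble::tibble(node = 1L, t_act = t_act, apd90 = 120)
  p3 <- extract_apd_di(ev3)
  expect_true(all(diff(p3$di_ms) <= 1e-9))

  # non-physiologic pairs dropped and counted
  ev4 <- tibble::tibble(node = 1L, t_act = c(0, 100), apd90 = c(150, 80))
  p4 <- extract_apd_di(ev4)
  expect_equal(nrow(p4), 0)
  expect_equal(attr(p4, "n_dropped"), 1L)

  # fewer than two beats -> empty with diagnostic
  p5 <- extract_apd_di(tibble::tibble(node = 1L, t_act = 0, apd90 = 100))
  expect_equal(nrow(p5), 0)
  expect_match(attr(p5, "diagnostic"), "fewer than 2")
})

test_that("restitution fitting recovers known parameters and the slope formula", {
  y0 <- 100; a1 <- 150; tau1 <- 60
  di <- seq(20, 400, by = 20)
  pairs <- tibble::tibble(di_ms = di, apd90_ms = y0 + a1 * (1 - exp(-di / tau1)))
  fit <- fit_restitution(pairs)
  expect_true(fit$ok)
  expect_lt(abs(fit$tau1 - tau1) / tau1, 0.01)
  expect_lt(abs(fit$y0 - y0), 1)
  # closed-form slope at DI_min = 20: (150/60) exp(-1/3)
  expect_equal(fit$smax, (150 / 60) * exp(-20 / 60), tolerance = 1e-3)
  expect_equal(restitution_slope(150, 60, 20), (150 / 60) * exp(-20 / 60))

  # flat restitution -> zero slope
  flat <- fit_restitution(tibble::tibble(di_ms = di, apd90_ms = 200))
  expect_true(flat$ok)
  expect_equal(flat$smax, 0)

  # degenerate inputs are reported, not zeroed
  expect_false(fit_restitution(pairs[1:3, ])$ok)
  one_di <- tibble::tibble(di_ms = rep(50, 6), apd90_ms = rnorm(6, 150, 5))
  expect_false(fit_restitution(one_di)$ok)

  # broom-style accessors
  expect_equal(tidy(fit)$term, c("y0", "a1", "tau1"))
  expect_true(glance(fit)$ok)
})

test_that("noisy restitution recovery stays within 10% median Smax error", {
  y0 <- 100; a1 <- 150; tau1 <- 60
  di <- seq(20, 400, by = 5)
  truth <- restitution_slope(a1, tau1, min(di))
  set.seed(202)
  errs <- replicate(50, {
    apd <- (y0 + a1 * (1 - exp(-di / tau1))) * (1 + rnorm(length(di), 0, 0.05))
    f <- fit_restitution(tibble::tibble(di_ms = di, apd90_ms = apd))
    abs(f$smax - truth) / truth
  })
  expect_lt(median(errs), 0.10)
})

test_that("dominant frequency resolves pure and mixed tones", {
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)[-1]
  d <- dominant_frequency(sin(2 * pi * 6 * t), fs)
  expect_lt(abs(d$df_hz - 6), 1 / 6)
  # dominant component wins
  mix <- sin(2 * pi * 4 * t) + 0.3 * sin(2 * pi * 8 * t)
  expect_lt(abs(dominant_frequency(mix, fs)$df_hz - 4), 1 / 6)
  # constant signal -> explicit no-frequency flag
  expect_false(dominant_frequency(rep(3.3, 6000), fs)$found)
  # one-bin accuracy across the physiologic band
  for (f0 in c(1.5, 3.7, 9.2, 14.9, 19.5)) {
    dd <- dominant_frequency(sin(2 * pi * f0 * t), fs)
    expect_lt(abs(dd$df_hz - f0), 1 / 6)
  }
})

test_that("regional aggregation is exact against brute force", {
  sheet <- make_sheet(24, 24, 400)
  cloud <- voltage_cloud(c(0, 9.2), c(0, 9.2), c(2, 2))
  sub <- build_substrate(sheet, cloud, seed = 1)
  set.seed(31)
  vals <- tibble::tibble(node = sample(nrow(sub), 300),
                         value = runif(300, 0.5, 3))
  reg <- regional_summary(vals, sub)
  # brute force per-region means
  for (rg in region_labels()) {
    ids <- vals$node[!is.na(sub$region[vals$node]) & sub$region[vals$node] == rg]
    if (length(ids) > 0) {
      manual <- mean(vals$value[match(ids, vals$node)])
      expect_equal(reg$per_region$mean[reg$per_region$region == rg], manual)
    }
  }
  expect_true(reg$highest >= reg$mean && reg$mean >= reg$lowest)
  expect_equal(reg$delta_regional, reg$highest - reg$lowest)
  expect_gte(reg$delta_regional, 0)
  # node-count-weighted regional mean equals the global mean exactly
  pr <- reg$per_region[reg$per_region$n > 0, ]
  expect_equal(sum(pr$mean * pr$n) / sum(pr$n), reg$mean, tolerance = 1e-12)
})
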