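test_that("IDW interpolation matches hand-computed cases and stays bounded", {
  nodes <- tibble::tibble(x_mm = c(0, 1, 0.5, 3), y_mm = c(0, 0, 0, 4))
  cloud <- voltage_cloud(c(0, 1), c(0, 0), c(1.0, 2.0))

  out <- idw_interpolate(nodes, cloud, radius_mm = 10, power = 2)
  # exact at sample points
  expect_equal(out$voltage_mv[1], 1.0)
  expect_equal(out$voltage_mv[2], 2.0)
  # equidistant from 1.0 and 2.0 -> midpoint
  expect_equal(out$voltage_mv[3], 1.5)

  # hand evaluation: distances 1 and 2 from samples 0 and 3 mV, a = 2
  nodes2 <- tibble::tibble(x_mm = 1, y_mm = 0)
  cloud2 <- voltage_cloud(c(0, 3), c(0, 0), c(0, 3))
  out2 <- idw_interpolate(nodes2, cloud2, radius_mm = 10, power = 2)
  expect_equal(out2$voltage_mv, (1 * 0 + 0.25 * 3) / 1.25, tolerance = 1e-12)

  # bounded by the extrema of contributing samples (random configurations)
  set.seed(11)
  for (k in 1:5) {
    cl <- voltage_cloud(runif(30, 0, 10), runif(30, 0, 10), runif(30, 0, 3))
    nd <- tibble::tibble(x_mm = runif(50, 0, 10), y_mm = runif(50, 0, 10))
    o <- idw_interpolate(nd, cl, radius_mm = 4, power = 2)
    expect_true(all(o$voltage_mv >= min(cl$voltage_mv) - 1e-12))
    expect_true(all(o$voltage_mv <= max(cl$voltage_mv) + 1e-12))
  }

  # uncovered nodes are flagged and filled from the nearest sample
  far <- idw_interpolate(tibble::tibble(x_mm = 100, y_mm = 0), cloud,
                         radius_mm = 10)
  expect_false(far$covered)
  expect_equal(far$voltage_mv, 2.0)

  expect_error(idw_interpolate(nodes, cloud[0, ]), "empty")
})

test_that("fibrosis probability follows the piecewise cubic with clamping", {
  expect_equal(fibrosis_probability(-0.5), 1)
  expect_equal(fibrosis_probability(2.0), 0)
  expect_equal(fibrosis_probability(0), 0.998)
  # raw cubic slightly negative at the boundary -> clamped to 0
  raw <- (-40 * 1.74^3 + 155 * 1.74^2 - 206 * 1.74 + 99.8) / 100
  expect_lt(raw, 0)
  expect_equal(fibrosis_probability(1.74), 0)
  # non-increasing over the active range
  v <- seq(0, 1.74, by = 0.005)
  expect_true(all(diff(fibrosis_probability(v)) <= 1e-12))
  expect_true(all(fibrosis_probability(seq(-2, 5, 0.1)) >= 0))
  expect_true(all(fibrosis_probability(seq(-2, 5, 0.1)) <= 1))
  expect_error(fibrosis_probability(NA_real_), "finite")
})

test_that("stochastic fibrosis assignment is seeded and concentrates correctly", {
  expect_true(all(assign_fibrosis(rep(-1, 50), seed = 1)))
  expect_false(any(assign_fibrosis(rep(5, 50), seed = 1)))
  # binomial concentration at V = 0.5 mV
  n <- 1e5
  p <- fibrosis_probability(0.5)
  frac <- mean(assign_fibrosis(rep(0.5, n), seed = 99))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
  # reproducibility at fixed seed
  v <- runif(100, 0, 1.8)
  expect_identical(assign_fibrosis(v, seed = 7), assign_fibrosis(v, seed = 7))
  expect_false(identical(assign_fibrosis(v, seed = 7),
                         assign_fibrosis(v, seed = 8)))
})

test_that("fiber fields are unit length and geometrically consistent", {
  sheet <- make_sheet(16, 16, 500)
  u <- build_fiber_field(sheet, "uniform", angle_deg = 0)
  expect_true(all(u$fx == 1 & u$fy == 0))
  circ <- build_fiber_field(sheet, "circular")
  ctr <- c(mean(sheet$x_mm), mean(sheet$y_mm))
  dotp <- (circ$x_mm - ctr[1]) * circ$fx + (circ$y_mm - ctr[2]) * circ$fy
  expect_lt(max(abs(dotp)), 1e-9)
  for (mode in c("uniform", "circular", "parametric")) {
    f <- build_fiber_field(sheet, mode, angle_deg = 30)
    expect_lt(max(abs(sqrt(f$fx^2 + f$fy^2) - 1)), 1e-12)
  }
  expect_error(build_fiber_field(sheet, "swirl"))
})

test_that("conductivity assignment uses the four-value table", {
  fib <- c(TRUE, FALSE, TRUE)
  ct <- assign_conductivity(fib)
  expect_equal(ct$sigma_l, c(0.0546, 0.1264, 0.0546))
  expect_equal(ct$sigma_t, c(0.0068, 0.0252, 0.0068))
  expect_equal(ct$sigma_l[2] / ct$sigma_t[2], 0.1264 / 0.0252)
  allf <- assign_conductivity(rep(TRUE, 10))
  expect_false(any(allf$sigma_l == 0.1264))
  expect_error(assign_conductivity(fib, table = list(nonfibrotic_l = 1)),
               "missing")
})

test_that("region segmentation partitions non-lesion nodes into six patches", {
  sheet <- make_sheet(32, 32, 500)
  lesion <- sheet$x_mm > 7 & sheet$x_mm < 9 & sheet$y_mm > 7 & sheet$y_mm < 9
  reg <- segment_regions(sheet, lesion)
  expect_equal(sum(!is.na(reg)), sum(!lesion))
  expect_setequal(levels(reg), region_labels())
  expect_true(all(table(reg) > 0))
  # determinism
  expect_identical(reg, segment_regions(sheet, lesion))
  # degenerate geometry: all nodes in one corner cell -> empty regions
  tiny <- tibble::tibble(x_mm = c(0, 0.1), y_mm = c(0, 0.1))
  expect_error(segment_regions(tiny), "empty region")
})

test_that("the full substrate build is reproducible and internally consistent", {
  sheet <- make_sheet(24, 24, 400)
  set.seed(5)
  cloud <- voltage_cloud(runif(200, 0, 9.2), runif(200, 0, 9.2),
                         pmax(rnorm(200, 1.0, 0.5), 0))
  tpl <- pvi_lesion_template(sheet)
  s1 <- build_substrate(sheet, cloud, seed = 3, lesion_template = tpl)
  s2 <- build_substrate(sheet, cloud, seed = 3, lesion_template = tpl)
  expect_identical(s1$fibrotic, s2$fibrotic)
  expect_true(all(s1$sigma_l >= s1$sigma_t))
  expect_true(all(s1$sigma_t > 0))
  expect_true(all(is.na(s1$region[s1$removed | s1$lesion])))
  expect_true(all(!is.na(s1$region[!(s1$removed | s1$lesion)])))
  # different seed differs only stochastically: probabilities unchanged
  s3 <- build_substrate(sheet, cloud, seed = 4, lesion_template = tpl)
  expect_identical(s1$p_fibrosis, s3$p_fibrosis)
  expect_false(identical(s1$fibrotic, s3$fibrotic))
})
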