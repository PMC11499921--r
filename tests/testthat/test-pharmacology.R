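test_that("Hill blockade obeys its closed forms and limits", {
  drug <- drug_spec("test", tibble::tibble(
    channel = c("IKr", "INa"), ic50_um = c(1.0, 5.0), hill_coef = c(1, 2)))

  # theta = 0.5 exactly at D = IC50, for any Hill coefficient
  th <- hill_blockade(drug, 1.0)
  expect_equal(th$theta[th$channel == "IKr"], 0.5)
  th5 <- hill_blockade(drug, 5.0)
  expect_equal(th5$theta[th5$channel == "INa"], 0.5)

  # continuous limit at zero concentration
  th0 <- hill_blockade(drug, 0)
  expect_true(all(th0$theta == 0))

  # direct evaluation: IC50 = 1, nh = 1, D = 3.9 -> 3.9/4.9
  expect_equal(hill_blockade(drug_spec("x", tibble::tibble(
    channel = "IKr", ic50_um = 1, hill_coef = 1)), 3.9)$theta[5],
    3.9 / 4.9, tolerance = 1e-12)

  # unlisted channels stay unblocked
  expect_equal(th$theta[th$channel == "ICaL"], 0)
})

test_that("blockade is monotone in dose and IC50, and scales with D/IC50 only", {
  drug1 <- drug_spec("a", tibble::tibble(channel = "IKr", ic50_um = 2, hill_coef = 1.3))
  doses <- c(0.1, 0.5, 1, 2, 5, 20)
  th <- vapply(doses, function(d) hill_blockade(drug1, d)$theta[5], numeric(1))
  expect_true(all(diff(th) > 0))
  # decreasing in IC50 at fixed D
  th_ic <- vapply(c(0.5, 1, 2, 8), function(ic) {
    dg <- drug_spec("a", tibble::tibble(channel = "IKr", ic50_um = ic, hill_coef = 1.3))
    hill_blockade(dg, 1)$theta[5]
  }, numeric(1))
  expect_true(all(diff(th_ic) < 0))
  # ratio invariance: scaling D and IC50 together leaves theta unchanged
  dg10 <- drug_spec("a", tibble::tibble(channel = "IKr", ic50_um = 20, hill_coef = 1.3))
  expect_equal(hill_blockade(drug1, 3)$theta[5], hill_blockade(dg10, 30)$theta[5])
  # saturation
  expect_gt(hill_blockade(drug1, 1e6)$theta[5], 0.999)
})

test_that("conductance scaling composes multiplicatively and validates", {
  base <- conductance_scaling()
  expect_true(all(unclass(base) == 1))

  fib <- conductance_scaling(fibrotic = TRUE)
  expect_equal(fib[["IK1"]], 0.5)
  expect_equal(fib[["ICaL"]], 0.5)
  expect_equal(fib[["INa"]], 0.6)

  # identity blockade
  blk0 <- tibble::tibble(channel = "INa", theta = 0)
  expect_equal(unclass(apply_drug(base, blk0)), unclass(base))
  # full block
  blk1 <- tibble::tibble(channel = "INa", theta = 1)
  expect_equal(apply_drug(base, blk1)[["INa"]], 0)
  # composition on a fibrotic cell: 0.6 * (1 - 0.4) = 0.36
  blk <- tibble::tibble(channel = "INa", theta = 0.4)
  expect_equal(apply_drug(fib, blk)[["INa"]], 0.36, tolerance = 1e-12)
  # order independence of remodeling x drug
  af <- conductance_scaling(af_remodeling = TRUE)
  expect_equal(unclass(apply_drug(af, blk)),
               unclass(conductance_scaling(af_remodeling = TRUE, blockade = blk)))

  expect_error(apply_drug(base, tibble::tibble(channel = "INa", theta = 1.2)),
               "0, 1")
  expect_error(hill_blockade(amiodarone(), -1), ">= 0")
  expect_error(drug_spec("bad", tibble::tibble(channel = "INa", ic50_um = -1,
                                               hill_coef = 1)))
})

test_that("dose presets match the therapeutic-range definition", {
  dp <- dose_presets()
  expect_equal(dp$concentration_um, c(0, 1.6, 3.9, 8.0))
  expect_equal(dp$label[dp$therapeutic], c("low", "high"))
})
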