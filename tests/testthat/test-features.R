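test_that("APD of a synthetic trapezoidal AP is exact to one sample interval", {
  # upstroke at t = 10, plateau 200 ms, linear 100-ms ramp to rest:
  # APD90 = 1 (upstroke) + 200 (plateau) + 0.9 * 100 (ramp) within a sample
  tr <- trapezoid_trace(v0 = -85, v1 = 40, t_up = 10, plateau = 200,
                        ramp = 100, dt = 0.1)
  ap <- action_potential_features(tr)
  expect_true(ap$captured)
  expect_equal(ap$apd, 1 + 200 + 90, tolerance = 0.2)
  expect_equal(ap$v_rest, -85)
  expect_equal(ap$v_peak, 40)
  expect_equal(ap$dvdt_max, (40 - (-85)) / 1, tolerance = 1)
})

test_that("constant-voltage trace is masked without an exception", {
  tr <- tibble::tibble(time = seq(0, 100, 0.5), voltage = -80,
                       cai = NA_real_, nai = NA_real_, ki = NA_real_,
                       stim = 0)
  ap <- action_potential_features(tr)
  expect_false(ap$captured)
  expect_true(all(is.na(ap[c("apd", "v_rest", "v_peak", "dvdt_max")])))
})

test_that("Ca decay fit recovers the true time constant within 1%", {
  tr <- ca_transient_trace(tau_r = 2, tau_d = 80)
  cf <- calcium_features(tr)
  expect_equal(cf$ca_decay, 80, tolerance = 0.8)
  expect_gt(cf$dca, 0)
  expect_lt(cf$ca_ttp, 30)
})

test_that("flat Ca signal gives zero amplitude and masked decay", {
  tr <- tibble::tibble(time = seq(0, 100, 0.5), voltage = -80, cai = 1e-4,
                       nai = NA_real_, ki = NA_real_,
                       stim = c(30, rep(0, 200)))
  cf <- calcium_features(tr)
  expect_true(is.na(cf$ca_decay))
})

test_that("APD is monotone in the repolarization fraction (APD50 <= APD90)", {
  tr <- run_protocol("tnnp", baseline_parameters("tnnp"),
                     protocol_spec("paced", n_beats = 3,
                                   record_from_beat = 3))
  a90 <- action_potential_features(tr, 3, repol_fraction = 0.9)
  a50 <- action_potential_features(tr, 3, repol_fraction = 0.5)
  expect_true(a50$apd <= a90$apd)
})

test_that("notch precedes dome on an epicardial TNNP action potential", {
  tr <- run_protocol("tnnp", baseline_parameters("tnnp"),
                     protocol_spec("paced", n_beats = 3,
                                   record_from_beat = 3))
  ap <- action_potential_features(tr, 3)
  expect_false(ap$shape_fallback)
  expect_lt(ap$v_maxmin, ap$v_minmax)  # notch trough below dome
  expect_gt(ap$t_minmax, 0)            # dome after the upstroke
  expect_lt(ap$t_minmax, 150)
})

test_that("assemble_output_vector enforces order, completeness, and mask bookkeeping", {
  suite <- output_suite("tnnp_full")
  expect_length(suite, 32)
  feats <- setNames(as.list(seq_along(suite)), suite)
  v <- assemble_output_vector(feats, suite)
  expect_identical(names(v), suite)
  expect_equal(as.numeric(v), as.numeric(seq_along(suite)),
               ignore_attr = TRUE)
  expect_false(any(attr(v, "mask")))
  # a single masked entry propagates exactly one mask bit
  feats$bcl_alt <- NA_real_
  v2 <- assemble_output_vector(feats, suite)
  expect_equal(sum(attr(v2, "mask")), 1)
  expect_true(attr(v2, "mask")[["bcl_alt"]])
  # an unrecorded protocol is an error, never silently missing
  expect_error(assemble_output_vector(feats[-1], suite),
               "no recorded result")
})

test_that("feature extraction is pure: identical traces give identical features", {
  tr <- run_protocol("lr1", baseline_parameters("lr1"),
                     protocol_spec("paced", n_beats = 2,
                                   record_from_beat = 2))
  expect_identical(action_potential_features(tr), action_potential_features(tr))
  expect_identical(calcium_features(tr), calcium_features(tr))
})
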