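test_that("baseline parameter rosters have the documented sizes and are positive", {
  expect_equal(nrow(baseline_parameters("tnnp")), 16)
  expect_equal(nrow(baseline_parameters("lr1")), 6)
  expect_equal(nrow(baseline_parameters("bernus")), 8)
  for (id in c("tnnp", "lr1", "bernus")) {
    bp <- baseline_parameters(id)
    expect_true(all(bp$value > 0))
    expect_equal(bp$scale_factor, rep(1, nrow(bp)))
    spec <- model_spec(id)
    expect_equal(sum(spec$state_names == "V"), 1)
  }
  expect_error(baseline_parameters("hodgkin"), "unknown model_id")
})

test_that("scale_parameters round-trips factors and rejects bad input", {
  base <- baseline_parameters("tnnp")
  f <- exp(seq(-0.4, 0.4, length.out = 16))
  scaled <- scale_parameters(base, f)
  expect_equal(scaled$scale_factor, f, tolerance = 1e-12)
  expect_equal(scaled$value / scaled$baseline, f, tolerance = 1e-12)
  expect_identical(base$value, baseline_parameters("tnnp")$value)
  expect_equal(scale_parameters(base, rep(1, 16))$value, base$value)
  expect_error(scale_parameters(base, c(rep(1, 15), 0)), "K_rel2")
  expect_error(scale_parameters(base, rep(1, 15)), "expected 16")
  # named factors are matched by name
  fn <- setNames(f, base$parameter)[sample(16)]
  expect_equal(scale_parameters(base, fn)$scale_factor, f)
})

test_that("LR1 settles to a true resting state and derivatives are deterministic", {
  p <- baseline_parameters("lr1")
  tr <- run_protocol("lr1", p, protocol_spec("quiescence",
                                             pause_duration = 10000))
  settled <- attr(tr, "final_state")
  d <- evaluate_derivatives("lr1", settled, p)
  expect_lt(max(abs(d)), 1e-6)
  expect_identical(evaluate_derivatives("lr1", settled, p),
                   evaluate_derivatives("lr1", settled, p))
})

test_that("voltage derivative equals an independently summed current balance (LR1)", {
  # independent R transcription of the LR1 current balance
  lr1_currents <- function(s, g, Ko = 5.4) {
    V <- s[["V"]]; RTF <- 8314.472 * 310 / 96485.3415
    ENa <- RTF * log(140 / 18)
    INa <- g[["G_Na"]] * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - ENa)
    Esi <- 7.7 - 13.0287 * log(s[["Cai"]])
    Isi <- g[["G_si"]] * s[["d"]] * s[["f"]] * (V - Esi)
    EK <- RTF * log((Ko + 0.01833 * 140) / (145 + 0.01833 * 18))
    Xi <- if (V > -100) {
      2.837 * (exp(0.04 * (V + 77)) - 1) / ((V + 77) * exp(0.04 * (V + 35)))
    } else 1
    IK <- g[["G_K"]] * sqrt(Ko / 5.4) * s[["X"]] * Xi * (V - EK)
    EK1 <- RTF * log(Ko / 145)
    aK1 <- 1.02 / (1 + exp(0.2385 * (V - EK1 - 59.215)))
    bK1 <- (0.49124 * exp(0.08032 * (V - EK1 + 5.476)) +
            exp(0.06175 * (V - EK1 - 594.31))) /
           (1 + exp(-0.5143 * (V - EK1 + 4.753)))
    IK1 <- g[["G_K1"]] * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK1)
    IKp <- g[["G_Kp"]] / (1 + exp((7.488 - V) / 5.98)) * (V - EK1)
    Ib <- g[["G_b"]] * (V + 59.87)
    INa + Isi + IK + IK1 + IKp + Ib
  }
  p <- baseline_parameters("lr1")
  g <- setNames(p$value, p$parameter)
  state <- c(V = -40, m = 0.4, h = 0.3, j = 0.5, d = 0.2, f = 0.8,
             X = 0.1, Cai = 5e-4)
  for (stim in c(0, 20)) {
    d <- evaluate_derivatives("lr1", state, p, stim = stim)
    expect_equal(d[["V"]], -lr1_currents(state, g) + stim, tolerance = 1e-10)
  }
})

test_that("evaluate_derivatives validates its input", {
  p <- baseline_parameters("lr1")
  st <- model_initial_state("lr1")
  expect_error(evaluate_derivatives("lr1", st[-1], p), "length")
  st2 <- st; st2[["V"]] <- NaN
  expect_error(evaluate_derivatives("lr1", st2, p), "non-finite")
  expect_error(evaluate_derivatives("tnnp", model_initial_state("tnnp"), p),
               "parameter set is for model")
})

test_that("gating variables stay in [0, 1] throughout paced integration", {
  for (id in c("lr1", "tnnp", "bernus")) {
    tr <- run_protocol(id, baseline_parameters(id),
                       protocol_spec("paced", n_beats = 3,
                                     record_from_beat = 1))
    states <- attr(tr, "states")
    # fCa is excluded from the upper bound: its published steady-state
    # curve slightly exceeds 1 at diastolic Ca2+, a quirk of the source
    # model rather than an integration artifact
    gates <- setdiff(names(states), c("V", "Cai", "CaSR", "Nai", "Ki",
                                      "fCa"))
    gm <- as.matrix(states[gates])
    expect_gte(min(gm), -1e-6)
    expect_lte(max(gm), 1 + 1e-6)
    if ("fCa" %in% names(states)) {
      expect_gte(min(states$fCa), -1e-6)
      expect_lte(max(states$fCa), 1.05)
    }
  }
})

test_that("baseline TNNP pacing converges and APD is stable to step halving", {
  p <- baseline_parameters("tnnp")
  m <- cardiosens:::.resolve_model("tnnp")
  pv <- cardiosens:::.param_values(p)
  pace_apd <- function(n, acc = solver_accuracy()) {
    b <- as.data.frame(cardiosens:::.sim_pace(m, pv, m$initial_state, 1000,
                                              n, 40, 1, 5.4, acc = acc)$beats)
    b$apd
  }
  apds <- pace_apd(100)
  # beat-to-beat APD change < 0.1% at the default pre-pacing length
  expect_lt(abs(apds[100] - apds[99]) / apds[100], 0.001)
  # APD stable to < 0.1 ms when the step-controller targets are halved
  fine <- solver_accuracy(dv_step = 0.1, dt_min = 0.0025, dt_max = 0.125,
                          cai_step = 0.01)
  expect_lt(abs(tail(pace_apd(20), 1) - tail(pace_apd(20, fine), 1)), 0.1)
})

test_that("different conductance sets can produce matching APs with distinct Ca transients", {
  # the degeneracy the analysis is built around: nearly identical APs from
  # drastically different conductance combinations, distinguished by Ca2+
  n <- 30
  f <- sample_scale_factors(n, 16, 0.3, seed = 404)
  base <- baseline_parameters("tnnp")
  m <- cardiosens:::.resolve_model("tnnp")
  feats <- purrr::map_dfr(seq_len(n), function(i) {
    pv <- cardiosens:::.param_values(scale_parameters(base, f[i, ]))
    b <- as.data.frame(cardiosens:::.sim_pace(m, pv, m$initial_state, 1000,
                                              15, 40, 1, 5.4)$beats)
    tibble::tibble(apd = tail(b$apd, 1), dca = tail(b$cai_amp, 1))
  })
  ok <- which(is.finite(feats$apd) & is.finite(feats$dca))
  pairs <- expand.grid(i = ok, j = ok)
  pairs <- pairs[pairs$i < pairs$j, ]
  apd_close <- abs(feats$apd[pairs$i] - feats$apd[pairs$j]) /
    feats$apd[pairs$i] < 0.02
  dca_distinct <- abs(feats$dca[pairs$i] - feats$dca[pairs$j]) /
    pmax(feats$dca[pairs$i], feats$dca[pairs$j]) > 0.10
  expect_gt(sum(apd_close & dca_distinct), 0)
})
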