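test_that("stimulation-threshold bisection matches an analytic surrogate", {
  theta <- 17.3
  surrogate <- function(amp) amp >= theta
  thr <- find_stimulation_threshold(NULL, NULL, lower = 2, upper = 80,
                                    .elicits = surrogate)
  expect_lt(abs(thr - theta), 0.1)
  # fine-grid oracle
  grid <- seq(2, 80, by = 0.01)
  oracle <- grid[which(vapply(grid, surrogate, logical(1)))[1]]
  expect_lt(abs(thr - oracle), 0.1)
  # invariance to bracket width
  thr2 <- find_stimulation_threshold(NULL, NULL, lower = 15, upper = 20,
                                     .elicits = surrogate)
  expect_lt(abs(thr - thr2), 0.2)
})

test_that("threshold search rejects invalid brackets", {
  expect_error(
    find_stimulation_threshold(NULL, NULL, .elicits = function(a) TRUE),
    "lower bracket")
  expect_error(
    find_stimulation_threshold(NULL, NULL, .elicits = function(a) FALSE),
    "upper bound subthreshold")
})

test_that("threshold search converges on a real cell", {
  thr <- find_stimulation_threshold("lr1", baseline_parameters("lr1"))
  expect_true(is.finite(thr) && thr > 2 && thr < 80)
})

test_that("alternans scan matches brute-force restitution-map iteration", {
  # APD map APD_{n+1} = f(BCL - APD_n) with a steep exponential restitution;
  # period doubling appears once the slope at the fixed point exceeds 1
  a <- 260; b <- 160; tau <- 60
  f <- function(di) a - b * exp(-pmax(di, 1) / tau)
  iterate <- function(bcl, n = 60, apd0 = 200) {
    apds <- numeric(n)
    apd <- apd0
    for (k in seq_len(n)) {
      apd <- f(bcl - apd)
      apds[k] <- apd
    }
    apds
  }
  spec <- protocol_spec("alternans_scan", scan_max = 350, scan_min = 150,
                        scan_step = 5)
  got <- find_alternans_threshold(NULL, NULL, spec,
                                  .apd_fun = function(bcl) {
                                    tail(iterate(bcl), 8)
                                  })
  # brute-force oracle over the same grid with the same sustained criterion
  grid <- seq(350, 150, by = -5)
  oracle <- NA_real_
  for (bcl in grid) {
    tail4 <- tail(iterate(bcl), 4)
    d <- diff(tail4)
    if (all(abs(d) > 1) && all(diff(sign(d)) != 0)) { oracle <- bcl; break }
  }
  expect_false(is.na(oracle))
  expect_lte(abs(as.numeric(got) - oracle), 5)
})

test_that("constant-APD surrogate yields the no-alternans sentinel", {
  spec <- protocol_spec("alternans_scan", scan_max = 300, scan_min = 200,
                        scan_step = 5)
  got <- find_alternans_threshold(NULL, NULL, spec,
                                  .apd_fun = function(bcl) rep(210, 8))
  expect_equal(as.numeric(got), 195) # scan_min - scan_step
})

test_that("restitution maximum slope matches the closed form on an exponential surrogate", {
  a <- 300; b <- 150; tau <- 50
  apd_fun <- function(di) a - b * exp(-di / tau)
  di <- seq(5, 300, by = 5)
  slope <- restitution_max_slope(NULL, NULL, di_grid = di,
                                 .apd_fun = apd_fun)
  # centered finite differences of the closed form around the smallest DI
  analytic <- (apd_fun(di[3]) - apd_fun(di[1])) / (di[3] - di[1])
  expect_equal(as.numeric(slope), analytic, tolerance = 1e-10)
  # and that approximates the true derivative (b/tau) e^(-DI/tau) at DI_2
  expect_equal(as.numeric(slope), (b / tau) * exp(-di[2] / tau),
               tolerance = 0.02)
  # flat curve has slope zero
  expect_equal(as.numeric(
    restitution_max_slope(NULL, NULL, di_grid = di,
                          .apd_fun = function(di) 250)), 0)
  # fewer than 3 valid points is masked
  expect_true(is.na(max_restitution_slope(c(10, 20), c(200, 210))))
})

test_that("paced protocol without stimulus never fires", {
  spec <- protocol_spec("paced", n_beats = 2, stim_amplitude = 0,
                        record_from_beat = 1)
  tr <- run_protocol("lr1", baseline_parameters("lr1"), spec)
  expect_lt(max(tr$voltage), -40)
})

test_that("quiescence protocol returns ionic concentrations at its end", {
  spec <- protocol_spec("quiescence", pause_duration = 20000)
  tr <- run_protocol("tnnp", baseline_parameters("tnnp"), spec)
  fs <- attr(tr, "final_state")
  expect_true(all(is.finite(fs[c("Cai", "Nai", "Ki")])))
  expect_gt(fs[["Ki"]], 100)
  expect_lt(fs[["Cai"]], 1e-3)
  expect_equal(max(tr$time), 20000)
  expect_true(all(tr$stim == 0))
})

test_that("protocols are deterministic: identical inputs give identical traces", {
  spec <- protocol_spec("paced", n_beats = 3, record_from_beat = 2)
  p <- scale_parameters(baseline_parameters("lr1"), rep(1.1, 6))
  tr1 <- run_protocol("lr1", p, spec)
  tr2 <- run_protocol("lr1", p, spec)
  expect_identical(tr1$voltage, tr2$voltage)
  expect_identical(attr(tr1, "beats"), attr(tr2, "beats"))
})

test_that("pause protocol inserts the pause and delivers one post-pause beat", {
  spec <- protocol_spec("pause", n_beats = 3, pause_duration = 2000,
                        record_from_beat = 3)
  tr <- run_protocol("lr1", baseline_parameters("lr1"), spec)
  beats <- attr(tr, "beats")
  expect_equal(nrow(beats), 4)
  expect_equal(beats$t_stim[4] - beats$t_stim[3], 1000 + 2000)
})

test_that("alternans scan on a cell records an audit trail", {
  spec <- protocol_spec("alternans_scan", scan_max = 240, scan_min = 200,
                        scan_step = 20)
  res <- find_alternans_threshold("lr1", baseline_parameters("lr1"), spec,
                                  n_scan_beats = 6)
  audit <- attr(res, "scan")
  expect_true(nrow(audit) >= 1)
  expect_true(all(c("bcl", "captured", "alternans") %in% names(audit)))
})
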