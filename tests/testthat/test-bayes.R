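test_that("best-trial selection is an exact argmin with low-index ties", {
  Y <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  # residual norms 2, 1, 3 -> row 2
  Yh <- Y - matrix(c(1, 1, 1, 0, 1, sqrt(2)), 3, 2, byrow = TRUE)
  expect_equal(select_best_trial(Y, Yh), 2)
  expect_equal(select_best_trial(Y, Y), 1) # all-zero residuals tie to row 1
  # exhaustive oracle on random matrices
  set.seed(10)
  A <- matrix(rnorm(50), 10, 5); B <- matrix(rnorm(50), 10, 5)
  expect_equal(select_best_trial(A, B),
               which.min(sapply(1:10, function(i) sum((A[i, ] - B[i, ])^2))))
  expect_error(select_best_trial(matrix(0, 0, 2), matrix(0, 0, 2)), "empty")
})

test_that("conditional_subset returns the marginal under an infinite window", {
  set.seed(3)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("g1", "g2")))
  Y <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "out"))
  cs <- conditional_subset(X, Y, "out", -Inf, Inf)
  expect_equal(cs$indices, 1:200)
  for (h in cs$histograms) expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_error(conditional_subset(X, Y, "out", 100, 200), "no trials")
  expect_error(conditional_subset(X, Y, "out", 2, 1), "lower < upper")
})

test_that("conditioning on an independent output leaves the distribution unchanged", {
  n <- 10000
  set.seed(21)
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("g1", "g2")))
  # output depends only on g2; conditioning must not move g1
  Y <- matrix(2 * X[, 2] + rnorm(n, sd = 0.3), n, 1,
              dimnames = list(NULL, "out"))
  cs <- conditional_subset(X, Y, "out", -0.5, 0.5)
  ks <- suppressWarnings(stats::ks.test(X[cs$indices, 1], X[, 1]))
  expect_gt(ks$p.value, 0.01)
  # while g2 narrows substantially
  expect_lt(sd(X[cs$indices, 2]), 0.5 * sd(X[, 2]))
})

test_that("sequential analysis keeps subsets nested and histograms normalized", {
  fx <- synthetic_linear_fixture(2000, 3, 4, noise_sd = 0.3, seed = 17)
  fit <- fit_regression(fx$X, fx$Y)
  ba <- sequential_constraint_analysis(fx$X, fx$Y, fx$X %*% fit$B,
                                       constraint_outputs = c("y1", "y2",
                                                              "y3"))
  sizes <- vapply(ba$subsets, length, integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (s in seq_along(ba$subsets)[-1]) {
    expect_true(all(ba$subsets[[s]] %in% ba$subsets[[s - 1]]))
  }
  sums <- ba$histograms |>
    dplyr::group_by(stage, parameter) |>
    dplyr::summarise(s = sum(prob), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # probabilities are proper
  expect_true(all(ba$histograms$prob >= 0 & ba$histograms$prob <= 1))
  # single constraint reproduces conditional_subset
  cs <- conditional_subset(fx$X, fx$Y, "y1",
                           ba$constraints$lower[1], ba$constraints$upper[1])
  expect_equal(ba$subsets[[2]], cs$indices)
})

test_that("a duplicated constraint output shrinks the subset no further", {
  fx <- synthetic_linear_fixture(1000, 2, 2, noise_sd = 0.2, seed = 29)
  Y <- cbind(fx$Y, y1dup = fx$Y[, 1])
  fit <- fit_regression(fx$X, Y)
  ba <- sequential_constraint_analysis(fx$X, Y, fx$X %*% fit$B,
                                       constraint_outputs = c("y1", "y1dup"),
                                       window_mode = "relative", rel = 0.3)
  expect_identical(ba$subsets[[3]], ba$subsets[[2]])
})

test_that("empirical conditional probability obeys P(A|B) P(B) = P(A and B)", {
  n <- 5000
  set.seed(40)
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g"))
  Y <- matrix(X[, 1] + rnorm(n, sd = 0.8), n, 1,
              dimnames = list(NULL, "out"))
  cs <- conditional_subset(X, Y, "out", 0, 1)
  in_B <- Y[, 1] >= 0 & Y[, 1] <= 1
  in_A <- X[, 1] > 0.5
  p_A_given_B <- mean(X[cs$indices, 1] > 0.5)
  expect_equal(p_A_given_B * mean(in_B), mean(in_A & in_B),
               tolerance = 1e-12)
})

test_that("conditioning narrows parameters on a cardiac population", {
  # small LR1 population: constraining APD and upstroke-linked outputs
  # must not widen any parameter distribution
  cfg <- cheap_config()
  ds <- build_population_dataset("lr1", n = 40, sigma = 0.25, seed = 31,
                                 config = cfg)
  cc <- which(rowSums(is.na(ds$Y)) == 0)
  fwd <- fit_population_regression(list(X = ds$X[cc, ], Y = ds$Y[cc, ]),
                                   "forward", drop_constant = TRUE)
  Yc <- ds$Y[cc, colnames(fwd$B)]
  Yhat <- destandardize(fwd$standardizer_y,
                        apply_standardizer(fwd$standardizer_x,
                                           ds$X[cc, ]) %*% fwd$B)
  ba <- sequential_constraint_analysis(
    ds$X[cc, ], Yc, Yhat, constraint_outputs = c("apd", "v_rest", "v_peak"),
    window_mode = "percentile", pct = 0.5)
  sdt <- tidyr::pivot_wider(ba$spread, names_from = stage, values_from = sd,
                            id_cols = parameter)
  expect_true(all(sdt[["+v_peak"]] <= sdt[["marginal"]] + 1e-9))
})
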