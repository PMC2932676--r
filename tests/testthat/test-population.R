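test_that("scale-factor sampling is reproducible and respects sigma", {
  f0 <- sample_scale_factors(5, 4, 0, seed = 9)
  expect_true(all(f0 == 1))
  f1 <- sample_scale_factors(20, 4, 0.3, seed = 9)
  f2 <- sample_scale_factors(20, 4, 0.3, seed = 9)
  expect_identical(f1, f2)
  # per-trial substreams: the first rows do not depend on n
  f3 <- sample_scale_factors(5, 4, 0.3, seed = 9)
  expect_identical(f1[1:5, ], f3)
  expect_error(sample_scale_factors(5, 4, -0.1, seed = 1), "sigma")
})

test_that("mean log factor obeys the CLT bound at large n", {
  n <- 10000; p <- 3; sigma <- 0.3
  f <- sample_scale_factors(n, p, sigma, seed = 123)
  expect_lt(abs(mean(log(f))), 3 * sigma / sqrt(n * p))
})

test_that("a sigma = 0 population of one reproduces the baseline outputs", {
  cfg <- cheap_config()
  ds <- build_population_dataset("lr1", n = 1, sigma = 0, seed = 1,
                                 config = cfg)
  direct <- compute_trial_outputs("lr1", baseline_parameters("lr1"),
                                  config = cfg)
  expect_equal(ds$Y[1, ], as.numeric(direct), ignore_attr = TRUE)
  expect_true(all(ds$X[1, ] == 0))
})

test_that("population dataset has consistent shapes, column order, and metadata", {
  cfg <- cheap_config()
  ds <- build_population_dataset("lr1", n = 4, sigma = 0.2, seed = 5,
                                 config = cfg)
  expect_equal(dim(ds$X), c(4, 6))
  expect_equal(dim(ds$Y), c(4, length(output_suite("lr1_core"))))
  expect_identical(colnames(ds$X), model_spec("lr1")$parameter_names)
  expect_identical(colnames(ds$Y), output_suite("lr1_core"))
  expect_true(all(is.finite(ds$X)))
  g <- glance(ds)
  expect_equal(g$n, 4)
  td <- tidy(ds)
  expect_equal(nrow(td), 4 * (6 + ncol(ds$Y)))
  # bitwise reproducibility of X from the seed
  ds2 <- build_population_dataset("lr1", n = 4, sigma = 0.2, seed = 5,
                                  config = cfg)
  expect_identical(ds$X, ds2$X)
})

test_that("an injected trial failure is logged and the dataset still returned", {
  cfg <- cheap_config()
  k_fail <- 2L
  real <- compute_trial_outputs
  calls <- 0L
  local_mocked_bindings(
    compute_trial_outputs = function(...) {
      calls <<- calls + 1L
      if (calls == k_fail) {
        stop(cardiosens:::trial_failure("injected solver failure"))
      }
      real(...)
    },
    .package = "cardiosens"
  )
  ds <- build_population_dataset("lr1", n = 3, sigma = 0.2, seed = 77,
                                 config = cfg, max_failure_rate = 0.9)
  expect_true(k_fail %in% ds$failure_log$trial)
  expect_true(all(is.na(ds$Y[k_fail, ])))
  expect_false(anyNA(ds$X))
})

test_that("noiseless synthetic fixture satisfies its exact algebra", {
  fx <- synthetic_linear_fixture(120, 4, 6, noise_sd = 0, seed = 11)
  expect_equal(fx$Y, fx$X %*% fx$B_true, tolerance = 1e-12)
  # condition number of B_true is controlled
  sv <- svd(fx$B_true)$d
  expect_equal(max(sv) / min(sv), 5, tolerance = 1e-8)
  # reproducible
  fx2 <- synthetic_linear_fixture(120, 4, 6, noise_sd = 0, seed = 11)
  expect_identical(fx$Y, fx2$Y)
})
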