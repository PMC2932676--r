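test_that("standardization satisfies its algebraic contracts", {
  set.seed(31)
  M <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  s <- standardize(M)
  expect_lt(max(abs(colMeans(s$z))), 1e-10)
  expect_lt(max(abs(apply(s$z, 2, sd) - 1)), 1e-10)
  # round trip
  expect_equal(destandardize(s$standardizer, s$z), M, tolerance = 1e-10)
  # already-standardized input passes through
  s2 <- standardize(s$z)
  expect_equal(s2$z, s$z, tolerance = 1e-10)
  # apply uses stored moments, never refits
  M2 <- M + 100
  expect_equal(apply_standardizer(s$standardizer, M2),
               s$z + 100 / matrix(s$standardizer$sd, 20, 3, byrow = TRUE),
               tolerance = 1e-10)
  # constant column errors with its name
  M3 <- cbind(M, k = 7)
  expect_error(standardize(M3), "k")
})

test_that("column_r_squared matches brute-force evaluation", {
  set.seed(5)
  Yt <- matrix(rnorm(40), 10, 4)
  expect_equal(unname(column_r_squared(Yt, Yt)), rep(1, 4))
  Ym <- matrix(colMeans(Yt), 10, 4, byrow = TRUE)
  expect_equal(unname(column_r_squared(Yt, Ym)), rep(0, 4))
  Yp <- Yt + matrix(rnorm(40, sd = 0.5), 10, 4)
  brute <- vapply(1:4, function(j) {
    1 - sum((Yt[, j] - Yp[, j])^2) / sum((Yt[, j] - mean(Yt[, j]))^2)
  }, numeric(1))
  expect_equal(unname(column_r_squared(Yt, Yp)), brute, tolerance = 1e-12)
  expect_error(column_r_squared(cbind(Yt, 1), cbind(Yp, 1)),
               "zero-variance")
})

test_that("full-rank regression solves the identity problem and recovers B_true", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  fit <- fit_regression(X, X)
  expect_equal(fit$B, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fit$r_squared), rep(1, 4), tolerance = 1e-12)
  fx <- synthetic_linear_fixture(150, 5, 9, noise_sd = 0, seed = 8)
  fit2 <- fit_regression(fx$X, fx$Y)
  expect_lt(max(abs(fit2$B - fx$B_true)), 1e-8)
  expect_error(fit_regression(fx$X, fx$Y, n_components = 0), "n_components")
  expect_error(fit_regression(fx$X, fx$Y, n_components = 6), "n_components")
})

test_that("reduced-component NIPALS agrees with an established PLS implementation", {
  set.seed(77)
  n <- 60; p <- 6; m <- 4; k <- 3
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", 1:p))))
  B0 <- matrix(rnorm(p * m), p, m)
  Y <- scale(X %*% B0 + matrix(rnorm(n * m, sd = 0.5), n, m))
  fit <- fit_regression(X, Y, n_components = k)
  ref <- mixOmics::pls(X, Y, ncomp = k, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, X)$predict[, , k]
  pred_own <- X %*% fit$B
  expect_equal(unname(pred_own), unname(pred_ref), tolerance = 1e-6)
})

test_that("square-system inversion is exact and guards against singularity", {
  expect_inv <- function(B) {
    fitlike <- structure(list(B = B, direction = "forward",
                              n_components = nrow(B), n = 100),
                         class = "sens_regression")
    invert_square_regression(fitlike)
  }
  # identity inverts to identity
  I5 <- diag(5); dimnames(I5) <- list(paste0("p", 1:5), paste0("y", 1:5))
  inv <- expect_inv(I5)
  expect_equal(unname(inv$B), diag(5))
  # well-conditioned random 16 x 16: B %*% Binv = I to 1e-10
  set.seed(12)
  B16 <- crossprod(matrix(rnorm(256), 16)) + diag(16)
  dimnames(B16) <- list(paste0("p", 1:16), paste0("y", 1:16))
  inv16 <- expect_inv(B16)
  expect_lt(max(abs(B16 %*% inv16$B - diag(16))), 1e-10)
  # exactly singular (duplicated column) raises
  Bd <- B16; Bd[, 2] <- Bd[, 1]
  expect_error(expect_inv(Bd), "not linearly independent")
})

test_that("reverse regression inverts a noiseless square fixture", {
  fx <- synthetic_linear_fixture(200, 5, 5, noise_sd = 0, seed = 3,
                                 condition_number = 4)
  rev <- reverse_regress(fx$Y, fx$X)
  expect_lt(max(abs(rev$B - solve(fx$B_true))), 1e-6)
  expect_true(all(rev$r_squared > 0.999))
})

test_that("greedy elimination matches exhaustive single-removal search at every step", {
  fx <- synthetic_linear_fixture(100, 3, 6, noise_sd = 0.3, seed = 15)
  Xz <- standardize(fx$X)$z
  Yz <- standardize(fx$Y)$z
  eh <- eliminate_outputs(Xz, Yz, target_m = 3)
  # exhaustive oracle replaying the greedy policy step by step
  keep <- colnames(Yz)
  for (s in seq_len(nrow(eh$steps))) {
    scores <- vapply(seq_along(keep), function(k) {
      mean(reverse_regress(Yz[, keep[-k], drop = FALSE], Xz)$r_squared)
    }, numeric(1))
    best <- keep[which.max(scores)]
    expect_identical(eh$steps$removed[s], best)
    expect_equal(eh$steps$score_after[s], max(scores), tolerance = 1e-12)
    keep <- setdiff(keep, best)
  }
  expect_identical(sort(c(eh$retained, eh$rejected)), sort(colnames(Yz)))
  expect_length(eh$retained, 3)
})

test_that("an exact duplicate output column is eliminated first at zero cost", {
  fx <- synthetic_linear_fixture(80, 3, 4, noise_sd = 0.2, seed = 6)
  Y <- cbind(fx$Y, dup = fx$Y[, 1])
  Xz <- standardize(fx$X)$z
  Yz <- standardize(Y)$z
  full <- mean(reverse_regress(Yz, Xz)$r_squared)
  eh <- eliminate_outputs(Xz, Yz, target_m = 4)
  expect_true(eh$steps$removed[1] %in% c("y1", "dup"))
  expect_equal(eh$steps$score_after[1], full, tolerance = 1e-8)
})

test_that("pure-noise outputs are eliminated before informative ones", {
  fx <- synthetic_linear_fixture(150, 3, 5, noise_sd = 0.1, seed = 21)
  set.seed(99)
  Y <- cbind(fx$Y, noise1 = rnorm(150), noise2 = rnorm(150))
  Xz <- standardize(fx$X)$z
  Yz <- standardize(Y)$z
  eh <- eliminate_outputs(Xz, Yz, target_m = 3)
  expect_true(all(c("noise1", "noise2") %in% eh$rejected))
})

test_that("reverse R2 is invariant to affine rescaling of an output column", {
  fx <- synthetic_linear_fixture(100, 3, 5, noise_sd = 0.2, seed = 33)
  r2a <- fit_population_regression(list(X = fx$X, Y = fx$Y),
                                   "reverse")$r_squared
  Y2 <- fx$Y
  Y2[, 2] <- 100 + 42 * Y2[, 2]
  r2b <- fit_population_regression(list(X = fx$X, Y = Y2),
                                   "reverse")$r_squared
  expect_equal(r2a, r2b, tolerance = 1e-10)
})

test_that("predict_parameters recovers training rows and maps the mean to unity", {
  fx <- synthetic_linear_fixture(150, 4, 4, noise_sd = 0, seed = 44,
                                 condition_number = 3)
  # treat fixture X as log factors: build a population-like object
  ds <- list(X = fx$X, Y = fx$Y)
  rev <- fit_population_regression(ds, "reverse")
  pred <- predict_parameters(rev, fx$Y[7, ])
  expect_equal(as.numeric(pred), unname(exp(fx$X[7, ])), tolerance = 1e-6)
  # centering identity: population-mean outputs map back to the population
  # mean of the log factors (exactly 1 when the log factors are centered)
  pred_mean <- predict_parameters(rev, colMeans(fx$Y))
  expect_equal(as.numeric(pred_mean), unname(exp(colMeans(fx$X))),
               tolerance = 1e-8)
  Xc <- scale(fx$X, scale = FALSE)
  rev_c <- fit_population_regression(list(X = Xc, Y = fx$Y), "reverse")
  expect_equal(as.numeric(predict_parameters(rev_c, colMeans(fx$Y))),
               rep(1, 4), tolerance = 1e-8)
  # masked entries within the model's output set are rejected
  y_bad <- fx$Y[7, ]; y_bad[2] <- NA
  expect_error(predict_parameters(rev, y_bad), "masked")
})

test_that("forward/inverse round trip is an algebraic identity on fitted rows", {
  fx <- synthetic_linear_fixture(120, 6, 10, noise_sd = 0.05, seed = 55)
  ds <- list(X = fx$X, Y = fx$Y)
  fwd <- fit_population_regression(ds, "forward")
  Xz <- apply_standardizer(fwd$standardizer_x, fx$X)
  eh <- eliminate_outputs(Xz, apply_standardizer(fwd$standardizer_y, fx$Y),
                          target_m = 6)
  inv <- invert_square_regression(fwd, outputs = eh$retained)
  inv$standardizer_x <- fwd$standardizer_x
  inv$standardizer_y <- fwd$standardizer_y
  # rows of Y_hat = X B map back to X exactly through the inverse
  Yz_hat <- Xz %*% fwd$B
  Y_hat <- destandardize(fwd$standardizer_y, Yz_hat)
  pred <- predict_parameters(inv, Y_hat[3, ])
  expect_equal(as.numeric(pred), unname(exp(fx$X[3, ])), tolerance = 1e-8)
})
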