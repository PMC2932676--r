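# Population generation: randomized parameter scale factors, per-trial
# protocol batteries, and the synthetic linear fixture used to oracle-test
# the regression machinery without any ODE solving.

#' Sample random parameter scale factors
#'
#' Draws i.i.d. lognormal multiplicative scale factors with median 1;
#' `sigma` is the standard deviation of the natural-log factor.  Each trial
#' uses its own deterministic substream (`seed` XOR trial index) so that any
#' trial can be regenerated in isolation.
#'
#' @param n Number of trials.
#' @param p Number of parameters.
#' @param sigma Standard deviation of log factors (>= 0).
#' @param seed Integer seed.
#' @param parameter_names Optional column names.
#' @return An `n x p` matrix of positive factors.
#' @export
#' @examples
#' f <- sample_scale_factors(5, 3, 0.3, seed = 1)
sample_scale_factors <- function(n, p, sigma, seed,
                                 parameter_names = NULL) {
  stopifnot(n >= 1, p >= 1)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    sub <- bitwXor(as.integer(seed), i)
    out[i, ] <- withr::with_seed(sub, exp(rnorm(p, mean = 0, sd = sigma)))
  }
  if (!is.null(parameter_names)) colnames(out) <- parameter_names
  out
}

#' Build a population dataset
#'
#' Randomizes the model's parameters `n` times, runs the full protocol
#' battery of the output suite for every variant, and collects the input
#' matrix `X` (natural-log scale factors, `n x p`) and output matrix `Y`
#' (native units, `n x m`).  Trials whose battery fails in part have the
#' affected outputs masked (NA); trials that fail outright are logged.  If
#' more than `max_failure_rate` of trials fail outright the build aborts,
#' since that signals an unstable configuration.
#'
#' @inheritParams compute_trial_outputs
#' @param n Number of trials (300 for the standard analysis).
#' @param sigma Standard deviation of the natural-log scale factors.
#' @param seed Integer seed.
#' @param max_failure_rate Abort threshold for outright trial failures.
#' @param progress Print a line every 25 trials.
#' @return An object of class `population_dataset`: list with elements `X`,
#'   `Y`, `model_id`, `suite`, `parameter_names`, `output_names`, `sigma`,
#'   `seed`, `failure_log` (tibble), `config`.
#' @export
build_population_dataset <- function(model_id, n = 300, sigma = 0.1823,
                                     seed = 1, suite = NULL,
                                     config = suite_config(),
                                     max_failure_rate = 0.2,
                                     progress = FALSE) {
  m <- .resolve_model(model_id)
  if (is.null(suite)) suite <- .default_suite(model_id)
  out_names <- output_suite(suite)
  base <- baseline_parameters(model_id)
  p <- nrow(base)
  factors <- sample_scale_factors(n, p, sigma, seed,
                                  parameter_names = base$parameter)
  X <- log(factors)
  Y <- matrix(NA_real_, n, length(out_names),
              dimnames = list(NULL, out_names))
  failures <- list()
  for (i in seq_len(n)) {
    params <- scale_parameters(base, factors[i, ])
    res <- tryCatch(
      compute_trial_outputs(model_id, params, suite = suite, config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(trial = i, step = "trial",
                       reason = conditionMessage(res))
      next
    }
    Y[i, ] <- as.numeric(res)
    fl <- attr(res, "failures")
    if (length(fl) > 0) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(trial = i, step = names(fl), reason = unname(fl))
    }
    if (progress && i %% 25 == 0) {
      message("trial ", i, "/", n)
    }
  }
  failure_log <- if (length(failures) > 0) dplyr::bind_rows(failures)
                 else tibble::tibble(trial = integer(), step = character(),
                                     reason = character())
  # outright failures: more than half of the outputs masked
  hard <- sum(rowSums(is.na(Y)) > length(out_names) / 2)
  if (hard > max_failure_rate * n) {
    stop(hard, " of ", n, " trials failed (", length(out_names),
         " outputs); configuration looks unstable. Failure summary:\n",
         paste(utils::capture.output(print(failure_log)), collapse = "\n"),
         call. = FALSE)
  }
  structure(
    list(X = X, Y = Y, model_id = tolower(model_id), suite = suite,
         parameter_names = base$parameter, output_names = out_names,
         sigma = sigma, seed = seed, failure_log = failure_log,
         config = config),
    class = "population_dataset"
  )
}

#' @export
print.population_dataset <- function(x, ...) {
  cat("<population_dataset> ", x$model_id, " (suite ", x$suite, ")\n",
      sep = "")
  cat("  X: ", nrow(x$X), " x ", ncol(x$X), " log scale factors (sigma = ",
      x$sigma, ", seed = ", x$seed, ")\n", sep = "")
  cat("  Y: ", nrow(x$Y), " x ", ncol(x$Y), " outputs; ",
      sum(is.na(x$Y)), " masked entries; ",
      length(unique(x$failure_log$trial)), " trials with failures\n",
      sep = "")
  invisible(x)
}

#' @describeIn build_population_dataset Long tibble of the population: one
#'   row per trial x variable with `role` = "parameter" (log scale factor)
#'   or "output".
#' @param x A `population_dataset`.
#' @param ... Unused.
#' @export
tidy.population_dataset <- function(x, ...) {
  xp <- tibble::as_tibble(x$X) |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    tidyr::pivot_longer(-"trial", names_to = "variable",
                        values_to = "value") |>
    dplyr::mutate(role = "parameter")
  yp <- tibble::as_tibble(x$Y) |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    tidyr::pivot_longer(-"trial", names_to = "variable",
                        values_to = "value") |>
    dplyr::mutate(role = "output")
  dplyr::bind_rows(xp, yp)
}

#' @describeIn build_population_dataset One-row summary (sizes, masking,
#'   failure counts).
#' @export
glance.population_dataset <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, suite = x$suite, n = nrow(x$X), p = ncol(x$X),
    m = ncol(x$Y), sigma = x$sigma, seed = x$seed,
    n_masked = sum(is.na(x$Y)),
    n_failed_trials = length(unique(x$failure_log$trial))
  )
}

#' Synthetic linear fixture
#'
#' Generates a dataset with the exact statistical structure the regression
#' stage assumes: standard-normal inputs, a linear map with controlled
#' condition number, and additive Gaussian noise.  Used to oracle-test every
#' statistical operation without any ODE solving.
#'
#' @param n,p,m Dimensions (trials, inputs, outputs).
#' @param noise_sd Standard deviation of the additive output noise.
#' @param seed Integer seed.
#' @param condition_number Ratio of largest to smallest singular value of
#'   the true coefficient matrix.
#' @return List with `X` (`n x p`), `Y` (`n x m`), `B_true` (`p x m`).
#' @export
synthetic_linear_fixture <- function(n, p, m, noise_sd = 0, seed = 1,
                                     condition_number = 5) {
  stopifnot(n >= 2, p >= 1, m >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    # controlled-condition-number coefficient matrix via its SVD
    k <- min(p, m)
    U <- qr.Q(qr(matrix(rnorm(p * p), p, p)))[, seq_len(k), drop = FALSE]
    V <- qr.Q(qr(matrix(rnorm(m * m), m, m)))[, seq_len(k), drop = FALSE]
    s <- seq(condition_number, 1, length.out = k)
    B_true <- U %*% diag(s, k) %*% t(V)
    Y <- X %*% B_true + matrix(rnorm(n * m, sd = noise_sd), n, m)
  })
  colnames(X) <- paste0("x", seq_len(p))
  colnames(Y) <- paste0("y", seq_len(m))
  dimnames(B_true) <- list(colnames(X), colnames(Y))
  list(X = X, Y = Y, B_true = B_true)
}
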