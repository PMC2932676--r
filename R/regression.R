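# Regression machinery: Z-scoring, forward (parameters -> outputs) and
# reverse (outputs -> parameters) multivariable regression, inversion of the
# square regression matrix on a selected output set, greedy backward output
# elimination, and condition reconstruction.
#
# At full rank (the default, n_components = p) the partial-least-squares fit
# coincides with ordinary least squares on standardized data and is computed
# directly by OLS; reduced-component fits use NIPALS PLS2.

#' Z-score standardization
#'
#' `standardize()` mean-centers each column and scales it by its standard
#' deviation, returning the Z-matrix and the fitted `standardizer`.
#' `apply_standardizer()` applies stored moments to new data (never refits);
#' `destandardize()` inverts the transformation.
#'
#' Missing entries are ignored when fitting the moments and propagate
#' through the transform.
#'
#' @param M Numeric matrix (or data frame) with named columns.
#' @return For `standardize()`: list with `z` and `standardizer`.
#' @export
standardize <- function(M) {
  M <- as.matrix(M)
  mu <- colMeans(M, na.rm = TRUE)
  sdev <- apply(M, 2, sd, na.rm = TRUE)
  bad <- which(!is.finite(sdev) | sdev <= 0)
  if (length(bad) > 0) {
    nm <- if (!is.null(colnames(M))) colnames(M)[bad] else as.character(bad)
    stop("constant (zero-variance) column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  std <- structure(list(mean = mu, sd = sdev, names = colnames(M)),
                   class = "standardizer")
  list(z = apply_standardizer(std, M), standardizer = std)
}

#' @rdname standardize
#' @param std A `standardizer`.
#' @export
apply_standardizer <- function(std, M) {
  stopifnot(inherits(std, "standardizer"))
  M <- as.matrix(M)
  if (ncol(M) != length(std$mean)) {
    stop("column count does not match the fitted standardizer", call. = FALSE)
  }
  sweep(sweep(M, 2, std$mean, "-"), 2, std$sd, "/")
}

#' @rdname standardize
#' @param Z A Z-scored matrix.
#' @export
destandardize <- function(std, Z) {
  stopifnot(inherits(std, "standardizer"))
  Z <- as.matrix(Z)
  sweep(sweep(Z, 2, std$sd, "*"), 2, std$mean, "+")
}

#' Per-column coefficient of determination
#'
#' `1 - SSE/SST` per column, with SST taken about the column mean of
#' `Y_true`.
#'
#' @param Y_true,Y_pred Matrices of identical shape.
#' @return Named numeric vector of per-column R-squared values.
#' @export
column_r_squared <- function(Y_true, Y_pred) {
  Y_true <- as.matrix(Y_true)
  Y_pred <- as.matrix(Y_pred)
  stopifnot(identical(dim(Y_true), dim(Y_pred)))
  mu <- colMeans(Y_true)
  sst <- colSums(sweep(Y_true, 2, mu, "-")^2)
  if (any(sst <= 0)) {
    nm <- colnames(Y_true)[sst <= 0]
    stop("zero-variance column(s) in Y_true: ",
         paste(if (is.null(nm)) which(sst <= 0) else nm, collapse = ", "),
         call. = FALSE)
  }
  sse <- colSums((Y_true - Y_pred)^2)
  setNames(1 - sse / sst, colnames(Y_true))
}

# SVD least squares (minimum-norm under exact collinearity, as in the
# full-rank PLS limit); relative singular-value cutoff 1e-10
.lstsq <- function(X, Y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * crossprod(sv$u[, keep, drop = FALSE], Y))
}

# NIPALS PLS2 on centered (Z-scored) matrices; returns the coefficient
# matrix mapping X to Y using `ncomp` latent components.
.pls_nipals <- function(X, Y, ncomp, max_iter = 500, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  Tm <- matrix(0, n, ncomp)
  Xr <- X; Yr <- Y
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(apply(Yr, 2, var)), drop = FALSE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xr, u); w <- w / sqrt(sum(w^2))
      tt <- Xr %*% w
      qv <- crossprod(Yr, tt); qv <- qv / sqrt(sum(qv^2))
      u <- Yr %*% qv
      if (sqrt(sum((tt - t_old)^2)) < tol) break
      t_old <- tt
    }
    pv <- crossprod(Xr, tt) / sum(tt^2)
    qload <- crossprod(Yr, tt) / sum(tt^2)
    Xr <- Xr - tt %*% t(pv)
    Yr <- Yr - tt %*% t(qload)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qload; Tm[, a] <- tt
  }
  # B = W (P'W)^-1 Q'
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a multivariable regression between Z-scored matrices
#'
#' Fits the coefficient matrix `B` such that `X_z %*% B` approximates `Y_z`.
#' With `n_components` equal to the number of predictors (the default) the
#' partial-least-squares solution coincides with ordinary least squares and
#' is computed directly; with fewer components NIPALS PLS2 is used.
#'
#' @param X_z,Y_z Z-scored predictor and response matrices.
#' @param n_components Number of latent components (1..ncol(X_z)).
#' @param direction Label stored on the model (`"forward"` or `"reverse"`).
#' @return An object of class `sens_regression` with elements `B`
#'   (`ncol(X_z) x ncol(Y_z)`), `r_squared` (per response column),
#'   `n_components`, `direction`.
#' @export
fit_regression <- function(X_z, Y_z, n_components = ncol(X_z),
                           direction = "forward") {
  X_z <- as.matrix(X_z); Y_z <- as.matrix(Y_z)
  stopifnot(nrow(X_z) == nrow(Y_z))
  if (anyNA(X_z)) stop("X_z contains missing values", call. = FALSE)
  if (anyNA(Y_z)) stop("Y_z contains missing values", call. = FALSE)
  p <- ncol(X_z)
  if (n_components < 1 || n_components > p) {
    stop("n_components must be in 1..", p, call. = FALSE)
  }
  B <- if (n_components == p) {
    .lstsq(X_z, Y_z)
  } else {
    .pls_nipals(X_z, Y_z, n_components)
  }
  dimnames(B) <- list(colnames(X_z), colnames(Y_z))
  r2 <- column_r_squared(Y_z, X_z %*% B)
  structure(
    list(B = B, r_squared = r2, n_components = n_components,
         direction = direction, n = nrow(X_z)),
    class = "sens_regression"
  )
}

#' Reverse regression: predict parameters from outputs
#'
#' Derives the matrix `B'` such that `Y_z %*% B'` approximates `X_z`; this
#' is [fit_regression()] with the roles of the matrices swapped.
#'
#' @inheritParams fit_regression
#' @param n_components Number of latent components (1..ncol(Y_z)).
#' @return A `sens_regression` with `direction = "reverse"`; `B` is
#'   `ncol(Y_z) x ncol(X_z)`.
#' @export
reverse_regress <- function(Y_z, X_z, n_components = ncol(Y_z)) {
  fit_regression(Y_z, X_z, n_components = n_components,
                 direction = "reverse")
}

#' @export
print.sens_regression <- function(x, ...) {
  cat("<sens_regression> ", x$direction, ": ", nrow(x$B), " -> ", ncol(x$B),
      " (", x$n_components, " components, n = ", x$n, ")\n", sep = "")
  cat("  per-column R2: ", paste(sprintf("%.3f", x$r_squared),
                                 collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_regression Coefficients as a long tibble (`predictor`,
#'   `response`, `estimate`).
#' @param x A `sens_regression`.
#' @param ... Unused.
#' @export
tidy.sens_regression <- function(x, ...) {
  B <- x$B
  tibble::tibble(
    predictor = rep(rownames(B) %||% paste0("p", seq_len(nrow(B))),
                    times = ncol(B)),
    response = rep(colnames(B) %||% paste0("r", seq_len(ncol(B))),
                   each = nrow(B)),
    estimate = as.numeric(B)
  )
}

#' @describeIn fit_regression One-row fit summary.
#' @export
glance.sens_regression <- function(x, ...) {
  tibble::tibble(
    direction = x$direction, n = x$n, n_predictors = nrow(x$B),
    n_responses = ncol(x$B), n_components = x$n_components,
    mean_r_squared = mean(x$r_squared), min_r_squared = min(x$r_squared)
  )
}

#' Invert the square regression matrix on a retained output set
#'
#' Restricts the forward coefficient matrix `B` (`p x m`) to `p` retained
#' output columns and inverts it, yielding the matrix that predicts the
#' Z-scored parameters from the Z-scored retained outputs
#' (`X_z = Y_z[, retained] %*% B_inv`).
#'
#' @param model A forward `sens_regression`.
#' @param outputs Retained output names or indices (length = number of
#'   parameters).  Defaults to all outputs (requires a square `B`).
#' @param min_rcond Minimal reciprocal condition number; below this the
#'   outputs are declared linearly dependent and an error is raised.
#' @return A `sens_regression` with `direction = "inverse"`; element `B` is
#'   the `p x p` inverse matrix (rows = retained outputs, columns =
#'   parameters), and `outputs` names the retained set.
#' @export
invert_square_regression <- function(model, outputs = NULL,
                                     min_rcond = 1e-10) {
  stopifnot(inherits(model, "sens_regression"))
  if (model$direction != "forward") {
    stop("expected a forward regression model", call. = FALSE)
  }
  B <- model$B
  if (is.null(outputs)) outputs <- colnames(B) %||% seq_len(ncol(B))
  Bsq <- B[, outputs, drop = FALSE]
  if (nrow(Bsq) != ncol(Bsq)) {
    stop("retained output set must have exactly ", nrow(Bsq),
         " outputs to invert; got ", ncol(Bsq), call. = FALSE)
  }
  sv <- svd(Bsq, nu = 0, nv = 0)$d
  rc <- min(sv) / max(sv)
  if (!is.finite(rc) || rc < min_rcond) {
    stop("outputs not linearly independent (reciprocal condition number ",
         format(rc, digits = 3), ")", call. = FALSE)
  }
  Binv <- solve(Bsq)
  dimnames(Binv) <- list(colnames(Bsq), rownames(Bsq))
  structure(
    list(B = Binv, r_squared = NULL, n_components = model$n_components,
         direction = "inverse", n = model$n, outputs = colnames(Bsq),
         rcond = rc),
    class = "sens_regression"
  )
}

#' Greedy backward elimination of outputs
#'
#' Repeatedly removes the output whose removal causes the smallest change in
#' the reverse-regression prediction of the parameters (quantified by the
#' mean per-parameter R-squared), until `target_m` outputs remain.  Each
#' greedy step evaluates every remaining single removal.  Ties are broken by
#' removing the lowest-index output.
#'
#' @param X_z,Y_z Z-scored input and output matrices.
#' @param target_m Number of outputs to retain (defaults to `ncol(X_z)`).
#' @param criterion Aggregate of the per-parameter R-squared used as the
#'   score: `"mean"` (default) or `"min"`.
#' @return An object of class `elimination_history`: list with `steps` (a
#'   tibble: `step`, `removed`, `score_after`), `retained`, `rejected`.
#' @export
eliminate_outputs <- function(X_z, Y_z, target_m = ncol(X_z),
                              criterion = c("mean", "min")) {
  criterion <- match.arg(criterion)
  agg <- if (criterion == "mean") mean else min
  X_z <- as.matrix(X_z); Y_z <- as.matrix(Y_z)
  m <- ncol(Y_z)
  if (target_m > m) stop("target_m exceeds the number of outputs",
                         call. = FALSE)
  if (target_m < ncol(X_z)) {
    stop("target_m below the number of parameters leaves the system ",
         "under-determined for inversion", call. = FALSE)
  }
  nm <- colnames(Y_z) %||% paste0("y", seq_len(m))
  colnames(Y_z) <- nm
  keep <- seq_len(m)
  steps <- list()
  while (length(keep) > target_m) {
    scores <- vapply(seq_along(keep), function(k) {
      sub <- keep[-k]
      fit <- fit_regression(Y_z[, sub, drop = FALSE], X_z,
                            direction = "reverse")
      agg(fit$r_squared)
    }, numeric(1))
    # remove the output whose removal leaves the highest score
    # (= smallest drop); which.max takes the lowest index on ties
    k_best <- which.max(scores)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1L, removed = nm[keep[k_best]],
      score_after = scores[k_best]
    )
    keep <- keep[-k_best]
  }
  structure(
    list(steps = dplyr::bind_rows(steps), retained = nm[keep],
         rejected = setdiff(nm, nm[keep]), criterion = criterion),
    class = "elimination_history"
  )
}

#' @export
print.elimination_history <- function(x, ...) {
  cat("<elimination_history> removed ", nrow(x$steps), " outputs (",
      x$criterion, " R2 criterion)\n", sep = "")
  cat("  retained: ", paste(x$retained, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn eliminate_outputs Steps as a tibble.
#' @param x An `elimination_history`.
#' @param ... Unused.
#' @export
tidy.elimination_history <- function(x, ...) x$steps

#' Fit a regression model on a population dataset
#'
#' High-level wrapper: Z-scores `X` and `Y` of a [build_population_dataset()]
#' result (or any list with `X` and `Y` matrices), mean-imputes masked
#' output entries in Z-space (a masked output contributes no signal), fits
#' the requested direction, and stores the standardizers for later
#' prediction on new data.
#'
#' @param dataset A `population_dataset` or list with `X` and `Y`.
#' @param direction `"forward"` (parameters to outputs) or `"reverse"`.
#' @param n_components Latent components; default full rank (= OLS).
#' @param outputs Optional subset of output columns to use.
#' @param drop_constant Drop zero-variance output columns (with a warning)
#'   instead of erroring.
#' @return A `sens_regression` with `standardizer_x` and `standardizer_y`
#'   attached.
#' @export
fit_population_regression <- function(dataset,
                                      direction = c("forward", "reverse"),
                                      n_components = NULL, outputs = NULL,
                                      drop_constant = FALSE) {
  direction <- match.arg(direction)
  X <- as.matrix(dataset$X)
  Y <- as.matrix(dataset$Y)
  if (!is.null(outputs)) Y <- Y[, outputs, drop = FALSE]
  if (drop_constant) {
    sdev <- apply(Y, 2, sd, na.rm = TRUE)
    const <- !is.finite(sdev) | sdev <= 0
    if (any(const)) {
      warning("dropping constant output column(s): ",
              paste(colnames(Y)[const], collapse = ", "), call. = FALSE)
      Y <- Y[, !const, drop = FALSE]
    }
  }
  sx <- standardize(X)
  sy <- standardize(Y)
  Yz <- sy$z
  Yz[is.na(Yz)] <- 0 # masked outputs carry no signal
  if (anyNA(sx$z)) stop("X contains missing values", call. = FALSE)
  fit <- if (direction == "forward") {
    fit_regression(sx$z, Yz,
                   n_components = n_components %||% ncol(X))
  } else {
    reverse_regress(Yz, sx$z, n_components = n_components %||% ncol(Yz))
  }
  fit$standardizer_x <- sx$standardizer
  fit$standardizer_y <- sy$standardizer
  fit
}

#' Predict parameter scale factors from outputs
#'
#' Standardizes a new output vector (or matrix of rows) with the model's
#' stored output standardizer, maps it through the reverse or inverse
#' coefficient matrix, de-standardizes the predicted log scale factors and
#' exponentiates them to multiplicative factors.
#'
#' @param model A `sens_regression` of direction `"reverse"` or `"inverse"`
#'   carrying standardizers (see [fit_population_regression()] and
#'   [invert_square_regression()]).
#' @param y_new Named numeric vector, or matrix/data frame with one row per
#'   cell; columns must cover the model's outputs.
#' @return Tibble with one row per input row and one column per parameter:
#'   predicted multiplicative scale factors.
#' @export
predict_parameters <- function(model, y_new) {
  stopifnot(inherits(model, "sens_regression"))
  if (!model$direction %in% c("reverse", "inverse")) {
    stop("predict_parameters needs a reverse or inverse model", call. = FALSE)
  }
  if (is.null(model$standardizer_x) || is.null(model$standardizer_y)) {
    stop("model carries no standardizers; fit it with ",
         "fit_population_regression()", call. = FALSE)
  }
  if (is.null(dim(y_new))) y_new <- matrix(y_new, 1,
                                           dimnames = list(NULL, names(y_new)))
  y_new <- as.matrix(y_new)
  need <- model$standardizer_y$names
  if (!all(need %in% colnames(y_new))) {
    stop("y_new lacks output(s): ",
         paste(setdiff(need, colnames(y_new)), collapse = ", "),
         call. = FALSE)
  }
  y_new <- y_new[, need, drop = FALSE]
  if (anyNA(y_new)) {
    stop("y_new contains masked entries within the model's output set",
         call. = FALSE)
  }
  Yz <- apply_standardizer(model$standardizer_y, y_new)
  Yz_used <- if (model$direction == "inverse") {
    Yz[, model$outputs, drop = FALSE]
  } else {
    Yz
  }
  Xz <- Yz_used %*% model$B
  lf <- destandardize(model$standardizer_x, Xz)
  out <- tibble::as_tibble(exp(lf))
  names(out) <- model$standardizer_x$names %||% names(out)
  out
}

# outputs of the condition battery: paced_core features at each Ko level
.condition_outputs <- function(model_id, params, config, Ko_levels) {
  m <- .resolve_model(model_id)
  pvals <- .param_values(params)
  core <- output_suite("paced_core")
  res <- list()
  stim <- if (config$stim_mode == "fixed") {
    config$stim_amp
  } else {
    config$stim_rel * find_stimulation_threshold(
      model_id, params, spec = protocol_spec("threshold_search",
                                             acc = config$acc),
      lower = config$thr_lower, upper = config$thr_upper)
  }
  for (ko in Ko_levels) {
    pb <- .sim_pace(m, pvals, m$initial_state, config$bcl, config$n_prepace,
                    stim, 1, ko, dt_out = config$dt_out,
                    record_from_beat = config$n_prepace, acc = config$acc)
    b <- tibble::as_tibble(as.data.frame(pb$beats))
    last <- b[nrow(b), ]
    tr <- .trace_tibble(m, pb$trace)
    attr(tr, "beats") <- last
    ap <- action_potential_features(tr, 1)
    cf <- calcium_features(tr, 1)
    v <- c(last$apd, last$v_rest,
           ifelse(last$captured > 0, last$v_peak, NA_real_),
           ifelse(last$captured > 0, last$dvdt_max, NA_real_),
           last$cai_amp, ap$v_maxmin, ap$v_minmax, ap$t_minmax,
           last$cai_ttp, cf$ca_decay, last$apd - b$apd[1])
    names(v) <- paste0(core, "_ko", gsub("[.]", "p", format(ko)))
    res[[length(res) + 1]] <- v
  }
  unlist(res, use.names = TRUE)
}

#' Reconstruct condition-induced parameter changes
#'
#' Emulates the heart-failure reconstruction workflow: a population is built
#' in which only the `condition_params` are randomized, the paced output
#' battery is evaluated under normal, low, and high extracellular potassium
#' for every variant, a reverse regression is fitted, and the fold-changes
#' of a "condition" cell (the baseline model with `fold_changes` applied)
#' are predicted from its outputs.
#'
#' @inheritParams build_population_dataset
#' @param condition_params Names of the altered parameters (subset of the
#'   model's parameters).
#' @param fold_changes Multiplicative changes applied to those parameters in
#'   the condition cell (named or in `condition_params` order).
#' @param Ko_levels Extracellular potassium levels (mM) of the battery.
#' @return Tibble: `parameter`, `true_fold`, `predicted_fold`, plus the
#'   fitted reverse model as attribute `"model"`.
#' @export
reconstruct_condition <- function(model_id, condition_params, fold_changes,
                                  n = 150, sigma = 0.1823, seed = 1,
                                  config = suite_config(),
                                  Ko_levels = c(5.4, 3, 8)) {
  base <- baseline_parameters(model_id)
  bad <- setdiff(condition_params, base$parameter)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  k <- length(condition_params)
  if (length(fold_changes) != k) {
    stop("fold_changes must match condition_params", call. = FALSE)
  }
  if (!is.null(names(fold_changes))) {
    fold_changes <- fold_changes[condition_params]
  }
  idx <- match(condition_params, base$parameter)

  sub_factors <- sample_scale_factors(n, k, sigma, seed,
                                      parameter_names = condition_params)
  X <- log(sub_factors)
  Y <- NULL
  for (i in seq_len(n)) {
    f <- rep(1, nrow(base))
    f[idx] <- sub_factors[i, ]
    yi <- tryCatch(
      .condition_outputs(model_id, scale_parameters(base, f), config,
                         Ko_levels),
      error = function(e) NULL
    )
    if (is.null(Y) && !is.null(yi)) {
      Y <- matrix(NA_real_, n, length(yi), dimnames = list(NULL, names(yi)))
    }
    if (!is.null(yi)) Y[i, ] <- yi
  }
  if (is.null(Y)) stop("every population trial failed", call. = FALSE)

  f <- rep(1, nrow(base))
  f[idx] <- fold_changes
  y_cond <- .condition_outputs(model_id, scale_parameters(base, f), config,
                               Ko_levels)
  # only outputs measurable on the condition cell can carry information
  usable <- names(y_cond)[is.finite(y_cond)]
  model <- fit_population_regression(list(X = X, Y = Y[, usable,
                                                       drop = FALSE]),
                                     "reverse", drop_constant = TRUE)
  pred <- predict_parameters(model, y_cond[model$standardizer_y$names])

  out <- tibble::tibble(
    parameter = condition_params,
    true_fold = as.numeric(fold_changes),
    predicted_fold = as.numeric(pred[1, condition_params])
  )
  attr(out, "model") <- model
  out
}
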