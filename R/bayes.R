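# Bayesian sequential conditioning: estimate how strongly windows on model
# outputs constrain model parameters, by conditioning the empirical joint
# distribution of a population on one output window after another and
# watching the per-parameter distributions narrow.

#' Select the best-predicted trial
#'
#' Returns the row whose prediction residual (sum of squared differences
#' between `Y` and `Y_hat`) is minimal; ties go to the lowest index.
#' Conditioning windows are centered on this trial so that the constrained
#' region is guaranteed to be populated.
#'
#' @param Y,Y_hat Matrices of identical shape (typically Z-scored outputs
#'   and their regression predictions).
#' @return Integer row index (1-based).
#' @export
select_best_trial <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  stopifnot(identical(dim(Y), dim(Y_hat)))
  if (nrow(Y) == 0) stop("empty matrices", call. = FALSE)
  rss <- rowSums((Y - Y_hat)^2, na.rm = TRUE)
  which.min(rss)
}

# shared histogram edges per parameter: `bins` equal bins over the marginal
.histogram_edges <- function(X, bins) {
  apply(as.matrix(X), 2, function(v) {
    r <- range(v, finite = TRUE)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }, simplify = FALSE)
}

# normalized histogram (sums to 1) of v over fixed edges
.norm_hist <- function(v, edges) {
  counts <- graphics::hist(pmin(pmax(v, edges[1]), edges[length(edges)]),
                           breaks = edges, plot = FALSE)$counts
  counts / sum(counts)
}

#' Condition a population on one output window
#'
#' Returns the trials whose output lies inside the window, together with the
#' per-parameter histograms of the surviving subset (normalized to the
#' subset size, over bin edges shared with the marginal distribution).
#'
#' @param X Matrix of parameter values (or log scale factors), one column
#'   per parameter.
#' @param Y Matrix of outputs, one column per output.
#' @param output Output name (or index) to constrain.
#' @param lower,upper Window bounds in the units of `Y` (`lower < upper`).
#' @param bins Number of histogram bins.
#' @param edges Optional pre-computed bin edges (as produced internally from
#'   the marginal) so histograms stay comparable across conditioning stages.
#' @return List with `indices`, `histograms` (named list of per-parameter
#'   probability vectors), `edges`.
#' @export
conditional_subset <- function(X, Y, output, lower, upper, bins = 20,
                               edges = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  yv <- Y[, output]
  idx <- which(!is.na(yv) & yv >= lower & yv <= upper)
  if (length(idx) == 0) {
    stop("no trials satisfy constraint on ", output, call. = FALSE)
  }
  if (is.null(edges)) edges <- .histogram_edges(X, bins)
  hists <- lapply(seq_len(ncol(X)), function(jp) {
    .norm_hist(X[idx, jp], edges[[jp]])
  })
  names(hists) <- colnames(X)
  list(indices = idx, histograms = hists, edges = edges)
}

# window for one constraint centered on the best trial's value
.constraint_window <- function(yv, center, mode, pct, rel) {
  if (mode == "relative") {
    half <- rel * abs(center)
    if (half == 0) half <- rel
    c(center - half, center + half)
  } else {
    ys <- sort(yv[!is.na(yv)])
    n <- length(ys)
    k <- max(1L, round(pct * n))
    r_center <- which.min(abs(ys - center))
    lo <- max(1L, r_center - floor((k - 1) / 2))
    hi <- min(n, lo + k - 1L)
    lo <- max(1L, hi - k + 1L)
    c(ys[lo], ys[hi])
  }
}

#' Sequential Bayesian constraint analysis
#'
#' Applies output windows one after another, intersecting the surviving
#' trials, and records how the per-parameter distributions narrow.  Windows
#' are centered on the best-predicted trial (see [select_best_trial()]):
#' `window_mode = "percentile"` keeps the `pct` fraction of samples ranked
#' around that trial's value; `window_mode = "relative"` keeps trials within
#' `rel` of the value.
#'
#' @inheritParams conditional_subset
#' @param Y_hat Predicted outputs (same shape as `Y`) used to pick the best
#'   trial; alternatively pass `best_trial` directly.
#' @param constraint_outputs Ordered output names to constrain on.
#' @param window_mode `"percentile"` (default) or `"relative"`.
#' @param pct Fraction of samples in a percentile window.
#' @param rel Half-width of a relative window (fraction of the center).
#' @param best_trial Optional explicit center trial index.
#' @return Object of class `bayes_analysis`: list with `best_trial`,
#'   `constraints` (tibble: `output`, `lower`, `upper`), `subsets` (list of
#'   index vectors, marginal first), `histograms` (tibble: `stage`,
#'   `parameter`, `bin_mid`, `prob`), `spread` (tibble: `stage`,
#'   `parameter`, `sd`, `n`), `edges`.
#' @export
sequential_constraint_analysis <- function(X, Y, Y_hat = NULL,
                                           constraint_outputs,
                                           window_mode = c("percentile",
                                                           "relative"),
                                           pct = 0.10, rel = 0.05,
                                           bins = 20, best_trial = NULL) {
  window_mode <- match.arg(window_mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(constraint_outputs) == 0) {
    stop("constraint_outputs must be non-empty", call. = FALSE)
  }
  if (is.null(best_trial)) {
    if (is.null(Y_hat)) {
      stop("provide Y_hat or best_trial", call. = FALSE)
    }
    best_trial <- select_best_trial(Y, Y_hat)
  }
  pnames <- colnames(X) %||% paste0("p", seq_len(ncol(X)))
  colnames(X) <- pnames
  edges <- .histogram_edges(X, bins)

  live <- seq_len(nrow(X))
  subsets <- list(live)
  hist_rows <- list()
  spread_rows <- list()
  record_stage <- function(stage_label, idx) {
    for (jp in seq_along(pnames)) {
      e <- edges[[jp]]
      pr <- .norm_hist(X[idx, jp], e)
      hist_rows[[length(hist_rows) + 1]] <<- tibble::tibble(
        stage = stage_label, parameter = pnames[jp],
        bin_mid = (head(e, -1) + tail(e, -1)) / 2, prob = pr
      )
      spread_rows[[length(spread_rows) + 1]] <<- tibble::tibble(
        stage = stage_label, parameter = pnames[jp],
        sd = if (length(idx) > 1) sd(X[idx, jp]) else 0,
        n = length(idx)
      )
    }
  }
  record_stage("marginal", live)

  cons <- list()
  for (s in seq_along(constraint_outputs)) {
    out_nm <- constraint_outputs[s]
    yv <- Y[, out_nm]
    wnd <- .constraint_window(yv, Y[best_trial, out_nm], window_mode, pct,
                              rel)
    keep <- live[!is.na(yv[live]) & yv[live] >= wnd[1] & yv[live] <= wnd[2]]
    if (length(keep) == 0) {
      stop("no trials survive constraint ", s, " on ", out_nm, call. = FALSE)
    }
    live <- keep
    subsets[[length(subsets) + 1]] <- live
    cons[[s]] <- tibble::tibble(output = out_nm, lower = wnd[1],
                                upper = wnd[2])
    record_stage(paste0("+", out_nm), live)
  }

  structure(
    list(best_trial = best_trial,
         constraints = dplyr::bind_rows(cons),
         subsets = subsets,
         histograms = dplyr::bind_rows(hist_rows),
         spread = dplyr::bind_rows(spread_rows),
         edges = edges,
         stage_labels = c("marginal",
                          paste0("+", constraint_outputs))),
    class = "bayes_analysis"
  )
}

#' @export
print.bayes_analysis <- function(x, ...) {
  cat("<bayes_analysis> ", nrow(x$constraints), " constraints, best trial ",
      x$best_trial, "\n", sep = "")
  sizes <- vapply(x$subsets, length, integer(1))
  cat("  surviving trials: ", paste(sizes, collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn sequential_constraint_analysis Histograms as a long tibble.
#' @param x A `bayes_analysis`.
#' @param ... Unused.
#' @export
tidy.bayes_analysis <- function(x, ...) x$histograms

#' @describeIn sequential_constraint_analysis Per-stage subset sizes and the
#'   mean parameter-distribution standard deviation.
#' @export
glance.bayes_analysis <- function(x, ...) {
  x$spread |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = dplyr::first(.data$n),
                     mean_sd = mean(.data$sd), .groups = "drop")
}
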