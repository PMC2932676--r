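# End-to-end orchestration: run configuration, the full analysis pipeline,
# and artifact serialization.

#' Run configuration
#'
#' Bundles everything needed to reproduce a full analysis run: the model,
#' population sizing, protocol settings, regression settings, and the
#' Bayesian-conditioning settings.  Fully serializable to YAML/JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param model_id Model to analyse.
#' @param n Population size.
#' @param sigma Log-scale-factor spread.
#' @param seed Integer seed.
#' @param suite Output suite name (default per model).
#' @param protocol Named list of [suite_config()] overrides.
#' @param n_components PLS components (`NULL` = full rank, i.e. OLS).
#' @param target_m Retained output count for inversion (`NULL` = number of
#'   parameters).
#' @param bayes_constraints Output names for sequential conditioning.
#' @param bayes_window_mode `"percentile"` or `"relative"`.
#' @param bayes_pct,bayes_rel Window sizes.
#' @return A list of class `run_config`.
#' @export
run_config <- function(model_id = "tnnp", n = 300, sigma = 0.1823, seed = 1,
                       suite = NULL, protocol = list(),
                       n_components = NULL, target_m = NULL,
                       bayes_constraints = c("apd", "v_rest", "v_peak"),
                       bayes_window_mode = "percentile", bayes_pct = 0.10,
                       bayes_rel = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("[.]json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- run_config()
  for (nm in names(x)) defaults[[nm]] <- x[[nm]]
  # empty lists deserialize as list(); normalize NULL-able fields
  for (nm in c("suite", "n_components", "target_m")) {
    if (length(defaults[[nm]]) == 0) defaults[[nm]] <- NULL
  }
  defaults$bayes_constraints <- unlist(defaults$bayes_constraints)
  class(defaults) <- "run_config"
  defaults
}

.write_matrix_csv <- function(M, path, row_label = "trial") {
  df <- tibble::as_tibble(M)
  df <- dplyr::bind_cols(tibble::tibble(!!row_label := seq_len(nrow(M))), df)
  readr::write_csv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow: simulate the population, assemble the
#' X/Y dataset, fit the forward regression, greedily select the retained
#' output set, invert the square regression matrix, fit the reverse
#' regression, run the sequential Bayesian conditioning, and write every
#' artifact to `out_dir`:
#' `X.csv`, `Y.csv`, `B.json`, `Binv.json`, `r2_forward.csv`,
#' `r2_reverse.csv`, `elimination_history.json`, `bayes.json`,
#' `failures.csv`, `config.json`, `meta.json`, `run.log`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param overwrite Allow writing into a directory holding artifacts from a
#'   different configuration.
#' @param progress Log per-stage progress to the console as well.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `forward`, `reverse`, `elimination`, `inverse`, `bayes`).
#' @export
run_full_pipeline <- function(config, out_dir, overwrite = FALSE,
                              progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  meta_path <- file.path(out_dir, "meta.json")
  if (file.exists(meta_path)) {
    old <- jsonlite::read_json(meta_path)
    if (!identical(old$config_hash, cfg_hash) && !overwrite) {
      stop("out_dir holds artifacts from a different configuration (hash ",
           old$config_hash, "); use overwrite = TRUE", call. = FALSE)
    }
  }
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
    if (progress) message(line)
  }
  stage <- "init"
  result <- list()
  tryCatch({
    stage <- "simulate"
    logmsg("simulate: model ", config$model_id, ", n = ", config$n,
           ", sigma = ", config$sigma, ", seed = ", config$seed)
    sc <- do.call(suite_config, config$protocol)
    ds <- build_population_dataset(config$model_id, n = config$n,
                                   sigma = config$sigma, seed = config$seed,
                                   suite = config$suite, config = sc)
    result$dataset <- ds
    .write_matrix_csv(ds$X, file.path(out_dir, "X.csv"))
    .write_matrix_csv(ds$Y, file.path(out_dir, "Y.csv"))
    readr::write_csv(ds$failure_log, file.path(out_dir, "failures.csv"))

    stage <- "forward"
    logmsg("forward regression")
    fwd <- fit_population_regression(ds, "forward",
                                     n_components = config$n_components,
                                     drop_constant = TRUE)
    result$forward <- fwd
    jsonlite::write_json(
      list(config_hash = cfg_hash, direction = "forward",
           parameters = rownames(fwd$B), outputs = colnames(fwd$B),
           B = fwd$B),
      file.path(out_dir, "B.json"), digits = NA, auto_unbox = TRUE,
      matrix = "rowmajor")
    readr::write_csv(
      tibble::tibble(output = names(fwd$r_squared),
                     r_squared = fwd$r_squared),
      file.path(out_dir, "r2_forward.csv"))

    stage <- "eliminate"
    target_m <- config$target_m %||% ncol(ds$X)
    logmsg("greedy output elimination to ", target_m)
    Xz <- standardize(ds$X)$z
    sy <- standardize(ds$Y[, colnames(fwd$B), drop = FALSE])
    Yz <- sy$z
    Yz[is.na(Yz)] <- 0
    elim <- eliminate_outputs(Xz, Yz, target_m = target_m)
    result$elimination <- elim
    jsonlite::write_json(
      list(config_hash = cfg_hash, steps = elim$steps,
           retained = elim$retained, rejected = elim$rejected),
      file.path(out_dir, "elimination_history.json"), digits = NA,
      auto_unbox = TRUE)

    stage <- "invert"
    logmsg("invert square regression on ", length(elim$retained),
           " retained outputs")
    inv <- invert_square_regression(fwd, outputs = elim$retained)
    inv$standardizer_x <- fwd$standardizer_x
    inv$standardizer_y <- fwd$standardizer_y
    result$inverse <- inv
    jsonlite::write_json(
      list(config_hash = cfg_hash, direction = "inverse",
           outputs = rownames(inv$B), parameters = colnames(inv$B),
           rcond = inv$rcond, Binv = inv$B),
      file.path(out_dir, "Binv.json"), digits = NA, auto_unbox = TRUE,
      matrix = "rowmajor")

    stage <- "reverse"
    logmsg("reverse regression (all outputs)")
    rev <- fit_population_regression(ds, "reverse",
                                     n_components = config$n_components,
                                     drop_constant = TRUE)
    result$reverse <- rev
    readr::write_csv(
      tibble::tibble(parameter = names(rev$r_squared),
                     r_squared = rev$r_squared),
      file.path(out_dir, "r2_reverse.csv"))

    stage <- "bayes"
    logmsg("sequential Bayesian conditioning on ",
           paste(config$bayes_constraints, collapse = ", "))
    Yz_hat <- Xz %*% fwd$B
    keep_rows <- which(rowSums(is.na(ds$Y)) == 0)
    ba <- sequential_constraint_analysis(
      ds$X[keep_rows, , drop = FALSE],
      ds$Y[keep_rows, , drop = FALSE],
      Y_hat = destandardize(sy$standardizer,
                            Yz_hat)[keep_rows, , drop = FALSE],
      constraint_outputs = config$bayes_constraints,
      window_mode = config$bayes_window_mode,
      pct = config$bayes_pct, rel = config$bayes_rel)
    result$bayes <- ba
    jsonlite::write_json(
      list(config_hash = cfg_hash, best_trial = ba$best_trial,
           constraints = ba$constraints,
           subset_sizes = vapply(ba$subsets, length, integer(1)),
           spread = ba$spread, histograms = ba$histograms),
      file.path(out_dir, "bayes.json"), digits = NA, auto_unbox = TRUE)

    stage <- "finish"
    write_run_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(config_hash = cfg_hash, package = "cardiosens",
           version = as.character(utils::packageVersion("cardiosens")),
           finished = format(Sys.time())),
      meta_path, auto_unbox = TRUE)
    logmsg("done")
  }, error = function(e) {
    logmsg("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
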