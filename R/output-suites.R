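# Output suites: which physiological outputs are computed for each model and
# how the protocol battery that produces them is orchestrated for one trial.

.SUITES <- list(
  # full 32-output suite for the TNNP model, in canonical order
  tnnp_full = c(
    "apd", "v_rest", "v_peak", "dvdt_max", "dca", "v_maxmin", "v_minmax",
    "t_minmax", "bcl_alt", "i_thresh", "max_slope", "ca_ttp", "ca_decay",
    "apd_pause", "dca_pause", "v_maxmin_pause", "v_minmax_pause",
    "t_minmax_pause", "apd_diff", "dca_diff", "apd_hypo", "apd_hyper",
    "v_maxmin_hypo", "v_minmax_hypo", "t_minmax_hypo", "v_maxmin_hyper",
    "v_minmax_hyper", "t_minmax_hyper", "cai_quiet", "nai_quiet", "ki_quiet",
    "freq_adapt"
  ),
  # reduced suite for LR1 (no detailed Ca handling; Nai/Ki fixed)
  lr1_core = c(
    "apd", "v_rest", "v_peak", "dvdt_max", "v_plateau", "dca", "i_thresh",
    "max_slope", "ca_ttp", "apd_pause", "dca_pause", "apd_diff", "dca_diff",
    "apd_hypo", "apd_hyper", "v_rest_hypo", "v_rest_hyper", "cai_quiet",
    "freq_adapt"
  ),
  # voltage-only suite for the Bernus-type model (fixed concentrations)
  bernus_core = c(
    "apd", "v_rest", "v_peak", "dvdt_max", "v_maxmin", "v_minmax", "t_minmax",
    "i_thresh", "apd_pause", "apd_diff", "apd_hypo", "apd_hyper",
    "v_rest_hypo", "v_rest_hyper", "freq_adapt"
  ),
  # cheap paced-only suite evaluated at the three Ko levels; used by
  # condition reconstruction (33-output style batteries are built from it)
  paced_core = c(
    "apd", "v_rest", "v_peak", "dvdt_max", "dca", "v_maxmin", "v_minmax",
    "t_minmax", "ca_ttp", "ca_decay", "apd_diff"
  )
)

#' Output suites
#'
#' An output suite is the ordered set of physiological outputs computed for
#' each trial of a population.  `output_suite()` returns the output names of
#' a named suite; the default suite is `tnnp_full` (the 32-output battery)
#' for the TNNP model, `lr1_core` for LR1, and `bernus_core` for the
#' Bernus-type model.
#'
#' @param suite Suite name, or `NULL` to list available suites.
#' @return Character vector of output names (or a list of all suites).
#' @export
output_suite <- function(suite = NULL) {
  if (is.null(suite)) return(.SUITES)
  if (!suite %in% names(.SUITES)) {
    stop("unknown output suite ", deparse(suite), "; available: ",
         paste(names(.SUITES), collapse = ", "), call. = FALSE)
  }
  .SUITES[[suite]]
}

.default_suite <- function(model_id) {
  switch(tolower(model_id),
         tnnp = "tnnp_full", lr1 = "lr1_core", bernus = "bernus_core",
         stop("no default suite for model ", model_id, call. = FALSE))
}

#' Protocol-battery configuration for output suites
#'
#' Bundles the protocol parameters used when computing a trial's output
#' vector: pre-pacing length, cycle lengths, pause and quiescence durations,
#' alternans-scan grid, restitution grid, and stimulus sizing (the stimulus
#' amplitude is `stim_rel` times the trial's own measured threshold).
#'
#' @param bcl Basic cycle length for pacing (ms).
#' @param n_prepace Pre-pacing beats before steady-state features are read.
#' @param n_ko Beats paced after switching extracellular potassium.
#' @param n_freq Beats per rate used for the frequency-adaptation ratio.
#' @param bcl_slow,bcl_fast Cycle lengths of the frequency-adaptation pair (ms).
#' @param pause Pause duration (ms).
#' @param quiescence Quiescence duration (ms).
#' @param Ko_hypo,Ko_hyper Altered extracellular potassium levels (mM).
#' @param scan_max,scan_min,scan_step Alternans-scan cycle-length grid (ms).
#' @param n_scan_beats Beats paced per scanned cycle length.
#' @param di_grid Diastolic intervals of the S1S2 restitution protocol (ms).
#' @param n_s1 S1 beats before each premature stimulus.
#' @param stim_mode `"fixed"`: all feature protocols use the strong fixed
#'   stimulus `stim_amp`, decoupling every output from the threshold
#'   measurement and guaranteeing capture at altered extracellular potassium
#'   (hyperpolarized cells need more charge than a threshold measured at
#'   normal potassium provides).  `"relative"`: stimulate at `stim_rel`
#'   times the trial's measured threshold.
#' @param stim_amp Fixed stimulus amplitude in pA/pF.
#' @param stim_rel Stimulus amplitude relative to the measured threshold
#'   (`stim_mode = "relative"`).
#' @param thr_lower,thr_upper Threshold-search bracket (pA/pF).
#' @param measure_tail Extra unstimulated observation window appended to
#'   each protocol's measured beat (ms), so that action potentials longer
#'   than the cycle length still yield an APD.
#' @param dt_out Trace sampling interval for recorded beats (ms).
#' @param acc Integrator accuracy settings, see [solver_accuracy()].
#' @return A list of class `suite_config`.
#' @export
suite_config <- function(bcl = 1000, n_prepace = 100, n_ko = 20, n_freq = 30,
                         bcl_slow = 2000, bcl_fast = 500, pause = 5000,
                         quiescence = 60000, Ko_hypo = 3, Ko_hyper = 8,
                         scan_max = 350, scan_min = 150, scan_step = 5,
                         n_scan_beats = 8,
                         di_grid = c(5, 10, 20, 40, 60, 80, 120, 160, 200,
                                     300),
                         n_s1 = 10, stim_mode = c("fixed", "relative"),
                         stim_amp = 52, stim_rel = 1.5, thr_lower = 2,
                         thr_upper = 80, measure_tail = 1000,
                         dt_out = .DEFAULT_DT_OUT,
                         acc = solver_accuracy()) {
  stim_mode <- match.arg(stim_mode)
  structure(as.list(environment()), class = "suite_config")
}

# shape-parameter helper: rename action_potential_features columns
.shape_named <- function(ap, suffix = "") {
  nm <- function(x) paste0(x, suffix)
  out <- list()
  out[[nm("v_maxmin")]] <- ap$v_maxmin
  out[[nm("v_minmax")]] <- ap$v_minmax
  out[[nm("t_minmax")]] <- ap$t_minmax
  out
}

# run one measured beat in an extended observation window (bcl + tail);
# returns cm_run result plus a trace tibble for shape/Ca features
.measured_beat <- function(m, pvals, state, bcl, stim, Ko, config) {
  res <- .sim_run(m, pvals, state, bcl + config$measure_tail,
                  stim_amp = stim, stim_start = 0, stim_dur = 1, Ko = Ko,
                  dt_out = config$dt_out, acc = config$acc)
  tr <- .trace_tibble(m, res$trace)
  res$trace_tbl <- tr
  res$ap <- action_potential_features(tr, 1)
  res
}

#' Compute the full output vector for one parameter set
#'
#' Runs the protocol battery of an output suite for a single cell (one
#' parameter set) and returns the ordered output vector.  The stimulation
#' threshold is measured first and all subsequent protocols stimulate at
#' `config$stim_rel` times that threshold when `config$stim_mode` is
#' `"relative"`; by default a strong fixed stimulus (`config$stim_amp`) is
#' used instead.  Protocol failures (loss of
#' excitability, integrator failure under extreme parameter combinations)
#' mask the affected outputs and are recorded in the `failures` attribute.
#'
#' @inheritParams run_protocol
#' @param suite Suite name (see [output_suite()]); defaults per model.
#' @param config A [suite_config()].
#' @return Named numeric vector over the suite's outputs with attributes
#'   `mask` (logical) and `failures` (named character vector).
#' @export
compute_trial_outputs <- function(model_id, params, suite = NULL,
                                  config = suite_config()) {
  m <- .resolve_model(model_id)
  if (is.null(suite)) suite <- .default_suite(model_id)
  wanted <- output_suite(suite)
  pvals <- .param_values(params)
  acc <- config$acc
  feats <- list()
  failures <- character(0)
  fail <- function(step, e) {
    failures[[step]] <<- conditionMessage(e)
    NULL
  }
  has <- function(...) any(c(...) %in% wanted)
  state0 <- m$initial_state

  # 1. stimulation threshold (an output in its own right; in "relative"
  # stimulus mode it also sizes every other protocol's stimulus)
  thr <- NULL
  if (has("i_thresh") || config$stim_mode == "relative") {
    thr <- tryCatch(
      find_stimulation_threshold(model_id, params,
                                 spec = protocol_spec("threshold_search",
                                                      Ko = 5.4, acc = acc),
                                 initial_state = state0,
                                 lower = config$thr_lower,
                                 upper = config$thr_upper),
      error = function(e) fail("i_thresh", e)
    )
  }
  if (is.null(thr) && config$stim_mode == "relative") {
    # unexcitable cell: every output is masked
    out <- assemble_output_vector(
      setNames(as.list(rep(NA_real_, length(wanted))), wanted), wanted)
    attr(out, "failures") <- failures
    return(out)
  }
  feats$i_thresh <- thr %||% NA_real_
  stim <- if (config$stim_mode == "fixed") config$stim_amp
          else config$stim_rel * thr

  # 2. pacing train from quiescent start; steady-state + first/last features
  steady_state <- NULL
  pre <- tryCatch({
    train <- .sim_pace(m, pvals, state0, config$bcl, config$n_prepace - 1L,
                       stim, 1, 5.4, acc = acc)
    meas <- .measured_beat(m, pvals, train$state, config$bcl, stim, 5.4,
                           config)
    list(train = train, meas = meas)
  }, trial_failure = function(e) fail("paced", e))
  if (!is.null(pre)) {
    b <- tibble::as_tibble(as.data.frame(pre$train$beats))
    first <- b[1, ]
    meas <- pre$meas
    steady_state <- meas$state
    feats$apd <- meas$apd
    feats$v_rest <- meas$v_rest
    feats$v_peak <- if (meas$v_peak > 0) meas$v_peak else NA_real_
    feats$dvdt_max <- if (meas$v_peak > 0) meas$dvdt_max else NA_real_
    feats <- c(feats, .shape_named(meas$ap))
    feats$apd_diff <- meas$apd - first$apd
    if (has("v_plateau")) {
      # plateau voltage 100 ms after stimulus onset (reads on plateau currents)
      feats$v_plateau <- stats::approx(meas$trace_tbl$time,
                                       meas$trace_tbl$voltage,
                                       xout = 100, rule = 2)$y
    }
    if (has("dca", "ca_ttp", "ca_decay", "dca_diff")) {
      cf <- calcium_features(meas$trace_tbl, 1)
      feats$dca <- cf$dca
      feats$ca_ttp <- cf$ca_ttp
      feats$ca_decay <- cf$ca_decay
      feats$dca_diff <- cf$dca - first$cai_amp
    }
  }

  if (is.null(steady_state)) {
    # without a steady paced state no further protocol is defined
    out_list <- setNames(as.list(rep(NA_real_, length(wanted))), wanted)
    out_list$i_thresh <- thr
    out <- assemble_output_vector(out_list, wanted)
    attr(out, "failures") <- failures
    return(out)
  }

  # 3. long pause, then one beat
  if (has("apd_pause", "dca_pause", "v_maxmin_pause", "v_minmax_pause",
          "t_minmax_pause")) {
    pp <- tryCatch({
      qp <- .sim_run(m, pvals, steady_state, config$pause, Ko = 5.4,
                     acc = acc)
      .measured_beat(m, pvals, qp$state, config$bcl, stim, 5.4, config)
    }, trial_failure = function(e) fail("pause", e))
    if (!is.null(pp)) {
      feats$apd_pause <- pp$apd
      feats$dca_pause <- calcium_features(pp$trace_tbl, 1)$dca
      feats <- c(feats, .shape_named(pp$ap, "_pause"))
    }
  }

  # 4. altered extracellular potassium
  for (ko_case in list(c("hypo", config$Ko_hypo), c("hyper", config$Ko_hyper))) {
    sfx <- ko_case[1]
    ko <- as.numeric(ko_case[2])
    if (!has(paste0("apd_", sfx), paste0("v_rest_", sfx),
             paste0("v_maxmin_", sfx))) next
    kk <- tryCatch({
      train <- .sim_pace(m, pvals, steady_state, config$bcl,
                         config$n_ko - 1L, stim, 1, ko, acc = acc)
      .measured_beat(m, pvals, train$state, config$bcl, stim, ko, config)
    }, trial_failure = function(e) fail(paste0("ko_", sfx), e))
    if (!is.null(kk)) {
      feats[[paste0("apd_", sfx)]] <- kk$apd
      feats[[paste0("v_rest_", sfx)]] <- kk$v_rest
      feats <- c(feats, .shape_named(kk$ap, paste0("_", sfx)))
    }
  }

  # 5. quiescence: intracellular concentrations after 60 s of rest
  if (has("cai_quiet", "nai_quiet", "ki_quiet")) {
    qq <- tryCatch(
      .sim_run(m, pvals, steady_state, config$quiescence, Ko = 5.4,
               acc = acc),
      trial_failure = function(e) fail("quiescence", e)
    )
    if (!is.null(qq)) {
      st <- setNames(qq$state, m$state_names)
      feats$cai_quiet <- if ("Cai" %in% m$state_names) st[["Cai"]] else NA_real_
      feats$nai_quiet <- if ("Nai" %in% m$state_names) st[["Nai"]] else NA_real_
      feats$ki_quiet <- if ("Ki" %in% m$state_names) st[["Ki"]] else NA_real_
    }
  }

  # 6. frequency adaptation: APD at slow over fast pacing
  if (has("freq_adapt")) {
    fa <- tryCatch({
      slow <- .sim_pace(m, pvals, steady_state, config$bcl_slow,
                        config$n_freq, stim, 1, 5.4, acc = acc)
      fast <- .sim_pace(m, pvals, steady_state, config$bcl_fast,
                        config$n_freq, stim, 1, 5.4, acc = acc)
      bs <- as.data.frame(slow$beats)
      bf <- as.data.frame(fast$beats)
      tail(bs$apd, 1) / tail(bf$apd, 1)
    }, trial_failure = function(e) fail("freq_adapt", e))
    if (!is.null(fa)) feats$freq_adapt <- fa
  }

  # 7. alternans threshold
  if (has("bcl_alt")) {
    ba <- tryCatch(
      find_alternans_threshold(
        model_id, params,
        spec = protocol_spec("alternans_scan", stim_amplitude = stim,
                             scan_max = config$scan_max,
                             scan_min = config$scan_min,
                             scan_step = config$scan_step, acc = acc),
        initial_state = steady_state, n_scan_beats = config$n_scan_beats),
      trial_failure = function(e) fail("bcl_alt", e)
    )
    if (!is.null(ba)) feats$bcl_alt <- as.numeric(ba)
  }

  # 8. restitution maximum slope
  if (has("max_slope")) {
    ms <- tryCatch(
      restitution_max_slope(
        model_id, params,
        spec = protocol_spec("restitution", bcl = config$bcl,
                             stim_amplitude = stim, acc = acc),
        initial_state = steady_state, di_grid = config$di_grid,
        n_s1 = config$n_s1),
      trial_failure = function(e) fail("max_slope", e)
    )
    if (!is.null(ms)) feats$max_slope <- as.numeric(ms)
  }

  # fill anything not produced with NA and assemble in suite order
  for (nm in setdiff(wanted, names(feats))) feats[[nm]] <- NA_real_
  out <- assemble_output_vector(feats[wanted], wanted)
  attr(out, "failures") <- failures
  out
}
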