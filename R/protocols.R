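# Stimulation protocols.  All simulations go through the compiled adaptive
# integrator; beat-level summaries (APD at 90% repolarization, peak voltage,
# maximal upstroke velocity, Ca transient amplitude) are extracted inside the
# integration loop so that iterative scans do not need to record full traces.

.DEFAULT_DT_OUT <- 0.25 # ms, trace sampling interval for recorded beats

#' Integrator accuracy settings
#'
#' Step-size controls of the hybrid Rush-Larsen integrator: gates are updated
#' exactly (exponential update), voltage and concentrations explicitly with a
#' step chosen so the voltage change per step stays near `dv_step` and the
#' relative Ca2+ change per step near `cai_step`, clamped to
#' `[dt_min, dt_max]`.
#'
#' @param dv_step Target voltage change per step (mV).
#' @param dt_min,dt_max Step bounds (ms).
#' @param cai_step Target relative intracellular Ca2+ change per step.
#' @return Numeric vector of length 4 used by the protocol runners.
#' @export
solver_accuracy <- function(dv_step = 0.2, dt_min = 0.005, dt_max = 0.25,
                            cai_step = 0.02) {
  c(dv_step = dv_step, dt_min = dt_min, dt_max = dt_max, cai_step = cai_step)
}

#' Construct a protocol specification
#'
#' @param protocol_id One of `"paced"`, `"pause"`, `"quiescence"`,
#'   `"restitution"`, `"alternans_scan"`, `"threshold_search"`.
#' @param bcl Basic cycle length in ms.
#' @param n_beats Number of paced beats.
#' @param stim_amplitude Stimulus amplitude in pA/pF (depolarizing positive).
#' @param stim_duration Stimulus duration in ms (rectangular pulse).
#' @param Ko Extracellular potassium in mM (5.4 normal; 3 hypokalemia;
#'   8 hyperkalemia).
#' @param pause_duration Pause length in ms (pause protocol) or quiescence
#'   duration (quiescence protocol).
#' @param scan_max,scan_min,scan_step Cycle-length grid for the alternans scan
#'   (ms), descending from `scan_max` to `scan_min` in steps of `scan_step`.
#' @param record_from_beat First beat whose trace is recorded (earlier beats
#'   are integrated without recording).
#' @param tail_duration Unstimulated tail appended after the final beat (ms).
#' @param dt_out Trace sampling interval in ms.
#' @param acc Integrator accuracy settings, see [solver_accuracy()].
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol_id = "paced", bcl = 1000, n_beats = 100,
                          stim_amplitude = 40, stim_duration = 1, Ko = 5.4,
                          pause_duration = 5000, scan_max = 350,
                          scan_min = 150, scan_step = 5,
                          record_from_beat = NULL, tail_duration = 0,
                          dt_out = .DEFAULT_DT_OUT, acc = solver_accuracy()) {
  ids <- c("paced", "pause", "quiescence", "restitution", "alternans_scan",
           "threshold_search")
  if (!protocol_id %in% ids) {
    stop("unknown protocol_id ", deparse(protocol_id), call. = FALSE)
  }
  if (!(bcl > stim_duration && stim_duration > 0)) {
    stop("need bcl > stim_duration > 0", call. = FALSE)
  }
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (Ko <= 0) stop("Ko must be positive", call. = FALSE)
  if (is.null(record_from_beat)) record_from_beat <- n_beats
  structure(
    list(protocol_id = protocol_id, bcl = bcl, n_beats = as.integer(n_beats),
         stim_amplitude = stim_amplitude, stim_duration = stim_duration,
         Ko = Ko, pause_duration = pause_duration, scan_max = scan_max,
         scan_min = scan_min, scan_step = scan_step,
         record_from_beat = as.integer(record_from_beat),
         tail_duration = tail_duration, dt_out = dt_out, acc = acc),
    class = "protocol_spec"
  )
}

# condition raised when the integrator fails for a trial
trial_failure <- function(message, context = list()) {
  structure(
    class = c("trial_failure", "error", "condition"),
    list(message = message, call = NULL, context = context)
  )
}

.sim_pace <- function(m, pvals, state, bcl, n_beats, stim_amp, stim_dur, Ko,
                      dt_out = 0, record_from_beat = n_beats + 1L,
                      acc = solver_accuracy(), t_offset = 0) {
  res <- cm_pace_cpp(m$code, unname(pvals), as.numeric(state), bcl, n_beats,
                     stim_amp, stim_dur, Ko, dt_out, record_from_beat,
                     unname(acc), t_offset)
  if (res$status != 0) {
    stop(trial_failure("integrator failure (non-finite state) during pacing",
                       context = list(bcl = bcl, Ko = Ko)))
  }
  res
}

.sim_run <- function(m, pvals, state, duration, stim_amp = 0, stim_start = 0,
                     stim_dur = 1, Ko = 5.4, dt_out = 0,
                     acc = solver_accuracy(), t_offset = 0) {
  res <- cm_run_cpp(m$code, unname(pvals), as.numeric(state), duration,
                    stim_amp, stim_start, stim_dur, Ko, dt_out, unname(acc),
                    t_offset)
  if (res$status != 0) {
    stop(trial_failure("integrator failure (non-finite state)",
                       context = list(duration = duration, Ko = Ko)))
  }
  res
}

# convert a raw trace matrix (t, states..., stim) to the Trace tibble
.trace_tibble <- function(m, tr) {
  sn <- m$state_names
  colnames(tr) <- c("time", sn, "stim")
  df <- tibble::as_tibble(as.data.frame(tr))
  out <- tibble::tibble(
    time = df$time,
    voltage = df$V,
    cai = if ("Cai" %in% sn) df$Cai else NA_real_,
    nai = if ("Nai" %in% sn) df$Nai else NA_real_,
    ki = if ("Ki" %in% sn) df$Ki else NA_real_,
    stim = df$stim
  )
  attr(out, "states") <- df[, sn, drop = FALSE]
  out
}

#' Run a stimulation protocol and return the trace
#'
#' Runs the requested protocol and returns a `trace` tibble with columns
#' `time` (ms), `voltage` (mV), `cai`, `nai`, `ki` (mM; `NA` for models that
#' do not carry the corresponding state), and `stim` (pA/pF).  Beat summaries
#' (per-beat APD, peak voltage, maximal upstroke velocity, Ca transient
#' amplitude) are attached as attribute `"beats"`, stimulus-onset sample
#' indices as attribute `"beat_boundaries"`, and the final state as
#' `"final_state"`.
#'
#' For the scan protocols (`restitution`, `alternans_scan`,
#' `threshold_search`) the corresponding search is run and its scalar result
#' is attached as attribute `"result"`; the returned trace is that of the
#' decisive simulation.
#'
#' @inheritParams evaluate_derivatives
#' @param spec A [protocol_spec()].
#' @param initial_state Optional state vector; defaults to the model's
#'   published initial conditions.
#' @return A tibble of class `trace`.
#' @export
run_protocol <- function(model_id, params, spec = protocol_spec(),
                         initial_state = NULL) {
  m <- .resolve_model(model_id)
  stopifnot(inherits(spec, "protocol_spec"))
  pvals <- .param_values(params)
  state <- if (is.null(initial_state)) m$initial_state else initial_state
  if (length(state) != length(m$state_names)) {
    stop("initial_state length does not match model", call. = FALSE)
  }

  if (spec$protocol_id == "quiescence") {
    res <- .sim_run(m, pvals, state, spec$pause_duration, stim_amp = 0,
                    Ko = spec$Ko, dt_out = max(spec$dt_out, 10),
                    acc = spec$acc)
    out <- .trace_tibble(m, res$trace)
    attr(out, "final_state") <- setNames(res$state, m$state_names)
    attr(out, "beats") <- tibble::tibble()
    attr(out, "beat_boundaries") <- integer(0)
    class(out) <- c("trace", class(out))
    return(out)
  }

  if (spec$protocol_id == "threshold_search") {
    thr <- find_stimulation_threshold(model_id, params, spec,
                                      initial_state = state)
    spec2 <- spec
    spec2$protocol_id <- "paced"
    spec2$n_beats <- 1L
    spec2$record_from_beat <- 1L
    spec2$stim_amplitude <- thr
    out <- run_protocol(model_id, params, spec2, initial_state = state)
    attr(out, "result") <- thr
    return(out)
  }
  if (spec$protocol_id == "alternans_scan") {
    bclalt <- find_alternans_threshold(model_id, params, spec,
                                       initial_state = state)
    spec2 <- spec
    spec2$protocol_id <- "paced"
    spec2$bcl <- max(attr(bclalt, "decisive_bcl") %||% spec$scan_max,
                     spec$stim_duration * 2)
    spec2$n_beats <- 8L
    spec2$record_from_beat <- 1L
    out <- run_protocol(model_id, params, spec2, initial_state = state)
    attr(out, "result") <- as.numeric(bclalt)
    return(out)
  }
  if (spec$protocol_id == "restitution") {
    slope <- restitution_max_slope(model_id, params, spec,
                                   initial_state = state)
    spec2 <- spec
    spec2$protocol_id <- "paced"
    spec2$n_beats <- 1L
    spec2$record_from_beat <- 1L
    out <- run_protocol(model_id, params, spec2, initial_state = state)
    attr(out, "result") <- as.numeric(slope)
    return(out)
  }

  # paced / pause
  res <- .sim_pace(m, pvals, state, spec$bcl, spec$n_beats,
                   spec$stim_amplitude, spec$stim_duration, spec$Ko,
                   dt_out = spec$dt_out,
                   record_from_beat = spec$record_from_beat,
                   acc = spec$acc)
  beats <- tibble::as_tibble(as.data.frame(res$beats))
  trace <- res$trace
  state <- res$state
  t_now <- spec$bcl * spec$n_beats

  if (spec$protocol_id == "pause") {
    resp <- .sim_run(m, pvals, state, spec$pause_duration, stim_amp = 0,
                     Ko = spec$Ko, dt_out = spec$dt_out, acc = spec$acc, t_offset = t_now)
    t_now <- t_now + spec$pause_duration
    resb <- .sim_pace(m, pvals, resp$state, spec$bcl, 1L,
                      spec$stim_amplitude, spec$stim_duration, spec$Ko,
                      dt_out = spec$dt_out, record_from_beat = 1L,
                      acc = spec$acc, t_offset = t_now)
    bp <- tibble::as_tibble(as.data.frame(resb$beats))
    bp$beat <- max(beats$beat) + 1
    beats <- dplyr::bind_rows(beats, bp)
    trace <- rbind(trace, resp$trace, resb$trace)
    state <- resb$state
    t_now <- t_now + spec$bcl
  }

  if (spec$tail_duration > 0) {
    rest <- .sim_run(m, pvals, state, spec$tail_duration, stim_amp = 0,
                     Ko = spec$Ko, dt_out = spec$dt_out, acc = spec$acc, t_offset = t_now)
    trace <- rbind(trace, rest$trace)
    state <- rest$state
  }

  out <- .trace_tibble(m, trace)
  boundaries <- vapply(beats$t_stim, function(ts) {
    w <- which(out$time >= ts - 1e-9)
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  attr(out, "beats") <- beats
  attr(out, "beat_boundaries") <- boundaries[!is.na(boundaries)]
  attr(out, "final_state") <- setNames(state, m$state_names)
  class(out) <- c("trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find the stimulation threshold by bisection
#'
#' Iteratively applies sub- and supra-threshold stimuli until the minimal
#' amplitude that elicits an action potential is bracketed to within `tol`.
#' An action potential counts as elicited when the membrane voltage crosses
#' 0 mV within 50 ms of stimulus onset.
#'
#' @inheritParams run_protocol
#' @param lower,upper Initial bracketing amplitudes in pA/pF; `lower` must
#'   not elicit an AP and `upper` must.
#' @param tol Bisection tolerance in pA/pF.
#' @param .elicits Optional function `f(amplitude) -> logical` replacing the
#'   simulation (used to test the search against analytic surrogates).
#' @return Threshold amplitude in pA/pF (midpoint of the final bracket).
#' @export
find_stimulation_threshold <- function(model_id, params,
                                       spec = protocol_spec("threshold_search"),
                                       initial_state = NULL, lower = 2,
                                       upper = 80, tol = 0.1,
                                       .elicits = NULL) {
  if (is.null(.elicits)) {
    m <- .resolve_model(model_id)
    pvals <- .param_values(params)
    state <- if (is.null(initial_state)) m$initial_state else initial_state
    .elicits <- function(amp) {
      res <- .sim_run(m, pvals, state, duration = 60, stim_amp = amp,
                      stim_start = 0, stim_dur = spec$stim_duration,
                      Ko = spec$Ko, acc = spec$acc)
      res$v_peak > 0 && res$t_v_peak <= 50
    }
  }
  if (.elicits(lower)) {
    stop("lower bracket already elicits an action potential", call. = FALSE)
  }
  if (!.elicits(upper)) {
    stop("upper bound subthreshold: no action potential at the upper bracket",
         call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (upper + lower) / 2
    if (.elicits(mid)) upper <- mid else lower <- mid
  }
  (upper + lower) / 2
}

#' Detect APD alternans in a beat sequence
#'
#' @param apds Numeric APD sequence (ms) of consecutive beats.
#' @param delta Minimal beat-to-beat APD difference in ms.
#' @param n_beats Number of final beats over which the alternation must be
#'   sustained.
#' @return `TRUE` when every beat-to-beat difference over the final `n_beats`
#'   exceeds `delta` in magnitude with alternating sign.
#' @export
detect_alternans <- function(apds, delta = 1, n_beats = 4) {
  if (length(apds) < n_beats || anyNA(tail(apds, n_beats))) return(FALSE)
  d <- diff(tail(apds, n_beats))
  all(abs(d) > delta) && all(diff(sign(d)) != 0)
}

#' Find the alternans threshold cycle length
#'
#' Scans basic cycle lengths descending from `spec$scan_max` to
#' `spec$scan_min` in steps of `spec$scan_step`, pacing at each cycle length
#' and testing the final beats for sustained APD alternans.  The cell state
#' carries over from one cycle length to the next, as in a ramp experiment.
#'
#' @inheritParams run_protocol
#' @param n_scan_beats Beats paced per scanned cycle length (the final 4 are
#'   tested for alternans).
#' @param delta Alternans criterion in ms.
#' @param .apd_fun Optional function `f(bcl) -> numeric APD sequence`
#'   replacing the simulation (used to test against map-iteration
#'   surrogates).
#' @return The largest scanned cycle length at which alternans is detected,
#'   or the sentinel `scan_min - scan_step` when it never is.  Attribute
#'   `"scan"` holds the per-cycle-length audit tibble.
#' @export
find_alternans_threshold <- function(model_id, params,
                                     spec = protocol_spec("alternans_scan"),
                                     initial_state = NULL, n_scan_beats = 8,
                                     delta = 1, .apd_fun = NULL) {
  grid <- seq(spec$scan_max, spec$scan_min, by = -spec$scan_step)
  sentinel <- spec$scan_min - spec$scan_step
  audit <- vector("list", length(grid))
  state <- NULL
  m <- NULL
  pvals <- NULL
  if (is.null(.apd_fun)) {
    m <- .resolve_model(model_id)
    pvals <- .param_values(params)
    state <- if (is.null(initial_state)) m$initial_state else initial_state
  }
  result <- sentinel
  decisive <- NA_real_
  capture_lost <- FALSE
  for (i in seq_along(grid)) {
    bcl <- grid[i]
    if (is.null(.apd_fun)) {
      res <- .sim_pace(m, pvals, state, bcl, as.integer(n_scan_beats),
                       spec$stim_amplitude, spec$stim_duration, spec$Ko,
                       acc = spec$acc)
      state <- res$state
      b <- as.data.frame(res$beats)
      apds <- b$apd
      captured <- b$captured > 0
    } else {
      apds <- .apd_fun(bcl)
      captured <- !is.na(apds)
    }
    alt <- detect_alternans(apds, delta = delta)
    audit[[i]] <- tibble::tibble(
      bcl = bcl, captured = all(tail(captured, 4)),
      alternans = alt,
      apd_last = tail(apds, 1)[1],
      apd_prev = if (length(apds) >= 2) apds[length(apds) - 1] else NA_real_
    )
    if (!all(tail(captured, 4)) || anyNA(tail(apds, 4))) {
      capture_lost <- TRUE
      break
    }
    if (alt) {
      result <- bcl
      decisive <- bcl
      break
    }
  }
  structure(result,
            scan = dplyr::bind_rows(audit),
            capture_lost = capture_lost,
            decisive_bcl = decisive)
}

#' Maximum slope of a restitution curve
#'
#' Centered finite-difference maximum slope of APD versus diastolic interval.
#'
#' @param di Diastolic intervals (ms), increasing.
#' @param apd APDs (ms), same length.
#' @return Maximal centered-difference slope (dimensionless); `NA` with
#'   fewer than 3 valid points.
#' @export
max_restitution_slope <- function(di, apd) {
  ok <- is.finite(di) & is.finite(apd)
  di <- di[ok]; apd <- apd[ok]
  if (length(di) < 3) return(NA_real_)
  o <- order(di)
  di <- di[o]; apd <- apd[o]
  n <- length(di)
  slopes <- (apd[3:n] - apd[1:(n - 2)]) / (di[3:n] - di[1:(n - 2)])
  max(slopes)
}

#' Maximum restitution slope from an S1S2 protocol
#'
#' Paces an S1 train, then delivers a single premature (S2) stimulus at each
#' diastolic interval of the grid and measures the resulting APD.  Returns
#' the maximal centered finite-difference slope of APD versus diastolic
#' interval.
#'
#' @inheritParams run_protocol
#' @param di_grid Diastolic intervals in ms.
#' @param n_s1 Number of S1 beats at `spec$bcl` before each S2.
#' @param .apd_fun Optional function `f(di) -> APD` replacing the simulation
#'   (used to test against closed-form surrogates).
#' @return Maximal slope (dimensionless), with the `(di, apd)` curve attached
#'   as attribute `"curve"`; `NA` when fewer than 3 grid points yield a
#'   captured AP.
#' @export
restitution_max_slope <- function(model_id, params,
                                  spec = protocol_spec("restitution"),
                                  initial_state = NULL,
                                  di_grid = c(5, 10, 20, 40, 60, 80, 120,
                                              160, 200, 300),
                                  n_s1 = 10, .apd_fun = NULL) {
  if (is.null(.apd_fun)) {
    m <- .resolve_model(model_id)
    pvals <- .param_values(params)
    state <- if (is.null(initial_state)) m$initial_state else initial_state
    # S1 train minus one beat; reuse for every S2
    pre <- .sim_pace(m, pvals, state, spec$bcl, as.integer(n_s1 - 1),
                     spec$stim_amplitude, spec$stim_duration, spec$Ko,
                     acc = spec$acc)
    # probe the final S1 beat for its APD and upstroke time
    probe <- .sim_run(m, pvals, pre$state, spec$bcl, spec$stim_amplitude,
                      0, spec$stim_duration, spec$Ko, acc = spec$acc)
    if (!is.finite(probe$apd)) {
      return(structure(NA_real_, curve = tibble::tibble()))
    }
    t_end90 <- probe$t_upstroke + probe$apd
    .apd_fun <- function(di) {
      ci <- t_end90 + di
      upto <- .sim_run(m, pvals, pre$state, ci, spec$stim_amplitude, 0,
                       spec$stim_duration, spec$Ko, acc = spec$acc)
      s2 <- .sim_run(m, pvals, upto$state, min(spec$bcl, 600),
                     spec$stim_amplitude, 0, spec$stim_duration, spec$Ko,
                     acc = spec$acc)
      if (s2$v_peak > 0 && is.finite(s2$apd)) s2$apd else NA_real_
    }
  }
  apds <- vapply(di_grid, function(di) {
    tryCatch(.apd_fun(di), trial_failure = function(e) NA_real_)
  }, numeric(1))
  curve <- tibble::tibble(di = di_grid, apd = apds)
  structure(max_restitution_slope(di_grid, apds), curve = curve)
}
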