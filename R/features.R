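# Feature extraction from simulated traces: action-potential morphology,
# Ca2+ transient metrics, and assembly of the per-trial output vector.
#
# All extractors are pure functions of the trace; a beat that did not capture
# yields masked (NA) features rather than an error.

# window of one beat: list(t, v, cai, t_stim, t_end)
.beat_window <- function(trace, beat_index) {
  beats <- attr(trace, "beats")
  if (is.null(beats) || nrow(beats) == 0) {
    i0 <- which(trace$stim != 0)
    t_stim <- if (length(i0) > 0) trace$time[i0[1]] else trace$time[1]
    list(t = trace$time, v = trace$voltage, cai = trace$cai,
         t_stim = t_stim, t_end = max(trace$time))
  } else {
    if (beat_index < 1 || beat_index > nrow(beats)) {
      stop("beat_index ", beat_index, " out of range", call. = FALSE)
    }
    t_stim <- beats$t_stim[beat_index]
    t_end <- if (beat_index < nrow(beats)) beats$t_stim[beat_index + 1]
             else max(trace$time)
    sel <- trace$time >= t_stim & trace$time <= t_end
    list(t = trace$time[sel], v = trace$voltage[sel], cai = trace$cai[sel],
         t_stim = t_stim, t_end = t_end)
  }
}

# moving-average smoother with window w samples (odd)
.smooth <- function(x, w) {
  if (w <= 1 || length(x) < w) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

# linear-interpolated first downward crossing of v through thr after index i0
.cross_down <- function(t, v, thr, i0) {
  n <- length(v)
  if (i0 >= n) return(NA_real_)
  for (i in seq(i0 + 1, n)) {
    if (v[i - 1] > thr && v[i] <= thr) {
      w <- (thr - v[i - 1]) / (v[i] - v[i - 1])
      return(t[i - 1] + w * (t[i] - t[i - 1]))
    }
  }
  NA_real_
}

#' Action-potential morphology features of one beat
#'
#' Computes APD (time from the fastest-upstroke instant to 90% repolarization
#' toward the pre-stimulus diastolic voltage), resting and peak voltage,
#' maximal upstroke velocity, and the spike-and-dome shape parameters: the
#' phase-1 notch trough (`v_maxmin`), the subsequent dome peak (`v_minmax`),
#' and the dome time relative to the upstroke (`t_minmax`).  When no
#' notch/dome pair is detected the shape parameters fall back to the voltage
#' 20 ms and 50 ms after the upstroke and a `t_minmax` of 50 ms, and
#' `shape_fallback` is `TRUE`.
#'
#' @param trace A `trace` tibble (see [run_protocol()]), or any tibble with
#'   `time`, `voltage`, and `stim` columns.
#' @param beat_index Which beat to analyse (defaults to the last).
#' @param repol_fraction Repolarization fraction defining APD (default 0.9).
#' @return A one-row tibble: `apd`, `v_rest`, `v_peak`, `dvdt_max`,
#'   `v_maxmin`, `v_minmax`, `t_minmax`, `shape_fallback`, `captured`.
#'   All-NA (masked) when the beat has no action potential.
#' @export
action_potential_features <- function(trace, beat_index = NULL,
                                      repol_fraction = 0.9) {
  beats <- attr(trace, "beats")
  if (is.null(beat_index)) {
    beat_index <- if (!is.null(beats) && nrow(beats) > 0) nrow(beats) else 1L
  }
  w <- .beat_window(trace, beat_index)
  masked <- tibble::tibble(
    apd = NA_real_, v_rest = NA_real_, v_peak = NA_real_, dvdt_max = NA_real_,
    v_maxmin = NA_real_, v_minmax = NA_real_, t_minmax = NA_real_,
    shape_fallback = NA, captured = FALSE
  )
  if (length(w$t) < 5) return(masked)

  v_rest <- w$v[1]
  i_pk <- which.max(w$v)
  v_peak <- w$v[i_pk]
  if (!is.finite(v_peak) || v_peak < 0) return(masked)

  dt <- stats::median(diff(w$t))
  dv <- c(NA, diff(w$v) / diff(w$t))
  # upstroke must precede the peak
  i_up <- which.max(dv[seq_len(i_pk)])
  dvdt_max <- dv[i_up]
  t_up <- w$t[i_up]

  thr <- v_rest + (1 - repol_fraction) * (v_peak - v_rest)
  t90 <- .cross_down(w$t, w$v, thr, i_pk)
  apd <- if (is.finite(t90)) t90 - t_up else NA_real_

  # notch/dome via sign changes of a smoothed derivative (1 ms window)
  win <- max(1L, round(1 / dt))
  if (win %% 2 == 0) win <- win + 1L
  vs <- .smooth(w$v, win)
  dvs <- diff(vs) / diff(w$t)
  horizon <- which(w$t <= w$t[i_pk] + 150)
  n_h <- max(horizon)
  v_maxmin <- v_minmax <- t_minmax <- NA_real_
  fallback <- TRUE
  if (i_pk + 3 < n_h) {
    seg <- seq(i_pk + 1, n_h - 1)
    up_cross <- seg[dvs[seg - 1] < 0 & dvs[seg] >= 0]   # local minimum
    if (length(up_cross) > 0) {
      i_notch <- up_cross[1]
      rest_seg <- seq(i_notch + 1, n_h - 1)
      down_cross <- rest_seg[dvs[rest_seg - 1] > 0 & dvs[rest_seg] <= 0]
      if (length(down_cross) > 0) {
        i_dome <- down_cross[1]
        if (w$v[i_dome] > w$v[i_notch]) {
          v_maxmin <- w$v[i_notch]
          v_minmax <- w$v[i_dome]
          t_minmax <- w$t[i_dome] - t_up
          fallback <- FALSE
        }
      }
    }
  }
  if (fallback) {
    v_maxmin <- stats::approx(w$t, w$v, t_up + 20, rule = 2)$y
    v_minmax <- stats::approx(w$t, w$v, t_up + 50, rule = 2)$y
    t_minmax <- 50
  }

  tibble::tibble(
    apd = apd, v_rest = v_rest, v_peak = v_peak, dvdt_max = dvdt_max,
    v_maxmin = v_maxmin, v_minmax = v_minmax, t_minmax = t_minmax,
    shape_fallback = fallback, captured = TRUE
  )
}

#' Ca2+ transient features of one beat
#'
#' Transient amplitude (peak minus pre-stimulus diastolic level), time to
#' peak from stimulus onset, and the time constant of a single-exponential
#' least-squares fit to the decay from `lag` ms after the peak to the end of
#' the beat.
#'
#' @inheritParams action_potential_features
#' @param lag Delay after the Ca2+ peak before the decay fit starts (ms).
#' @return A one-row tibble: `dca`, `ca_ttp`, `ca_decay`.  Masked (NA) when
#'   the Ca2+ signal is absent, flat, or peaks at the very start of the beat.
#' @export
calcium_features <- function(trace, beat_index = NULL, lag = 20) {
  beats <- attr(trace, "beats")
  if (is.null(beat_index)) {
    beat_index <- if (!is.null(beats) && nrow(beats) > 0) nrow(beats) else 1L
  }
  w <- .beat_window(trace, beat_index)
  masked <- tibble::tibble(dca = NA_real_, ca_ttp = NA_real_,
                           ca_decay = NA_real_)
  ca <- w$cai
  if (length(ca) < 5 || anyNA(ca)) return(masked)
  i_pk <- which.max(ca)
  dca <- ca[i_pk] - ca[1]
  if (i_pk <= 2) return(masked) # peak at beat start: garbage
  if (dca <= 0) {
    return(tibble::tibble(dca = 0, ca_ttp = NA_real_, ca_decay = NA_real_))
  }
  ttp <- w$t[i_pk] - w$t_stim

  sel <- w$t >= w$t[i_pk] + lag
  decay <- NA_real_
  if (sum(sel) >= 10) {
    td <- w$t[sel] - (w$t[i_pk] + lag)
    yd <- ca[sel]
    c0 <- min(yd)
    a0 <- max(yd[1] - c0, 1e-12)
    fit <- tryCatch(
      minpack.lm::nlsLM(yd ~ C + A * exp(-td / tau),
                        start = list(C = c0, A = a0, tau = max(ttp, 20)),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      tau <- coef(fit)[["tau"]]
      if (is.finite(tau) && tau > 0) decay <- tau
    }
  }
  tibble::tibble(dca = dca, ca_ttp = ttp, ca_decay = decay)
}

#' Assemble an ordered output vector from per-protocol feature sets
#'
#' Collects the named features computed by the individual protocols into the
#' ordered output vector of an output suite (see [output_suite()]).  Missing
#' protocols are an error; masked features propagate as NA with the mask
#' recorded.
#'
#' @param features Named list mapping output name to value (NA = masked).
#' @param suite Character vector of output names defining order.
#' @return Named numeric vector of length `length(suite)` with attribute
#'   `mask` (logical).
#' @export
assemble_output_vector <- function(features, suite) {
  missing <- setdiff(suite, names(features))
  if (length(missing) > 0) {
    stop("no recorded result for output(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vapply(suite, function(nm) {
    v <- features[[nm]]
    if (length(v) != 1) {
      stop("feature ", nm, " does not have length 1", call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  attr(out, "mask") <- !is.finite(out)
  out
}
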