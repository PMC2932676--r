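# Shared helpers: cheap protocol configurations and synthetic traces.

# protocol battery scaled to test size (short pre-pacing, short quiescence)
cheap_config <- function(...) {
  suite_config(n_prepace = 15, n_ko = 6, n_freq = 8, quiescence = 10000,
               pause = 3000, n_s1 = 5, scan_max = 320, scan_min = 200,
               scan_step = 10, ...)
}

# synthetic trapezoidal action potential with analytically known APD:
# rest at v0, instantaneous-ish upstroke to v1, plateau, linear ramp down
trapezoid_trace <- function(v0 = -85, v1 = 40, t_up = 10, plateau = 200,
                            ramp = 100, dt = 0.1, t_end = 500) {
  tt <- seq(0, t_end, by = dt)
  v <- ifelse(tt < t_up, v0,
       ifelse(tt < t_up + 1, v0 + (v1 - v0) * (tt - t_up),
       ifelse(tt < t_up + 1 + plateau, v1,
       ifelse(tt < t_up + 1 + plateau + ramp,
              v1 - (v1 - v0) * (tt - t_up - 1 - plateau) / ramp, v0))))
  stim <- ifelse(tt >= t_up & tt < t_up + 1, 30, 0)
  tibble::tibble(time = tt, voltage = v, cai = NA_real_, nai = NA_real_,
                 ki = NA_real_, stim = stim)
}

# synthetic Ca transient with known rise and decay time constants
ca_transient_trace <- function(D = 1e-4, A = 8e-4, tau_r = 5, tau_d = 60,
                               dt = 0.25, t_end = 600) {
  tt <- seq(0, t_end, by = dt)
  cai <- D + A * (1 - exp(-tt / tau_r)) * exp(-tt / tau_d)
  tibble::tibble(time = tt, voltage = -80, cai = cai, nai = NA_real_,
                 ki = NA_real_, stim = ifelse(tt < 1, 30, 0))
}

# variance of a N(0, s^2) variable truncated to [a, b] (closed form)
truncnorm_var <- function(s, a, b) {
  al <- a / s
  be <- b / s
  Z <- pnorm(be) - pnorm(al)
  mu <- (dnorm(al) - dnorm(be)) / Z
  s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - mu^2)
}
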