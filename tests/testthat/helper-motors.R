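# Shared fixtures and independent oracles for the test suite.

PRESET_NAMES <- c("DmK", "Bovine", "HsK", "HsK-6AA", "HsK-CL",
                  "HsK-CL-6AA", "KIF17")
WT_NAMES <- c("DmK", "Bovine", "HsK", "HsK-CL")

KBT298 <- 0.0138065 * 298

# Independent dwell-time oracle: partial sum over the number n of ATP
# hydrolyses preceding a mechanical step.  Each hydrolysis takes mean time
# 1/(k+ + k-); the step completes at hydrolysis n with probability
# p q^(n-1), where p is the per-hydrolysis stepping probability and
# q = 1 - p.  Generalised to escape probabilities < 1.
dwell_series_oracle <- function(force, params, n_terms = 5000) {
  kp <- params$k_plus
  km <- params$k_minus
  rho <- params$r0^(1 - force / params$FS)
  P00 <- params$P0_zero
  P0F <- 1 - (1 - P00) * exp(-abs(force) * params$delta / KBT298)
  PE <- rho / (rho + kp / km)
  p0f <- if (force >= 0) P00 else P0F
  p0b <- if (force >= 0) P0F else P00
  A <- p0f * PE * kp + p0b * (1 - PE) * km   # stepping rate
  ktot <- kp + km
  n <- seq_len(n_terms)
  p_step <- A / ktot                          # per-hydrolysis step probability
  sum(n / ktot * p_step * (1 - p_step)^(n - 1))
}

# Minimal hand-built trace for bead-convention tests.
fake_trace <- function(events, force = 2, name = "HsK-CL-6AA",
                       t_max = 1) {
  params <- motor_preset(name)
  structure(
    list(events = events,
         com_samples = tibble::tibble(time = c(0, t_max),
                                      com_nm = c(0, 0)),
         counts = tibble::tibble(n_hyd = 0, n_fwd = 0, n_back = 0,
                                 n_futile = 0, com_end = 0),
         params = params, conditions = conditions(force = force),
         t_max = t_max, t_burn = 0, seed = 0, engine = "exact", dt = 0),
    class = "kin_trace"
  )
}

event_row <- function(time, kind, detail = -1L, com = 0) {
  tibble::tibble(time = time,
                 kind = factor(kind, levels = c(
                   "ATP_BIND", "ATP_DISSOC", "HYDROLYSIS_TRAILING",
                   "HYDROLYSIS_LEADING", "DETACH_TO_INT", "REBIND_FORWARD",
                   "REBIND_BACKWARD", "REBIND_SAME")),
                 detail = as.integer(detail), com_nm = com)
}

# Piecewise-constant series from explicit levels (value, duration).
staircase_series <- function(levels, durations, dt = 5e-4) {
  time <- numeric(0)
  pos <- numeric(0)
  t0 <- 0
  for (i in seq_along(levels)) {
    tt <- seq(t0, t0 + durations[i] - dt / 2, by = dt)
    time <- c(time, tt)
    pos <- c(pos, rep(levels[i], length(tt)))
    t0 <- t0 + durations[i]
  }
  tibble::tibble(time = time, position_nm = pos)
}
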