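EVENT_KINDS <- c("ATP_BIND", "ATP_DISSOC", "HYDROLYSIS_TRAILING",
                 "HYDROLYSIS_LEADING", "DETACH_TO_INT", "REBIND_FORWARD",
                 "REBIND_BACKWARD", "REBIND_SAME")

# Resolve the side-dependent escape probabilities and rebinding probability
# for the engine: a backward load acts only on the leading head, an
# assisting load only on the trailing head, so exactly one side carries the
# force-dependent P0(F) while the other keeps P0(0).
engine_probs <- function(params, force) {
  P00 <- params$P0_zero
  P0F <- kin_p_escape(force, params)
  list(
    p0_trail = if (force < 0) P0F else P00,
    p0_lead = if (force > 0) P0F else P00,
    pe = kin_p_forward(force, params)
  )
}

check_timestep <- function(params, cond, dt) {
  rates <- c(k_plus = params$k_plus, k_minus = params$k_minus)
  if (!is.infinite(cond$atp)) {
    rates <- c(rates,
               binding = params$kb * cond$atp,
               k_off_leading = params$k_off_leading,
               k_off_other = params$k_off_other)
  }
  bad <- rates[rates * dt >= 0.01]
  if (length(bad)) {
    stop("Fixed-timestep stability violated: rate * dt must stay below ",
         "0.01 but ", paste0(names(bad), " * dt = ",
                             signif(bad * dt, 3), collapse = ", "),
         ". Reduce `dt` or use the exact event-driven engine ",
         "(engine = \"exact\" / exact_trace()).", call. = FALSE)
  }
  invisible(TRUE)
}

run_engine <- function(params, cond, t_max, seed, dt, t_burn,
                       sample_times, record_events) {
  pr <- engine_probs(params, cond$force)
  saturating <- is.infinite(cond$atp)
  kbA <- if (saturating) Inf else params$kb * cond$atp
  set.seed(seed)
  sim_trace_cpp(
    k_plus = params$k_plus, k_minus = params$k_minus,
    p0_trail = pr$p0_trail, p0_lead = pr$p0_lead, pe = pr$pe,
    kbA = if (saturating) 0 else kbA,
    k1 = params$k_off_leading, k2 = params$k_off_other,
    d = params$d, saturating = saturating,
    t_max = t_max, dt = dt, t_burn = t_burn,
    sample_times = sample_times, record_events = record_events
  )
}

trace_sample_grid <- function(t_max, t_burn, n_samples) {
  sort(unique(c(t_burn, seq(0, t_max, length.out = n_samples))))
}

build_trace <- function(raw, params, cond, t_max, t_burn, seed, engine,
                        dt, sample_times) {
  events <- tibble::tibble(
    time = raw$event_time,
    kind = factor(EVENT_KINDS[raw$event_kind], levels = EVENT_KINDS),
    detail = raw$event_detail,
    com_nm = raw$event_com
  )
  structure(
    list(events = events,
         com_samples = tibble::tibble(time = sample_times,
                                      com_nm = raw$com_samples),
         counts = tibble::tibble(n_hyd = raw$n_hyd, n_fwd = raw$n_fwd,
                                 n_back = raw$n_back,
                                 n_futile = raw$n_futile,
                                 com_end = raw$com_end),
         params = params, conditions = cond, t_max = t_max,
         t_burn = t_burn, seed = seed, engine = engine, dt = dt),
    class = "kin_trace"
  )
}

#' Simulate one stepping trace (fixed timestep)
#'
#' Runs the chemomechanical cycle with the fixed-timestep scheme
#' (default dt = 1e-4 s): per timestep each head draws one uniform variate
#' per candidate transition, at most one chemical transition fires per
#' head per step, and the instantaneous cascades (detachment to the
#' one-head-bound intermediate, docking, rebinding, ADP release) resolve
#' within the same step. Every active rate must satisfy rate * dt < 0.01;
#' otherwise an error directs to [exact_trace()].
#'
#' @param params A `motor_params` object, preset name, or parameter list.
#' @param cond A [conditions()] object (force, ATP concentration).
#' @param t_max Simulated time, s.
#' @param seed Integer RNG seed; traces are bit-reproducible given the
#'   seed.
#' @param dt Timestep, s.
#' @param t_burn Burn-in discarded from the event counters, s (default 1%
#'   of `t_max`; the position series is kept in full).
#' @param n_samples Number of uniformly spaced centre-of-mass samples
#'   retained.
#' @return A `kin_trace` object: `events` (time, kind, detail, position),
#'   `com_samples` (sampled centre-of-mass series), `counts` (hydrolyses,
#'   forward/backward steps, futile cycles after burn-in), and the full
#'   provenance (parameters, conditions, seed, engine, dt).
#' @examples
#' tr <- simulate_trace("HsK-CL-6AA", conditions(force = 0, atp = 10),
#'                      t_max = 2, seed = 1)
#' tr$counts
#' @export
simulate_trace <- function(params, cond = conditions(), t_max = 10,
                           seed = 1, dt = 1e-4, t_burn = 0.01 * t_max,
                           n_samples = 201) {
  params <- as_motor_params(params)
  stopifnot(inherits(cond, "motor_conditions"))
  if (!is.numeric(t_max) || t_max <= 0) {
    stop("`t_max` must be positive.", call. = FALSE)
  }
  check_timestep(params, cond, dt)
  grid <- trace_sample_grid(t_max, t_burn, n_samples)
  raw <- run_engine(params, cond, t_max, seed, dt, t_burn, grid,
                    record_events = TRUE)
  build_trace(raw, params, cond, t_max, t_burn, seed, "fixed", dt, grid)
}

#' Simulate one stepping trace (exact event-driven engine)
#'
#' Continuous-time simulation of the identical Markov state machine with
#' exponential waiting times (Gillespie scheme); distributionally the
#' limit of [simulate_trace()] as dt -> 0, with no timestep constraint.
#'
#' @inheritParams simulate_trace
#' @return A `kin_trace` object (see [simulate_trace()]).
#' @examples
#' tr <- exact_trace("KIF17", conditions(force = 2), t_max = 5, seed = 7)
#' head(tr$events)
#' @export
exact_trace <- function(params, cond = conditions(), t_max = 10,
                        seed = 1, t_burn = 0.01 * t_max, n_samples = 201) {
  params <- as_motor_params(params)
  stopifnot(inherits(cond, "motor_conditions"))
  if (!is.numeric(t_max) || t_max <= 0) {
    stop("`t_max` must be positive.", call. = FALSE)
  }
  grid <- trace_sample_grid(t_max, t_burn, n_samples)
  raw <- run_engine(params, cond, t_max, seed, dt = 0, t_burn, grid,
                    record_events = TRUE)
  build_trace(raw, params, cond, t_max, t_burn, seed, "exact", dt = 0, grid)
}

#' @export
print.kin_trace <- function(x, ...) {
  cat(sprintf("<kin_trace: %s, F = %g pN, [ATP] = %s, %g s, %s engine, seed %d>\n",
              x$params$name, x$conditions$force,
              if (is.infinite(x$conditions$atp)) "saturating"
              else paste0(x$conditions$atp, " uM"),
              x$t_max, x$engine, x$seed))
  cat(sprintf("  %d events; %d forward / %d backward steps, %d hydrolyses (post burn-in)\n",
              nrow(x$events), x$counts$n_fwd, x$counts$n_back,
              x$counts$n_hyd))
  invisible(x)
}

#' Simulate an ensemble of independent traces
#'
#' Runs `n_traces` independent traces with per-trace seeds
#' `base_seed + index` and collects per-trace summary counts plus the
#' sampled centre-of-mass series (event logs are not retained, keeping
#' large ensembles light). Use [summarize_traces()] for ensemble means
#' and SEMs.
#'
#' @inheritParams simulate_trace
#' @param n_traces Number of independent traces.
#' @param base_seed Base RNG seed; trace i uses `base_seed + i`.
#' @param engine `"exact"` (event-driven, default) or `"fixed"`
#'   (fixed-timestep; subject to the rate * dt < 0.01 stability check).
#' @return A `kin_trace_set`: `per_trace` tibble (counts and end-to-end
#'   velocity per trace), `com` matrix (traces x sample times),
#'   `sample_times`, and provenance.
#' @examples
#' ts <- simulate_ensemble("HsK-CL-6AA", conditions(force = 0),
#'                         t_max = 2, n_traces = 20, base_seed = 42)
#' summarize_traces(ts)
#' @export
simulate_ensemble <- function(params, cond = conditions(), t_max = 10,
                              n_traces = 1000, base_seed = 1,
                              engine = c("exact", "fixed"), dt = 1e-4,
                              t_burn = 0.01 * t_max, n_samples = 201) {
  params <- as_motor_params(params)
  stopifnot(inherits(cond, "motor_conditions"), n_traces >= 1)
  engine <- match.arg(engine)
  if (engine == "fixed") check_timestep(params, cond, dt)
  grid <- trace_sample_grid(t_max, t_burn, n_samples)
  dt_use <- if (engine == "fixed") dt else 0
  com <- matrix(NA_real_, nrow = n_traces, ncol = length(grid))
  per <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    raw <- run_engine(params, cond, t_max, base_seed + i, dt_use, t_burn,
                      grid, record_events = FALSE)
    com[i, ] <- raw$com_samples
    per[[i]] <- c(n_hyd = raw$n_hyd, n_fwd = raw$n_fwd,
                  n_back = raw$n_back, n_futile = raw$n_futile,
                  com_end = raw$com_end)
  }
  per_trace <- tibble::as_tibble(do.call(rbind, per))
  i_burn <- which.min(abs(grid - t_burn))
  span <- t_max - grid[i_burn]
  per_trace$trace <- seq_len(n_traces)
  per_trace$velocity_nm_s <- (com[, length(grid)] - com[, i_burn]) / span
  structure(
    list(per_trace = per_trace[, c("trace", "n_hyd", "n_fwd", "n_back",
                                   "n_futile", "com_end",
                                   "velocity_nm_s")],
         com = com, sample_times = grid, params = params,
         conditions = cond, t_max = t_max, t_burn = t_burn,
         base_seed = base_seed, engine = engine,
         dt = if (engine == "fixed") dt else NA_real_),
    class = "kin_trace_set"
  )
}

#' @export
print.kin_trace_set <- function(x, ...) {
  cat(sprintf("<kin_trace_set: %s, F = %g pN, [ATP] = %s, %d traces x %g s, %s engine, base seed %d>\n",
              x$params$name, x$conditions$force,
              if (is.infinite(x$conditions$atp)) "saturating"
              else paste0(x$conditions$atp, " uM"),
              nrow(x$per_trace), x$t_max, x$engine, x$base_seed))
  cat(sprintf("  mean velocity %.1f nm/s (SEM %.2f)\n",
              mean(x$per_trace$velocity_nm_s),
              stats::sd(x$per_trace$velocity_nm_s) /
                sqrt(nrow(x$per_trace))))
  invisible(x)
}
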