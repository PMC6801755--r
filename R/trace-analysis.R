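#' Bead position series from a simulated trace
#'
#' Converts a trace's event log into the position an optical-trap bead
#' would report, sampled uniformly (default 2 kHz, the acquisition rate
#' of the single-molecule recordings the step-detection convention was
#' designed for).
#'
#' Under backward load (F > 0) the bead follows the head farther from it:
#' moves of the rear head to/from the one-head-bound intermediate produce
#' no bead displacement, a rebind from the intermediate to the front site
#' reads +d, and detachment of the front head to the intermediate reads
#' -d. Under zero or assisting load (F <= 0) the centre-of-mass
#' convention is used instead (the convention switch at F = 0 follows the
#' analytic results, which are all centre-of-mass quantities).
#'
#' @param trace A `kin_trace` object.
#' @param sample_rate Sampling rate, Hz.
#' @return A tibble with columns `time` (s) and `position_nm`.
#' @examples
#' tr <- exact_trace("HsK-CL-6AA", conditions(force = 2, atp = 20),
#'                   t_max = 1, seed = 3)
#' bead_position_series(tr)
#' @export
bead_position_series <- function(trace, sample_rate = 2000) {
  stopifnot(inherits(trace, "kin_trace"), sample_rate > 0)
  t_grid <- seq(0, trace$t_max, by = 1 / sample_rate)
  ev <- trace$events
  if (nrow(ev) == 0) {
    return(tibble::tibble(time = t_grid, position_nm = 0))
  }
  d <- trace$params$d
  if (trace$conditions$force > 0) {
    delta <- numeric(nrow(ev))
    delta[ev$kind == "DETACH_TO_INT" & ev$detail == 1L] <- -d
    delta[ev$kind == "REBIND_FORWARD"] <- d
    delta[ev$kind == "REBIND_SAME" & ev$detail == 1L] <- d
    pos <- cumsum(delta)
  } else {
    pos <- ev$com_nm
  }
  idx <- findInterval(t_grid, ev$time)
  tibble::tibble(time = t_grid,
                 position_nm = c(0, pos)[idx + 1L])
}

#' Detect mechanical steps in a position series
#'
#' Applies the dwell-based step-calling convention: a level change counts
#' as a step only if the new level persists longer than `min_dwell`
#' (default 0.5 ms); shorter excursions are merged with the surrounding
#' level. Level changes of more than one step size are counted as that
#' many steps in the same direction.
#'
#' @param series A tibble with columns `time` and `position_nm`
#'   (piecewise-constant positions on the step-size lattice), as returned
#'   by [bead_position_series()].
#' @param min_dwell Minimum dwell for a level to count, s.
#' @param step_size Lattice spacing, nm.
#' @return A `kin_steps` object: counts of forward and backward steps,
#'   `step_times` (time and direction of each call), and the dwell times
#'   between consecutive calls.
#' @examples
#' s <- tibble::tibble(time = seq(0, 0.1, by = 5e-4),
#'                     position_nm = 8.2 * (seq(0, 0.1, by = 5e-4) %/% 0.02))
#' detect_steps(s)
#' @export
detect_steps <- function(series, min_dwell = 5e-4, step_size = 8.2) {
  stopifnot(all(c("time", "position_nm") %in% names(series)),
            min_dwell >= 0)
  time <- series$time
  pos <- series$position_nm
  empty <- function() {
    structure(list(forward_steps = 0L, backward_steps = 0L,
                   step_times = tibble::tibble(time = numeric(),
                                               direction = integer()),
                   dwell_times = numeric()),
              class = "kin_steps")
  }
  if (length(time) == 0) return(empty())
  # run-length encode into levels
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  dt_sample <- if (length(time) > 1) stats::median(diff(time)) else 0
  level_start <- time[starts]
  level_end <- c(time[starts[-1]], time[length(time)] + dt_sample)
  duration <- level_end - level_start
  keep <- duration > min_dwell
  if (!any(keep)) return(empty())
  vals <- r$values[keep]
  t0 <- level_start[keep]
  # collapse consecutive retained levels with the same value (separated
  # only by sub-threshold excursions)
  same <- c(FALSE, vals[-1] == vals[-length(vals)])
  vals <- vals[!same]
  t0 <- t0[!same]
  if (length(vals) < 2) return(empty())
  delta <- diff(vals)
  n_sub <- round(abs(delta) / step_size)
  dir <- sign(delta)
  step_times <- tibble::tibble(
    time = rep(t0[-1], n_sub),
    direction = as.integer(rep(dir, n_sub))
  )
  structure(
    list(forward_steps = sum(step_times$direction > 0),
         backward_steps = sum(step_times$direction < 0),
         step_times = step_times,
         dwell_times = diff(step_times$time)),
    class = "kin_steps"
  )
}

#' @export
print.kin_steps <- function(x, ...) {
  ratio <- if (x$backward_steps > 0) {
    sprintf("%.2f", x$forward_steps / x$backward_steps)
  } else "Inf"
  cat(sprintf("<kin_steps: %d forward, %d backward (ratio %s)>\n",
              x$forward_steps, x$backward_steps, ratio))
  invisible(x)
}

#' Ensemble observables from simulated traces
#'
#' Reduces a [simulate_ensemble()] trace set to the experiment-style
#' observables with standard errors: velocity (end-to-end displacement
#' over time, averaged over traces), stepping ratio (pooled
#' forward/backward step counts), diffusion constant (slope of the
#' ensemble position variance over the second half of the traces, where
#' the initial-condition transient has decayed), randomness parameter
#' (2D/(v d)), ATP consumed per step and per forward step (hydrolysis
#' events over step counts), and the total hydrolysis rate.
#'
#' SEMs: velocity, N, NF and hydrolysis rate across traces; the stepping
#' ratio by count propagation (r sqrt(1/n_fwd + 1/n_back)); D by a
#' 10-block jackknife over traces; randomness by propagation from v and
#' D.
#'
#' @param trace_set A `kin_trace_set` from [simulate_ensemble()].
#' @param n_blocks Number of trace blocks for the D jackknife.
#' @return A one-row tibble keyed by (motor, force, ATP) with value and
#'   `*_sem` columns; `ratio` is `Inf` (flagged by `ratio_defined =
#'   FALSE`) when no backward steps occurred.
#' @examples
#' ts <- simulate_ensemble("KIF17", conditions(force = 2), t_max = 2,
#'                         n_traces = 20, base_seed = 5)
#' summarize_traces(ts)
#' @export
summarize_traces <- function(trace_set, n_blocks = 10) {
  stopifnot(inherits(trace_set, "kin_trace_set"))
  pt <- trace_set$per_trace
  n <- nrow(pt)
  d <- trace_set$params$d
  span <- trace_set$t_max - trace_set$t_burn

  mean_sem <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  }
  v <- mean_sem(pt$velocity_nm_s)

  nf <- sum(pt$n_fwd)
  nb <- sum(pt$n_back)
  ratio_defined <- nb > 0 && nf > 0
  ratio <- if (nb > 0) nf / nb else Inf
  ratio_sem <- if (ratio_defined) ratio * sqrt(1 / nf + 1 / nb) else NA_real_

  # D from the ensemble variance growth over the second half of the run;
  # blocks need at least two traces each for a variance
  n_blocks <- max(min(n_blocks, n %/% 2), 1)
  half <- trace_set$sample_times >= trace_set$t_max / 2
  D_of <- function(rows) {
    vv <- apply(trace_set$com[rows, half, drop = FALSE], 2, stats::var)
    unname(stats::coef(stats::lm(vv ~ trace_set$sample_times[half]))[2]) / 2
  }
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  if (n >= 2) {
    D_hat <- D_of(seq_len(n))
    D_blocks <- vapply(blocks, D_of, numeric(1))
    D_sem <- if (n_blocks >= 2) {
      stats::sd(D_blocks) / sqrt(length(D_blocks))
    } else {
      NA_real_
    }
  } else {
    D_hat <- NA_real_
    D_sem <- NA_real_
  }

  R_hat <- 2 * D_hat / (v[["mean"]] * d)
  R_sem <- abs(R_hat) * sqrt((D_sem / D_hat)^2 + (v[["sem"]] / v[["mean"]])^2)

  # N and NF from pooled totals (per-trace ratios are biased at finite
  # step counts); SEM by the same block jackknife as D
  steps <- pt$n_fwd + pt$n_back
  pooled_sem <- function(num, den) {
    if (sum(den) == 0) return(c(mean = NA_real_, sem = NA_real_))
    vals <- vapply(blocks, function(i) sum(num[i]) / sum(den[i]),
                   numeric(1))
    c(mean = sum(num) / sum(den),
      sem = stats::sd(vals) / sqrt(length(vals)))
  }
  N_hat <- pooled_sem(pt$n_hyd, steps)
  NF_hat <- pooled_sem(pt$n_hyd, pt$n_fwd)
  hyd <- mean_sem(pt$n_hyd / span)

  tibble::tibble(
    name = trace_set$params$name,
    force_pN = trace_set$conditions$force,
    atp_uM = trace_set$conditions$atp,
    n_traces = n,
    t_max_s = trace_set$t_max,
    velocity_nm_s = v[["mean"]], velocity_sem = v[["sem"]],
    ratio = ratio, ratio_sem = ratio_sem, ratio_defined = ratio_defined,
    D_nm2_s = D_hat, D_sem = D_sem,
    randomness = R_hat, randomness_sem = R_sem,
    N = N_hat[["mean"]], N_sem = N_hat[["sem"]],
    NF = NF_hat[["mean"]], NF_sem = NF_hat[["sem"]],
    hydrolysis_rate_s = hyd[["mean"]],
    hydrolysis_rate_sem = hyd[["sem"]]
  )
}
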