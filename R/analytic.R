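#' @useDynLib kinesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

as_motor_params <- function(params) {
  if (inherits(params, "motor_params")) return(params)
  if (is.character(params) && length(params) == 1L) {
    return(motor_preset(params))
  }
  if (is.list(params)) return(do.call(make_motor_params, params))
  stop("`params` must be a motor_params object, a preset name, or a list ",
       "of fields.", call. = FALSE)
}

# Forward and backward stepping rates (s^-1) at saturating ATP.
#
# The whole closed-form theory reduces to these two rates:
#   forward  = P0_fwd * PE(F) * k(+)
#   backward = P0_back * (1 - PE(F)) * k(-)
# where PE = rho / (rho + k(+)/k(-)) with the reduced ratio
# rho = r0^(1 - F/FS) -- r0 raised to the power (1 - F/FS), i.e. the
# exponential r0 exp(-beta d(+) F) rewritten through FS = ln(r0)/(beta d(+)).
# A backward force (F > 0) acts only on the leading head, so only the
# backward branch feels the force-dependent escape probability P0(F);
# a forward force (F < 0) acts only on the trailing head, mirroring the
# roles. Both branches coincide at F = 0.
stepping_rates <- function(force, params) {
  params <- as_motor_params(params)
  rho <- kin_reduced_ratio(force, params)
  P00 <- params$P0_zero
  P0F <- kin_p_escape(force, params)
  PE <- kin_p_forward(force, params)
  p0_fwd <- ifelse(force >= 0, P00, P0F)
  p0_back <- ifelse(force >= 0, P0F, P00)
  list(forward = p0_fwd * PE * params$k_plus,
       backward = p0_back * (1 - PE) * params$k_minus)
}

#' Reduced stepping ratio
#'
#' The force-dependent factor `r0^(1 - F/FS)`: equal to `r0` at zero
#' force, 1 at `F = FS`, strictly decreasing in force. For wild-type
#' motors this is the stepping ratio itself.
#'
#' @param force External force, pN (vectorised; positive = backward).
#' @param params A `motor_params` object, preset name, or parameter list.
#' @return Numeric vector.
#' @examples
#' kin_reduced_ratio(c(0, 4, 8), motor_preset("DmK"))
#' @export
kin_reduced_ratio <- function(force, params) {
  params <- as_motor_params(params)
  params$r0^(1 - force / params$FS)
}

#' Escape probability P0(F)
#'
#' Probability that, within the brief low-affinity window after phosphate
#' release, the ADP-head escapes its binding site. Force-independent (and
#' equal to 1) for wild-type motors; for extended-neck-linker mutants it
#' rises from `P0_zero` toward 1 with the magnitude of the load:
#' `P0(F) = 1 - (1 - P0(0)) exp(-|F| delta / kBT)`.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector of probabilities in `[P0_zero, 1]`.
#' @examples
#' kin_p_escape(2, motor_preset("HsK-6AA"))
#' @export
kin_p_escape <- function(force, params) {
  params <- as_motor_params(params)
  beta <- thermal_scale(params$temperature)$beta
  1 - (1 - params$P0_zero) * exp(-beta * abs(force) * params$delta)
}

#' Forward-rebinding probability PE(F)
#'
#' Probability that the detached head in the intermediate one-head-bound
#' state rebinds to the forward rather than the rearward site:
#' `PE = rho / (rho + k(+)/k(-))` with `rho = r0^(1 - F/FS)`. Returns 1
#' when `k_minus = 0` (no backward pathway, the limiting case).
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector of probabilities in (0, 1].
#' @examples
#' kin_p_forward(0, motor_preset("DmK"))
#' @export
kin_p_forward <- function(force, params) {
  params <- as_motor_params(params)
  if (params$k_minus == 0) {
    return(rep(1, length(force)))
  }
  rho <- kin_reduced_ratio(force, params)
  rho / (rho + params$k_plus / params$k_minus)
}

#' Stepping ratio r(F)
#'
#' Ratio of forward to backward steps. For wild-type motors this is the
#' reduced ratio `r0^(1 - F/FS)`; for mutants the escape probabilities of
#' the two heads no longer cancel and
#' `r = rho P0(0)/P0(F)` for backward load (`rho P0(F)/P0(0)` for
#' assisting load).
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector (dimensionless).
#' @examples
#' kin_stepping_ratio(c(0, 2), motor_preset("HsK-6AA"))
#' @export
kin_stepping_ratio <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  if (params$k_minus == 0) {
    return(rep(Inf, length(force)))
  }
  rt$forward / rt$backward
}

#' Velocity v(F)
#'
#' Mean velocity at saturating ATP: (forward rate - backward rate) times
#' the step size. Negative values indicate net backward motion beyond
#' stall.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector, nm/s.
#' @examples
#' kin_velocity(0, motor_preset("DmK")) # 751.4 nm/s
#' @export
kin_velocity <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  (rt$forward - rt$backward) * params$d
}

#' Mean dwell time between mechanical steps
#'
#' Reciprocal of the total stepping rate (forward + backward). For
#' wild-type motors this is the closed form of the dwell-time series over
#' the number of ATP hydrolyses preceding a step; for mutants the same
#' reciprocal generalises it.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector, s.
#' @examples
#' kin_dwell_time(0, motor_preset("Bovine")) # 8.7 ms
#' @export
kin_dwell_time <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  total <- rt$forward + rt$backward
  if (any(total <= 0)) {
    stop("Total stepping rate is zero; dwell time undefined.", call. = FALSE)
  }
  1 / total
}

#' Diffusion constant D(F)
#'
#' Long-time diffusion constant of the centre-of-mass position,
#' `(forward + backward) d^2 / 2`; strictly positive.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector, nm^2/s.
#' @examples
#' kin_diffusion(0, motor_preset("DmK"))
#' @export
kin_diffusion <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  (rt$forward + rt$backward) * params$d^2 / 2
}

#' Randomness parameter R(F)
#'
#' Dimensionless stepping irregularity `R = 2D/(v d)`, equal to
#' (forward + backward)/(forward - backward); 1 for a Poisson stepper,
#' diverging at stall where the net rate vanishes.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector (dimensionless).
#' @examples
#' kin_randomness(0, motor_preset("DmK"))
#' @export
kin_randomness <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  net <- rt$forward - rt$backward
  if (any(abs(net) < 1e-12 * (rt$forward + rt$backward))) {
    stop("Randomness parameter diverges at stall (net stepping rate ~ 0).",
         call. = FALSE)
  }
  (rt$forward + rt$backward) / net
}

#' ATP consumed per forward step
#'
#' Mean number of ATP molecules hydrolysed per forward step,
#' `NF = (k(+) + k(-)) / forward rate`; at least 1, and well above 1 for
#' loosely coupled mutants where futile hydrolyses are common.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector (ATP per forward step).
#' @examples
#' kin_atp_per_forward_step(0, motor_preset("HsK-CL-6AA")) # ~3.3
#' @export
kin_atp_per_forward_step <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  (params$k_plus + params$k_minus) / rt$forward
}

#' ATP consumed per mechanical step
#'
#' Mean number of ATP molecules hydrolysed per step, forward or backward:
#' `N = (k(+) + k(-)) / (forward + backward)`; never exceeds the
#' per-forward-step count.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector (ATP per step).
#' @examples
#' kin_atp_per_step(0, motor_preset("KIF17")) # ~1.8
#' @export
kin_atp_per_step <- function(force, params) {
  params <- as_motor_params(params)
  rt <- stepping_rates(force, params)
  (params$k_plus + params$k_minus) / (rt$forward + rt$backward)
}

#' Power output
#'
#' Mechanical power delivered against the load, `(v/d rates) F d`,
#' expressed in kBT/s. Zero at zero force and at stall, with a single
#' interior maximum between.
#'
#' @inheritParams kin_reduced_ratio
#' @return Numeric vector, kBT/s.
#' @examples
#' kin_power(2, motor_preset("HsK-CL-6AA"))
#' @export
kin_power <- function(force, params) {
  params <- as_motor_params(params)
  kBT <- thermal_scale(params$temperature)$kBT
  kin_velocity(force, params) * force / kBT
}

#' Thermodynamic efficiency
#'
#' `eta = W / ((k(+) + k(-)) deltaG)`: output power divided by the free
#' energy consumed per unit time by the constant total ATPase rate
#' `k(+) + k(-)`. `deltaG` is the free energy of one ATP hydrolysis in
#' kBT (20 under physiological conditions).
#'
#' @inheritParams kin_reduced_ratio
#' @param deltaG Free energy per ATP, kBT (default 20).
#' @return Numeric vector (dimensionless fraction).
#' @examples
#' kin_efficiency(2, motor_preset("HsK")) # ~0.16
#' @export
kin_efficiency <- function(force, params, deltaG = 20) {
  stopifnot(is.numeric(deltaG), deltaG > 0)
  params <- as_motor_params(params)
  kin_power(force, params) / ((params$k_plus + params$k_minus) * deltaG)
}

#' Stall force
#'
#' The backward force at which forward and backward stepping rates
#' balance (zero net velocity). Equals `FS` exactly for wild-type motors;
#' for extended-neck-linker mutants the force-assisted escape of the
#' leading head shifts stall below `FS`, and the root is located by
#' bisection to 1e-6 pN.
#'
#' @param params A `motor_params` object, preset name, or parameter list.
#' @return Stall force, pN.
#' @examples
#' kin_stall_force(motor_preset("HsK"))     # 7 (wild type)
#' kin_stall_force(motor_preset("HsK-6AA")) # ~6.03
#' @export
kin_stall_force <- function(params) {
  params <- as_motor_params(params)
  if (params$P0_zero == 1) {
    return(params$FS)
  }
  f <- function(force) {
    rt <- stepping_rates(force, params)
    rt$forward - rt$backward
  }
  lo <- 0
  hi <- params$FS
  if (f(lo) <= 0 || f(hi) >= 0) {
    stop("No sign change on [0, FS]; cannot bracket the stall force.",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Maximum power and the force at which it occurs
#'
#' Locates the maximum of the power-force curve on (0, stall force) by
#' bounded scalar maximisation.
#'
#' @inheritParams kin_stall_force
#' @return A tibble with columns `name`, `force_pN` (location of the
#'   maximum) and `power_kBT_s`.
#' @examples
#' kin_max_power(motor_preset("KIF17")) # ~552.6 kBT/s
#' @export
kin_max_power <- function(params) {
  params <- as_motor_params(params)
  stall <- kin_stall_force(params)
  opt <- stats::optimize(function(f) kin_power(f, params),
                         interval = c(0, stall), maximum = TRUE,
                         tol = 1e-9)
  tibble::tibble(name = params$name,
                 force_pN = opt$maximum,
                 power_kBT_s = opt$objective)
}

#' Neck-linker docking energy
#'
#' The energy barrier supplied by neck-linker docking against backward
#' rebinding, inferred from the zero-force stepping ratio:
#' `ED = kBT ln(r0 k(-)/k(+))`. If parameter uncertainties are stored,
#' a first-order propagated error
#' `(dr0/r0 + dk(-)/k(-) + dk(+)/k(+)) kBT` is attached.
#'
#' @inheritParams kin_stall_force
#' @return A tibble with columns `name`, `ED_kBT` and `ED_err_kBT`
#'   (NA when no uncertainties are stored).
#' @examples
#' kin_docking_energy(motor_preset("DmK")) # 3.34 +/- 0.28 kBT
#' @export
kin_docking_energy <- function(params) {
  params <- as_motor_params(params)
  if (params$k_minus <= 0) {
    stop("Docking energy undefined for k_minus = 0.", call. = FALSE)
  }
  ed <- log(params$r0 * params$k_minus / params$k_plus)
  err <- NA_real_
  u <- params$uncertainties
  if (!is.null(u) && all(c("r0", "k_plus", "k_minus") %in% names(u))) {
    err <- u$r0 / params$r0 + u$k_minus / params$k_minus +
      u$k_plus / params$k_plus
  }
  tibble::tibble(name = params$name, ED_kBT = ed, ED_err_kBT = err)
}

#' Characteristic distance of forward rebinding
#'
#' The distance `d(+) = kBT ln(r0) / FS` over which a backward load tilts
#' the intermediate-state rebinding; about half a step for wild-type
#' kinesin-1.
#'
#' @inheritParams kin_stall_force
#' @return Distance, nm.
#' @examples
#' kin_characteristic_distance(
#'   make_motor_params(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4)
#' ) # ~4 nm
#' @export
kin_characteristic_distance <- function(params) {
  params <- as_motor_params(params)
  thermal_scale(params$temperature)$kBT * log(params$r0) / params$FS
}

#' Scan the closed-form observables over a force grid
#'
#' Evaluates every saturating-ATP observable of the model on a grid of
#' forces and returns them as one tidy tibble, the package's curve-scan
#' entry point. Quantities that diverge at stall (`ratio` with
#' `k_minus = 0`, `randomness` at zero net rate) are returned as `Inf`
#' rather than raising.
#'
#' @param params A `motor_params` object, preset name, or parameter list.
#' @param force Numeric vector of forces, pN.
#' @param deltaG Free energy per ATP for the efficiency column, kBT.
#' @return A tibble with columns `name`, `force_pN`, `ratio`,
#'   `velocity_nm_s`, `dwell_s`, `D_nm2_s`, `randomness`, `NF`, `N`,
#'   `power_kBT_s`, `efficiency`.
#' @examples
#' kin_scan("DmK", force = seq(0, 8, by = 2))
#' @export
kin_scan <- function(params, force = seq(0, 7, by = 0.5), deltaG = 20) {
  params <- as_motor_params(params)
  stopifnot(is.numeric(force), length(force) >= 1)
  rt <- stepping_rates(force, params)
  net <- rt$forward - rt$backward
  total <- rt$forward + rt$backward
  ktot <- params$k_plus + params$k_minus
  kBT <- thermal_scale(params$temperature)$kBT
  out <- tibble::tibble(
    name = params$name,
    force_pN = force,
    ratio = ifelse(rt$backward > 0, rt$forward / rt$backward, Inf),
    velocity_nm_s = net * params$d,
    dwell_s = 1 / total,
    D_nm2_s = total * params$d^2 / 2,
    randomness = ifelse(abs(net) > 1e-12 * total, total / net, Inf),
    NF = ktot / rt$forward,
    N = ktot / total,
    power_kBT_s = net * params$d * force / kBT,
    efficiency = net * params$d * force / kBT / (ktot * deltaG)
  )
  class(out) <- c("kin_scan", class(out))
  out
}
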