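# Construct a motor_params object from a named parameter vector without
# re-validation (optimizer-internal; bounds keep proposals in range).
quick_params <- function(th, template) {
  out <- template
  for (nm in names(th)) out[[nm]] <- th[[nm]]
  out
}

FIT_BOUNDS <- list(
  r0 = c(1 + 1e-6, 1e5),
  FS = c(0.5, 20),
  k_plus = c(0.1, 1e4),
  k_minus = c(0.1, 1e4),
  P0_zero = c(0.01, 1)
)

DEFAULT_INIT <- c(r0 = 500, FS = 6, k_plus = 100, k_minus = 4,
                  P0_zero = 0.5)

# Deterministic multiplicative jitters for multi-start fitting; the
# r0-FS ridge (they enter only through ln(r0)/FS near stall) makes a
# single start unreliable.
start_grid <- function(init, n_starts = 5) {
  factors <- matrix(c(1, 1, 1, 1, 1,
                      0.6, 1.3, 0.8, 1.2, 1,
                      1.5, 0.75, 1.25, 0.8, 1,
                      0.8, 1.1, 1.4, 0.7, 0.9,
                      1.2, 0.9, 0.7, 1.4, 1.1),
                    nrow = 5, byrow = TRUE)
  lapply(seq_len(min(n_starts, 5)), function(i) {
    f <- factors[i, seq_along(init)]
    pmin(pmax(init * f,
              vapply(names(init), function(p) FIT_BOUNDS[[p]][1], 0) * 1.001),
         vapply(names(init), function(p) FIT_BOUNDS[[p]][2], 0) * 0.999)
  })
}

run_nls <- function(residual_fn, init, free) {
  lower <- vapply(free, function(p) FIT_BOUNDS[[p]][1], numeric(1))
  upper <- vapply(free, function(p) FIT_BOUNDS[[p]][2], numeric(1))
  best <- NULL
  for (start in start_grid(init[free])) {
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("All optimisation starts failed.", call. = FALSE)
  }
  best
}

make_fit_result <- function(fit, free, fixed, n_obs, model, data) {
  est <- stats::setNames(as.numeric(fit$par), free)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(free)))
  se <- stats::setNames(as.numeric(se), free)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("Fit did not converge cleanly: ", fit$message, call. = FALSE)
  }
  structure(
    list(estimates = est, std_errors = se, rss = fit$deviance,
         n_obs = n_obs, df_residual = n_obs - length(free),
         converged = converged, message = fit$message,
         fixed = fixed, free = free, model = model, data = data),
    class = "kin_fit"
  )
}

#' Generate a synthetic force-velocity dataset
#'
#' Evaluates the closed-form velocity on a force grid and applies
#' multiplicative Gaussian noise with coefficient of variation
#' `noise_cv`; the per-point uncertainty `|v| * noise_cv` is recorded as
#' `sigma_nm_s` when `noise_cv > 0`. Used for parameter-recovery studies
#' of the fitting routines.
#'
#' @param params A `motor_params` object, preset name, or parameter list.
#' @param forces Numeric vector of forces, pN.
#' @param noise_cv Coefficient of variation of the noise (0 = exact
#'   curve).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `force_pN`, `velocity_nm_s` and (for
#'   noisy data) `sigma_nm_s`; the generating motor name is attached as
#'   attribute `motor`.
#' @examples
#' generate_synthetic_fv("DmK", seq(-5, 7.5, length.out = 15),
#'                       noise_cv = 0.02, seed = 1)
#' @export
generate_synthetic_fv <- function(params, forces, noise_cv = 0, seed = 1) {
  params <- as_motor_params(params)
  stopifnot(is.numeric(forces), length(forces) >= 1, noise_cv >= 0)
  v <- kin_velocity(forces, params)
  out <- tibble::tibble(force_pN = forces, velocity_nm_s = v)
  if (noise_cv > 0) {
    set.seed(seed)
    out$velocity_nm_s <- v * (1 + stats::rnorm(length(v), sd = noise_cv))
    out$sigma_nm_s <- abs(v) * noise_cv
  }
  attr(out, "motor") <- params$name
  out
}

fv_residuals <- function(data) {
  sigma <- if ("sigma_nm_s" %in% names(data) &&
               all(is.finite(data$sigma_nm_s)) && all(data$sigma_nm_s > 0)) {
    data$sigma_nm_s
  } else {
    rep(1, nrow(data))
  }
  list(force = data$force_pN, v = data$velocity_nm_s, sigma = sigma)
}

#' Fit the force-velocity relation
#'
#' Weighted nonlinear least squares of the saturating-ATP velocity model
#' against (force, velocity) data, estimating any subset of
#' `r0, FS, k_plus, k_minus, P0_zero`. Residuals are
#' `(v_model - v_obs)/sigma` (unit weights when no `sigma_nm_s` column is
#' present). Bounded Levenberg-Marquardt with five deterministic jittered
#' starts guards against the r0-FS ridge; standard errors come from the
#' Jacobian-based covariance at the optimum.
#'
#' When `mutant_data` is supplied, the wild-type and mutant datasets are
#' fitted jointly: both share `r0, FS, k_plus, k_minus`, the wild-type
#' curve has escape probability 1, and `P0_zero` applies to the mutant
#' only (add it to `free_params`).
#'
#' @param data A force-velocity tibble with columns `force_pN`,
#'   `velocity_nm_s` and optionally `sigma_nm_s`.
#' @param free_params Character vector of parameters to estimate.
#' @param fixed_params Named list of parameters to hold fixed.
#' @param init Named numeric vector of starting values for the free
#'   parameters (defaults provided).
#' @param mutant_data Optional second dataset for the joint
#'   wild-type/mutant protocol.
#' @return A `kin_fit` object; see [tidy.kin_fit()] and
#'   [glance.kin_fit()].
#' @examples
#' d <- generate_synthetic_fv("DmK", seq(-5, 7.5, length.out = 15))
#' fit <- fit_force_velocity(d)
#' tidy(fit)
#' @export
fit_force_velocity <- function(data,
                               free_params = c("r0", "FS", "k_plus",
                                               "k_minus"),
                               fixed_params = list(),
                               init = NULL,
                               mutant_data = NULL) {
  joint <- !is.null(mutant_data)
  all_names <- c("r0", "FS", "k_plus", "k_minus", "P0_zero")
  stopifnot(all(free_params %in% all_names))
  if (length(intersect(free_params, names(fixed_params)))) {
    stop("A parameter cannot be both free and fixed.", call. = FALSE)
  }
  need <- if (joint) all_names else setdiff(all_names, "P0_zero")
  missing_p <- setdiff(need, c(free_params, names(fixed_params)))
  if (!joint && "P0_zero" %in% missing_p) missing_p <- setdiff(missing_p, "P0_zero")
  if (length(missing_p)) {
    stop("Parameters neither free nor fixed: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  n_obs <- nrow(data) + if (joint) nrow(mutant_data) else 0L
  if (n_obs < length(free_params)) {
    stop("Under-determined fit: fewer observations than free parameters.",
         call. = FALSE)
  }

  obs <- fv_residuals(data)
  obs_mut <- if (joint) fv_residuals(mutant_data) else NULL
  template <- unclass(make_motor_params(name = "fit", r0 = 2, FS = 5,
                                        k_plus = 100, k_minus = 4))
  base <- stats::setNames(as.numeric(DEFAULT_INIT[free_params]), free_params)
  if (!is.null(init)) base[names(init)] <- init

  residual_fn <- function(th) {
    th <- stats::setNames(as.numeric(th), free_params)
    full <- utils::modifyList(as.list(th), fixed_params)
    if (joint) {
      p_wt <- quick_params(utils::modifyList(full, list(P0_zero = 1)),
                           template)
      p_mut <- quick_params(full, template)
      c((kin_velocity(obs$force, structure(p_wt, class = "motor_params")) -
           obs$v) / obs$sigma,
        (kin_velocity(obs_mut$force,
                      structure(p_mut, class = "motor_params")) -
           obs_mut$v) / obs_mut$sigma)
    } else {
      if (is.null(full$P0_zero)) full$P0_zero <- 1
      p <- structure(quick_params(full, template), class = "motor_params")
      (kin_velocity(obs$force, p) - obs$v) / obs$sigma
    }
  }

  fit <- run_nls(residual_fn, base, free_params)
  make_fit_result(fit, free_params, fixed_params, n_obs,
                  if (joint) "force_velocity_joint" else "force_velocity",
                  data)
}

#' Fit the stepping-ratio relation
#'
#' Least squares on the log stepping ratio, `ln r_obs` versus the model
#' prediction. For a wild-type motor `ln r` is linear in force with slope
#' `-ln(r0)/FS`, so the fit recovers `(r0, FS)`; with a free `P0_zero`
#' the mutant curvature is fitted as well.
#'
#' @param data A tibble with columns `force_pN` and `ratio` (positive).
#' @inheritParams fit_force_velocity
#' @return A `kin_fit` object.
#' @examples
#' d <- tibble::tibble(force_pN = seq(0, 6, by = 0.5),
#'                     ratio = kin_stepping_ratio(seq(0, 6, by = 0.5),
#'       make_motor_params(r0 = 900, FS = 7, k_plus = 90.5, k_minus = 4)))
#' tidy(fit_stepping_ratio(d, free_params = c("r0", "FS"),
#'                         fixed_params = list(k_plus = 90.5, k_minus = 4)))
#' @export
fit_stepping_ratio <- function(data,
                               free_params = c("r0", "FS"),
                               fixed_params = list(k_plus = 100,
                                                   k_minus = 4),
                               init = NULL) {
  stopifnot(all(c("force_pN", "ratio") %in% names(data)))
  if (any(!is.finite(data$ratio) | data$ratio <= 0)) {
    stop("Stepping ratios must be positive and finite for the log-scale ",
         "fit.", call. = FALSE)
  }
  all_names <- c("r0", "FS", "k_plus", "k_minus", "P0_zero")
  stopifnot(all(free_params %in% all_names))
  if (nrow(data) < length(free_params)) {
    stop("Under-determined fit: fewer observations than free parameters.",
         call. = FALSE)
  }
  template <- unclass(make_motor_params(name = "fit", r0 = 2, FS = 5,
                                        k_plus = 100, k_minus = 4))
  base <- stats::setNames(as.numeric(DEFAULT_INIT[free_params]), free_params)
  if (!is.null(init)) base[names(init)] <- init

  residual_fn <- function(th) {
    th <- stats::setNames(as.numeric(th), free_params)
    full <- utils::modifyList(as.list(th), fixed_params)
    if (is.null(full$P0_zero)) full$P0_zero <- 1
    p <- structure(quick_params(full, template), class = "motor_params")
    log(kin_stepping_ratio(data$force_pN, p)) - log(data$ratio)
  }

  fit <- run_nls(residual_fn, base, free_params)
  make_fit_result(fit, free_params, fixed_params, nrow(data),
                  "stepping_ratio", data)
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit: %s, %d obs, RSS %.4g, %s>\n", x$model, x$n_obs,
              x$rss, if (x$converged) "converged" else "NOT converged"))
  for (p in x$free) {
    cat(sprintf("  %-8s %10.4g +/- %.3g\n", p, x$estimates[[p]],
                x$std_errors[[p]]))
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a kinesin fit
#'
#' @param x A `kin_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`, `std.error`).
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  tibble::tibble(term = x$free,
                 estimate = as.numeric(x$estimates[x$free]),
                 std.error = as.numeric(x$std_errors[x$free]))
}

#' One-row summary of a kinesin fit
#'
#' @param x A `kin_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the residual sum of squares, residual
#'   standard deviation, degrees of freedom, observation count and
#'   convergence flag.
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss,
                 sigma = sqrt(x$rss / max(x$df_residual, 1)),
                 df.residual = x$df_residual,
                 nobs = x$n_obs,
                 converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
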