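#' Write and read tabular results with a provenance header
#'
#' All tabular output of the package is plain CSV preceded by `#`-prefixed
#' comment lines recording the package version, the full motor parameter
#' set, the conditions, and any RNG seed, so every file is reproducible
#' from its own header. `read_kin_csv()` ignores the header.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list written as `# key: value` header lines.
#' @return The path (write) or a tibble (read).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_kin_csv(kin_scan("DmK", 0:3), p, meta = list(motor = "DmK"))
#' read_kin_csv(p)
#' @export
write_kin_csv <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("kinesim ",
                                  as.character(utils::packageVersion("kinesim")))),
            meta)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15),
                                 collapse = " "))
  }, character(1))
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_kin_csv
#' @export
read_kin_csv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

params_meta <- function(params, extra = list()) {
  c(list(motor = params$name, r0 = params$r0, FS = params$FS,
         k_plus = params$k_plus, k_minus = params$k_minus,
         P0_zero = params$P0_zero, kb = params$kb,
         k_off_leading = params$k_off_leading, delta = params$delta,
         d = params$d, temperature = params$temperature),
    extra)
}

#' Read a force-velocity dataset
#'
#' Reads a CSV with columns `force_pN`, `velocity_nm_s` and optionally
#' `sigma_nm_s` (comma-separated, `.` decimal, `#` comments allowed) and
#' validates the schema.
#'
#' @param path Path to the CSV file.
#' @return A tibble suitable for [fit_force_velocity()].
#' @export
read_fv_csv <- function(path) {
  d <- read_kin_csv(path)
  need <- c("force_pN", "velocity_nm_s")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("Malformed force-velocity CSV ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  bad <- which(!is.finite(d$force_pN) | !is.finite(d$velocity_nm_s))
  if (length(bad)) {
    stop("Malformed force-velocity CSV ", path, ": non-numeric value near ",
         "data line ", bad[1], ".", call. = FALSE)
  }
  d
}

resolve_config <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(config, overrides)  # CLI/explicit overrides win
}

config_motor <- function(config) {
  if (!is.null(config$motor)) return(as_motor_params(config$motor))
  if (!is.null(config$params)) return(as_motor_params(config$params))
  stop("Config must name a `motor` preset or give inline `params`.",
       call. = FALSE)
}

config_grid <- function(x, default) {
  if (is.null(x)) return(default)
  if (is.list(x) && !is.null(x$from)) {
    return(seq(x$from, x$to, length.out = if (!is.null(x$n)) x$n else 25))
  }
  as.numeric(unlist(x))
}

#' Run a closed-form curve scan from a configuration
#'
#' Evaluates [kin_scan()] over a force grid defined by a configuration
#' (a named list or the path to a YAML file) and optionally writes the
#' deterministic curve CSV. Recognised fields: `motor` (preset name) or
#' `params` (inline list), `force` (vector or `{from, to, n}`), `deltaG`,
#' `out` (output CSV path).
#'
#' @param config Named list or YAML path.
#' @param ... Field overrides (take precedence over the file).
#' @return The scan tibble, invisibly if written to file.
#' @examples
#' run_scan(list(motor = "HsK", force = list(from = 0, to = 7, n = 8)))
#' @export
run_scan <- function(config, ...) {
  config <- resolve_config(config, list(...))
  params <- config_motor(config)
  force <- config_grid(config$force, seq(0, params$FS, length.out = 25))
  deltaG <- if (!is.null(config$deltaG)) config$deltaG else 20
  out <- kin_scan(params, force, deltaG = deltaG)
  if (!is.null(config$out)) {
    write_kin_csv(out, config$out,
                  meta = params_meta(params, list(deltaG_kBT = deltaG)))
    return(invisible(out))
  }
  out
}

#' Run a stochastic simulation from a configuration
#'
#' Simulates ensembles over a (force x ATP) grid and returns the
#' observables summary (one row per condition, value and SEM columns,
#' mirroring the curve-scan schema). Recognised fields: `motor`/`params`,
#' `force`, `atp` (uM; `"saturating"` or `Inf` for the saturating
#' branch), `t_max`, `n_traces`, `seed`, `engine`, `dt`, `out`.
#'
#' @inheritParams run_scan
#' @return A tibble of per-condition summaries.
#' @examples
#' run_scan(list(motor = "KIF17", force = 0))
#' @export
run_simulate <- function(config, ...) {
  config <- resolve_config(config, list(...))
  params <- config_motor(config)
  force <- config_grid(config$force, 0)
  atp <- config$atp
  if (is.null(atp)) atp <- Inf
  atp <- vapply(atp, function(a) {
    if (identical(a, "saturating")) Inf else as.numeric(a)
  }, numeric(1))
  t_max <- if (!is.null(config$t_max)) config$t_max else 10
  n_traces <- if (!is.null(config$n_traces)) config$n_traces else 1000
  seed <- if (!is.null(config$seed)) config$seed else 1
  engine <- if (!is.null(config$engine)) config$engine else "exact"
  dt <- if (!is.null(config$dt)) config$dt else 1e-4
  grid <- tidyr::expand_grid(force = force, atp = atp)
  out <- purrr::pmap_dfr(grid, function(force, atp) {
    ts <- simulate_ensemble(params, conditions(force = force, atp = atp),
                            t_max = t_max, n_traces = n_traces,
                            base_seed = seed, engine = engine, dt = dt)
    summarize_traces(ts)
  })
  if (!is.null(config$out)) {
    write_kin_csv(out, config$out,
                  meta = params_meta(params,
                                     list(seed = seed, t_max = t_max,
                                          n_traces = n_traces,
                                          engine = engine)))
    return(invisible(out))
  }
  out
}

#' Run a least-squares fit from a configuration
#'
#' Fits the force-velocity (or stepping-ratio) model to a CSV dataset.
#' Recognised fields: `data` (CSV path), `mutant_data` (optional second
#' CSV for the joint wild-type/mutant protocol), `type`
#' (`"velocity"`/`"ratio"`), `free` (character vector), `fixed` (named
#' list), `init`, `out` (report path).
#'
#' @inheritParams run_scan
#' @return A `kin_fit` object.
#' @export
run_fit <- function(config, ...) {
  config <- resolve_config(config, list(...))
  if (is.null(config$data)) stop("Config must give a `data` CSV path.",
                                 call. = FALSE)
  type <- if (!is.null(config$type)) config$type else "velocity"
  free <- if (!is.null(config$free)) unlist(config$free) else NULL
  fixed <- if (!is.null(config$fixed)) config$fixed else list()
  init <- if (!is.null(config$init)) unlist(config$init) else NULL
  fit <- if (type == "velocity") {
    d <- read_fv_csv(config$data)
    mut <- if (!is.null(config$mutant_data)) read_fv_csv(config$mutant_data)
    if (is.null(free)) {
      free <- c("r0", "FS", "k_plus", "k_minus",
                if (!is.null(mut)) "P0_zero")
    }
    fit_force_velocity(d, free_params = free, fixed_params = fixed,
                       init = init, mutant_data = mut)
  } else if (type == "ratio") {
    d <- read_kin_csv(config$data)
    if (is.null(free)) free <- c("r0", "FS")
    fit_stepping_ratio(d, free_params = free, fixed_params = fixed,
                       init = init)
  } else {
    stop("Unknown fit type: ", type, call. = FALSE)
  }
  if (!is.null(config$out)) {
    write_kin_csv(tidy(fit), config$out,
                  meta = c(list(model = fit$model, rss = fit$rss,
                                converged = fit$converged),
                           fit$fixed))
  }
  fit
}

#' Export a trace as tabular CSV
#'
#' Writes the event log of one trace (time, centre-of-mass and bead
#' positions, event kind) with full provenance in the header.
#'
#' @param trace A `kin_trace` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kin_trace"))
  bead <- bead_position_series(trace)
  ev <- trace$events
  idx <- findInterval(ev$time, bead$time)
  out <- tibble::tibble(time_s = ev$time, com_nm = ev$com_nm,
                        bead_nm = bead$position_nm[pmax(idx, 1L)],
                        event = as.character(ev$kind))
  write_kin_csv(out, path,
                meta = params_meta(trace$params,
                                   list(force_pN = trace$conditions$force,
                                        atp_uM = trace$conditions$atp,
                                        t_max = trace$t_max,
                                        seed = trace$seed,
                                        engine = trace$engine)))
}
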