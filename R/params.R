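#' Physical constants
#'
#' Boltzmann constant in pN nm / K (CODATA 1.380649e-23 J/K expressed in
#' piconewton-nanometres). All energies in the package are expressed in
#' multiples of kBT unless stated otherwise.
#' @keywords internal
KB_PN_NM <- 0.0138065

#' Thermal energy scale
#'
#' Returns the thermal energy `kBT` (pN nm) and its inverse `beta`
#' ((pN nm)^-1) at absolute temperature `temperature`. Room temperature
#' (298 K) gives kBT = 4.114 pN nm, the value used throughout the
#' closed-form theory.
#'
#' @param temperature Absolute temperature in kelvin (default 298).
#' @return A list with elements `kBT` (pN nm), `beta` ((pN nm)^-1) and
#'   `temperature` (K).
#' @examples
#' thermal_scale()$kBT # 4.114 pN nm
#' @export
thermal_scale <- function(temperature = 298) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin).",
         call. = FALSE)
  }
  kBT <- KB_PN_NM * temperature
  list(kBT = kBT, beta = 1 / kBT, temperature = temperature)
}

#' Construct a validated motor parameter set
#'
#' Bundles the kinetic constants of one kinesin species into a
#' `motor_params` object. The parameters are those of the stepping-rate
#' decomposition: at saturating ATP the forward stepping rate is
#' P0(0) PE(F) k_plus and the backward stepping rate is
#' P0(F) (1 - PE(F)) k_minus, with PE fixed by the zero-force stepping
#' ratio `r0` and the stall-force scale `FS`.
#'
#' @param name Species label.
#' @param r0 Stepping ratio (forward/backward steps) at zero force; must
#'   exceed 1 for a forward-directed motor.
#' @param FS Stall-force scale in pN (the actual stall force for wild-type
#'   motors, where the escape probability is force-independent).
#' @param k_plus ATPase rate constant of the trailing head, s^-1.
#' @param k_minus ATPase rate constant of the leading head, s^-1.
#' @param P0_zero Probability that the ADP-head escapes its weakened
#'   binding site at zero force; 1 for wild-type dimers, < 1 for
#'   extended-neck-linker mutants.
#' @param kb Second-order ATP binding rate constant, uM^-1 s^-1.
#' @param k_off_leading ATP dissociation rate from the leading head
#'   (backward neck-linker orientation), s^-1.
#' @param k_off_other ATP dissociation rate from a head in the trailing or
#'   intermediate position, s^-1 (0 in the model).
#' @param delta Characteristic distance for the force dependence of the
#'   escape probability, nm (~ the Debye length, 1 nm).
#' @param d Step size, nm (8.2 nm, the microtubule lattice period).
#' @param temperature Absolute temperature, K.
#' @param uncertainties Optional named list of parameter uncertainties
#'   (e.g. `list(r0 = 120, k_plus = 1)`); stored for error propagation in
#'   derived quantities, not used in simulation.
#' @return A `motor_params` object (a named list).
#' @examples
#' make_motor_params(name = "DmK", r0 = 890, FS = 8, k_plus = 95, k_minus = 3)
#' @export
make_motor_params <- function(name = "custom",
                              r0,
                              FS,
                              k_plus,
                              k_minus,
                              P0_zero = 1,
                              kb = 3.3,
                              k_off_leading = 30,
                              k_off_other = 0,
                              delta = 1,
                              d = 8.2,
                              temperature = 298,
                              uncertainties = NULL) {
  check_num <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number.", field),
           call. = FALSE)
    }
    x
  }
  r0 <- check_num(r0, "r0")
  FS <- check_num(FS, "FS")
  k_plus <- check_num(k_plus, "k_plus")
  k_minus <- check_num(k_minus, "k_minus")
  P0_zero <- check_num(P0_zero, "P0_zero")
  kb <- check_num(kb, "kb")
  k_off_leading <- check_num(k_off_leading, "k_off_leading")
  k_off_other <- check_num(k_off_other, "k_off_other")
  delta <- check_num(delta, "delta")
  d <- check_num(d, "d")
  temperature <- check_num(temperature, "temperature")

  fail <- function(field, rule) {
    stop(sprintf("Invalid motor parameter `%s`: %s.", field, rule),
         call. = FALSE)
  }
  if (r0 <= 1) fail("r0", "must exceed 1 (forward-directed motor)")
  if (FS <= 0) fail("FS", "must be positive (pN)")
  if (k_plus <= 0) fail("k_plus", "must be positive (s^-1)")
  if (k_minus < 0) fail("k_minus", "must be non-negative (s^-1)")
  if (P0_zero <= 0 || P0_zero > 1) fail("P0_zero", "must lie in (0, 1]")
  if (kb < 0) fail("kb", "must be non-negative (uM^-1 s^-1)")
  if (k_off_leading < 0) fail("k_off_leading", "must be non-negative (s^-1)")
  if (k_off_other < 0) fail("k_off_other", "must be non-negative (s^-1)")
  if (delta <= 0) fail("delta", "must be positive (nm)")
  if (d <= 0) fail("d", "must be positive (nm)")
  if (temperature <= 0) fail("temperature", "must be positive (K)")

  if (!is.null(uncertainties)) {
    stopifnot(is.list(uncertainties))
    known <- c("r0", "FS", "k_plus", "k_minus", "P0_zero", "kb",
               "k_off_leading")
    bad <- setdiff(names(uncertainties), known)
    if (length(bad)) {
      stop("Unknown uncertainty field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  structure(
    list(name = as.character(name)[1], r0 = r0, FS = FS,
         k_plus = k_plus, k_minus = k_minus, P0_zero = P0_zero,
         kb = kb, k_off_leading = k_off_leading, k_off_other = k_off_other,
         delta = delta, d = d, temperature = temperature,
         uncertainties = uncertainties),
    class = "motor_params"
  )
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf("<motor_params: %s>\n", x$name))
  cat(sprintf("  r0 = %g, FS = %g pN, k(+) = %g /s, k(-) = %g /s, P0(0) = %g\n",
              x$r0, x$FS, x$k_plus, x$k_minus, x$P0_zero))
  cat(sprintf("  kb = %g /uM/s, k-1 = %g /s, delta = %g nm, d = %g nm, T = %g K\n",
              x$kb, x$k_off_leading, x$delta, x$d, x$temperature))
  invisible(x)
}

# Registry of fitted parameter sets for the seven motor species.
# Wild-type dimers (DmK, Bovine, HsK, HsK-CL) carry P0_zero = 1: the large
# internal neck-linker tension makes escape from the weakened site certain.
# kb / k_off_leading for species never characterised at low ATP are carried
# over from the extended-neck-linker values (3.3 uM^-1 s^-1, 30 s^-1) so any
# preset can be run in the stochastic engine; this is an extrapolation.
preset_table <- function() {
  tibble::tribble(
    ~name,         ~r0, ~FS, ~k_plus, ~k_minus, ~P0_zero, ~kb, ~k_off_leading, ~kb_extrapolated,
    "DmK",          890,   8,      95,        3,        1, 3.3,             30, TRUE,
    "Bovine",       220, 7.6,     138,        3,        1, 3.3,             30, TRUE,
    "HsK",          900,   7,    90.5,        4,        1, 3.3,             30, TRUE,
    "HsK-6AA",      900,   7,    90.5,        4,     0.33, 3.3,             30, TRUE,
    "HsK-CL",       600,   5,     107,        4,        1, 3.3,             30, TRUE,
    "HsK-CL-6AA",   600,   5,     107,        4,     0.33, 3.3,             30, FALSE,
    "KIF17",        220,   8,     307,      9.8,     0.65, 3.3,             30, FALSE
  )
}

preset_uncertainties <- function() {
  list(
    "DmK"        = list(r0 = 120, FS = 0.3, k_plus = 1,   k_minus = 0.4),
    "Bovine"     = list(r0 = 68,  FS = 1.1, k_plus = 20,  k_minus = 1.1),
    "HsK"        = list(k_plus = 7.1, k_minus = 0.5),
    "HsK-6AA"    = list(k_plus = 7.1, k_minus = 0.5, P0_zero = 0.02),
    "HsK-CL"     = list(r0 = 50, FS = 0.4, k_plus = 3),
    "HsK-CL-6AA" = list(r0 = 50, FS = 0.4, k_plus = 3),
    "KIF17"      = list(k_plus = 22, k_minus = 1.6, P0_zero = 0.1)
  )
}

#' Motor parameter presets
#'
#' `motor_preset()` returns the fitted parameter set for one of the seven
#' characterised kinesin species; `motor_presets()` lists all of them as a
#' tibble (one row per species).
#'
#' Species: `DmK` (Drosophila kinesin-1), `Bovine` (bovine brain
#' kinesin-1), `HsK` (human kinesin-1), `HsK-6AA` (HsK with each neck
#' linker extended by six residues), `HsK-CL` (cysteine-light HsK),
#' `HsK-CL-6AA` (cysteine-light, extended), and `KIF17` (vertebrate
#' kinesin-2).
#'
#' @param name Preset name (see Details); case-sensitive.
#' @return `motor_preset()` a `motor_params` object; `motor_presets()` a
#'   tibble with one row per species.
#' @examples
#' motor_preset("KIF17")
#' motor_presets()
#' @export
motor_preset <- function(name) {
  tab <- preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% tab$name) {
    stop("Unknown motor preset ", deparse(substitute(name)),
         ". Valid names: ", paste(tab$name, collapse = ", "), ".",
         call. = FALSE)
  }
  row <- tab[tab$name == name, ]
  make_motor_params(
    name = row$name, r0 = row$r0, FS = row$FS,
    k_plus = row$k_plus, k_minus = row$k_minus, P0_zero = row$P0_zero,
    kb = row$kb, k_off_leading = row$k_off_leading,
    uncertainties = preset_uncertainties()[[name]]
  )
}

#' @rdname motor_preset
#' @export
motor_presets <- function() {
  dplyr::select(preset_table(), -"kb_extrapolated")
}

#' Experimental conditions
#'
#' Bundles the external load and ATP concentration of a run. Force is in
#' pN and is positive when directed backward (resisting forward motion),
#' the optical-trap convention. Use `atp = Inf` for saturating ATP, the
#' regime of the closed-form theory where nucleotide binding is never
#' rate-limiting (experimentally ~2 mM).
#'
#' @param force External force on the stalk, pN (signed; positive =
#'   backward).
#' @param atp ATP concentration in uM, or `Inf` for saturating ATP.
#' @param temperature Absolute temperature, K.
#' @return A `motor_conditions` object.
#' @examples
#' conditions(force = 2, atp = Inf)
#' conditions(force = 0, atp = 10)
#' @export
conditions <- function(force = 0, atp = Inf, temperature = 298) {
  stopifnot(is.numeric(force), length(force) == 1L, is.finite(force))
  if (!is.numeric(atp) || length(atp) != 1L || is.na(atp) || atp < 0) {
    stop("`atp` must be a non-negative concentration in uM (Inf = saturating).",
         call. = FALSE)
  }
  ts <- thermal_scale(temperature)
  structure(list(force = force, atp = atp, temperature = ts$temperature),
            class = "motor_conditions")
}

#' @export
print.motor_conditions <- function(x, ...) {
  atp <- if (is.infinite(x$atp)) "saturating" else paste0(x$atp, " uM")
  cat(sprintf("<conditions: F = %g pN, [ATP] = %s, T = %g K>\n",
              x$force, atp, x$temperature))
  invisible(x)
}

#' Read and write motor parameter configuration files
#'
#' Motor parameter sets can be stored in a plain-text YAML file with one
#' block per motor (key: value per parameter; `#` comments allowed).
#' Unspecified fields take the `make_motor_params()` defaults.
#'
#' @param path Path to the configuration file.
#' @return `read_motor_config()` a named list of `motor_params`;
#'   `write_motor_config()` the path, invisibly.
#' @examples
#' cfg <- tempfile(fileext = ".yml")
#' write_motor_config(list(motor_preset("DmK")), cfg)
#' read_motor_config(cfg)
#' @export
read_motor_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || !length(raw)) {
    stop("Config file must contain at least one motor block: ", path,
         call. = FALSE)
  }
  out <- lapply(names(raw), function(nm) {
    block <- raw[[nm]]
    block$name <- nm
    do.call(make_motor_params, block)
  })
  stats::setNames(out, names(raw))
}

#' @rdname read_motor_config
#' @param motors A list of `motor_params` objects.
#' @export
write_motor_config <- function(motors, path) {
  if (inherits(motors, "motor_params")) motors <- list(motors)
  blocks <- lapply(motors, function(p) {
    p <- unclass(p)
    p$uncertainties <- NULL
    p[setdiff(names(p), "name")]
  })
  names(blocks) <- vapply(motors, function(p) p$name, character(1))
  yaml::write_yaml(blocks, path)
  invisible(path)
}
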