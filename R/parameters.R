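# Model constants and derived quantities.
#
# Unit conventions are fixed package-wide: lengths in nm, forces in nN,
# times in s, concentrations in M, temperature in K. Rates are 1/s,
# stiffness nN/nm, energies nN*nm (1 nN*nm = 1e-18 J).

#' Boltzmann constant in nN*nm/K
#' @noRd
.kB <- 1.380649e-23 / 1e-18

.param_fields <- c(
  "k_cat", "k_on", "k0_off", "atp", "F_s", "d_s", "d_l", "delta_l",
  "proc_A", "proc_B", "T", "k_el", "l0", "P_att", "P_back",
  "F_load", "sigma_th", "m_bar", "n_cap"
)

#' Kinetic and mechanical parameters of a kinesin ensemble
#'
#' Constructs a validated parameter set for a cargo carried by an ensemble
#' of identical kinesin motors on a microtubule. Defaults are the
#' experimentally determined Kinesin-I constants used throughout the
#' package; any field can be overridden.
#'
#' @param k_cat Catalytic (hydrolysis) rate, 1/s.
#' @param k_on ATP binding rate, 1/(M*s).
#' @param k0_off Zero-force backward hydrolysis rate, 1/s.
#' @param atp ATP concentration, M.
#' @param F_s Stall force, nN. A motor loaded at or above `F_s` cannot step.
#' @param d_s Microtubule lattice period, nm.
#' @param d_l Force-sensitivity length of the hydrolysis back reaction, nm.
#' @param delta_l Force-sensitivity length of detachment, nm.
#' @param proc_A Processivity constant A (dimensionless).
#' @param proc_B Processivity constant B, M.
#' @param T Temperature, K.
#' @param k_el Motor-cargo linkage stiffness, nN/nm.
#' @param l0 Linkage rest length, nm. The linkage is slack below `l0` and
#'   Hookean beyond it.
#' @param P_att Attachment rate per unattached motor, 1/s.
#' @param P_back Detachment rate at or above stall, 1/s.
#' @param F_load Constant load on the cargo opposing motion, nN.
#' @param sigma_th Thermal standard deviation of the cargo position, nm.
#'   Defaults to the equipartition value `sqrt(kB*T/k_el)`; set to 0 for the
#'   noiseless model.
#' @param m_bar Number of motors bound to the cargo (ensemble size).
#' @param n_cap Optional cap on the configuration extent in lattice sites;
#'   `NULL` uses the theoretical bound (see [max_extent()]).
#'
#' @return An object of class `motor_params` (a named list).
#' @examples
#' p <- motor_params()
#' p$F_s          # 0.006 nN stall force
#' thermal_energy(p)
#' @export
motor_params <- function(k_cat = 105, k_on = 2e6, k0_off = 55, atp = 2e-3,
                         F_s = 0.006, d_s = 8, d_l = 1.6, delta_l = 1.3,
                         proc_A = 107, proc_B = 2.9e-8, T = 300,
                         k_el = 0.32e-3, l0 = 110, P_att = 5, P_back = 2,
                         F_load = 0, sigma_th = NULL, m_bar = 2,
                         n_cap = NULL) {
  if (is.null(sigma_th)) {
    # equipartition width; invalid T or k_el surfaces through validation below
    sigma_th <- suppressWarnings(sqrt(.kB * T / k_el))
    if (!is.finite(sigma_th)) sigma_th <- -1
  }
  p <- list(
    k_cat = k_cat, k_on = k_on, k0_off = k0_off, atp = atp, F_s = F_s,
    d_s = d_s, d_l = d_l, delta_l = delta_l, proc_A = proc_A,
    proc_B = proc_B, T = T, k_el = k_el, l0 = l0, P_att = P_att,
    P_back = P_back, F_load = F_load, sigma_th = sigma_th,
    m_bar = as.integer(m_bar), n_cap = if (is.null(n_cap)) NULL else as.integer(n_cap)
  )
  class(p) <- "motor_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity and sign constraints on every field. Called by
#' [motor_params()]; exported so deserialized sets can be re-checked.
#'
#' @param p A `motor_params` object.
#' @return `p`, invisibly, if valid; otherwise an error of class
#'   `motorensemble_invalid_params`.
#' @export
validate_params <- function(p) {
  bad <- function(msg) {
    stop(errorCondition(msg, class = c("motorensemble_invalid_params", "error")))
  }
  if (!inherits(p, "motor_params")) bad("not a motor_params object")
  for (f in setdiff(.param_fields, "n_cap")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(sprintf("field '%s' must be a finite scalar", f))
    }
  }
  pos <- c("k_cat", "k_on", "k0_off", "atp", "F_s", "d_s", "d_l", "delta_l",
           "proc_A", "proc_B", "T", "k_el", "P_att", "P_back")
  for (f in pos) if (p[[f]] <= 0) bad(sprintf("field '%s' must be strictly positive", f))
  if (p$F_load < 0) bad("F_load must be >= 0")
  if (p$sigma_th < 0) bad("sigma_th must be >= 0")
  if (p$l0 < 0) bad("l0 must be >= 0")
  if (p$m_bar < 1) bad("m_bar must be >= 1")
  if (!is.null(p$n_cap) && p$n_cap < 1) bad("n_cap must be >= 1 when set")
  invisible(p)
}

#' Thermal energy kB*T
#'
#' @param p A `motor_params` object.
#' @return Thermal energy in nN*nm.
#' @export
thermal_energy <- function(p) {
  if (p$T <= 0) stop("temperature must be strictly positive")
  .kB * p$T
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Motor ensemble parameters (nm, nN, s, M, K):\n")
  for (f in .param_fields) {
    v <- x[[f]]
    cat(sprintf("  %-8s %s\n", f, if (is.null(v)) "<unset>" else format(v)))
  }
  invisible(x)
}

#' Read parameters from a YAML or JSON file
#'
#' The file holds a flat mapping with the field names of [motor_params()];
#' missing fields take their defaults, unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `motor_params` object.
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown) > 0) {
    stop(sprintf("unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(motor_params, raw)
}

#' Write parameters to a YAML or JSON file
#'
#' @param p A `motor_params` object.
#' @param path Destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  out <- unclass(p)
  out$n_cap <- if (is.null(out$n_cap)) NULL else out$n_cap
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
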