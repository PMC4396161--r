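#' Physical constants of the cell model
#'
#' Bundles the membrane and bulk constants of the coupled
#' electrodiffusion / cable-equation model. The defaults are the standard
#' human-myocardium values used throughout the package: membrane
#' capacitance `Cm = 2.0` uF/cm^2, surface-to-volume ratio `S = 0.2` um^-1,
#' cellular resistivity `rho = 162` Ohm*cm, resting potential
#' `phi_rest = 0` mV and initial potential `phi0 = -80` mV.
#'
#' The electromigration scale `Fa/(R*Te)` (Faraday constant over gas
#' constant times temperature) is kept configurable and defaults to 1 in
#' model units, i.e. `Fa = R = Te = 1`: the PDE system is solved in a
#' single consistent model-unit regime (see the methods vignette), and the
#' physical Faraday constant / temperature never enter the dimensionless
#' drift coupling unless the user supplies them.
#'
#' @param Cm membrane capacitance per unit area (uF/cm^2), > 0.
#' @param S surface-to-volume ratio (um^-1), > 0.
#' @param rho cellular resistivity (Ohm*cm), > 0.
#' @param phi_rest resting potential (mV).
#' @param phi0 initial potential (mV).
#' @param Fa Faraday constant (model units; 96485 C/mol in SI), > 0.
#' @param R universal gas constant (model units; 8.314 J/(mol K) in SI), > 0.
#' @param Te local temperature (model units; Kelvin in SI), > 0.
#' @param g_leak optional linear leak conductance pulling the potential
#'   back to `phi_rest` (sensitivity studies only; default 0 = off), >= 0.
#' @return An object of class `physical_constants` (named list).
#' @examples
#' pc <- physical_constants()
#' pc$Cm
#' @export
physical_constants <- function(Cm = 2.0, S = 0.2, rho = 162,
                               phi_rest = 0, phi0 = -80,
                               Fa = 1, R = 1, Te = 1, g_leak = 0) {
  for (nm in c("Cm", "S", "rho", "Fa", "R", "Te")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("physical_constants: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  stopifnot(is.numeric(phi_rest), is.numeric(phi0),
            is.finite(phi_rest), is.finite(phi0))
  if (!is.numeric(g_leak) || !is.finite(g_leak) || g_leak < 0) {
    stop("physical_constants: 'g_leak' must be >= 0", call. = FALSE)
  }
  structure(list(Cm = Cm, S = S, rho = rho,
                 phi_rest = phi_rest, phi0 = phi0,
                 Fa = Fa, R = R, Te = Te, g_leak = g_leak),
            class = "physical_constants")
}

#' Cable-equation diffusion coefficient D = 1/(rho * S * Cm)
#'
#' The modified cable equation treats the membrane as an RC circuit, which
#' yields an effective "diffusion" coefficient for the potential,
#' `D = 1/(rho * S * Cm)`. Arguments are taken in the units in which these
#' quantities are conventionally quoted (Ohm*cm, um^-1, uF/cm^2) and the
#' result is returned in cm^2/ms by default (`S` is converted to cm^-1 and
#' `Cm` to F/cm^2 internally; note Ohm * F = s). With the default
#' myocardium constants this gives 0.00154 cm^2/ms.
#'
#' The PDE solver, whose time unit is the second, uses the equivalent
#' per-second value (`unit = "cm2_per_s"`, 1000 times larger).
#'
#' @param rho cellular resistivity (Ohm*cm), > 0.
#' @param S surface-to-volume ratio (um^-1), > 0.
#' @param Cm membrane capacitance per unit area (uF/cm^2), > 0.
#' @param unit `"cm2_per_ms"` (default) or `"cm2_per_s"`.
#' @return The scalar diffusion coefficient in the requested unit.
#' @examples
#' cable_diffusion(162, 0.2, 2.0)           # ~0.00154 cm^2/ms
#' cable_diffusion(162, 0.2, 2.0, "cm2_per_s")
#' @export
cable_diffusion <- function(rho, S, Cm, unit = c("cm2_per_ms", "cm2_per_s")) {
  unit <- match.arg(unit)
  args <- c(rho = rho, S = S, Cm = Cm)
  if (!all(is.finite(args)) || any(args <= 0)) {
    stop("cable_diffusion: rho, S and Cm must all be positive and finite",
         call. = FALSE)
  }
  S_per_cm <- S * 1e4    # um^-1 -> cm^-1
  Cm_F <- Cm * 1e-6      # uF/cm^2 -> F/cm^2
  D_cm2_per_s <- 1 / (rho * S_per_cm * Cm_F)
  switch(unit, cm2_per_ms = D_cm2_per_s / 1000, cm2_per_s = D_cm2_per_s)
}

#' Einstein relation between mobility and diffusion coefficient
#'
#' Ionic mobility `m_i = d_i * z_i * Fa / (R * Te)`: the drift coefficient
#' of a species in the Nernst-Planck flux is proportional to its diffusion
#' coefficient, signed by its valence. In the solver's model-unit regime
#' the factor `Fa/(R*Te)` defaults to 1 (see [physical_constants()]).
#'
#' @param d diffusion coefficient(s), > 0 (vectorised).
#' @param z integer valence(s) (vectorised; may be 0 or negative).
#' @param Fa Faraday constant, > 0.
#' @param R gas constant, > 0.
#' @param Te temperature, > 0.
#' @return Mobility (same length as `d`/`z`).
#' @examples
#' einstein_mobility(1e-3, 1)                      # model units
#' einstein_mobility(1e-3, 1, Fa = 96485, R = 8.314, Te = 310)
#' @export
einstein_mobility <- function(d, z, Fa = 1, R = 1, Te = 1) {
  if (!all(is.finite(d)) || any(d <= 0)) {
    stop("einstein_mobility: diffusion coefficients must be positive",
         call. = FALSE)
  }
  cst <- c(Fa = Fa, R = R, Te = Te)
  if (!all(is.finite(cst)) || any(cst <= 0)) {
    stop("einstein_mobility: Fa, R, Te must be positive", call. = FALSE)
  }
  d * z * Fa / (R * Te)
}

#' Species table for the suicide-substrate system
#'
#' Per-species transport data for the six reactants of the
#' mechanism-based-inhibition network, in the fixed order
#' E, S, X, Y, P, Ei (enzyme, substrate, two intermediates, product,
#' inactivated enzyme), mapped positionally onto concentration fields
#' C1..C6. Defaults are the standard configuration: diffusion coefficients
#' `d = (1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6)` (model units), valences
#' `z = (1, -1, 1, 1, 1, -1)` and initial concentrations
#' `c0 = (0.5, 0.5, 0, 0, 0, 0)` uM (e0 = s0 = 0.5 uM).
#'
#' @param name character vector of species names.
#' @param d positive diffusion coefficients.
#' @param z integer valences.
#' @param c0 non-negative initial concentrations (uM).
#' @return A `data.frame` with columns `name`, `d`, `z`, `c0`.
#' @examples
#' species_table()
#' @export
species_table <- function(name = c("E", "S", "X", "Y", "P", "Ei"),
                          d = c(1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6),
                          z = c(1, -1, 1, 1, 1, -1),
                          c0 = c(0.5, 0.5, 0, 0, 0, 0)) {
  n <- length(name)
  if (length(d) != n || length(z) != n || length(c0) != n) {
    stop("species_table: name, d, z, c0 must have equal length", call. = FALSE)
  }
  if (!all(is.finite(d)) || any(d <= 0)) {
    stop("species_table: all diffusion coefficients must be positive",
         call. = FALSE)
  }
  if (any(z != round(z))) {
    stop("species_table: valences must be integers", call. = FALSE)
  }
  if (!all(is.finite(c0)) || any(c0 < 0)) {
    stop("species_table: initial concentrations must be non-negative",
         call. = FALSE)
  }
  data.frame(name = as.character(name), d = as.numeric(d),
             z = as.integer(z), c0 = as.numeric(c0),
             stringsAsFactors = FALSE)
}
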