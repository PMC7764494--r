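#' Physical constants
#'
#' Fixed constants used throughout the package. Units are package-wide:
#' lengths in angstrom, time in picoseconds, charge in elementary charges,
#' energy in kcal/mol, temperature in kelvin, conductance in picosiemens,
#' current in picoamperes, voltage in millivolts.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0019872041 kcal mol^-1 K^-1.}
#'   \item{e}{Elementary charge, 1.602176634e-19 C.}
#'   \item{kB_SI}{Boltzmann constant, 1.380649e-23 J K^-1.}
#' }
#' @export
ionperm_constants <- list(
  kB    = 0.0019872041,
  e     = 1.602176634e-19,
  kB_SI = 1.380649e-23
)

# default species charge registry, elementary-charge units
.default_species_charges <- c(
  "NA" = +1, "CA" = +2, "CL" = -1,
  "OW" = 0, "OD" = 0, "OP" = 0
)

#' Species charge registry
#'
#' Returns the charge (in elementary-charge units, e) assigned to each
#' registered species label. The built-in vocabulary is `NA` (sodium, +1e),
#' `CA` (calcium, +2e), `CL` (chloride, -1e), and the three uncharged
#' coordination-partner categories `OW` (water oxygen), `OD` (acidic
#' side-chain oxygen) and `OP` (other protein oxygen). The registry is
#' extensible via `extra`.
#'
#' @param extra optional named numeric vector of additional species charges,
#'   e.g. `c(K = 1)`; overrides built-ins on name collision.
#' @return named numeric vector of charges in e.
#' @export
species_charges <- function(extra = NULL) {
  reg <- .default_species_charges
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("`extra` species charges must be a fully named numeric vector")
    }
    reg[names(extra)] <- as.numeric(extra)
  }
  reg
}

#' Thermal energy kB*T
#'
#' @param T absolute temperature, kelvin.
#' @param units `"kcal_per_mol"` (default) or `"joule"`.
#' @return kB*T in the requested units.
#' @examples
#' thermal_energy(300)            # 0.59616 kcal/mol
#' thermal_energy(300, "joule")   # 4.141947e-21 J
#' @export
thermal_energy <- function(T, units = c("kcal_per_mol", "joule")) {
  units <- match.arg(units)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("temperature must be a single positive number (kelvin)")
  }
  switch(units,
    kcal_per_mol = ionperm_constants$kB * T,
    joule        = ionperm_constants$kB_SI * T
  )
}

#' Convert a charge diffusion coefficient to a conductance
#'
#' Linear-response conversion of the collective charge diffusion coefficient
#' DQ (in e^2/ps) to a channel conductance G = DQ e^2 / (kB T), reported in
#' picosiemens. The steady current induced by a small voltage V is then
#' I = G V (see [predict_iv()]).
#'
#' @param DQ charge diffusion coefficient, e^2/ps; must be non-negative.
#' @param T absolute temperature, kelvin.
#' @return conductance in pS.
#' @examples
#' dq_to_conductance(1e-6, 300)   # ~6.198 pS
#' @export
dq_to_conductance <- function(DQ, T) {
  if (!is.numeric(DQ) || length(DQ) != 1L || !is.finite(DQ) || DQ < 0) {
    stop("DQ must be a single non-negative number (e^2/ps)")
  }
  kT <- thermal_energy(T, "joule")
  # e^2/ps -> C^2/s: x e_C^2 x 1e12; G in S; x 1e12 -> pS
  DQ * ionperm_constants$e^2 * 1e12 / kT * 1e12
}

#' Invert [dq_to_conductance()]
#'
#' @param G conductance, pS; non-negative.
#' @param T absolute temperature, kelvin.
#' @return DQ in e^2/ps.
#' @export
conductance_to_dq <- function(G, T) {
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 0) {
    stop("G must be a single non-negative number (pS)")
  }
  kT <- thermal_energy(T, "joule")
  G * kT / (ionperm_constants$e^2 * 1e12) / 1e12
}

#' Slab region along the pore axis
#'
#' A closed axial interval `[z1, z2]` (angstrom) used for occupancy counting
#' and charge-transport accounting. The default limits -4.5 to 16.5 angstrom
#' cover the selectivity filter extended into vestibule and central cavity,
#' with positive z pointing extracellular.
#'
#' @param z1,z2 axial limits, angstrom; `z1 < z2`.
#' @return an object of class `slab_region` with fields `z1`, `z2`, `Lz`.
#' @export
slab_region <- function(z1 = -4.5, z2 = 16.5) {
  if (!is.numeric(z1) || !is.numeric(z2) || length(z1) != 1L ||
      length(z2) != 1L || !is.finite(z1) || !is.finite(z2)) {
    stop("z1 and z2 must be single finite numbers (angstrom)")
  }
  if (z1 >= z2) stop("slab region requires z1 < z2")
  structure(list(z1 = z1, z2 = z2, Lz = z2 - z1), class = "slab_region")
}

#' @export
print.slab_region <- function(x, ...) {
  cat(sprintf("slab_region: [%g, %g] A (Lz = %g A)\n", x$z1, x$z2, x$Lz))
  invisible(x)
}
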