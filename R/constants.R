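# Physical constants pinned to CODATA-2014 so closed-form oracles and the
# numerical engines agree to machine precision regardless of later CODATA
# revisions.
.codata2014 <- list(
  N_A     = 6.022140857e23,   # mol^-1
  h       = 6.626070040e-34,  # J s
  hbar    = 1.054571800e-34,  # J s
  c_cm    = 2.99792458e10,    # cm s^-1 (exact)
  kB      = 1.38064852e-23,   # J K^-1
  amu     = 1.660539040e-27,  # kg
  hartree = 4.359744650e-18,  # J
  bohr    = 0.52917721067,    # Angstrom
  cal     = 4.184             # J (thermochemical, exact)
)

# Derived conversion factors, computed once at load time.
.iso_env <- new.env(parent = emptyenv())

.derived_constants <- function() {
  cc <- .codata2014
  bohr_m <- cc$bohr * 1e-10
  list(
    # Boltzmann constant in kcal mol^-1 K^-1 (0.0019872036...)
    kB_kcal = cc$kB * cc$N_A / (cc$cal * 1000),
    # second radiation constant hc/kB in cm K (1.43877736...)
    c2 = cc$h * cc$c_cm / cc$kB,
    # sqrt(hartree/(bohr^2 amu)) -> cm^-1 (about 5140.49)
    hessian_to_wavenumber = sqrt(cc$hartree / (bohr_m^2 * cc$amu)) /
      (2 * pi * cc$c_cm),
    # hbar^2 in (kcal/mol) amu Angstrom^2 (about 0.09640)
    hbar2_kcal = cc$hbar^2 / (cc$amu * 1e-20) * cc$N_A / (cc$cal * 1000),
    # N m^-1 -> hartree bohr^-2
    npm_to_hartree_bohr2 = bohr_m^2 / cc$hartree,
    # 1 cm^-1 of photon energy in kcal/mol (about 2.8591e-3)
    wavenumber_to_kcal = cc$h * cc$c_cm * cc$N_A / (cc$cal * 1000)
  )
}

#' Physical constants and conversion factors
#'
#' Returns the bundle of physical constants (CODATA-2014) and derived unit
#' conversion factors used consistently throughout the package: Boltzmann
#' constant in kcal/(mol K), the second radiation constant \eqn{hc/k_B} in
#' cm K, the conversion from Hessian eigenvalues in hartree/(bohr^2 amu) to
#' wavenumbers in cm^-1, and \eqn{\hbar^2} in (kcal/mol) amu A^2.
#'
#' @return Named list of constants. Base SI values under `$base`; derived
#'   conversion factors at the top level.
#' @examples
#' phys_constants()$kB_kcal    # 0.0019872...
#' phys_constants()$c2         # 1.438777... cm K
#' @export
phys_constants <- function() {
  if (is.null(.iso_env$const)) {
    d <- .derived_constants()
    d$base <- .codata2014
    .iso_env$const <- d
  }
  .iso_env$const
}

# internal shorthand
.kB_kcal <- function() phys_constants()$kB_kcal
.c2 <- function() phys_constants()$c2
.hbar2 <- function() phys_constants()$hbar2_kcal

#' Convert a bond force constant from N/m to hartree/bohr^2
#'
#' @param k Force constant(s) in N m^-1.
#' @return Force constant(s) in hartree bohr^-2.
#' @examples
#' newton_per_metre_to_hartree_bohr2(516) # about 0.3314
#' @export
newton_per_metre_to_hartree_bohr2 <- function(k) {
  k * phys_constants()$npm_to_hartree_bohr2
}
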