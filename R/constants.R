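## Physical constants, in the meV / Angstrom / amu / fs unit system used
## throughout the package.

## hbar^2 / (2 m_n) in meV * A^2 (m_n = neutron mass). Chosen so that recoil
## energies hbar^2 q^2 / 2M evaluate directly from q in 1/A.
.hbar2_2mn <- 2.07212

## neutron mass in amu
.m_n_amu <- 1.00866

## Boltzmann constant in meV / K
.k_B <- 0.0861733

## hbar in meV * fs (for time-domain <-> energy-domain transforms)
.hbar_meV_fs <- 658.2119569

## neutron speed in m/s for a kinetic energy of 1 meV: v = .v_conv * sqrt(E_meV)
.v_conv <- 437.3853

## 1 amu * (A/fs)^2 in meV (converts m v^2 to energy)
.amu_A2fs2_meV <- 1.036427e5

#' Physical constants used by the package
#'
#' Returns the constants of the meV / Angstrom / amu unit system in which all
#' computations are carried out: `hbar2_2mn` = \eqn{\hbar^2/2m_n} in
#' meV\eqn{\cdot}A\eqn{^2}, `m_n_amu` the neutron mass in amu, `k_B` in meV/K,
#' `hbar_meV_fs` in meV\eqn{\cdot}fs and `v_conv`, the neutron speed in m/s at
#' 1 meV kinetic energy.
#'
#' @return Named list of constants.
#' @export
neutron_constants <- function() {
  list(hbar2_2mn = .hbar2_2mn, m_n_amu = .m_n_amu, k_B = .k_B,
       hbar_meV_fs = .hbar_meV_fs, v_conv = .v_conv,
       amu_A2fs2_meV = .amu_A2fs2_meV)
}

## hbar^2 / (2 M) for a nucleus of mass `mass` amu, in meV * A^2
.hbar2_2M <- function(mass) .hbar2_2mn * .m_n_amu / mass

#' Tabulated neutron constants per isotopic species
#'
#' Reads the bound scattering and thermal absorption cross-sections shipped
#' with the package (Sears 1992 compilation): natural-abundance H, B, O, Al
#' and the separated boron isotopes `B10` and `B11`.
#'
#' @param file Optional path to an alternative constants table with the same
#'   columns (`species`, `mass_amu`, `sigma_scatt_barn`, `sigma_abs_barn`).
#' @return `data.frame` with one row per species.
#' @export
isotope_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "neutron_constants.csv",
                        package = "neutronics", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "mass_amu", "sigma_scatt_barn", "sigma_abs_barn")
  if (!all(need %in% names(tab)))
    stop("constants table must have columns: ", paste(need, collapse = ", "))
  tab
}
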