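## Nuclear quantum observables: kinetic energies, momentum-distribution
## widths, delocalisation lengths, heat capacities, mean-field isotope
## scalings.

## Prepare (omega, density) for Bose-weighted integrals: the omega -> 0 grid
## point takes its neighbour's density (the stored VDoS is untouched), and the
## integrand's omega*coth(omega/2kT) factor is continued analytically to 2kT
## at omega = 0.
.coth_density <- function(v) {
  d <- v$density
  if (v$omega[1] == 0 && length(d) > 1) d[1] <- d[2]
  d
}

#' Nuclear kinetic energy from a VDoS
#'
#' \deqn{E_k = \frac{3}{4}\int \omega\,G(\omega)\coth\!\big(\tfrac{\omega}{2k_BT}\big)\,d\omega}
#' (energies in meV, \eqn{\hbar\omega \equiv \omega}), evaluated by the
#' trapezoidal rule. At \eqn{T = 0} the Bose factor is 1 and the result is the
#' pure zero-point kinetic energy \eqn{\tfrac{3}{4}\langle\omega\rangle}; at
#' high temperature it approaches the classical \eqn{\tfrac{3}{2}k_BT}.
#'
#' @param v A unit-normalised [vdos()].
#' @param T Temperature in K (>= 0).
#' @return Kinetic energy in meV.
#' @export
kinetic_energy <- function(v, T) {
  if (!inherits(v, "vdos")) stop("v must be a vdos")
  if (T < 0) stop("T must be >= 0")
  itg <- trapz(v$omega, v$density)
  if (abs(itg - 1) > 1e-6) stop("VDoS must be unit-normalised")
  d <- .coth_density(v)
  w <- v$omega
  if (T == 0) {
    f <- w
  } else {
    x <- w / (2 * .k_B * T)
    f <- ifelse(w == 0, 2 * .k_B * T, w / tanh(x))
  }
  0.75 * trapz(w, f * d)
}

#' Kinetic energy from an NMD width, and back
#'
#' The isotropic-Gaussian closure \eqn{E_k = 3\hbar^2\sigma^2/2M} linking a
#' nuclear momentum distribution width \eqn{\sigma} (1/A) to the nuclear
#' kinetic energy (meV). `ek_from_width` and `width_from_ek` are exact
#' inverses.
#'
#' @param sigma NMD standard deviation in 1/A (> 0).
#' @param ek Kinetic energy in meV (> 0).
#' @param mass Nuclear mass in amu (> 0).
#' @return meV (`ek_from_width`) or 1/A (`width_from_ek`).
#' @export
ek_from_width <- function(sigma, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  3 * .hbar2_2M(mass) * sigma^2
}

#' @rdname ek_from_width
#' @export
width_from_ek <- function(ek, mass) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(ek <= 0)) stop("ek must be > 0")
  sqrt(ek / (3 * .hbar2_2M(mass)))
}

#' Spatial delocalisation length
#'
#' The uncertainty-principle conjugate of the NMD width: \eqn{1/\sigma} in A.
#'
#' @param sigma NMD width in 1/A (> 0).
#' @return Length in A.
#' @export
delocalisation <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  1 / sigma
}

#' Mean-field isotope scaling of widths and kinetic energies
#'
#' Within an effective single-oscillator (mean-field) picture the NMD width
#' scales with nuclear mass as \eqn{\sigma(M')/\sigma(M) = (M'/M)^{1/4}} and
#' the kinetic energy as \eqn{E(M')/E(M) = (M/M')^{1/2}}.
#'
#' @param value Width (1/A) or kinetic energy (meV) at mass `M`.
#' @param M,M_new Reference and target masses in amu (> 0).
#' @param which `"width"` or `"energy"`.
#' @return Scaled value at `M_new`.
#' @export
isotope_scale <- function(value, M, M_new, which = c("width", "energy")) {
  which <- match.arg(which)
  if (any(c(M, M_new) <= 0)) stop("masses must be > 0")
  if (which == "width") value * (M_new / M)^0.25 else value * (M / M_new)^0.5
}

#' Isochoric heat capacity from a total VDoS
#'
#' Harmonic heat capacity per formula unit,
#' \deqn{C_V(T) = n_\mathrm{modes}\,k_B \int x^2 \frac{e^x}{(e^x-1)^2} G(\omega)\,d\omega,\qquad x = \frac{\omega}{k_BT},}
#' with the integrand continued to its finite \eqn{\omega \to 0} limit (1).
#' Returned in units of \eqn{k_B} by default, or J/(mol K) with
#' `units = "J/mol/K"` (Avogadro scaling). Equals Dulong-Petit
#' (\eqn{n_\mathrm{modes} k_B}) as \eqn{T \to \infty}.
#'
#' @param v Unit-normalised total [vdos()].
#' @param T Temperature(s) in K (> 0); vectorised.
#' @param modes_per_fu Number of vibrational modes per formula unit
#'   (3 x atoms; 21 for H3BO3).
#' @param units `"kB"` (default) or `"J/mol/K"`.
#' @return Data frame with columns `T` and `cv`.
#' @export
heat_capacity_cv <- function(v, T, modes_per_fu = 1, units = c("kB", "J/mol/K")) {
  units <- match.arg(units)
  if (any(T <= 0)) stop("T must be > 0")
  d <- .coth_density(v)
  w <- v$omega
  cv <- vapply(T, function(Ti) {
    x <- w / (.k_B * Ti)
    f <- ifelse(x < 1e-8, 1, x^2 * exp(x) / expm1(x)^2)
    f[!is.finite(f)] <- 0  # x so large the mode is frozen out
    modes_per_fu * trapz(w, f * d)
  }, numeric(1))
  if (units == "J/mol/K") cv <- cv * 8.31446261815324  # R = N_A * k_B
  data.frame(T = T, cv = cv)
}

#' Isobaric from isochoric heat capacity
#'
#' \eqn{C_P = C_V + T V_0 \alpha^2/\beta} with isotropic thermal expansion
#' coefficient \eqn{\alpha} (1/K), compressibility \eqn{\beta} (1/Pa) and
#' molar volume \eqn{V_0} (m^3/mol). Defaults give \eqn{C_P = C_V}.
#'
#' @param cv Isochoric heat capacity (any unit; the correction is added in
#'   the same unit as supplied via `correction_unit` handling by the caller —
#'   with SI inputs the correction term is in J/(mol K)).
#' @param T Temperature in K.
#' @param V0 Molar volume in m^3/mol.
#' @param alpha Thermal expansion coefficient in 1/K (default 0).
#' @param beta Compressibility in 1/Pa (> 0 when `alpha != 0`).
#' @return Isobaric heat capacity.
#' @export
cp_from_cv <- function(cv, T, V0 = 0, alpha = 0, beta = 1) {
  if (alpha != 0 && beta <= 0) stop("beta must be > 0")
  cv + T * V0 * alpha^2 / beta
}

#' Kinetic energy of a free classical gas
#'
#' Maxwell-Boltzmann reference value \eqn{\tfrac{3}{2}k_BT} in meV.
#'
#' @param T Temperature in K.
#' @return meV.
#' @export
free_gas_ek <- function(T) 1.5 * .k_B * T

#' Observables table for a set of species
#'
#' Convenience wrapper producing, per species, the kinetic energy (from a
#' VDoS at temperature `T` or from a supplied width), the NMD width and the
#' delocalisation length, with the Eq.-closure \eqn{E_k = 3\hbar^2\sigma^2/2M}
#' holding exactly by construction.
#'
#' @param vdos_list Named list of [vdos()] per species (or `NULL` entries if
#'   `sigma` is given).
#' @param masses Named numeric vector of masses in amu.
#' @param T Temperature in K.
#' @param sigma Optional named vector of NMD widths (1/A) overriding the
#'   VDoS route.
#' @return Data frame: species, mass, kinetic_energy (meV), nmd_width (1/A),
#'   delocalisation (A), temperature.
#' @export
observables_table <- function(vdos_list = NULL, masses, T = 300, sigma = NULL) {
  species <- names(masses)
  ek <- sapply(species, function(s) {
    if (!is.null(sigma) && s %in% names(sigma))
      ek_from_width(sigma[[s]], masses[[s]])
    else kinetic_energy(vdos_list[[s]], T)
  })
  sg <- width_from_ek(ek, masses[species])
  data.frame(species = species, mass = as.numeric(masses[species]),
             kinetic_energy = as.numeric(ek), nmd_width = as.numeric(sg),
             delocalisation = 1 / as.numeric(sg), temperature = T,
             row.names = NULL)
}
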