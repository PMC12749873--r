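---
title: "Neutron characterisation of boric acid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutron characterisation of boric acid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutronics)
```

## Scope

Solid boric acid (H3BO3) is both a thermal-neutron absorber (through the
boron-10 capture reaction that boron neutron capture therapy exploits) and
an epithermal-neutron moderator (through its hydroxyl hydrogen). This
package implements the computational chain that connects its lattice
dynamics to the neutron observables a thermal-to-epithermal beamline
measures:

1. vibrational densities of states (VDoS), total and atom-projected, from
   harmonic mode lists, velocity autocorrelation functions, or analytic
   models;
2. nuclear quantum observables derived from a VDoS: kinetic energies,
   Gaussian nuclear-momentum-distribution (NMD) widths, delocalisation
   lengths, harmonic heat capacities, and mean-field isotope scalings;
3. total neutron cross-sections and transmission: incoherent multiphonon
   expansion, 1/v absorption, the epithermal free-recoil law and its
   plateau;
4. neutron Compton scattering (NCS): inverse-geometry time-of-flight
   kinematics, y-scaling, spectrum simulation, and the
   backscattering-then-forward fitting protocol;
5. prompt-gamma activation analysis (PGAA): deconvolution of the
   Doppler-broadened 478 keV boron-capture line from the 511 keV
   annihilation line;
6. sensitivity parameters and limits of detection/quantitation (LOD/LOQ)
   for the NCS, transmission and PGAA channels.

All energies are in meV, momenta in 1/A, masses in amu, times of flight in
microseconds, cross-sections in barn. The working constants are
$\hbar^2/2m_n = 2.07212$ meV A$^2$ and $k_B = 0.0861733$ meV/K
(`neutron_constants()`); bound scattering and thermal absorption
cross-sections ship in `inst/extdata/neutron_constants.csv` (Sears 1992
compilation) and are overridable everywhere.

## Vibrational densities of states

A `vdos` is a non-negative density on a uniform energy grid, renormalised
on construction so its trapezoidal integral is exactly 1. The default grid
is 0-500 meV in 0.5 meV steps, wide enough for the O-H stretch region
(~390-412 meV). Three constructors exist:

* `apvdos_from_modes()` bins harmonic modes as delta functions weighted by
  the q-point weight times the squared eigenvector magnitude of one
  species, then optionally smears with a Gaussian kernel (default FWHM
  2 meV) that mimics finite q-sampling without materially moving moments.
  Negative (imaginary) frequencies are hard errors: a stable structure has
  none, so their appearance is diagnostic, not something to clamp.
* `vdos_from_vacf()` is the molecular-dynamics route: the normalised
  velocity autocorrelation function averaged over the atoms of a species,
  cosine-transformed to the energy grid. The estimator is FFT-based with
  per-lag overlap normalisation, mean removal, maximum lag of half the
  trajectory (both configurable) and an optional Hann taper (off by
  default); no correction is applied for the integrator-induced frequency
  shift. Small negative spectral values from the finite window are clipped
  before renormalisation.
* `debye_vdos()` and `mixture_vdos()` build analytic models: the
  $3\omega^2/\omega_D^3$ Debye form and renormalised linear combinations
  (the averaged-functional-group construction, e.g. an OH-stretch library
  average over a Debye base for the boron sublattice).

`boric_acid_toy_vdos()` is the package's stand-in for first-principles
atom-projected VDoSes of boric acid: hydrogen carries bending bands near
100 and 150 meV and the stretch band near 400 meV; boron and oxygen carry
their weight below 120 meV over Debye bases. It reproduces the morphology
of the real spectra, which is what the cross-section and observable
pipelines are sensitive to; it does not reproduce fine band structure, so
agreement of downstream tests says nothing about a specific
exchange-correlation functional - only that the pipeline arithmetic is
right.

## Nuclear quantum observables

The kinetic energy of a species with unit-normalised VDoS $G(\omega)$ at
temperature $T$ is

$$E_k = \tfrac{3}{4}\int \omega\, G(\omega) \coth\!\Big(\frac{\omega}{2k_BT}\Big)\, d\omega ,$$

the harmonic (virial) result: half the total vibrational energy is
kinetic. At $T=0$ this is the pure zero-point value
$\tfrac34\langle\omega\rangle$; at high $T$ it approaches the classical
$\tfrac32 k_BT$. The $\omega \to 0$ grid point is continued analytically
($\omega\coth(\omega/2k_BT) \to 2k_BT$) and, for Bose-weighted integrals
only, the density at $\omega = 0$ takes its neighbour's value; the stored
VDoS is untouched.

The isotropic-Gaussian NMD closure $E_k = 3\hbar^2\sigma^2/2M$
(`ek_from_width()`/`width_from_ek()`, exact inverses) links kinetic energy
to the momentum width $\sigma$; `delocalisation()` returns the conjugate
length $1/\sigma$. With the constants above, the fitted boric acid widths
(H 4.78, B 9.60, O 11.4 1/A) map to 142.1, 53.5 and 50.9 meV - all far
above the 38.8 meV of a room-temperature classical gas, the quantitative
signature of zero-point motion.

Mean-field isotope scaling replaces the full mode spectrum with one
effective oscillator, giving $\sigma \propto M^{1/4}$ and
$E_k \propto M^{-1/2}$ (`isotope_scale()`). Its boron-10 predictions agree
with a full dynamical-matrix re-diagonalisation to well under a percent
for boric acid; the package accepts externally re-diagonalised mode sets
when that route is wanted.

`heat_capacity_cv()` evaluates the harmonic
$C_V = n_\mathrm{modes} k_B \int x^2 e^x (e^x-1)^{-2} G(\omega)\, d\omega$
(per formula unit; 21 modes for H3BO3), reported in units of $k_B$ or
J/(mol K). The virial identity $C_V = 2\,\partial E_k/\partial T$ holds to
numerical precision and is enforced by test. `cp_from_cv()` adds the
$T V_0 \alpha^2/\beta$ isobaric correction, zero by default because the
expansion coefficient and compressibility are not inputs the neutron
chain itself provides.

## Total cross-sections and transmission

Absorption follows the 1/v law
$\sigma_a(E_0)=\sigma_a(E_\mathrm{ref})\sqrt{E_\mathrm{ref}/E_0}$ from the
tabulated 25.3 meV values; resonances are deliberately absent (H, B and O
show none below 100 eV).

Scattering uses the incoherent approximation - justified here by the
dominance of the hydrogen incoherent cross-section - with the full bound
cross-section applied to the self part. Per species the detailed-balanced
one-phonon kernel is built from the VDoS, phonon orders up to `n_max`
(default 8) follow by iterated convolution, higher orders enter through a
Gaussian central-limit closure up to `order_cap` (default 128), and the
Debye-Waller elastic term completes
$S(q,\omega)$. The double differential
$(\sigma_b/4\pi)\sqrt{E_1/E_0}\,S(q,\omega)$ is integrated over energy
transfer and solid angle (midpoint rule in $\cos\theta$). The expansion is
declared converged at a given incident energy when the last explicit
order's correction is below 0.5% and the closure terminates inside the
representable transfer range.

Above that energy the curve is continued with the epithermal free-recoil
law: per species a Gaussian in energy transfer centred on the recoil
energy $\omega_r = \hbar^2q^2/2M$. Two variance conventions are exposed:
the printed form ($3\omega_r E_k$) used by `epithermal_ddxs()` and the
acceptance check, and the short-collision-time/ideal-gas form
($\tfrac43\omega_r E_k$, i.e. $2\omega_r k_BT_\mathrm{eff}$ with
$k_BT_\mathrm{eff}=\tfrac23 E_k$) used for the continuation, because it is
the exact ideal-gas limit and sits slightly below the converged expansion
at the junction. The junction ratio decays geometrically over one decade
in $E_0$, which makes the stitched curve descend monotonically into the
plateau

$$\sigma_\mathrm{epi} = \sum_i c_i\, \frac{4\pi b_i^2}{(1+m/M_i)^2},$$

the free-atom sum that the 10-100 eV transmission plateau measures.
A subtlety worth recording: integrating the free-recoil kernel over solid
angle with the free-atom prefactor, as the formula is usually printed,
over-counts by up to $4\pi$; in the impulse-approximation form
$(\sigma_b/4\pi)\sqrt{E_1/E_0}S(q,\omega)$ the $(1+m/M)^{-2}$ reduction
emerges from the recoil kinematics (for hydrogen this includes a second,
low-final-energy recoil branch and broad tails at angles beyond 90
degrees, both of which the integrator covers explicitly). Evaluated this
way, the 50 eV double integral matches the plateau to a few parts in a
thousand.

Quadrature choices: angular midpoint rule with 200 points for the
free-recoil law (25 inside the expansion, where the integrand is
smoother); per-species composite final-energy grids - broad log coverage
plus a fine window around each recoil branch; up-scattering truncated at
$15 k_BT$ below the elastic line. Invariance of the converged expansion
under grid refinement x2 and extra orders is enforced at the 1% level by
test. The expansion's quasi-free limit is only expected when the energy
exchanged is large against the phonon spectrum: for a heavy, nearly
classical target the curve matches the Doppler-averaged
constant-cross-section gas within 2% once $E_0$ exceeds a few hundred
Debye energies, and below that the bound solid genuinely deviates from a
gas - a physical statement, not a numerical defect.

Transmission is Beer-Lambert in the areal density,
$T(E_0)=e^{-nd\,\sigma_\mathrm{tot}}$, with a container handled
multiplicatively; `plateau_scattering_power()` is one minus the mean
transmission over 10-100 eV. In the workflow scripts the mass series is
converted to areal density with a 12 cm$^2$ beam aperture, which places
the synthetic scattering-power slope near the measured 0.064/g.

## Neutron Compton scattering

The default instrument is a VESUVIO-like inverse geometry: incident
flight path 11.005 m, final path 0.7 m, fixed final energy 4897 meV, a
forward bank at 32-67 degrees and a backscattering bank at 130-165
degrees (16 detectors each by default). None of this is fixed: the
geometry object is a plain per-detector table. Resolution is a Gaussian
in the longitudinal momentum variable per detector, 2.0 1/A forward and
4.0 1/A back by default, treated as known during fitting - the real
per-detector widths are instrument calibration data the user must supply.

West scaling maps $(E_0,E_1,\theta)$ to the longitudinal momentum
$y = (M/\hbar^2q)(\hbar\omega - \hbar^2q^2/2M)$ of a recoiling nucleus;
the recoil peak sits at $y=0$, whose time-of-flight solution is a
quadratic in $\sqrt{E_0}$ (physical root). For a target at the neutron
mass the root only exists at forward angles - hydrogen recoil is
kinematically invisible in backscattering, and `recoil_center()` raises
an error saying so rather than returning silently.

The simulator sums per-species Gaussian momentum distributions
$J_M(y_M(t))$ convolved in quadrature with the resolution, mapped to TOF
with the kinematic Jacobian, with integral intensities constrained by
$I_M \propto c_M 4\pi b_M^2$, plus an optional flat background, and
Poisson-samples the counts. The fitter follows the standard protocol:
heavy-species widths are fitted per backscattering detector (where their
recoil peaks separate best), averaged (mean and sd) over converged
detectors, then held while hydrogen is fitted in the forward bank;
finally all forward detectors are focused into proton momentum space and
a single resolution-convolved Gaussian is fitted. The intensity
constraint is applied to H, B and O but not to the container aluminium,
whose amount per formula unit is unknown. Peak centres are never free:
kinematics fixes them. Weighted least squares uses Poisson weights with
one model-based reweighting pass, which removes the small-count bias that
observed-count weights otherwise induce (without it the recovered proton
width sits about 1% low at realistic counts). Non-converging detectors
are excluded from averages rather than failing the run.

## Prompt-gamma doublet

The 400-550 keV region of interest holds the Doppler-broadened 478 keV
boron-capture line (the emitting lithium-7 nucleus is in motion) and the
511 keV annihilation line. `fit_doublet()` fits two Gaussians or two
Lorentzians plus a linear background with Poisson weights; background
subtraction (`normalise_and_subtract()`) propagates per-bin errors so the
subtracted spectrum is weighted correctly. The Doppler contribution is a
fixed extra Gaussian width (default 7 keV FWHM, in quadrature) rather
than a free parameter, because the data in this region cannot separate it
from the detector response. Centres start at 478 and 511 keV and stay
within 25 keV of them; widths are bounded at 25 keV so neither profile
can flatten into the background - without those bounds the second peak
occasionally wanders into a quasi-background solution and the fit crawls.
The 478 keV environmental background (capture outside the target) is
carried by the measured blank, not by the polynomial.

Both profiles are area-parameterised, so `integral_intensity()` returns
the analytic area with its propagated uncertainty; an area within three
standard errors of zero raises the below-detection flag. Fitting a
Lorentzian to a Gaussian line inflates the area through the tails - the
pure-shape least-squares floor is about +26%, and the published
sensitivity slopes of the two models differ by a factor of two - so the
two models should be read as bracketing the truth, not as agreeing to a
few percent.

## Detection and quantitation limits

The sensitivity parameter is either the single-point
$S = (m - m_\mathrm{blank})/(C - C_\mathrm{blank})$ or the inverse slope
of an ordinary least-squares regression of response on analyte mass
(unweighted, as reported; a weighted option exists). The limits follow
the 3-sigma/10-sigma rule, $\mathrm{LOD} = 3 S s_\mathrm{blank}$ and
$\mathrm{LOQ} = 10 S s_\mathrm{blank}$, so their ratio is 10/3 by
construction. The largest-mass sample is excluded by default for the
transmission and PGAA channels (multiple scattering and gamma
self-attenuation bend the response), controlled by `exclude_saturated`.
Isotope-selective NCS limits scale the natural-abundance limit by the
bound scattering cross-section ratio. Note that a $\pm 2$ standard-error
band around a regression estimate has Student-t, not Gaussian, coverage:
86% for a five-point series - which is why the package's coverage test
uses a longer series and a 90% floor.

## Synthetic data and what passing means

Every generator takes a mandatory seed, returns its ground truth beside
the data, and is deterministic under that seed. The sample-mass series
copies the measured five masses (0.290, 0.575, 1.152, 1.580, 2.299 g) so
the LOD pipelines are structurally identical to the measured ones.
Counting channels use Poisson noise; transmission plateaus use Gaussian
noise at the blank standard deviation (0.003). The prompt-gamma generator
puts 3000 478-keV counts per gram of boron with a 600-count annihilation
line (30% of it beam-independent and hence present in the blank), which
reproduces the published sensitivity regression's signal-to-noise regime;
the NCS generator uses 2e4 counts per detector per gram. Replicate
studies in the test suite (50 seeded replicates each) recover the proton
momentum width within the ensemble scatter and the 478 keV area ratio
within 2%.

The generators emulate morphology and counting statistics - they do not
emulate multiple scattering, detector-response tails (escape peaks,
Compton continua), gamma self-attenuation, or instrument backgrounds
beyond flat/linear terms. Passing tests therefore validate the estimation
chain, not the treatment of those instrumental effects, which the
measured-data workflow delegates to upstream reduction.

## Problem sizes

The shipped workflow and tests run the cross-section curve on a 1 meV
VDoS grid with 15-21 angular points and about 25-120 incident energies,
the NCS replicate study on a 3+3-detector geometry at 5e4 counts, and the
expansion-refinement checks at thermal energy; these sizes keep every
result well inside its quoted tolerance while the full-size geometry
(16+16 detectors) and finer grids remain plain arguments.

## Known limitations

* The multiphonon/free-recoil junction is a stitch, not a theory: between
  roughly 0.3 and 2 eV for hydrogenous samples neither limit is exact and
  the curve there inherits the bridge construction.
* The impulse-approximation NCS model carries no final-state corrections;
  momentum distributions are isotropic Gaussians by construction.
* The PGAA model has no detector-response simulation beyond Gaussian or
  Lorentzian lines over a linear background.
* Mean-field isotope scaling is an effective-oscillator statement; for
  species with strongly structured spectra the dynamical-matrix route is
  the reference.
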