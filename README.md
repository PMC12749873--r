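# neutronics

Thermal-to-epithermal neutron characterisation of boron carriers, with
solid boric acid (H3BO3) as the reference system.

Boric acid is both a thermal-neutron absorber — boron-10 carries the
capture reaction behind boron neutron capture therapy (BNCT) — and an
epithermal moderator through its hydroxyl hydrogen. How well it does
either depends on the quantum motion of its nuclei: zero-point energy
Doppler-broadens the way each isotope scatters and absorbs neutrons. This
package implements, as tested reusable code, the full chain from lattice
dynamics to beamline observables for people evaluating boron compounds on
a thermal-to-epithermal station:

* **Vibrational densities of states** (total and atom-projected) from
  harmonic mode lists, from molecular-dynamics velocity autocorrelation
  functions, or from analytic Debye/band models.
* **Nuclear quantum observables**: kinetic energies
  $E_k = \tfrac34\int \omega\,G(\omega)\coth(\omega/2k_BT)\,d\omega$,
  Gaussian nuclear-momentum-distribution widths through the closure
  $E_k = 3\hbar^2\sigma^2/2M$, delocalisation lengths $1/\sigma$,
  harmonic heat capacities, and mean-field isotope scalings
  ($\sigma \propto M^{1/4}$, $E_k \propto M^{-1/2}$).
* **Total neutron cross-sections and transmission**: incoherent
  multiphonon expansion stitched to the epithermal free-recoil law, 1/v
  absorption, Beer–Lambert transmission and the 10–100 eV plateau
  $\sum_i c_i\,4\pi b_i^2/(1+m/M_i)^2$.
* **Neutron Compton scattering**: inverse-geometry time-of-flight
  kinematics, West y-scaling, spectrum simulation with cross-section-
  constrained intensities, and the backscattering-then-forward fitting
  protocol.
* **Prompt-gamma analysis**: deconvolution of the Doppler-broadened
  478 keV boron-capture line from the 511 keV annihilation line.
* **Detection limits**: sensitivity parameters (direct or regression) and
  the 3σ/10σ LOD/LOQ rule for the Compton, transmission and prompt-gamma
  channels, with isotope-selective scaling.

A synthetic-data module generates every input with known ground truth, so
the whole chain is testable without measured data.

## Worked example

Nuclear quantum observables of boric acid from the fitted momentum
widths, and the detection limit of the Compton channel:

```r
library(neutronics)

tab <- isotope_table()
masses <- setNames(tab$mass_amu, tab$species)
observables_table(masses = masses[c("H", "B", "O")], T = 300,
                  sigma = c(H = 4.78, B = 9.60, O = 11.4))
#>   species   mass kinetic_energy nmd_width delocalisation temperature
#> 1       H  1.008         142.14      4.78        0.20921         300
#> 2       B 10.811          53.45      9.60        0.10417         300
#> 3       O 15.999          50.93     11.40        0.08772         300

comp <- make_boric_acid_fixture()
epithermal_plateau(comp)
#> [1] 77.09  # barn per formula unit

S <- sensitivity_direct(0.4018, 33.5)  # g of boron, recoil-peak counts
lod_loq(S, blank_sd = 1)
#>   lod   loq
#> 0.036 0.120
isotope_scaled_lod(0.036, "B", "B10")
#> [1] 0.0609
```

Reading: all three nuclei carry far more kinetic energy than the 38.8 meV
of a room-temperature classical gas (hydrogen almost 4x) — the signature
of zero-point motion; the proton is delocalised over ~0.21 Å, about twice
the boron and oxygen values. The Compton channel detects 36 mg of natural
boron (3σ) and quantifies 120 mg (10σ); for isotopically pure boron-10
the limit rises to ~61 mg because its bound scattering cross-section is
smaller.

## Analysis workflow

The `analysis/` scripts run the study end to end on synthetic data and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_observables.R` | kinetic energies, widths, delocalisation, isotope scalings |
| `02_vdos_models.R` | model VDoS set, VACF-route check, heat capacity |
| `03_cross_sections.R` | multiphonon total cross-section, transmission mass series |
| `04_ncs.R` | Compton spectrum simulation + two-stage width fitting, boron sensitivity |
| `05_pgaa.R` | 478/511 keV doublet fits, both peak models, sensitivity regressions |
| `06_lod_summary.R` | all channels' LOD/LOQ collated |

Run them in order with `Rscript analysis/01_observables.R` etc.

## Layout

```
R/                  implementation (VDoS, observables, cross-sections,
                    NCS, PGAA, LOD/LOQ, synthetic data)
analysis/           numbered workflow scripts
inst/extdata/       neutron constants table (Sears 1992)
tests/testthat/     unit, property and end-to-end tests
vignettes/          methods vignette (models, conventions, limitations)
scripts/            acceptance script
```
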