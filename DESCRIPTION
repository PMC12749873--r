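Package: neutronics
Title: Thermal-to-Epithermal Neutron Characterisation of Boron Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising boron-containing neutron absorbers and
    moderators, with solid boric acid (H3BO3) as the reference system.
    Constructs total and atom-projected vibrational densities of states from
    harmonic mode lists, velocity autocorrelation functions or analytic
    models; derives nuclear quantum observables (kinetic energies, Gaussian
    momentum-distribution widths, delocalisation lengths, heat capacities,
    mean-field isotope scalings); models incident-energy-dependent total
    neutron cross-sections via the incoherent multiphonon expansion with 1/v
    absorption and the epithermal free-recoil law; simulates and fits
    inverse-geometry neutron Compton scattering time-of-flight spectra with
    the backscattering-then-forward protocol; deconvolutes the 478/511 keV
    prompt-gamma doublet; and computes sensitivities and limits of detection
    and quantitation for the Compton, transmission and prompt-gamma channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
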