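#!/usr/bin/env Rscript

# Incident-energy-dependent total neutron cross-section of boric acid from
# the multiphonon expansion, transmission curves for the sample-mass series,
# and the epithermal scattering powers they imply.

library(neutronics)

dir.create("results", showWarnings = FALSE)

comp <- make_boric_acid_fixture()
vd <- boric_acid_toy_vdos(default_grid(500, 1))

E0 <- 10^seq(-4, 2, length.out = 120)
curve <- multiphonon_total_xs(vd, comp, T = 300, E0_grid = E0, n_mu = 21)
write.csv(curve, "results/xsec_curve.csv", row.names = FALSE)

pl <- epithermal_plateau(comp)
i_th <- which.min(abs(curve$E0_eV - 0.0253))
message(sprintf(paste0("Total scattering cross-section: %.0f b per formula ",
                       "unit at thermal energy (bound enhancement), ",
                       "descending to the %.1f b epithermal plateau; ",
                       "absorption adds %.1f b at thermal via the 1/v law."),
                curve$sigma_scatt[i_th], pl, curve$sigma_abs[i_th]))
message(sprintf("Multiphonon expansion converged up to %.2f eV; %s",
                max(curve$E0_eV[curve$mpe]),
                "the free-recoil law carries the curve beyond."))

# transmission for the five-sample mass series; flat container geometry
# with a 12 cm^2 beam aperture
masses <- c(0.290, 0.575, 1.152, 1.580, 2.299)
area_cm2 <- 12
NA_ <- 6.02214076e23
power <- sapply(masses, function(m) {
  nd <- m / molar_mass(comp) * NA_ / area_cm2
  tr <- transmission(curve, sample_geometry(areal_density = nd))
  plateau_scattering_power(tr)
})
series <- data.frame(mass_g = masses, scattering_power = power)
write.csv(series, "results/transmission_series.csv", row.names = FALSE)

slope <- coef(lm(scattering_power ~ mass_g, series))["mass_g"]
message(sprintf(paste0("Epithermal scattering power of the mass series is ",
                       "linear at %.3f per gram (cf. the measured 0.064/g ",
                       "sensitivity slope)."), slope))
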