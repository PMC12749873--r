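#!/usr/bin/env Rscript

# Nuclear quantum observables of solid boric acid from the fitted nuclear
# momentum distribution widths: kinetic energies, delocalisation lengths,
# boron isotope scalings, and the comparison against a free classical gas.

library(neutronics)

dir.create("results", showWarnings = FALSE)

tab <- isotope_table()
masses <- setNames(tab$mass_amu, tab$species)

# fitted NMD widths (1/A) of the 2.299 g powder sample at 300 K
sigma_fit <- c(H = 4.78, B = 9.60, O = 11.4)

obs <- observables_table(masses = masses[names(sigma_fit)], T = 300,
                         sigma = sigma_fit)
obs$free_gas_ratio <- obs$kinetic_energy / free_gas_ek(300)
write.csv(obs, "results/observables.csv", row.names = FALSE)

message("Nuclear quantum observables (fitted widths, 300 K):")
print(obs, digits = 4)
message(sprintf(paste0("All species carry far more kinetic energy than the ",
                       "38.8 meV classical gas value: H %.1fx, B %.2fx, ",
                       "O %.2fx."),
                obs$free_gas_ratio[1], obs$free_gas_ratio[2],
                obs$free_gas_ratio[3]))

# mean-field boron isotope scaling
iso <- data.frame(
  isotope = c("B10", "B11"),
  mass = masses[c("B10", "B11")],
  sigma = isotope_scale(sigma_fit["B"], masses["B"],
                        masses[c("B10", "B11")], "width"),
  ek = isotope_scale(ek_from_width(sigma_fit["B"], masses["B"]),
                     masses["B"], masses[c("B10", "B11")], "energy"))
iso$delocalisation <- 1 / iso$sigma
write.csv(iso, "results/isotope_scaled.csv", row.names = FALSE)

message("\nMean-field boron isotope scaling:")
print(iso, digits = 4)
message(paste0("The lighter boron-10 has the broader momentum distribution ",
               "and the higher kinetic energy, as the quarter-power mass ",
               "law requires."))
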