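#!/usr/bin/env Rscript

# Vibrational densities of states: the analytic atom-projected models for
# boric acid, a VACF-route consistency check on synthetic oscillator
# trajectories, and the harmonic heat capacity they imply.

library(neutronics)

dir.create("results", showWarnings = FALSE)

grid <- default_grid(500, 0.5)
vd <- boric_acid_toy_vdos(grid)
for (s in names(vd))
  write_vdos(vd[[s]], file.path("results", paste0("vdos_", s, ".dat")))

ek <- sapply(names(vd), function(s) kinetic_energy(vd[[s]], 300))
message("Kinetic energies from the model VDoS set at 300 K (meV):")
print(round(ek, 1))
message(paste0("The hydrogen value is dominated by the zero-point energy of ",
               "the bending and O-H stretching bands; boron and oxygen sit ",
               "much closer to the classical limit."))

# VACF route: a two-tone thermal oscillator trajectory must reproduce its
# generating frequencies through the autocorrelation transform
osc <- make_oscillator_trajectory(c(100, 400), T = 300, n_steps = 8192,
                                  dt = 0.5, seed = 42, n_atoms = 4)
v_vacf <- vdos_from_vacf(osc$traj, "H")
write_vdos(v_vacf, "results/vdos_vacf_check.dat")
pk <- v_vacf$omega[order(v_vacf$density, decreasing = TRUE)[1:2]]
message(sprintf(paste0("VACF check: generating tones at 100 and 400 meV, ",
                       "spectral maxima recovered at %.1f and %.1f meV."),
                min(pk), max(pk)))

# harmonic heat capacity per formula unit from the total VDoS
vtot <- mixture_vdos(vd[c("H", "B", "O")], c(3, 1, 3) / 7, species = "TOT")
Ts <- c(seq(5, 50, 5), seq(60, 400, 20))
cv <- heat_capacity_cv(vtot, Ts, modes_per_fu = 21, units = "J/mol/K")
write.csv(cv, "results/heat_capacity.csv", row.names = FALSE)
message(sprintf(paste0("C_V at 300 K: %.1f J/(mol K) per formula unit, ",
                       "%.0f%% of the Dulong-Petit ceiling (21 R = %.1f)."),
                cv$cv[Ts == 300], 100 * cv$cv[Ts == 300] /
                  (21 * 8.3145), 21 * 8.3145))
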