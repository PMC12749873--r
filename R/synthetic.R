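## Synthetic data generators: every input the pipeline needs, with known
## ground truth, so all stages are testable without measured data.

#' Boric acid composition fixture
#'
#' H3BO3 stoichiometry (c_H = 3, c_B = 1, c_O = 3) with tabulated constants,
#' plus an optional aluminium container species.
#'
#' @param container_al Aluminium atoms per formula unit to include for the
#'   container (0 = none; the true value is never known a priori, which is
#'   why the fitters leave the Al intensity unconstrained).
#' @param table Constants table.
#' @return A [composition()].
#' @export
make_boric_acid_fixture <- function(container_al = 0, table = isotope_table()) {
  sp <- c("H", "B", "O"); ct <- c(3, 1, 3)
  if (container_al > 0) { sp <- c(sp, "Al"); ct <- c(ct, container_al) }
  composition(sp, ct, table = table)
}

#' Toy VDoS from Gaussian bands plus an optional Debye base
#'
#' Unit-normalised mixture of Gaussian bands (centre, width = sd, weight in
#' meV) with an optional Debye \eqn{\omega^2} base; the generating
#' parameters are returned as ground truth.
#'
#' @param bands List of `c(centre, width, weight)` triples.
#' @param debye_cutoff Optional Debye cutoff in meV.
#' @param debye_weight Weight of the Debye component.
#' @param grid Energy grid.
#' @param species Species label.
#' @return List: `vdos` (a [vdos()]) and `truth` (band parameters).
#' @export
make_toy_vdos <- function(bands, debye_cutoff = NULL, debye_weight = 0,
                          grid = default_grid(), species = "TOT") {
  comps <- list(); wts <- numeric(0)
  for (b in bands) {
    comps[[length(comps) + 1L]] <-
      vdos(grid, stats::dnorm(grid, b[1], b[2]), species = species)
    wts <- c(wts, b[3])
  }
  if (!is.null(debye_cutoff) && debye_weight > 0) {
    comps[[length(comps) + 1L]] <- debye_vdos(debye_cutoff, grid, species)
    wts <- c(wts, debye_weight)
  }
  v <- mixture_vdos(comps, wts, species = species)
  list(vdos = v, truth = list(bands = bands, debye_cutoff = debye_cutoff,
                              debye_weight = debye_weight))
}

#' Paper-like toy VDoS set for boric acid
#'
#' Three-band hydrogen VDoS (out-of-plane/in-plane bending bands near 100
#' and 150 meV and the O-H stretch near 400 meV) and boron/oxygen VDoSes
#' with their weight below 120 meV, emulating the morphology of
#' atom-projected VDoSes of molecular-crystal boric acid.
#'
#' @param grid Energy grid.
#' @return Named list of [vdos()] (`H`, `B`, `O`) with a `truth` attribute.
#' @export
boric_acid_toy_vdos <- function(grid = default_grid()) {
  h <- make_toy_vdos(list(c(100, 12, 0.40), c(150, 12, 0.33),
                          c(400, 10, 0.27)), grid = grid, species = "H")
  b <- make_toy_vdos(list(c(80, 15, 0.45), c(110, 12, 0.25)),
                     debye_cutoff = 45, debye_weight = 0.30,
                     grid = grid, species = "B")
  o <- make_toy_vdos(list(c(70, 15, 0.40), c(105, 12, 0.25)),
                     debye_cutoff = 40, debye_weight = 0.35,
                     grid = grid, species = "O")
  out <- list(H = h$vdos, B = b$vdos, O = o$vdos)
  attr(out, "truth") <- list(H = h$truth, B = b$truth, O = o$truth)
  out
}

#' Synthetic harmonic-oscillator velocity trajectory
#'
#' Superposed thermal harmonic tones with random phases: per Cartesian
#' component and mode, \eqn{v(t) = A\cos(\omega t/\hbar + \phi)} with the
#' amplitude set by equipartition (\eqn{\langle \tfrac12 m v^2\rangle =
#' k_BT/2} per mode per component).
#'
#' @param frequencies Mode energies in meV.
#' @param T Temperature in K.
#' @param n_steps Number of frames.
#' @param dt Timestep in fs.
#' @param seed RNG seed (mandatory).
#' @param mass_amu Oscillator mass.
#' @param n_atoms Number of identical atoms.
#' @param species Species label.
#' @param amplitudes Optional relative amplitude factors per mode
#'   (default 1).
#' @return List: `traj` (a [trajectory()]) and `truth`.
#' @export
make_oscillator_trajectory <- function(frequencies, T = 300, n_steps = 4096,
                                       dt = 0.5, seed, mass_amu = 1.00794,
                                       n_atoms = 1, species = "H",
                                       amplitudes = NULL) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(frequencies))
  A0 <- sqrt(2 * .k_B * T / (mass_amu * .amu_A2fs2_meV))  # A/fs
  tt <- (seq_len(n_steps) - 1) * dt
  vel <- array(0, dim = c(n_steps, n_atoms, 3))
  for (a in seq_len(n_atoms)) for (k in 1:3) {
    v <- numeric(n_steps)
    for (m in seq_along(frequencies)) {
      phi <- stats::runif(1, 0, 2 * pi)
      v <- v + A0 * amplitudes[m] *
        cos(frequencies[m] * tt / .hbar_meV_fs + phi)
    }
    vel[, a, k] <- v
  }
  list(traj = trajectory(vel, rep(species, n_atoms), dt,
                         temperature_nominal = T),
       truth = list(frequencies = frequencies, T = T, dt = dt, seed = seed,
                    amplitudes = amplitudes, mass_amu = mass_amu))
}

#' Synthetic NCS dataset for a sample-mass series
#'
#' For each sample mass, simulates Poisson-noised TOF spectra on every
#' detector of the geometry, with total counts proportional to the sample
#' mass (thin-sample counting statistics) plus an optional flat background.
#'
#' @param masses_g Sample masses in g (default the five-sample series
#'   0.290, 0.575, 1.152, 1.580, 2.299 g).
#' @param comp A [composition()] (default boric acid + container Al).
#' @param sigma Named generating NMD widths (1/A).
#' @param geometry An [instrument_geometry()].
#' @param counts_per_g Expected signal counts per detector per gram.
#' @param background Flat background counts per bin.
#' @param seed RNG seed (mandatory).
#' @return List: `samples` (per mass: list of spectra), `truth`.
#' @export
make_ncs_dataset <- function(masses_g = c(0.290, 0.575, 1.152, 1.580, 2.299),
                             comp = make_boric_acid_fixture(container_al = 2),
                             sigma = c(H = 4.78, B = 9.60, O = 11.4, Al = 13.8),
                             geometry = vesuvio_geometry(),
                             counts_per_g = 2e4, background = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  samples <- vector("list", length(masses_g))
  for (i in seq_along(masses_g)) {
    spectra <- vector("list", nrow(geometry))
    for (d in seq_len(nrow(geometry))) {
      spectra[[d]] <- simulate_spectrum(
        comp, sigma, geometry[d, ],
        total_counts = counts_per_g * masses_g[i],
        seed = seed + 1000L * i + d, background = background)
    }
    samples[[i]] <- spectra
  }
  list(samples = samples,
       truth = list(masses_g = masses_g, sigma = sigma,
                    counts_per_g = counts_per_g, background = background,
                    seed = seed))
}

#' Synthetic epithermal-transmission sensitivity series
#'
#' Scattering-power responses linear in sample mass with Gaussian noise of
#' the blank standard deviation, emulating the plateau-averaged transmission
#' analysis of a mass series.
#'
#' @param masses_g Sample masses in g.
#' @param slope_per_g Scattering power per gram (thin-sample linearity).
#' @param blank_sd Gaussian response noise / blank standard deviation.
#' @param seed RNG seed (mandatory).
#' @return List: `dataset` (a [sensitivity_dataset()]), `truth`.
#' @export
make_transmission_series <- function(masses_g = c(0.290, 0.575, 1.152,
                                                  1.580, 2.299),
                                     slope_per_g = 0.064, blank_sd = 0.003,
                                     seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  resp <- slope_per_g * masses_g + stats::rnorm(length(masses_g), 0, blank_sd)
  ds <- sensitivity_dataset(masses_g, resp, blank = 0, blank_sd = blank_sd,
                            channel = "transmission")
  list(dataset = ds, truth = list(slope_per_g = slope_per_g,
                                  blank_sd = blank_sd, seed = seed))
}

#' Synthetic prompt-gamma spectra for a sample-mass series
#'
#' For each sample, a 400-550 keV spectrum containing the Doppler-broadened
#' 478 keV boron line (area proportional to the boron mass), the 511 keV
#' annihilation line, and a linear background, Poisson-sampled; plus a
#' blank (boron-free apart from the environmental 478 keV background).
#'
#' @param masses_g Sample masses in g (boric acid).
#' @param area_per_gB 478 keV counts per gram of boron.
#' @param area511 511 keV annihilation line area in sample spectra
#'   (counts); dominated by pair production from beam-induced high-energy
#'   gammas, so only the fraction `blank511_frac` appears in the blank.
#' @param blank511_frac Fraction of the 511 keV line present in the blank.
#' @param env478 Environmental 478 keV background area present in every
#'   spectrum including the blank.
#' @param bg_level Flat background counts per keV.
#' @param width478,width511 Gaussian sd of the lines in keV (478 includes
#'   Doppler broadening).
#' @param comp Composition used to convert sample to boron mass.
#' @param seed RNG seed (mandatory).
#' @return List: `spectra` (per mass), `blank`, `boron_mass_g`, `truth`.
#' @export
make_gamma_series <- function(masses_g = c(0.290, 0.575, 1.152, 1.580, 2.299),
                              area_per_gB = 3000, area511 = 600,
                              blank511_frac = 0.3, env478 = 150,
                              bg_level = 20, width478 = 7.5, width511 = 4.5,
                              comp = make_boric_acid_fixture(), seed) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  E <- seq(400, 550, by = 1)
  fB <- mass_fraction(comp, "B")
  mk <- function(areaB, a511) {
    mu <- areaB * stats::dnorm(E, 478, width478) +
      a511 * stats::dnorm(E, 511, width511) +
      env478 * stats::dnorm(E, 478, width478) + bg_level
    gamma_spectrum(E, stats::rpois(length(E), mu))
  }
  spectra <- lapply(masses_g * fB * area_per_gB, mk, a511 = area511)
  blank <- mk(0, a511 = area511 * blank511_frac)
  list(spectra = spectra, blank = blank, boron_mass_g = masses_g * fB,
       truth = list(area_per_gB = area_per_gB, area511 = area511,
                    env478 = env478, bg_level = bg_level,
                    width478 = width478, width511 = width511, seed = seed))
}

#' Write generator ground truth next to a dataset
#'
#' Plain `key = value` text, one entry per generating parameter.
#'
#' @param truth Ground-truth list from a generator.
#' @param file Path.
#' @export
write_truth <- function(truth, file) {
  lines <- vapply(names(truth), function(k) {
    v <- truth[[k]]
    paste0(k, " = ", paste(format(unlist(v), digits = 10), collapse = " "))
  }, "")
  writeLines(lines, file)
  invisible(file)
}
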