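# Neutron Compton scattering: kinematics, y-scaling, simulation, fitting

test_that("y-transform vanishes at the recoil point and for elastic
          heavy-mass scattering", {
  # elastic point: omega = recoil energy -> y = 0 (fixed-point iteration
  # for the recoil E0, machine-precision accurate)
  E1 <- 4897
  recoil_E0 <- function(M, th) {
    bm <- 2.07212 * 1.00866 / M
    E0 <- E1
    for (i in 1:200) {
      q2 <- (E0 + E1 - 2 * sqrt(E0 * E1) * cos(th)) / 2.07212
      E0 <- E1 + bm * q2
    }
    E0
  }
  th <- 1.1
  for (M in c(1.00794, 10.811, 15.999)) {
    E0 <- recoil_E0(M, th)
    expect_equal(y_transform(E0, E1, th, M), 0, tolerance = 1e-6)
  }
  # M -> infinity: the y = 0 recoil point collapses onto the elastic line
  for (th in c(0.3, 1.0, 2.5)) {
    E0 <- recoil_E0(1e9, th)
    expect_equal(E0, E1, tolerance = 1e-6)
    expect_equal(y_transform(E0, E1, th, 1e9), 0, tolerance = 1e-4)
  }
})

test_that("y-transform agrees with an independently coded evaluation", {
  # oracle written in terms of wavevectors k0, k1 rather than energies
  y_oracle <- function(E0, E1, th, M) {
    C <- 2.07212                 # hbar^2/2m_n in meV A^2
    k0 <- sqrt(E0 / C); k1 <- sqrt(E1 / C)
    q <- sqrt(k0^2 + k1^2 - 2 * k0 * k1 * cos(th))
    hbar2_2M <- C * 1.00866 / M
    (E0 - E1 - hbar2_2M * q^2) / (2 * hbar2_2M * q)
  }
  for (p in list(c(21000, 4897, 0.8, 1.00794), c(9000, 4897, 2.4, 10.811),
                 c(6200, 4897, 2.0, 15.999))) {
    expect_equal(y_transform(p[1], p[2], p[3], p[4]),
                 y_oracle(p[1], p[2], p[3], p[4]), tolerance = 1e-9)
  }
})

test_that("recoil TOF: elastic limit, equal-mass kinematics and peak
          ordering in the forward window", {
  g <- vesuvio_geometry(8, 8)
  det <- g[4, ]
  # M -> infinity: E0 = E1 and t = (L0+L1)/v(E1)
  t_inf <- recoil_center(1e9, det)
  v1 <- neutron_constants()$v_conv * sqrt(det$E1_meV) * 1e-6
  expect_equal(t_inf, (det$L0 + det$L1) / v1, tolerance = 1e-6)

  # equal neutron-target masses at 60 degrees: E0 = 4 E1
  det60 <- instrument_geometry(11.005, 0.7, 60, 4897, 2, "forward")[1, ]
  t60 <- recoil_center(neutron_constants()$m_n_amu, det60)
  E0 <- tof_to_E0(t60, det60)
  expect_equal(E0, 4 * det60$E1_meV, tolerance = 1e-6 * E0)

  # forward-bank ordering and windows
  detf <- g[5, ]
  tH <- recoil_center(1.00794, detf); tB <- recoil_center(10.811, detf)
  tO <- recoil_center(15.999, detf); tAl <- recoil_center(26.98154, detf)
  expect_true(tH < tB && tB < tO && tO < tAl)
  expect_true(tH > 100 && tH < 350)
  expect_true(abs(tB - 360) < 20)
  expect_true(abs(tO - 370) < 15)
  expect_true(abs(tAl - 380) < 15)
})

test_that("hydrogen recoil is kinematically excluded beyond 90 degrees", {
  back <- instrument_geometry(11.005, 0.7, 135, 4897, 4, "back")[1, ]
  expect_error(recoil_center(1.00794, back), "forward scattering")
  expect_error(recoil_center(neutron_constants()$m_n_amu, back),
               "forward scattering")
})

test_that("simulated peaks sit at the kinematic recoil times", {
  # H + B only, so neighbouring recoil peaks cannot shadow the maxima
  comp <- composition(c("H", "B"), c(3, 1))
  det <- instrument_geometry(11.005, 0.7, 45, 4897, 0.3, "forward")[1, ]
  narrow <- c(H = 0.5, B = 0.8)
  sp <- simulate_spectrum(comp, narrow, det, total_counts = 1e6, seed = 5,
                          noise = FALSE, tof = seq(60, 460, by = 0.5))
  for (m in c(H = 1.00794, B = 10.811)) {
    tc <- recoil_center(m, det)
    sel <- abs(sp$tof - tc) < 15
    pk <- sp$tof[sel][which.max(sp$counts[sel])]
    expect_lt(abs(pk - tc), 1)  # within one to two TOF bins
  }
  # simulated peak maximum maps to y = 0 within one TOF bin
  tc <- recoil_center(10.811, det)
  E0pk <- tof_to_E0(tc, det)
  expect_equal(y_transform(E0pk, det$E1_meV, det$theta_deg * pi / 180,
                           10.811), 0, tolerance = 0.2)
})

test_that("simulated totals and constrained intensities follow the
          generating constants", {
  comp <- ba_comp(al = 2)
  det <- vesuvio_geometry(4, 4)[2, ]
  sp <- simulate_spectrum(comp, gen_sigma, det, total_counts = 2e4, seed = 9)
  expect_lt(abs(sum(sp$counts) - 2e4), 5 * sqrt(2e4))

  # Eq-constraint arithmetic with tabulated cross-sections
  expect_equal(intensity_ratio(comp, "H", "B"), 3 * 82.02 / 5.24,
               tolerance = 1e-9)
  expect_equal(intensity_ratio(comp, "B", "B"), 1)
  c2 <- composition(c("H", "B"), c(6, 1))
  expect_equal(intensity_ratio(c2, "H", "B"),
               2 * intensity_ratio(comp, "H", "B"), tolerance = 1e-12)
})

test_that("back-then-forward fit is an exact round trip without noise", {
  comp <- ba_comp(al = 2)
  geom <- small_geometry()
  spectra <- lapply(seq_len(nrow(geom)), function(d)
    simulate_spectrum(comp, gen_sigma, geom[d, ], total_counts = 5e4,
                      seed = 1, noise = FALSE))
  fit <- fit_back_then_forward(spectra, comp, geom)
  for (s in c("B", "O", "Al")) {
    got <- fit$back_avg$sigma[fit$back_avg$species == s]
    expect_equal(got, gen_sigma[[s]], tolerance = 0.005 * gen_sigma[[s]])
  }
  expect_equal(unname(fit$sigma_H["value"]), gen_sigma[["H"]],
               tolerance = 0.005 * gen_sigma[["H"]])
})

test_that("fitted widths are bias-free under count doubling", {
  comp <- ba_comp(al = 2)
  geom <- small_geometry()
  fit_at <- function(n) {
    spectra <- lapply(seq_len(nrow(geom)), function(d)
      simulate_spectrum(comp, gen_sigma, geom[d, ], total_counts = n,
                        seed = 1, noise = FALSE))
    fit_back_then_forward(spectra, comp, geom)
  }
  f1 <- fit_at(5e4); f2 <- fit_at(1e5)
  expect_equal(f2$back_avg$sigma, f1$back_avg$sigma, tolerance = 0.01)
  expect_equal(unname(f2$sigma_H["value"]), unname(f1$sigma_H["value"]),
               tolerance = 0.01)
})

test_that("Poisson-noised fits recover the generating widths", {
  comp <- ba_comp(al = 2)
  geom <- small_geometry()
  spectra <- lapply(seq_len(nrow(geom)), function(d)
    simulate_spectrum(comp, gen_sigma, geom[d, ], total_counts = 1e5,
                      seed = 40 + d, background = 3))
  fit <- fit_back_then_forward(spectra, comp, geom)
  sH <- fit$sigma_H
  expect_lt(abs(sH["value"] - gen_sigma[["H"]]),
            3 * max(sH["se"], 0.02))
  for (s in c("B", "O")) {
    row <- fit$back_avg[fit$back_avg$species == s, ]
    expect_lt(abs(row$sigma - gen_sigma[[s]]), 4 * max(row$sd, 0.05))
  }
})

test_that("a boron isotope mixture fits acceptably as one natural peak", {
  tab <- isotope_table()
  comp_mix <- composition(c("H", "B10", "B11", "O", "Al"),
                          c(3, 0.199, 0.801, 3, 2))
  s10 <- isotope_scale(9.60, 10.811, tab$mass_amu[tab$species == "B10"],
                       "width")
  s11 <- isotope_scale(9.60, 10.811, tab$mass_amu[tab$species == "B11"],
                       "width")
  sig_mix <- c(H = 4.78, B10 = s10, B11 = s11, O = 11.4, Al = 13.8)
  geom <- small_geometry()
  spectra <- lapply(seq_len(nrow(geom)), function(d)
    simulate_spectrum(comp_mix, sig_mix, geom[d, ], total_counts = 1e5,
                      seed = 2, noise = FALSE))
  # a single natural-B Gaussian describes the two-isotope mixture: the
  # recovered width sits at the natural value to within the broadening
  comp_nat <- ba_comp(al = 2)
  fit <- fit_back_then_forward(spectra, comp_nat, geom)
  sB <- fit$back_avg$sigma[fit$back_avg$species == "B"]
  expect_equal(sB, 9.60, tolerance = 0.02 * 9.60)
})
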