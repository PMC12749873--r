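# Total neutron cross-sections: 1/v absorption, epithermal plateau,
# free-recoil law, multiphonon expansion, transmission

test_that("1/v absorption law", {
  expect_equal(absorption_xs(0.0253, 767), 767)
  expect_equal(absorption_xs(4 * 0.0253, 767), 767 / 2)
  # boron-10 at 1 eV from the tabulated thermal value
  expect_equal(absorption_xs(1, 3835), 3835 * sqrt(0.0253), tolerance = 1e-9)
  expect_equal(absorption_xs(1, 3835), 610, tolerance = 1)
})

test_that("epithermal plateau is the free-atom cross-section sum", {
  tab <- isotope_table()
  heavy <- composition("Al", 1,
                       table = transform(tab, mass_amu = 1e9))
  expect_equal(epithermal_plateau(heavy),
               tab$sigma_scatt_barn[tab$species == "Al"], tolerance = 1e-6)

  h <- composition("H", 1)
  expect_equal(epithermal_plateau(h),
               h$sigma_scatt_barn / 4, tolerance = 1e-3 * h$sigma_scatt_barn)

  # term-by-term hand sum for boric acid
  comp <- ba_comp()
  mn <- neutron_constants()$m_n_amu
  oracle <- sum(comp$count * comp$sigma_scatt_barn /
                  (1 + mn / comp$mass_amu)^2)
  expect_equal(epithermal_plateau(comp), oracle, tolerance = 1e-12)
})

test_that("free-recoil double-differential peaks at the recoil energy", {
  comp <- composition("O", 1)
  E0 <- 50
  th <- pi / 3
  E1 <- seq(40, 50, by = 0.002)
  dd <- sapply(E1, function(e1) epithermal_ddxs(E0, e1, th, comp,
                                                c(O = 50.9)))
  # analytic recoil transfer at the maximising E1
  e1max <- E1[which.max(dd)]
  q2 <- (E0 * 1e3 + e1max * 1e3 -
           2 * sqrt(E0 * e1max) * 1e3 * cos(th)) / 2.07212
  wr <- 2.07212 * (1.00866 / 15.999) * q2
  expect_equal((E0 - e1max) * 1e3, wr, tolerance = 0.01 * wr)

  # M -> infinity: recoil collapses toward the elastic line
  big <- composition("O", 1, table = data.frame(
    species = "O", mass_amu = 1e6, sigma_scatt_barn = 4.232,
    sigma_abs_barn = 0))
  ddb <- sapply(E1, function(e1) epithermal_ddxs(E0, e1, pi / 3, big,
                                                 c(O = 50.9)))
  expect_gt(E1[which.max(ddb)], 49.9)
})

test_that("free-recoil integral reaches the plateau at epithermal energy", {
  comp <- ba_comp()
  pl <- epithermal_plateau(comp)
  es <- epithermal_sigma(50, comp, ba_ek)
  expect_equal(es, pl, tolerance = 0.005 * pl)
  # descends monotonically into the plateau from above
  vals <- epithermal_sigma(c(1, 3, 10, 30, 100), comp, ba_ek)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > pl))
})

test_that("multiphonon expansion has the free-gas limit for a heavy,
          nearly classical target", {
  tab <- data.frame(species = "X", mass_amu = 200, sigma_scatt_barn = 10,
                    sigma_abs_barn = 0)
  comp <- composition("X", 1, table = tab)
  vd <- list(X = debye_vdos(1, seq(0, 2, by = 0.004), "X"))
  Tgas <- 100
  kB <- neutron_constants()$k_B
  sigma_free <- 10 / (1 + 1.00866 / 200)^2
  mb <- function(E0eV) {  # Doppler-averaged constant cross-section gas
    a2 <- (200 / 1.00866) * E0eV * 1e3 / (kB * Tgas)
    a <- sqrt(a2)
    erfa <- 2 * stats::pnorm(a * sqrt(2)) - 1
    sigma_free * ((1 + 1 / (2 * a2)) * erfa + exp(-a2) / (a * sqrt(pi)))
  }
  E0 <- c(5e-4, 1e-3, 5e-3)
  cv <- multiphonon_total_xs(vd, comp, T = Tgas, E0_grid = E0, n_mu = 41,
                             absorption = FALSE)
  for (i in seq_along(E0))
    expect_equal(cv$sigma_scatt[i], mb(E0[i]), tolerance = 0.02 * mb(E0[i]))
})

test_that("hydrogen-dominated curve shows bound enhancement and descends
          to the plateau", {
  comp <- ba_comp()
  vd <- boric_acid_toy_vdos(default_grid(500, 1))
  E0 <- 10^seq(log10(0.0253), 2, length.out = 30)
  cv <- multiphonon_total_xs(vd, comp, T = 300, E0_grid = E0, n_mu = 15)
  pl <- epithermal_plateau(comp)
  bound <- sum(comp$count * comp$sigma_scatt_barn)
  i_th <- which.min(abs(cv$E0_eV - 0.0253))
  expect_gt(cv$sigma_scatt[i_th], pl)          # above free-atom value
  expect_lt(cv$sigma_scatt[i_th], bound)       # below the bound sum
  sel <- cv$E0_eV >= 0.1
  expect_true(all(diff(cv$sigma_scatt[sel]) < 1e-9))
  i50 <- which.min(abs(cv$E0_eV - 50))
  expect_equal(cv$sigma_scatt[i50], pl, tolerance = 0.01 * pl)
  expect_true(all(cv$sigma_total >= cv$sigma_abs))
  expect_true(all(cv$sigma_abs >= 0))
})

test_that("multiphonon result is invariant to grid refinement and order", {
  comp <- ba_comp()
  E0 <- c(0.0253, 0.1)
  a <- multiphonon_total_xs(boric_acid_toy_vdos(default_grid(500, 1)),
                            comp, 300, E0_grid = E0, n_mu = 15)
  b <- multiphonon_total_xs(boric_acid_toy_vdos(default_grid(500, 0.5)),
                            comp, 300, E0_grid = E0, n_mu = 15)
  d <- multiphonon_total_xs(boric_acid_toy_vdos(default_grid(500, 1)),
                            comp, 300, E0_grid = E0, n_mu = 15, n_max = 10)
  expect_equal(b$sigma_scatt, a$sigma_scatt, tolerance = 0.01)
  expect_equal(d$sigma_scatt, a$sigma_scatt, tolerance = 0.01)
  expect_true(all(a$mpe))
})

test_that("transmission follows Beer-Lambert in areal density", {
  curve <- data.frame(E0_eV = c(1, 10, 50, 100),
                      sigma_total = c(90, 80, 78, 77))
  g0 <- sample_geometry(areal_density = 0)
  expect_equal(transmission(curve, g0)$transmission, rep(1, 4))

  g1 <- sample_geometry(areal_density = 1e22)
  g2 <- sample_geometry(areal_density = 2e22)
  t1 <- transmission(curve, g1)$transmission
  t2 <- transmission(curve, g2)$transmission
  expect_equal(t2, t1^2, tolerance = 1e-12)

  # plateau average equals the closed form
  flat <- data.frame(E0_eV = seq(10, 100, by = 1),
                     sigma_total = rep(77.1, 91))
  tr <- transmission(flat, g1)
  expect_equal(plateau_scattering_power(tr),
               1 - exp(-1e22 * 77.1 * 1e-24), tolerance = 1e-12)

  # container multiplies in
  cont <- data.frame(E0_eV = flat$E0_eV, transmission = rep(0.9, 91))
  trc <- transmission(flat, g1, container = cont)
  expect_equal(trc$transmission, tr$transmission * 0.9, tolerance = 1e-12)
})

test_that("scattering power is linear in mass for thin samples", {
  expect_equal(plateau_scattering_power(
    data.frame(E0_eV = c(10, 50, 100), transmission = c(1, 1, 1))), 0)
  expect_equal(plateau_scattering_power(
    data.frame(E0_eV = c(10, 50, 100), transmission = rep(0.9, 3))), 0.1)

  sigma <- 77.1
  nd <- seq(5e19, 4e20, length.out = 5)  # thin samples
  power <- sapply(nd, function(x) {
    tr <- transmission(data.frame(E0_eV = seq(10, 100, 10),
                                  sigma_total = rep(sigma, 10)),
                       sample_geometry(areal_density = x))
    plateau_scattering_power(tr)
  })
  lin <- nd * sigma * 1e-24  # first-order expansion oracle
  expect_lt(max(abs(power - lin) / lin), 0.02)
})
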