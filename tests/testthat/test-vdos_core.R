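# VDoS construction: mode binning, VACF transform, analytic models, mixtures

test_that("mode binning puts delta weight in the right bins and normalises", {
  ms <- mode_set(q_weight = 1, branch = 1, omega = 100,
                 eigvec_weights = matrix(1, 1, 1, dimnames = list(NULL, "H")))
  v <- apvdos_from_modes(ms, "H", grid = default_grid(), smear_fwhm = 0)
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
  expect_equal(v$omega[which.max(v$density)], 100)

  # two modes sharing one q-point, eigenvector weighting 1:3 for H
  ew <- matrix(c(0.25, 0.75, 0.75, 0.25), 2, 2,
               dimnames = list(NULL, c("H", "X")))
  ms2 <- mode_set(q_weight = c(1, 1), branch = c(1, 2), omega = c(50, 150),
                  eigvec_weights = ew)
  v2 <- apvdos_from_modes(ms2, "H", smear_fwhm = 0)
  m50 <- v2$density[v2$omega == 50]
  m150 <- v2$density[v2$omega == 150]
  expect_equal(m150 / m50, 3, tolerance = 1e-9)
})

test_that("mode-binned VDoS first moment matches the direct weighted sum", {
  set.seed(42)
  n <- 30
  w <- runif(n, 5, 450)
  qw <- rep(1, n)
  eh <- runif(n); ew <- cbind(H = eh, X = 1 - eh)
  ms <- mode_set(qw, seq_len(n), w, ew)
  v <- apvdos_from_modes(ms, "H", smear_fwhm = 0)
  oracle <- sum(qw * eh * w) / sum(qw * eh)  # brute-force weighted mean
  m1 <- trapz(v$omega, v$omega * v$density)
  expect_lt(abs(m1 - oracle), (v$omega[2] - v$omega[1]) / 2)
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
})

test_that("imaginary modes and unknown species are rejected with context", {
  ew <- matrix(1, 1, 1, dimnames = list(NULL, "H"))
  expect_error(mode_set(1, 1, -5, ew), "imaginary")
  ms <- mode_set(1, 1, 100, ew)
  expect_error(apvdos_from_modes(ms, "Zr"), "unknown species")
})

test_that("Gaussian smearing preserves normalisation and the first moment", {
  ms <- mode_set(c(1, 1), c(1, 2), c(80, 220),
                 eigvec_weights = matrix(1, 2, 1,
                                         dimnames = list(NULL, "H")))
  v <- apvdos_from_modes(ms, "H", smear_fwhm = 2)
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
  m1 <- trapz(v$omega, v$omega * v$density)
  expect_equal(m1, 150, tolerance = 1e-3)
})

test_that("VACF route recovers tone frequencies and weights", {
  osc <- make_oscillator_trajectory(100, T = 300, n_steps = 4096, dt = 0.5,
                                    seed = 11)
  v <- vdos_from_vacf(osc$traj, "H")
  expect_equal(v$omega[which.max(v$density)], 100,
               tolerance = v$omega[2] - v$omega[1])
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)

  # two equal-amplitude tones: equal integrated band weights within 5%
  osc2 <- make_oscillator_trajectory(c(50, 150), T = 300, n_steps = 8192,
                                     dt = 0.5, seed = 12, n_atoms = 4)
  v2 <- vdos_from_vacf(osc2$traj, "H")
  band <- function(v, lo, hi) {
    sel <- v$omega >= lo & v$omega <= hi
    trapz(v$omega[sel], v$density[sel])
  }
  w50 <- band(v2, 30, 70); w150 <- band(v2, 130, 170)
  expect_equal(w50 / w150, 1, tolerance = 0.05)
})

test_that("white-noise velocities give a flat unit-integral spectrum", {
  set.seed(3)
  vel <- array(rnorm(2048 * 4 * 3, sd = 0.01), dim = c(2048, 4, 3))
  tr <- trajectory(vel, rep("H", 4), timestep = 0.5)
  v <- vdos_from_vacf(tr, "H", grid = default_grid(400, 1))
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
  # flat in the mean: halves of the band carry similar weight
  sel1 <- v$omega <= 200; sel2 <- v$omega > 200
  w1 <- trapz(v$omega[sel1], v$density[sel1])
  w2 <- trapz(v$omega[sel2], v$density[sel2])
  expect_equal(w1 / w2, 1, tolerance = 0.25)
})

test_that("Debye model follows the omega^2 law with analytic moments", {
  g <- seq(0, 100, by = 0.05)
  v <- debye_vdos(60, g)
  expect_equal(v$density[v$omega == 30] / v$density[v$omega == 15], 4)
  expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
  m1 <- trapz(v$omega, v$omega * v$density)
  expect_equal(m1, 45, tolerance = 1e-3)  # (3/4) cutoff
  expect_error(debye_vdos(200, g), "outside")
})

test_that("mixtures renormalise and preserve component bookkeeping", {
  g <- default_grid()
  a <- debye_vdos(50, g)
  expect_equal(mixture_vdos(list(a), 2)$density, a$density, tolerance = 1e-12)

  b <- vdos(g, dnorm(g, 300, 10))
  mix <- mixture_vdos(list(a, b), c(1, 1))
  lo <- trapz(g[g <= 100], mix$density[g <= 100])
  hi <- trapz(g[g >= 200], mix$density[g >= 200])
  expect_equal(lo, 0.5, tolerance = 1e-6)
  expect_equal(hi, 0.5, tolerance = 1e-6)
  expect_error(mixture_vdos(list(), numeric(0)), "empty")

  # Debye base + 3-band H model: integral bookkeeping
  h3 <- make_toy_vdos(list(c(100, 12, 0.4), c(150, 12, 0.33),
                           c(400, 10, 0.27)))$vdos
  m2 <- mixture_vdos(list(debye_vdos(45, g), h3), c(0.3, 0.7))
  expect_equal(trapz(g, m2$density), 1, tolerance = 1e-9)
})

test_that("VDoS and mode-table text round trips preserve content", {
  tf <- tempfile(fileext = ".dat")
  v <- debye_vdos(60)
  write_vdos(v, tf)
  v2 <- read_vdos(tf, species = "TOT")
  expect_equal(v2$density, v$density, tolerance = 1e-6)

  tf2 <- tempfile(fileext = ".dat")
  writeLines(c("# harmonic modes", "q_weight branch omega_meV H_w O_w",
               "0.5 1 100 0.7 0.3", "0.5 2 200 0.2 0.8",
               "0.5 1 110 0.7 0.3", "0.5 2 210 0.2 0.8"), tf2)
  ms <- read_mode_table(tf2)
  expect_equal(length(ms$omega), 4)
  v3 <- apvdos_from_modes(ms, "O", smear_fwhm = 0)
  expect_equal(trapz(v3$omega, v3$density), 1, tolerance = 1e-9)
})

test_that("every constructor yields a unit trapezoidal integral", {
  cases <- list(
    debye_vdos(60),
    make_toy_vdos(list(c(100, 10, 1)))$vdos,
    boric_acid_toy_vdos()$H,
    mixture_vdos(list(debye_vdos(40), debye_vdos(80)), c(1, 2))
  )
  for (v in cases)
    expect_equal(trapz(v$omega, v$density), 1, tolerance = 1e-9)
})
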