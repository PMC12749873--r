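# shared fixtures, all generated in code

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

ba_comp <- function(al = 0) make_boric_acid_fixture(container_al = al)

small_geometry <- function(nf = 4, nb = 4) vesuvio_geometry(nf, nb)

# generating NMD widths used across NCS tests
gen_sigma <- c(H = 4.78, B = 9.60, O = 11.4, Al = 13.8)

# nuclear kinetic energies (meV) as fitted for boric acid at room temperature
ba_ek <- c(H = 142.1, B = 53.5, O = 50.9)

# near-delta VDoS: all density in the grid point nearest each centre
delta_vdos <- function(centres, weights = rep(1, length(centres)),
                       grid = default_grid()) {
  dens <- numeric(length(grid))
  h <- grid[2] - grid[1]
  for (i in seq_along(centres)) {
    j <- which.min(abs(grid - centres[i]))
    dens[j] <- dens[j] + weights[i] / h
  }
  vdos(grid, dens)
}
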