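## Vibrational density of states: container, constructors from harmonic mode
## lists, normalisation and serialisation.

#' Construct a vibrational density of states
#'
#' A `vdos` object holds a non-negative density on a uniform, strictly
#' ascending energy grid (meV). On construction the density is renormalised so
#' that its trapezoidal integral is exactly 1 (the `unit` convention); the raw
#' integral is kept in the `scale` attribute so mode-count conventions can be
#' recovered.
#'
#' @param omega Energy grid in meV, uniform and strictly increasing.
#' @param density Non-negative density values on `omega`.
#' @param species Species label (e.g. `"H"`), or `"TOT"` for a total VDoS.
#' @param normalise Renormalise to unit integral (default `TRUE`).
#' @return Object of class `vdos`: list with `omega`, `density`, `species`.
#' @export
vdos <- function(omega, density, species = "TOT", normalise = TRUE) {
  omega <- as.numeric(omega)
  density <- as.numeric(density)
  if (length(omega) < 2L || length(omega) != length(density))
    stop("omega and density must have equal length >= 2")
  d <- diff(omega)
  if (any(d <= 0)) stop("omega grid must be strictly increasing")
  if (any(abs(d - d[1]) > 1e-8 * d[1])) stop("omega grid must be uniform")
  if (any(!is.finite(density)) || any(density < -1e-12 * max(abs(density))))
    stop("density must be finite and non-negative")
  density[density < 0] <- 0
  raw <- trapz(omega, density)
  if (normalise) {
    if (raw <= 0) stop("density integrates to zero; cannot normalise")
    density <- density / raw
  }
  structure(list(omega = omega, density = density, species = species),
            scale = raw, class = "vdos")
}

#' @export
print.vdos <- function(x, ...) {
  cat(sprintf("<vdos> species=%s, grid %g..%g meV (%d pts), integral=%.6f\n",
              x$species, min(x$omega), max(x$omega), length(x$omega),
              trapz(x$omega, x$density)))
  invisible(x)
}

## trapezoidal integral on an arbitrary grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Default energy grid
#'
#' 0 to 500 meV in 0.5 meV steps: covers the full vibrational range of
#' hydrogen-bonded molecular crystals including the O-H stretch region
#' (~390-412 meV in boric acid).
#'
#' @param max_meV Upper edge (meV).
#' @param step Grid spacing (meV).
#' @return Numeric vector.
#' @export
default_grid <- function(max_meV = 500, step = 0.5) seq(0, max_meV, by = step)

#' Construct a harmonic mode set
#'
#' Holds phonon modes as records of q-point weight, branch index, frequency
#' (meV) and per-atom-species eigenvector weights (magnitude squared,
#' summing to 1 over species for each mode).
#'
#' @param q_weight Fractional q-point weights; must sum to 1 per q-point
#'   partition (each mode row carries the weight of its q-point).
#' @param branch Integer branch index of each mode.
#' @param omega Mode frequencies in meV (must be >= 0; imaginary modes,
#'   encoded as negative frequencies, are rejected as diagnostic of an
#'   unstable structure).
#' @param eigvec_weights Matrix (modes x species) of squared eigenvector
#'   magnitudes, columns named by species; each row must sum to 1 within
#'   `tol`.
#' @param tol Tolerance on the per-mode eigenvector weight sum.
#' @return Object of class `mode_set`.
#' @export
mode_set <- function(q_weight, branch, omega, eigvec_weights, tol = 1e-6) {
  eigvec_weights <- as.matrix(eigvec_weights)
  n <- length(omega)
  if (length(q_weight) != n || length(branch) != n ||
      nrow(eigvec_weights) != n)
    stop("q_weight, branch, omega and eigvec_weights rows must align")
  if (is.null(colnames(eigvec_weights)))
    stop("eigvec_weights columns must be named by species")
  bad <- which(omega < 0)
  if (length(bad))
    stop(sprintf("imaginary (negative-frequency) mode rejected: branch %d at %g meV",
                 branch[bad[1]], omega[bad[1]]))
  if (any(eigvec_weights < -1e-12)) stop("eigenvector weights must be >= 0")
  rs <- rowSums(eigvec_weights)
  if (any(abs(rs - 1) > tol))
    stop("per-mode eigenvector weights must sum to 1 over species")
  ## q-weights must sum to 1 over distinct q-points; modes at one q-point
  ## share its weight, so sum(q_weight)/n_branches == 1
  nb <- length(unique(branch))
  if (abs(sum(q_weight) / nb - 1) > 1e-6)
    stop("q-point weights must sum to 1")
  structure(list(q_weight = q_weight, branch = branch, omega = omega,
                 eigvec_weights = eigvec_weights),
            class = "mode_set")
}

#' Atom-projected VDoS from a harmonic mode list
#'
#' Bins each mode as a delta function at its frequency, weighted by the
#' q-point weight times the squared eigenvector magnitude of the requested
#' species, then renormalises to unit integral. An optional Gaussian smearing
#' (post-binning) mimics finite q-sampling.
#'
#' @param modes A [mode_set()].
#' @param species Species column to project on.
#' @param grid Energy grid (meV) spanning `[0, max(omega)]`.
#' @param smear_fwhm Gaussian smearing FWHM in meV (default 2; 0 disables).
#' @return A [vdos()].
#' @export
apvdos_from_modes <- function(modes, species, grid = default_grid(),
                              smear_fwhm = 2) {
  if (!inherits(modes, "mode_set")) stop("modes must be a mode_set")
  if (!species %in% colnames(modes$eigvec_weights))
    stop("unknown species: ", species)
  if (max(modes$omega) > max(grid) || min(grid) > 0)
    stop("grid must span [0, max mode frequency]")
  w <- modes$q_weight * modes$eigvec_weights[, species]
  h <- grid[2] - grid[1]
  ## bin index of the grid point nearest each mode frequency
  idx <- pmin(pmax(round((modes$omega - grid[1]) / h), 0), length(grid) - 1L) + 1L
  dens <- numeric(length(grid))
  tab <- tapply(w, idx, sum)
  dens[as.integer(names(tab))] <- as.numeric(tab) / h
  out <- vdos(grid, dens, species = species)
  if (smear_fwhm > 0) out <- smear_vdos(out, smear_fwhm)
  out
}

#' Gaussian smearing of a VDoS
#'
#' Convolves the density with a Gaussian kernel of the given FWHM and
#' renormalises. Mass below the lower grid edge is reflected back so the
#' integral near omega = 0 is preserved.
#'
#' @param v A [vdos()].
#' @param fwhm Kernel FWHM in meV.
#' @return Smeared [vdos()].
#' @export
smear_vdos <- function(v, fwhm) {
  if (fwhm <= 0) return(v)
  h <- v$omega[2] - v$omega[1]
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sd / h))
  kx <- (-half:half) * h
  k <- exp(-kx^2 / (2 * sd^2))
  k <- k / sum(k)
  n <- length(v$density)
  ## full linear convolution; element j corresponds to grid index j - half
  conv <- stats::convolve(v$density, rev(k), type = "open")
  sm <- conv[(half + 1):(half + n)]
  ## fold mass leaked below omega = min(grid) back across the edge
  if (half >= 1) {
    for (m in 1:half) {
      if (1 + m <= n) sm[1 + m] <- sm[1 + m] + conv[half + 1 - m]
    }
  }
  sm[sm < 0] <- 0
  vdos(v$omega, sm, species = v$species)
}

#' Debye-model VDoS
#'
#' Density proportional to \eqn{\omega^2} up to the cutoff and zero above,
#' i.e. \eqn{G(\omega) = 3\omega^2/\omega_D^3} for
#' \eqn{\omega \le \omega_D}.
#'
#' @param cutoff Debye cutoff energy in meV (> 0, inside the grid).
#' @param grid Energy grid (meV).
#' @param species Species label.
#' @return A [vdos()].
#' @export
debye_vdos <- function(cutoff, grid = default_grid(), species = "TOT") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (cutoff > max(grid)) stop("cutoff lies outside the grid")
  dens <- ifelse(grid <= cutoff, 3 * grid^2 / cutoff^3, 0)
  vdos(grid, dens, species = species)
}

#' Weighted mixture of VDoSes
#'
#' Linear combination of component VDoSes with non-negative weights,
#' renormalised to unit integral (the construction behind averaged
#' functional-group VDoS models, e.g. an OH-stretch library average plus a
#' Debye base for the heavy sublattice).
#'
#' @param components List of [vdos()] objects on a common grid.
#' @param weights Non-negative weights, at least one positive.
#' @param species Label of the result.
#' @return A [vdos()].
#' @export
mixture_vdos <- function(components, weights, species = "MIX") {
  if (!length(components)) stop("empty component list")
  if (length(weights) != length(components)) stop("one weight per component")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be >= 0 and sum to > 0")
  g <- components[[1]]$omega
  for (v in components)
    if (length(v$omega) != length(g) || any(abs(v$omega - g) > 1e-9))
      stop("components must share a common grid")
  dens <- Reduce(`+`, Map(function(v, w) w * v$density, components,
                          as.list(weights)))
  vdos(g, dens, species = species)
}

#' Read a delimited mode table
#'
#' Expected header: `q_weight branch omega_meV <species>_w ...`, whitespace
#' separated, `#` comments tolerated.
#'
#' @param file Path.
#' @return A [mode_set()].
#' @export
read_mode_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, comment.char = "#")
  wcols <- grep("_w$", names(tab), value = TRUE)
  if (!length(wcols)) stop("no species weight columns (suffix _w) found")
  ew <- as.matrix(tab[, wcols, drop = FALSE])
  colnames(ew) <- sub("_w$", "", wcols)
  mode_set(tab$q_weight, tab$branch, tab$omega_meV, ew)
}

#' Write / read a VDoS as two-column text
#'
#' @param v A [vdos()] (for writing).
#' @param file Path.
#' @param species Species label to attach on reading.
#' @return `read_vdos` returns a [vdos()]; `write_vdos` returns `file`
#'   invisibly.
#' @export
write_vdos <- function(v, file) {
  utils::write.table(data.frame(omega_meV = v$omega, density = v$density),
                     file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_vdos
#' @export
read_vdos <- function(file, species = "TOT") {
  tab <- utils::read.table(file, header = TRUE, comment.char = "#")
  vdos(tab[[1]], tab[[2]], species = species)
}
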