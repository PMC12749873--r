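## VDoS from molecular-dynamics velocity trajectories via the velocity
## autocorrelation function (VACF).

#' Construct a velocity trajectory
#'
#' @param velocities Numeric array `frames x atoms x 3` of Cartesian
#'   velocities in A/fs, or a list of per-frame `atoms x 3` matrices.
#' @param species Character vector of per-atom species labels.
#' @param timestep Time between frames in fs (> 0).
#' @param temperature_nominal Nominal temperature in K (metadata only).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(velocities, species, timestep,
                       temperature_nominal = NA_real_) {
  if (is.list(velocities))
    velocities <- aperm(simplify2array(velocities), c(3, 1, 2))
  if (length(dim(velocities)) != 3L || dim(velocities)[3] != 3L)
    stop("velocities must be a frames x atoms x 3 array")
  if (dim(velocities)[1] < 2L) stop("trajectory needs at least 2 frames")
  if (dim(velocities)[2] != length(species))
    stop("one species label per atom required")
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be > 0")
  structure(list(velocities = velocities, species = species,
                 timestep = timestep,
                 temperature_nominal = temperature_nominal),
            class = "trajectory")
}

## FFT-based autocorrelation of one signal, lags 0..max_lag, unbiased-ish
## normalisation by the number of overlapping samples per lag.
.acf_fft <- function(x, max_lag) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2)
  fx <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1L)] / m
  ac / (n - 0:max_lag) * n  # rescale to per-sample averages
}

#' VDoS from the velocity autocorrelation function
#'
#' Computes the normalised VACF
#' \eqn{\langle v(t)\cdot v(0)\rangle/\langle v(0)^2\rangle} averaged over
#' all atoms of a species (all three Cartesian components) and
#' cosine-transforms it onto the energy grid. No correction is applied for
#' the integrator-induced frequency shift. Small negative spectral values
#' arising from the finite window are clipped to zero before the unit
#' renormalisation.
#'
#' @param traj A [trajectory()].
#' @param species Species to project on (must be present).
#' @param grid Energy grid in meV.
#' @param max_lag Maximum lag in frames; default `floor(frames/2)`, and the
#'   requested value may not exceed that.
#' @param remove_mean Subtract the per-atom mean velocity first (default
#'   `TRUE`).
#' @param window `"none"` (default) or `"hann"` taper on the VACF.
#' @return A [vdos()].
#' @export
vdos_from_vacf <- function(traj, species, grid = default_grid(),
                           max_lag = NULL, remove_mean = TRUE,
                           window = c("none", "hann")) {
  window <- match.arg(window)
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  atoms <- which(traj$species == species)
  if (!length(atoms)) stop("species absent from trajectory: ", species)
  nf <- dim(traj$velocities)[1]
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  if (max_lag > nf %/% 2L)
    stop("max_lag exceeds half the trajectory length")
  vacf <- numeric(max_lag + 1L)
  norm0 <- 0
  for (a in atoms) {
    for (k in 1:3) {
      x <- traj$velocities[, a, k]
      if (remove_mean) x <- x - mean(x)
      vacf <- vacf + .acf_fft(x, max_lag)
      norm0 <- norm0 + mean(x^2)
    }
  }
  vacf <- vacf / norm0
  t <- (0:max_lag) * traj$timestep  # fs
  w <- rep(1, length(t))
  if (window == "hann") w <- 0.5 * (1 + cos(pi * t / max(t)))
  ## trapezoid weights on the half-line cosine transform
  tw <- rep(traj$timestep, length(t))
  tw[c(1, length(t))] <- traj$timestep / 2
  phase <- outer(grid, t / .hbar_meV_fs)  # omega * t / hbar
  dens <- as.numeric(cos(phase) %*% (vacf * w * tw))
  dens[dens < 0] <- 0
  if (all(dens == 0)) stop("VACF transform produced an empty spectrum")
  vdos(grid, dens, species = species)
}

#' Read a velocity trajectory from extended-XYZ text
#'
#' Accepts the common extended-XYZ layout: per frame, an atom count line, a
#' comment line, then one line per atom with the species label followed by at
#' least six numeric columns of which the last three (or the columns named by
#' `vel_cols`) are the Cartesian velocities in A/fs.
#'
#' @param file Path.
#' @param timestep Frame spacing in fs.
#' @param vel_cols Indices of the three velocity columns among the numeric
#'   fields (default: the last three).
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(file, timestep, vel_cols = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  species <- NULL
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    sp <- vapply(toks, `[[`, "", 1L)
    num <- t(vapply(toks, function(tk) as.numeric(tk[-1]),
                    numeric(length(toks[[1]]) - 1L)))
    vc <- if (is.null(vel_cols)) (ncol(num) - 2L):ncol(num) else vel_cols
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1L]] <- num[, vc, drop = FALSE]
    i <- i + 2L + nat
  }
  trajectory(frames, species, timestep)
}
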