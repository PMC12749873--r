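## Inverse-geometry neutron Compton scattering: kinematics, y-scaling,
## time-of-flight spectrum simulation and the backscattering-then-forward
## fitting protocol.

#' Inverse-geometry instrument description
#'
#' One row per detector: incident flight path `L0` (m), final flight path
#' `L1` (m), scattering angle `theta_deg`, fixed final energy `E1_meV`,
#' Gaussian resolution width in the longitudinal momentum variable `res_y`
#' (1/A) and bank tag (`"forward"` or `"back"`).
#'
#' @param L0,L1 Flight paths in m (> 0).
#' @param theta_deg Scattering angles in degrees (0 < theta < 180).
#' @param E1_meV Fixed final energy in meV (> 0).
#' @param res_y Resolution width(s) in 1/A.
#' @param bank Bank tags.
#' @return Data frame of class `instrument_geometry`.
#' @export
instrument_geometry <- function(L0, L1, theta_deg, E1_meV, res_y, bank) {
  g <- data.frame(detector = seq_along(theta_deg), L0 = L0, L1 = L1,
                  theta_deg = theta_deg, E1_meV = E1_meV, res_y = res_y,
                  bank = bank, stringsAsFactors = FALSE)
  if (any(g$L0 <= 0) || any(g$L1 <= 0) || any(g$E1_meV <= 0))
    stop("L0, L1 and E1 must be > 0")
  if (any(g$theta_deg <= 0) || any(g$theta_deg >= 180))
    stop("theta must lie in (0, 180) degrees")
  class(g) <- c("instrument_geometry", "data.frame")
  g
}

#' Default inverse-geometry spectrometer layout
#'
#' A VESUVIO-like configuration: L0 = 11.005 m, L1 = 0.7 m, fixed final
#' energy 4897 meV, a forward bank spanning 32-67 degrees (resolution
#' 2.0 1/A in y) and a backscattering bank spanning 130-165 degrees
#' (resolution 4.0 1/A).
#'
#' @param n_forward,n_back Detectors per bank.
#' @return An [instrument_geometry()].
#' @export
vesuvio_geometry <- function(n_forward = 16, n_back = 16) {
  th_f <- seq(32, 67, length.out = n_forward)
  th_b <- seq(130, 165, length.out = n_back)
  instrument_geometry(L0 = 11.005, L1 = 0.7,
                      theta_deg = c(th_f, th_b), E1_meV = 4897,
                      res_y = c(rep(2.0, n_forward), rep(4.0, n_back)),
                      bank = c(rep("forward", n_forward),
                               rep("back", n_back)))
}

## neutron speed in m/us for kinetic energy in meV
.v_mus <- function(E_meV) .v_conv * sqrt(E_meV) * 1e-6

#' Incident energy from time of flight (and back)
#'
#' For an inverse-geometry detector with fixed final energy, the final leg
#' time is constant and the incident energy follows from the remaining
#' flight time over `L0`.
#'
#' @param tof Time of flight in microseconds.
#' @param det One-row detector record from an [instrument_geometry()].
#' @return `tof_to_E0`: incident energy in meV (NA where the TOF is shorter
#'   than the final leg); `E0_to_tof`: TOF in microseconds.
#' @export
tof_to_E0 <- function(tof, det) {
  t1 <- det$L1 / .v_mus(det$E1_meV)
  t0 <- tof - t1
  E0 <- ifelse(t0 > 0, (det$L0 / (t0 * .v_conv * 1e-6))^2, NA_real_)
  E0
}

#' @rdname tof_to_E0
#' @export
E0_to_tof <- function(E0, det) {
  det$L0 / .v_mus(E0) + det$L1 / .v_mus(det$E1_meV)
}

#' West y-scaling transform
#'
#' Longitudinal momentum of a recoiling nucleus of mass M:
#' \eqn{y = \frac{M}{\hbar^2 q}\left(\hbar\omega - \frac{\hbar^2q^2}{2M}\right)}
#' with \eqn{\omega = E_0 - E_1} and q from the kinematic triangle. The
#' recoil peak of mass M is centred at y = 0.
#'
#' @param E0,E1 Incident and final energies in meV.
#' @param theta Scattering angle in radians.
#' @param mass Nuclear mass in amu.
#' @return y in 1/A.
#' @export
y_transform <- function(E0, E1, theta, mass) {
  q2 <- (E0 + E1 - 2 * sqrt(E0 * E1) * cos(theta)) / .hbar2_2mn
  q <- sqrt(q2)
  bm <- .hbar2_2M(mass)
  (E0 - E1 - bm * q2) / (2 * bm * q)
}

#' Recoil-peak time of flight
#'
#' Solves y = 0 for the incident energy at fixed final energy and angle
#' (quadratic in \eqn{\sqrt{E_0}}, physical root) and converts to TOF. For a
#' nucleus at the neutron mass the solution only exists at forward angles:
#' hydrogen recoil can only be observed in forward scattering.
#'
#' @param mass Nuclear mass in amu.
#' @param det One-row detector record.
#' @return TOF in microseconds.
#' @export
recoil_center <- function(mass, det) {
  r <- .m_n_amu / mass
  mu <- cos(det$theta_deg * pi / 180)
  a <- 1 - r; b <- 2 * r * mu; cc <- -(1 + r)
  disc <- b^2 - 4 * a * cc
  kin_err <- function()
    stop(sprintf(paste0("no recoil solution for mass %.4f amu at theta = ",
                        "%.1f deg: scattering off this mass can only be ",
                        "observed in forward scattering angles"),
                 mass, det$theta_deg))
  if (disc < 0) kin_err()
  x <- if (abs(a) < 1e-12) -cc / b else (-b + sqrt(disc)) / (2 * a)
  if (!is.finite(x) || x <= 0) kin_err()
  E0 <- x^2 * det$E1_meV
  E0_to_tof(E0, det)
}

## Per-detector kinematic tables: y_M(t) and |dy_M/dt| for each species on a
## TOF grid. Centres are fixed by kinematics; only widths/intensities are fit.
.kinematic_tables <- function(tof, det, comp) {
  E0 <- tof_to_E0(tof, det)
  ok <- !is.na(E0) & E0 > det$E1_meV * 1e-6
  theta <- det$theta_deg * pi / 180
  ys <- lapply(seq_len(nrow(comp)), function(i) {
    y <- rep(NA_real_, length(tof))
    y[ok] <- y_transform(E0[ok], det$E1_meV, theta, comp$mass_amu[i])
    ## centred finite-difference Jacobian |dy/dt|
    dy <- rep(NA_real_, length(tof))
    dy[ok] <- c(NA, diff(y[ok])) ; dy2 <- c(diff(y[ok]), NA)
    dt <- c(NA, diff(tof[ok])); dt2 <- c(diff(tof[ok]), NA)
    jac <- abs((dy[ok] / dt + dy2 / dt2) / 2)
    jac[1] <- abs(dy2[1] / dt2[1]); n <- length(jac)
    jac[n] <- abs(dy[ok][n] / dt[n])
    j <- rep(NA_real_, length(tof)); j[ok] <- jac
    list(y = y, jac = j)
  })
  names(ys) <- comp$species
  list(tables = ys, ok = ok)
}

#' Simulate an NCS time-of-flight spectrum
#'
#' Forward model: each species contributes a Gaussian longitudinal momentum
#' distribution \eqn{J_M(y)} of width `sigma[M]`, convolved with the
#' detector resolution (in quadrature in y), mapped to TOF with the
#' kinematic Jacobian; integral intensities follow the bound cross-section
#' constraint \eqn{I_M \propto c_M 4\pi b_M^2}. Counts are Poisson-sampled
#' on top of an optional flat background.
#'
#' @param comp A [composition()].
#' @param sigma Named vector of NMD widths per species (1/A).
#' @param det One-row detector record.
#' @param total_counts Expected total counts in the spectrum (signal).
#' @param seed RNG seed (mandatory).
#' @param tof TOF grid in microseconds.
#' @param background Flat background counts per bin (expected; Poisson
#'   sampled with the signal).
#' @param noise Poisson-sample the counts (default `TRUE`).
#' @return Data frame: `tof`, `counts`, `error`, `detector`.
#' @export
simulate_spectrum <- function(comp, sigma, det, total_counts = 5e4,
                              seed, tof = seq(60, 460, by = 1),
                              background = 0, noise = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  sg <- sigma[comp$species]
  if (anyNA(sg)) stop("sigma must name every composition species")
  kin <- .kinematic_tables(tof, det, comp)
  model <- numeric(length(tof))
  for (i in seq_len(nrow(comp))) {
    tb <- kin$tables[[i]]
    width <- sqrt(sg[i]^2 + det$res_y^2)
    contrib <- comp$count[i] * comp$sigma_scatt_barn[i] *
      stats::dnorm(tb$y, 0, width) * tb$jac
    contrib[is.na(contrib)] <- 0
    model <- model + contrib
  }
  if (sum(model) <= 0) stop("empty model spectrum; check the TOF window")
  model <- model / sum(model) * total_counts + background
  counts <- if (noise) stats::rpois(length(tof), model) else model
  data.frame(tof = tof, counts = counts,
             error = pmax(sqrt(pmax(counts, 0)), 1),
             detector = det$detector)
}

#' Recoil-peak intensity ratio from bound cross-sections
#'
#' \eqn{I_a/I_b = (4\pi b_a^2 c_a)/(4\pi b_b^2 c_b)}: the linear constraint
#' imposed between recoil-peak integral intensities during fitting.
#'
#' @param comp A [composition()].
#' @param species_a,species_b Species labels.
#' @return Intensity ratio.
#' @export
intensity_ratio <- function(comp, species_a, species_b) {
  ia <- match(species_a, comp$species); ib <- match(species_b, comp$species)
  if (anyNA(c(ia, ib))) stop("species not in composition")
  (comp$sigma_scatt_barn[ia] * comp$count[ia]) /
    (comp$sigma_scatt_barn[ib] * comp$count[ib])
}

## Weighted least-squares fit of one detector spectrum.
## Free widths for `free_species`; widths in `fixed_sigma` are held.
## Intensities of `constrained` species move together (Eq.-constraint
## ratios); other species (the container) have free intensity.
.fit_detector <- function(spec, det, comp, free_species,
                          fixed_sigma = c(), constrained = NULL,
                          start_sigma = NULL, fit_background = TRUE) {
  ## only species with a known (free or held) width enter the model; in
  ## backscattering that drops hydrogen, whose recoil is kinematically absent
  modeled <- union(free_species, names(fixed_sigma))
  comp <- comp[comp$species %in% modeled, , drop = FALSE]
  if (is.null(constrained))
    constrained <- setdiff(comp$species, "Al")
  constrained <- intersect(constrained, comp$species)
  kin <- .kinematic_tables(spec$tof, det, comp)
  ok <- kin$ok & spec$error > 0
  wvec <- 1 / spec$error[ok]
  relint <- comp$count * comp$sigma_scatt_barn  # constraint weights
  names(relint) <- comp$species
  unconstrained <- setdiff(comp$species, constrained)

  model_counts <- function(sig_all, amp_con, amp_unc, bg) {
    m <- rep(bg, sum(ok))
    for (i in seq_len(nrow(comp))) {
      s <- comp$species[i]
      width <- sqrt(sig_all[s]^2 + det$res_y^2)
      amp <- if (s %in% constrained) amp_con * relint[s] else amp_unc[s]
      m <- m + amp * stats::dnorm(kin$tables[[s]]$y[ok], 0, width) *
        kin$tables[[s]]$jac[ok]
    }
    m
  }

  nf <- length(free_species)
  nu <- length(unconstrained)
  if (is.null(start_sigma)) {
    start_sigma <- c(H = 5, B = 10, B10 = 10, B11 = 10, O = 11, Al = 14)
  }
  amp0 <- sum(spec$counts[ok]) / sum(relint)
  p0 <- c(start_sigma[free_species],
          amp_con = amp0,
          if (nu) stats::setNames(amp0 * relint[unconstrained],
                                  paste0("amp_", unconstrained)),
          if (fit_background) c(bg = max(min(spec$counts[ok]), 0.1)))
  lower <- c(rep(0.5, nf), 0,
             if (nu) rep(0, nu), if (fit_background) 0)

  unpack <- function(p) {
    list(sig = c(fixed_sigma, stats::setNames(p[seq_len(nf)], free_species)),
         amp_con = p[nf + 1],
         amp_unc = if (nu)
           stats::setNames(p[nf + 1 + seq_len(nu)], unconstrained) else c(),
         bg = if (fit_background) p[length(p)] else 0)
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    (spec$counts[ok] - model_counts(q$sig, q$amp_con, q$amp_unc, q$bg)) * wvec
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000)
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, fn = resid_fn,
                            control = ctl)
  ## reweighting pass: Poisson weights from the fitted model rather than
  ## the observed counts, removing the small-count weighting bias
  if (fit$info %in% 1:3) {
    q <- unpack(fit$par)
    mdl <- model_counts(q$sig, q$amp_con, q$amp_unc, q$bg)
    wvec <- 1 / sqrt(pmax(mdl, 1))
    fit <- minpack.lm::nls.lm(par = fit$par, lower = lower, fn = resid_fn,
                              control = ctl)
  }
  conv <- fit$info %in% 1:3
  p <- fit$par
  cov <- tryCatch(solve(fit$hessian) *
                    fit$deviance / max(1, sum(ok) - length(p)),
                  error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, length(p))
  sig_out <- stats::setNames(p[seq_len(nf)], free_species)
  sig_se <- stats::setNames(se[seq_len(nf)], free_species)
  list(converged = conv, sigma = sig_out, sigma_se = sig_se,
       amp_con = p[nf + 1],
       amp_unc = if (nu) stats::setNames(p[nf + 1 + seq_len(nu)],
                                         unconstrained) else c(),
       background = if (fit_background) p[length(p)] else 0,
       chisq = fit$deviance, dof = sum(ok) - length(p), fit = fit)
}

#' Fit NCS spectra by the backscattering-then-forward protocol
#'
#' Stage 1 fits the widths of the species heavier than hydrogen on each
#' backscattering detector (where their recoil peaks separate best) and
#' averages them over detectors (mean and sd). Stage 2 holds those averages
#' fixed and fits the hydrogen width on each forward detector. Stage 3
#' subtracts the fitted non-hydrogen contributions, focuses all forward
#' detectors into the proton longitudinal momentum domain and fits a single
#' Gaussian convolved with the instrument resolution. Intensity ratios of
#' H, B and O are constrained by their bound cross-sections; the aluminium
#' container intensity is free. Detectors whose fit does not converge are
#' excluded from the averages.
#'
#' @param spectra List of spectra (as from [simulate_spectrum()]), one per
#'   geometry row, in geometry order.
#' @param comp A [composition()].
#' @param geometry An [instrument_geometry()].
#' @return List of class `nmd_fit`: `back` (per-detector data frame),
#'   `back_avg` (mean/sd widths), `forward` (per-detector H widths),
#'   `sigma_H` (stage-3 focused value with uncertainty), `focused` (the
#'   y-domain data), plus bookkeeping.
#' @export
fit_back_then_forward <- function(spectra, comp, geometry) {
  banks <- geometry$bank
  if (!all(c("forward", "back") %in% banks))
    stop("both forward and back banks must be present")
  heavy <- setdiff(comp$species, "H")
  constrained <- setdiff(comp$species, "Al")

  ## stage 1: heavy widths in backscattering
  back_idx <- which(banks == "back")
  back_rows <- list()
  for (d in back_idx) {
    det <- geometry[d, ]
    f <- tryCatch(.fit_detector(spectra[[d]], det, comp,
                                free_species = heavy,
                                constrained = constrained),
                  error = function(e) list(converged = FALSE))
    back_rows[[length(back_rows) + 1L]] <-
      data.frame(detector = det$detector, converged = f$converged,
                 amp_con = if (f$converged) f$amp_con else NA_real_,
                 t(if (f$converged) f$sigma else
                   stats::setNames(rep(NA_real_, length(heavy)), heavy)))
  }
  back <- do.call(rbind, back_rows)
  okb <- back$converged
  if (!any(okb)) stop("no backscattering detector converged")
  back_avg <- data.frame(
    species = heavy,
    sigma = vapply(heavy, function(s) mean(back[[s]][okb]), numeric(1)),
    sd = vapply(heavy, function(s) stats::sd(back[[s]][okb]), numeric(1)))

  fixed <- stats::setNames(back_avg$sigma, back_avg$species)

  ## stage 2: hydrogen width per forward detector, heavy widths held
  fwd_idx <- which(banks == "forward")
  fwd_rows <- list(); fwd_fits <- list()
  for (d in fwd_idx) {
    det <- geometry[d, ]
    f <- tryCatch(.fit_detector(spectra[[d]], det, comp,
                                free_species = "H", fixed_sigma = fixed,
                                constrained = constrained),
                  error = function(e) list(converged = FALSE))
    fwd_fits[[as.character(d)]] <- f
    fwd_rows[[length(fwd_rows) + 1L]] <-
      data.frame(detector = det$detector, converged = f$converged,
                 sigma_H = if (f$converged) f$sigma[["H"]] else NA_real_)
  }
  fwd <- do.call(rbind, fwd_rows)
  okf <- fwd$converged
  if (!any(okf)) stop("no forward detector converged")

  ## stage 3: focus to proton momentum space and fit J(y) * resolution
  ydat <- list()
  relint <- comp$count * comp$sigma_scatt_barn
  names(relint) <- comp$species
  for (d in fwd_idx[okf]) {
    det <- geometry[d, ]
    f <- fwd_fits[[as.character(d)]]
    if (!isTRUE(f$converged)) next
    spec <- spectra[[d]]
    kin <- .kinematic_tables(spec$tof, det, comp)
    ok <- kin$ok
    nonH <- rep(f$background, sum(ok))
    for (s in setdiff(comp$species, "H")) {
      width <- sqrt(fixed[s]^2 + det$res_y^2)
      amp <- if (s %in% constrained) f$amp_con * relint[s] else f$amp_unc[s]
      nonH <- nonH + amp * stats::dnorm(kin$tables[[s]]$y[ok], 0, width) *
        kin$tables[[s]]$jac[ok]
    }
    ampH <- f$amp_con * relint["H"]
    jac <- kin$tables[["H"]]$jac[ok]
    ydat[[length(ydat) + 1L]] <- data.frame(
      y = kin$tables[["H"]]$y[ok],
      J = (spec$counts[ok] - nonH) / (ampH * jac),
      err = spec$error[ok] / (ampH * jac),
      res_y = det$res_y, scale = ampH * jac, nonH = nonH)
  }
  ydat <- do.call(rbind, ydat)
  ydat <- ydat[is.finite(ydat$J) & is.finite(ydat$err) & ydat$err > 0 &
                 abs(ydat$y) < 30, ]
  errs <- ydat$err
  resid_fn <- function(p) {
    (ydat$J - p[1] * stats::dnorm(ydat$y, 0,
                                  sqrt(p[2]^2 + ydat$res_y^2))) / errs
  }
  yfit <- minpack.lm::nls.lm(par = c(amp = 1, sigma = 5),
                             lower = c(0, 0.5), fn = resid_fn)
  ## model-based Poisson reweighting, as in the detector fits
  if (yfit$info %in% 1:3) {
    Jm <- yfit$par[1] * stats::dnorm(ydat$y, 0,
                                     sqrt(yfit$par[2]^2 + ydat$res_y^2))
    errs <- sqrt(pmax(ydat$nonH + ydat$scale * Jm, 1)) / ydat$scale
    yfit <- minpack.lm::nls.lm(par = yfit$par, lower = c(0, 0.5),
                               fn = resid_fn)
  }
  cov <- tryCatch(solve(yfit$hessian) *
                    yfit$deviance / max(1, nrow(ydat) - 2),
                  error = function(e) matrix(NA, 2, 2))
  out <- list(back = back, back_avg = back_avg, forward = fwd,
              sigma_H = c(value = unname(yfit$par[2]),
                          se = sqrt(abs(cov[2, 2]))),
              sigma_H_stage2 = c(mean = mean(fwd$sigma_H[okf]),
                                 sd = stats::sd(fwd$sigma_H[okf])),
              focused = ydat)
  class(out) <- "nmd_fit"
  out
}

#' Integrated boron recoil-peak intensity over the backscattering bank
#'
#' Sum over converged backscattering detectors of the fitted boron peak
#' intensity (the constrained-group amplitude times the boron constraint
#' weight): the response used for the NCS detection-limit channel.
#'
#' @param fit An [fit_back_then_forward()] result.
#' @param comp The [composition()] used in the fit.
#' @param species Boron species label (default `"B"`).
#' @return Total counts.
#' @export
boron_intensity <- function(fit, comp, species = "B") {
  i <- match(species, comp$species)
  if (is.na(i)) stop("species not in composition")
  relint <- comp$count[i] * comp$sigma_scatt_barn[i]
  sum(fit$back$amp_con[fit$back$converged]) * relint
}

#' @export
print.nmd_fit <- function(x, ...) {
  cat("<nmd_fit>\n backscattering averages (1/A):\n")
  print(x$back_avg, row.names = FALSE)
  cat(sprintf(" sigma_H (focused forward fit): %.3f +/- %.3f 1/A\n",
              x$sigma_H["value"], x$sigma_H["se"]))
  invisible(x)
}
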