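## Incident-energy-dependent total neutron cross-sections: 1/v absorption,
## epithermal free-recoil scattering law, incoherent multiphonon expansion,
## transmission curves and the epithermal plateau.

#' 1/v neutron absorption cross-section
#'
#' \eqn{\sigma(E_0) = \sigma_\mathrm{ref}\sqrt{E_\mathrm{ref}/E_0}}, with the
#' reference point at thermal energy (25.3 meV) by default.
#'
#' @param E0 Incident energy in eV (vectorised).
#' @param sigma_ref Absorption cross-section at `E_ref`, barn.
#' @param E_ref Reference energy in eV (default 25.3e-3).
#' @return Barn.
#' @export
absorption_xs <- function(E0, sigma_ref, E_ref = 25.3e-3) {
  if (any(E0 <= 0)) stop("E0 must be > 0")
  sigma_ref * sqrt(E_ref / E0)
}

#' Epithermal scattering plateau per formula unit
#'
#' Free-atom cross-section sum
#' \eqn{\sum_i c_i\,4\pi b_i^2/(1+m/M_i)^2} (barn per formula unit), the
#' level the total scattering cross-section reaches between 10 and 100 eV.
#'
#' @param comp A [composition()].
#' @return Barn per formula unit.
#' @export
epithermal_plateau <- function(comp) {
  sum(comp$count * comp$sigma_scatt_barn /
        (1 + .m_n_amu / comp$mass_amu)^2)
}

#' Epithermal double-differential scattering cross-section
#'
#' The free-recoil (impulse-regime) law: for each species a Gaussian in
#' energy transfer \eqn{\omega = E_0 - E_1} centred at the recoil energy
#' \eqn{\omega_r = \hbar^2 q^2/2M} with variance \eqn{3\omega_r E_k},
#' \deqn{\frac{d^2\sigma}{d\omega\,d\Omega} = \sqrt{\tfrac{E_1}{E_0}}
#'   \sum_i c_i \frac{4\pi b_i^2}{(1+m/M_i)^2}
#'   \frac{\exp\{-(\omega-\omega_{r,i})^2/6\omega_{r,i}E_{k,i}\}}
#'        {\sqrt{6\pi\,\omega_{r,i}E_{k,i}}},}
#' where \eqn{E_{k,i}} is the nuclear kinetic energy of species `i` and
#' \eqn{q^2 = (2m/\hbar^2)(E_0+E_1-2\sqrt{E_0E_1}\cos\theta)}.
#'
#' @param E0,E1 Incident and final neutron energies in eV (> 0).
#' @param theta Scattering angle in radians.
#' @param comp A [composition()].
#' @param ek Named vector of nuclear kinetic energies in meV, one per
#'   composition species (> 0).
#' @return Barn / (eV sr) per formula unit.
#' @export
epithermal_ddxs <- function(E0, E1, theta, comp, ek) {
  if (any(c(E0, E1) <= 0)) stop("E0 and E1 must be > 0")
  ekv <- ek[comp$species]
  if (anyNA(ekv) || any(ekv <= 0))
    stop("ek must supply a positive kinetic energy for every species")
  e0 <- E0 * 1e3; e1 <- E1 * 1e3  # meV
  q2 <- (e0 + e1 - 2 * sqrt(e0 * e1) * cos(theta)) / .hbar2_2mn
  w <- e0 - e1
  out <- 0
  for (i in seq_len(nrow(comp))) {
    wr <- .hbar2_2M(comp$mass_amu[i]) * q2
    sfree <- comp$sigma_scatt_barn[i] / (1 + .m_n_amu / comp$mass_amu[i])^2
    g <- exp(-(w - wr)^2 / (6 * wr * ekv[i])) / sqrt(6 * pi * wr * ekv[i])
    out <- out + comp$count[i] * sfree * g
  }
  sqrt(E1 / E0) * out * 1e3  # per meV -> per eV
}

## Recoil-peak final energy fractions u = sqrt(E1/E0) solving
## omega = omega_r for mass ratio r = m/M at cos(theta) = mu. For r <= 1
## there is one root; for r > 1 (hydrogen) a second low-E1 branch exists at
## forward angles. Returns a vector of roots (possibly empty).
.recoil_u_all <- function(r, mu) {
  disc <- r^2 * mu^2 + 1 - r^2
  if (disc < 0) return(numeric(0))
  up <- (r * mu + sqrt(disc)) / (1 + r)
  um <- (r * mu - sqrt(disc)) / (1 + r)
  u <- c(up, um)
  u[u > 0]
}

#' Total scattering cross-section from the epithermal free-recoil law
#'
#' Numerically integrates the free-recoil Gaussian law over energy transfer
#' and solid angle using the impulse-approximation kernel
#' \eqn{(\sigma_b/4\pi)\sqrt{E_1/E_0}\,S(q,\omega)} per species (the
#' free-atom \eqn{(1+m/M)^{-2}} reduction emerges from the recoil
#' kinematics); at epithermal energies the result converges to the
#' [epithermal_plateau()].
#'
#' @param E0 Incident energies in eV (vectorised).
#' @param comp A [composition()].
#' @param ek Named vector of nuclear kinetic energies in meV per species.
#' @param n_mu Number of angular quadrature points (cos theta).
#' @param n_w Number of energy-transfer points per species peak.
#' @param variance `"printed"` (default): Gaussian variance
#'   \eqn{3\omega_r E_k}; `"free_gas"`: the short-collision-time /
#'   ideal-gas variance \eqn{\tfrac{4}{3}\omega_r E_k} (i.e.
#'   \eqn{2\omega_r k_B T_\mathrm{eff}} with
#'   \eqn{k_BT_\mathrm{eff} = \tfrac{2}{3}E_k}).
#' @return Barn per formula unit (scattering only).
#' @export
epithermal_sigma <- function(E0, comp, ek, n_mu = 200, n_w = 121,
                             variance = c("printed", "free_gas")) {
  variance <- match.arg(variance)
  vfac <- if (variance == "printed") 6 else 8 / 3  # 2 x variance / (wr * Ek)
  ekv <- ek[comp$species]
  if (anyNA(ekv) || any(ekv <= 0))
    stop("ek must supply a positive kinetic energy for every species")
  ## midpoint rule in cos(theta): avoids the quasi-elastic delta at mu = 1
  dmu <- 2 / n_mu
  mu <- -1 + (seq_len(n_mu) - 0.5) * dmu
  muw <- rep(dmu, n_mu)
  vapply(E0, function(e0eV) {
    e0 <- e0eV * 1e3  # meV
    tot <- 0
    for (i in seq_len(nrow(comp))) {
      r <- .m_n_amu / comp$mass_amu[i]
      bm <- .hbar2_2M(comp$mass_amu[i])
      ## gain-side tail decays in E1 on the scale 6 r Ek / (1+r)^2
      e1max <- 6 * e0 + 60 * ekv[i] * 6 * r / (1 + r)^2
      base <- 10^seq(log10(e0 * 1e-5), log10(e1max), length.out = 240)
      contrib <- numeric(n_mu)
      for (j in seq_len(n_mu)) {
        roots <- .recoil_u_all(r, mu[j])
        ## composite grid: broad log coverage plus a fine linear window
        ## around each recoil branch
        e1 <- base
        for (u0 in roots) {
          e1star <- e0 * u0^2
          wstar <- e0 - e1star
          sdw <- sqrt(3 * max(wstar, 0) * ekv[i])
          if (sdw <= 0) next
          win <- seq(max(e1star - 10 * sdw, e0 * 1e-5),
                     min(e1star + 10 * sdw, e1max), length.out = n_w)
          e1 <- c(e1, win)
        }
        e1 <- sort(unique(e1))
        w <- e0 - e1
        q2 <- pmax((e0 + e1 - 2 * sqrt(e0 * e1) * mu[j]) / .hbar2_2mn,
                   1e-12)
        wr <- bm * q2
        denom <- vfac * wr * ekv[i]
        g <- exp(-(w - wr)^2 / denom) / sqrt(pi * denom)
        contrib[j] <- trapz(e1, sqrt(e1 / e0) * g)
      }
      tot <- tot + comp$count[i] * comp$sigma_scatt_barn[i] / 2 *
        sum(contrib * muw)
    }
    tot
  }, numeric(1))
}

## One-phonon spectral function with detailed balance on a symmetric grid
## wide enough to hold n_max-fold convolutions. Positive omega = neutron
## energy loss (phonon creation).
.one_phonon <- function(v, T, n_max) {
  h <- v$omega[2] - v$omega[1]
  wmax <- max(v$omega[v$density > max(v$density) * 1e-12])
  L <- ceiling(n_max * wmax / h) * h
  wgrid <- seq(-L, L, by = h)
  dens <- stats::approx(v$omega, v$density, xout = abs(wgrid),
                        yleft = 0, yright = 0)$y
  beta <- 1 / (.k_B * T)
  g1 <- ifelse(wgrid == 0, NA,
               dens / (wgrid * (1 - exp(-beta * wgrid))))
  i0 <- which(wgrid == 0)
  if (length(i0)) {
    nb <- c(i0 - 1L, i0 + 1L)
    nb <- nb[nb >= 1 & nb <= length(g1)]
    g1[i0] <- mean(g1[nb], na.rm = TRUE)
  }
  g1[!is.finite(g1)] <- 0
  list(w = wgrid, g1 = g1, h = h, gamma = trapz(wgrid, g1), wmax = wmax, L = L)
}

#' Total neutron cross-section via the incoherent multiphonon expansion
#'
#' Per species, builds the detailed-balanced one-phonon kernel from the
#' (unit-normalised) VDoS, forms phonon orders 1..`n_max` by iterated
#' convolution with a Gaussian central-limit closure for higher orders, adds
#' the Debye-Waller elastic term, and integrates
#' \eqn{(\sigma_b/4\pi)\sqrt{E_1/E_0}\,S(q,\omega)} over energy transfer and
#' solid angle (incoherent approximation: the full bound cross-section is
#' applied to the self part). Above the energy where the expansion stops
#' converging (last-order correction > `conv_tol` or Debye-Waller exponent
#' beyond the order cap) the curve is continued with the epithermal
#' free-recoil law ([epithermal_sigma()]), whose kinetic energies are taken
#' from the same VDoSes at temperature `T`. 1/v absorption is added from the
#' composition table.
#'
#' @param vdos_list Named list of [vdos()] per composition species.
#' @param comp A [composition()].
#' @param T Temperature in K (> 0).
#' @param E0_grid Incident energies in eV (default log-spaced 1e-4..100 eV,
#'   400 points).
#' @param n_max Number of explicitly convolved phonon orders (default 8).
#' @param order_cap Maximum total order including the Gaussian closure.
#' @param n_mu Angular quadrature points.
#' @param conv_tol Relative last-order correction below which the expansion
#'   counts as converged (default 0.005).
#' @param absorption Include 1/v absorption (default `TRUE`).
#' @return `data.frame` of class `xsec_curve`: `E0_eV`, `sigma_scatt`,
#'   `sigma_abs`, `sigma_total` (barn per formula unit), `mpe` (logical:
#'   multiphonon value, or epithermal continuation), `order` (highest order
#'   used).
#' @export
multiphonon_total_xs <- function(vdos_list, comp, T,
                                 E0_grid = 10^seq(-4, 2, length.out = 400),
                                 n_max = 8, order_cap = 128, n_mu = 33,
                                 conv_tol = 0.005, absorption = TRUE) {
  if (T <= 0) stop("T must be > 0")
  missing <- setdiff(comp$species, names(vdos_list))
  if (length(missing))
    stop("no VDoS supplied for species: ", paste(missing, collapse = ", "))
  mu <- seq(-1, 1, length.out = n_mu)
  dmu <- mu[2] - mu[1]
  muw <- rep(dmu, n_mu); muw[c(1, n_mu)] <- dmu / 2
  ek <- vapply(comp$species,
               function(s) kinetic_energy(vdos_list[[s]], T), numeric(1))
  names(ek) <- comp$species

  per_species <- lapply(comp$species, function(s) {
    op <- .one_phonon(vdos_list[[s]], T, n_max)
    ## phonon orders by iterated convolution (discrete, step h) on a grid
    ## wide enough for n_max-fold support
    n <- length(op$w)
    g1n <- op$g1 / op$gamma
    Tn <- matrix(0, nrow = n_max, ncol = n)
    Tn[1, ] <- g1n
    if (n_max > 1) for (k in 2:n_max) {
      full <- stats::convolve(Tn[k - 1, ], rev(g1n), type = "open") * op$h
      off <- (n - 1L) %/% 2  # index offset of the original grid in full conv
      Tn[k, ] <- pmax(full[(1:n) + off], 0)
    }
    m1 <- trapz(op$w, op$w * g1n)
    v1 <- max(trapz(op$w, op$w^2 * g1n) - m1^2, 1e-12)
    list(op = op, Tn = Tn, m1 = m1, v1 = v1)
  })
  names(per_species) <- comp$species

  sig_s <- numeric(length(E0_grid))
  used_mpe <- logical(length(E0_grid))
  ord <- integer(length(E0_grid))
  wfloor <- -(15 * .k_B * T)  # up-scattering tail cut (detailed balance)
  n_fail <- 0L
  for (ie in order(E0_grid)) {
    if (n_fail >= 2L) break  # expansion has stopped converging for good
    e0 <- E0_grid[ie] * 1e3  # meV
    tot <- 0; last_corr <- 0; max_ord <- 0L; ok <- TRUE
    for (i in seq_len(nrow(comp))) {
      ps <- per_species[[comp$species[i]]]
      bm <- .hbar2_2M(comp$mass_amu[i])
      wlo <- max(-ps$op$L, wfloor - ps$op$wmax)
      wmask <- ps$op$w < e0 * (1 - 1e-9) & ps$op$w >= wlo
      w <- ps$op$w[wmask]
      e1 <- e0 - w
      sp_tot <- 0
      for (j in seq_len(n_mu)) {
        q2 <- (e0 + e1 - 2 * sqrt(e0 * e1) * mu[j]) / .hbar2_2mn
        W2 <- bm * q2 * ps$op$gamma           # 2W(q), omega-dependent
        q2el <- 2 * e0 * (1 - mu[j]) / .hbar2_2mn
        el <- exp(-bm * q2el * ps$op$gamma)
        pref <- sqrt(e1 / e0) * exp(-W2)
        sn <- numeric(length(w))
        term_n <- numeric(length(w))
        fac <- W2                              # (2W)^n / n!
        for (k in seq_len(n_max)) {
          term_n <- fac * ps$Tn[k, wmask]
          sn <- sn + term_n
          fac <- fac * W2 / (k + 1)
        }
        inel <- trapz(w, pref * sn)
        last_n <- trapz(w, pref * term_n)
        ## Gaussian central-limit closure for orders beyond n_max
        W2el <- bm * q2el * ps$op$gamma
        if (W2el > 0 && max(W2) > 1e-6) {
          k <- n_max
          fac_k <- fac                        # (2W)^{n_max+1}/(n_max+1)!
          repeat {
            k <- k + 1L
            if (k > order_cap) { ok <- FALSE; break }
            mu_k <- k * ps$m1
            if (mu_k > ps$op$L + 6 * sqrt(k * ps$v1)) {
              ## centre far beyond the representable grid; stop, and flag if
              ## this order still carries weight
              if (max(fac_k) * exp(-min(W2)) > conv_tol) ok <- FALSE
              break
            }
            sd_k <- sqrt(k * ps$v1)
            gk <- exp(-(w - mu_k)^2 / (2 * sd_k^2)) / (sd_k * sqrt(2 * pi))
            add <- trapz(w, pref * fac_k * gk)
            inel <- inel + add
            ## Poisson-type weight is past its mode and negligible: done
            if (k > W2el && max(fac_k * exp(-W2)) < 1e-10) break
            fac_k <- fac_k * W2 / (k + 1)
          }
          max_ord <- max(max_ord, k)
        } else max_ord <- max(max_ord, n_max)
        last_corr <- max(last_corr,
                         if (inel > 0) abs(last_n) / inel else 0)
        sp_tot <- sp_tot + (el + inel) * muw[j]
      }
      tot <- tot + comp$count[i] * comp$sigma_scatt_barn[i] / 2 * sp_tot
    }
    sig_s[ie] <- tot
    used_mpe[ie] <- ok && (last_corr < conv_tol)
    ord[ie] <- max_ord
    n_fail <- if (used_mpe[ie]) 0L else n_fail + 1L
  }

  ## Continuation above the crossover: the free-recoil asymptote with the
  ## short-collision-time (ideal gas) variance, times the junction ratio
  ## decaying geometrically over one decade in E0 so the stitched curve
  ## descends monotonically into the plateau.
  if (any(!used_mpe)) {
    idx <- which(!used_mpe)
    asym <- epithermal_sigma(E0_grid[idx], comp, ek, n_mu = max(n_mu, 101),
                             variance = "free_gas")
    ratio <- 1
    if (any(used_mpe)) {
      ic <- which(used_mpe)[which.max(E0_grid[used_mpe])]
      Ec <- E0_grid[ic]
      asym_c <- epithermal_sigma(Ec, comp, ek, n_mu = max(n_mu, 101),
                                 variance = "free_gas")
      ratio <- sig_s[ic] / asym_c
      wgt <- pmax(0, 1 - log10(pmax(E0_grid[idx] / Ec, 1)))
      sig_s[idx] <- asym * ratio^wgt
    } else {
      sig_s[idx] <- asym
    }
  }
  sig_a <- if (absorption) {
    rowSums(matrix(vapply(seq_len(nrow(comp)), function(i)
      comp$count[i] * absorption_xs(E0_grid, comp$sigma_abs_barn[i]),
      numeric(length(E0_grid))), nrow = length(E0_grid)))
  } else numeric(length(E0_grid))
  out <- data.frame(E0_eV = E0_grid, sigma_scatt = sig_s, sigma_abs = sig_a,
                    sigma_total = sig_s + sig_a, mpe = used_mpe, order = ord)
  class(out) <- c("xsec_curve", "data.frame")
  out
}

#' Sample geometry for transmission
#'
#' @param thickness_cm Thickness along the beam in cm.
#' @param number_density_percm3 Formula units per cm^3.
#' @param areal_density Directly the product n*d in formula units per cm^2
#'   (overrides the other two).
#' @return Object of class `sample_geometry` with element `nd` (1/cm^2).
#' @export
sample_geometry <- function(thickness_cm = NULL, number_density_percm3 = NULL,
                            areal_density = NULL) {
  nd <- if (!is.null(areal_density)) areal_density
  else thickness_cm * number_density_percm3
  if (is.null(nd) || nd < 0) stop("areal density n*d must be >= 0")
  structure(list(nd = nd), class = "sample_geometry")
}

#' Neutron transmission of a sample
#'
#' \eqn{T(E_0) = \exp(-n d\,\sigma_\mathrm{tot}(E_0))}; a container curve, if
#' supplied, multiplies in as \eqn{T_s T_c}.
#'
#' @param curve An `xsec_curve` from [multiphonon_total_xs()] (or any data
#'   frame with `E0_eV` and `sigma_total` in barn per formula unit).
#' @param geom A [sample_geometry()].
#' @param container Optional transmission data frame (`E0_eV`,
#'   `transmission`) of the empty container.
#' @return Data frame `E0_eV`, `transmission`.
#' @export
transmission <- function(curve, geom, container = NULL) {
  Ts <- exp(-geom$nd * curve$sigma_total * 1e-24)  # barn -> cm^2
  if (!is.null(container)) {
    Tc <- stats::approx(container$E0_eV, container$transmission,
                        xout = curve$E0_eV, rule = 2)$y
    Ts <- Ts * Tc
  }
  data.frame(E0_eV = curve$E0_eV, transmission = Ts)
}

#' Epithermal scattering power of a transmission curve
#'
#' One minus the mean transmission over the 10-100 eV plateau.
#'
#' @param trans Data frame `E0_eV`, `transmission`.
#' @param range Energy window in eV (default `c(10, 100)`).
#' @return Scalar scattering power.
#' @export
plateau_scattering_power <- function(trans, range = c(10, 100)) {
  sel <- trans$E0_eV >= range[1] & trans$E0_eV <= range[2]
  if (!any(sel)) stop("no points in the plateau window")
  1 - mean(trans$transmission[sel])
}
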