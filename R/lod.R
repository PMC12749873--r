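## Sensitivity parameters and limits of detection / quantitation for the
## NCS, transmission and PGAA channels.

#' Sensitivity dataset
#'
#' Analyte masses and detector responses for a mass series, plus the blank
#' response statistics. The `include` flags implement the exclusion of
#' saturated points (the largest mass deviates from the linear trend through
#' multiple scattering and gamma self-attenuation).
#'
#' @param mass_g Analyte masses in g (>= 0).
#' @param response Detector responses (counts, scattering power or peak
#'   area), one per mass.
#' @param blank Blank response (default 0).
#' @param blank_sd Standard deviation of the blank response (>= 0).
#' @param channel `"ncs"`, `"transmission"` or `"pgaa"`.
#' @param include Logical inclusion flags (default all).
#' @param exclude_saturated Drop the largest-mass point (default `TRUE` for
#'   the transmission and PGAA channels, `FALSE` for NCS).
#' @return Object of class `sensitivity_dataset`.
#' @export
sensitivity_dataset <- function(mass_g, response, blank = 0, blank_sd = 0,
                                channel = c("ncs", "transmission", "pgaa"),
                                include = NULL,
                                exclude_saturated = channel %in%
                                  c("transmission", "pgaa")) {
  channel <- match.arg(channel)
  if (length(mass_g) != length(response)) stop("mass and response must align")
  if (any(mass_g < 0)) stop("masses must be >= 0")
  if (blank_sd < 0) stop("blank sd must be >= 0")
  if (is.null(include)) include <- rep(TRUE, length(mass_g))
  if (isTRUE(exclude_saturated[1]) && length(mass_g) > 1)
    include[which.max(mass_g)] <- FALSE
  if (sum(include) < 2) stop("at least 2 included points required")
  structure(list(mass_g = mass_g, response = response, blank = blank,
                 blank_sd = blank_sd, channel = channel, include = include),
            class = "sensitivity_dataset")
}

#' Direct (single-point) sensitivity
#'
#' \eqn{S = (m - m_\mathrm{blank}) / (C - C_\mathrm{blank})} in grams per
#' response unit.
#'
#' @param mass_analyte Analyte mass in the sample, g.
#' @param counts Sample response.
#' @param blank_mass,blank_counts Blank analyte mass and response
#'   (default 0).
#' @return Sensitivity in g per response unit.
#' @export
sensitivity_direct <- function(mass_analyte, counts, blank_mass = 0,
                               blank_counts = 0) {
  if (counts == blank_counts)
    stop("sample and blank responses are equal; sensitivity undefined")
  (mass_analyte - blank_mass) / (counts - blank_counts)
}

#' Regression sensitivity
#'
#' Ordinary least squares of response on analyte mass over the included
#' points; the sensitivity is the inverse slope, with its uncertainty
#' propagated from the slope standard error
#' (\eqn{\mathrm{se}(1/k) = \mathrm{se}(k)/k^2}).
#'
#' @param dataset A [sensitivity_dataset()].
#' @return List: `S` (g per response unit), `S_se`, `slope`, `slope_se`,
#'   `fit` (the `lm` object), `flagged` (`TRUE` if the slope is not
#'   positive).
#' @export
sensitivity_regression <- function(dataset) {
  inc <- dataset$include
  fit <- stats::lm(response ~ mass_g,
                   data = data.frame(mass_g = dataset$mass_g[inc],
                                     response = dataset$response[inc]))
  sm <- summary(fit)$coefficients
  slope <- sm["mass_g", "Estimate"]
  slope_se <- sm["mass_g", "Std. Error"]
  flagged <- slope <= 0
  if (flagged)
    warning("non-positive regression slope; sensitivity not meaningful")
  list(S = 1 / slope, S_se = slope_se / slope^2,
       slope = slope, slope_se = slope_se, fit = fit, flagged = flagged)
}

#' Limits of detection and quantitation
#'
#' The 3-sigma / 10-sigma rule: \eqn{\mathrm{LOD} = 3 S s_\mathrm{blank}},
#' \eqn{\mathrm{LOQ} = 10 S s_\mathrm{blank}}; their ratio is 10/3 by
#' construction.
#'
#' @param S Sensitivity in g per response unit.
#' @param blank_sd Standard deviation of the blank response.
#' @param S_se Optional sensitivity uncertainty for propagation.
#' @return Named vector `lod`, `loq` (g), plus `lod_se`, `loq_se` when
#'   `S_se` is given.
#' @export
lod_loq <- function(S, blank_sd, S_se = NULL) {
  if (blank_sd < 0) stop("blank sd must be >= 0")
  out <- c(lod = 3 * S * blank_sd, loq = 10 * S * blank_sd)
  if (!is.null(S_se))
    out <- c(out, lod_se = 3 * S_se * blank_sd, loq_se = 10 * S_se * blank_sd)
  out
}

#' Isotope-scaled NCS limit of detection
#'
#' NCS recoil-peak intensity is proportional to the total bound scattering
#' cross-section, so the limit for a separated isotope scales by the
#' inverse cross-section ratio:
#' \eqn{\mathrm{LOD}_\mathrm{iso} = \mathrm{LOD}_\mathrm{nat}\,
#'      \sigma_s(\mathrm{nat})/\sigma_s(\mathrm{iso})}.
#'
#' @param lod_natural Natural-abundance limit in g.
#' @param natural,isotope Species labels in the constants table (e.g. `"B"`,
#'   `"B10"`).
#' @param table Constants table (default [isotope_table()]).
#' @return Scaled limit in g.
#' @export
isotope_scaled_lod <- function(lod_natural, natural = "B", isotope,
                               table = isotope_table()) {
  i <- match(natural, table$species); j <- match(isotope, table$species)
  if (anyNA(c(i, j))) stop("species not in constants table")
  lod_natural * table$sigma_scatt_barn[i] / table$sigma_scatt_barn[j]
}
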