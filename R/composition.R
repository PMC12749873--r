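## Sample composition: isotopic species counts per formula unit joined with
## tabulated neutron constants.

#' Construct a sample composition
#'
#' Per isotopic species: count per formula unit, mass (amu), total bound
#' scattering cross-section \eqn{4\pi b^2} (barn) and absorption
#' cross-section at 25.3 meV (barn). Constants default to the shipped table
#' ([isotope_table()]) and are overridable per species.
#'
#' @param species Character vector of species labels.
#' @param counts Numeric vector of counts per formula unit (> 0).
#' @param table Constants table (default [isotope_table()]).
#' @param mass_amu,sigma_scatt_barn,sigma_abs_barn Optional named overrides.
#' @return Object of class `composition` (a data frame).
#' @export
composition <- function(species, counts, table = isotope_table(),
                        mass_amu = NULL, sigma_scatt_barn = NULL,
                        sigma_abs_barn = NULL) {
  if (length(species) != length(counts)) stop("one count per species")
  if (any(counts <= 0)) stop("counts must be > 0")
  idx <- match(species, table$species)
  if (anyNA(idx))
    stop("species not in constants table: ",
         paste(species[is.na(idx)], collapse = ", "))
  comp <- data.frame(species = species, count = counts,
                     mass_amu = table$mass_amu[idx],
                     sigma_scatt_barn = table$sigma_scatt_barn[idx],
                     sigma_abs_barn = table$sigma_abs_barn[idx],
                     stringsAsFactors = FALSE)
  override <- function(col, vals) {
    if (!is.null(vals)) {
      j <- match(names(vals), comp$species)
      if (anyNA(j)) stop("override names must match species")
      comp[[col]][j] <<- as.numeric(vals)
    }
  }
  override("mass_amu", mass_amu)
  override("sigma_scatt_barn", sigma_scatt_barn)
  override("sigma_abs_barn", sigma_abs_barn)
  if (any(comp$sigma_scatt_barn < 0) || any(comp$sigma_abs_barn < 0))
    stop("cross-sections must be >= 0")
  class(comp) <- c("composition", "data.frame")
  comp
}

#' Molar mass of a composition
#'
#' @param comp A [composition()].
#' @return Formula-unit mass in g/mol (= amu).
#' @export
molar_mass <- function(comp) sum(comp$count * comp$mass_amu)

#' Mass fraction of one species
#'
#' @param comp A [composition()].
#' @param species Species label.
#' @return Fraction of the formula-unit mass carried by `species`.
#' @export
mass_fraction <- function(comp, species) {
  i <- match(species, comp$species)
  if (is.na(i)) stop("species not in composition: ", species)
  comp$count[i] * comp$mass_amu[i] / molar_mass(comp)
}

#' Read / write a composition as CSV
#'
#' Columns: `species, count, mass_amu, sigma_scatt_barn, sigma_abs_barn`.
#'
#' @param comp A [composition()] (for writing).
#' @param file Path.
#' @return `read_composition` returns a [composition()].
#' @export
write_composition <- function(comp, file) {
  utils::write.csv(as.data.frame(comp), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_composition
#' @export
read_composition <- function(file) {
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  composition(tab$species, tab$count,
              table = data.frame(species = tab$species,
                                 mass_amu = tab$mass_amu,
                                 sigma_scatt_barn = tab$sigma_scatt_barn,
                                 sigma_abs_barn = tab$sigma_abs_barn))
}
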