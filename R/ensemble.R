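# Conformer ensembles and Boltzmann population machinery.

# Gas constant in kJ/(mol K) and the hartree -> kJ/mol conversion.
.R_KJ <- 8.31446e-3
.HARTREE_KJMOL <- 2625.4996

#' Boltzmann populations from relative energies
#'
#' Computes p_i proportional to exp(-E_i / RT) with R = 8.31446 J/(mol K).
#' Populations are invariant under a uniform energy shift, so energies may be
#' absolute or relative as long as they share an origin.
#'
#' @param rel_energies Numeric vector of conformer energies in kJ/mol.
#' @param temperature Temperature in K (default 298.15).
#' @return Numeric vector of populations summing to 1, in input order.
#' @examples
#' boltzmann_weights(c(0, 0))            # 0.5 0.5
#' boltzmann_weights(c(0, 1.7183))       # ~ 2/3, 1/3 at 298.15 K
#' @export
boltzmann_weights <- function(rel_energies, temperature = 298.15) {
  if (!length(rel_energies)) stop("rel_energies must be non-empty")
  if (!all(is.finite(rel_energies))) stop("rel_energies must be finite")
  stopifnot(is.numeric(temperature), temperature > 0)
  # subtract the minimum before exponentiating for numerical stability
  e <- rel_energies - min(rel_energies)
  w <- exp(-e / (.R_KJ * temperature))
  w / sum(w)
}

#' Convert absolute energies in hartree to relative kJ/mol
#'
#' @param hartree Numeric vector of absolute electronic energies in hartree.
#' @return Energies in kJ/mol relative to the vector minimum.
#' @export
hartree_to_rel_kjmol <- function(hartree) {
  stopifnot(is.numeric(hartree), all(is.finite(hartree)))
  (hartree - min(hartree)) * .HARTREE_KJMOL
}

#' Construct a conformer record
#'
#' @param id Conformer identifier string.
#' @param rel_energy Energy in kJ/mol relative to the ensemble minimum.
#' @param shieldings Optional named numeric vector of isotropic shieldings
#'   (ppm), named by nucleus label such as `"C-17"`.
#' @param transitions Optional data frame of electronic transitions with
#'   columns `wavelength_nm`, `R_vel` (rotational strength, 1e-40 cgs) and
#'   optionally `f_osc`.
#' @param metadata Free-form provenance list (theory level, solvent model),
#'   carried verbatim.
#' @return An object of class `conformer_record`.
#' @export
conformer_record <- function(id, rel_energy, shieldings = NULL,
                             transitions = NULL, metadata = list()) {
  stopifnot(length(id) == 1L, is.numeric(rel_energy), is.finite(rel_energy))
  if (!is.null(shieldings)) {
    if (is.null(names(shieldings)) || anyDuplicated(names(shieldings)))
      stop("shieldings must be uniquely named by nucleus label")
  }
  if (!is.null(transitions)) {
    transitions <- as.data.frame(transitions)
    stopifnot(all(c("wavelength_nm", "R_vel") %in% names(transitions)))
    if (nrow(transitions) && any(transitions$wavelength_nm <= 0))
      stop("transition wavelengths must be positive")
  }
  structure(list(id = as.character(id), rel_energy = as.numeric(rel_energy),
                 shieldings = shieldings, transitions = transitions,
                 metadata = metadata),
            class = "conformer_record")
}

#' Construct a conformer ensemble for one candidate stereoisomer
#'
#' Energies are re-referenced so the ensemble minimum is 0 kJ/mol (Boltzmann
#' populations are unaffected by the shift).
#'
#' @param stereo_label Stereodescriptor string, e.g.
#'   `"(3R,4S,5R,8R,10S,19R,24R)"`.
#' @param conformers List of [conformer_record()] objects (non-empty).
#' @param temperature Ensemble temperature in K.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(stereo_label, conformers, temperature = 298.15) {
  if (!length(conformers)) stop("an ensemble needs at least one conformer")
  stopifnot(all(vapply(conformers, inherits, logical(1), "conformer_record")))
  ids <- vapply(conformers, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate conformer ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  labels <- lapply(conformers, function(cf) sort(names(cf$shieldings)))
  has_sigma <- vapply(labels, length, integer(1)) > 0
  if (any(has_sigma) &&
      !all(vapply(labels[has_sigma], identical, logical(1), labels[has_sigma][[1]])))
    stop("all conformers with shieldings must share the same nucleus labels")
  e0 <- min(vapply(conformers, `[[`, numeric(1), "rel_energy"))
  conformers <- lapply(conformers, function(cf) {
    cf$rel_energy <- cf$rel_energy - e0
    cf
  })
  structure(list(stereo_label = as.character(stereo_label),
                 conformers = conformers,
                 temperature = as.numeric(temperature)),
            class = "ensemble")
}

.rel_energies <- function(ens) {
  vapply(ens$conformers, `[[`, numeric(1), "rel_energy")
}

#' Boltzmann populations of an ensemble's conformers
#'
#' @param ens An [ensemble()].
#' @return Named numeric vector of populations (names = conformer ids).
#' @export
ensemble_populations <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  p <- boltzmann_weights(.rel_energies(ens), ens$temperature)
  stats::setNames(p, vapply(ens$conformers, `[[`, character(1), "id"))
}

#' Keep conformers inside a relative-energy window
#'
#' Conformers with relative energy less than or equal to `window` kJ/mol are
#' retained (inclusive boundary); the minimum-energy conformer always
#' survives.
#'
#' @param ens An [ensemble()].
#' @param window Energy window in kJ/mol (default 21, the conformational
#'   search window used for these compounds).
#' @return The filtered ensemble.
#' @export
apply_energy_window <- function(ens, window = 21) {
  stopifnot(inherits(ens, "ensemble"), is.numeric(window), window >= 0)
  keep <- .rel_energies(ens) <= window
  ensemble(ens$stereo_label, ens$conformers[keep], ens$temperature)
}

#' Drop conformers below a Boltzmann-population floor
#'
#' Conformers whose population is below `floor` are removed and the remaining
#' populations renormalize to 1 (equivalently, Boltzmann weights are
#' recomputed over the survivors). Retention is inclusive: population equal
#' to the floor survives.
#'
#' @param ens An [ensemble()].
#' @param floor Minimum population fraction in `[0, 1)` (default 0.01, i.e.
#'   keep conformers with at least 1\% Boltzmann population).
#' @return The filtered ensemble.
#' @export
apply_population_floor <- function(ens, floor = 0.01) {
  stopifnot(inherits(ens, "ensemble"), is.numeric(floor),
            floor >= 0, floor < 1)
  p <- ensemble_populations(ens)
  keep <- p >= floor
  if (!any(keep))
    stop("AmbiguousFloor: population floor ", floor,
         " exceeds every conformer population (max ",
         signif(max(p), 4), ")")
  ensemble(ens$stereo_label, ens$conformers[keep], ens$temperature)
}

#' Tabulate an ensemble's conformers and populations
#'
#' @param ens An [ensemble()].
#' @return Data frame with columns `id`, `rel_energy_kjmol`, `population`.
#' @export
ensemble_summary <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  data.frame(
    id = vapply(ens$conformers, `[[`, character(1), "id"),
    rel_energy_kjmol = .rel_energies(ens),
    population = unname(ensemble_populations(ens))
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", x$stereo_label, ": ", length(x$conformers),
      " conformer(s) at ", x$temperature, " K\n", sep = "")
  print(utils::head(ensemble_summary(x), 10L))
  invisible(x)
}
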