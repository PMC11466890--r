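# ECD stick-spectrum broadening, Boltzmann averaging, and similarity scoring.
#
# A broadened curve is a sum of Gaussians, one per electronic transition:
#
#   delta_eps(nu) = sum_i  nu_i * R_i / (22.97 * sqrt(pi) * sigma)
#                          * exp(-((nu - nu_i) / sigma)^2)
#
# with nu in cm^-1, R_i the dipole-velocity rotational strength in 1e-40 cgs
# units, and sigma the 1/e half-width of the band. The constant 22.97 comes
# from 2.297e-39 cgs with R expressed in 1e-40 units.

.ECD_PREFACTOR <- 22.97

#' Construct an ECD spectrum
#'
#' @param wavelength_nm Strictly monotone wavelength grid in nm.
#' @param delta_epsilon Differential molar absorptivity in 1/(M cm), same
#'   length as the grid.
#' @return An object of class `ecd_spectrum`.
#' @export
ecd_spectrum <- function(wavelength_nm, delta_epsilon) {
  stopifnot(length(wavelength_nm) == length(delta_epsilon),
            length(wavelength_nm) >= 1L,
            all(is.finite(wavelength_nm)), all(is.finite(delta_epsilon)))
  d <- diff(wavelength_nm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavelength grid must be strictly monotone")
  if (length(d) && all(d < 0)) { # store ascending
    wavelength_nm <- rev(wavelength_nm)
    delta_epsilon <- rev(delta_epsilon)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 delta_epsilon = as.numeric(delta_epsilon)),
            class = "ecd_spectrum")
}

#' @export
print.ecd_spectrum <- function(x, ...) {
  cat("<ecd_spectrum> ", length(x$wavelength_nm), " points, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm, |max| ",
      signif(max(abs(x$delta_epsilon)), 3), "\n", sep = "")
  invisible(x)
}

#' Broadening configuration
#'
#' @param width Band width in cm^-1 (default 3000).
#' @param width_convention `"half-height"` (the printed width is the full
#'   width at half maximum; converted internally to the 1/e half-width by
#'   sigma = FWHM / (2 sqrt(ln 2))) or `"1/e"` (the width is used as sigma
#'   directly, matching tools that exponentiate the printed value).
#' @param grid_nm Wavelength grid in nm on which curves are evaluated
#'   (default 180-450 nm in 1 nm steps).
#' @return A list of class `broadening_config`.
#' @export
broadening_config <- function(width = 3000,
                              width_convention = c("half-height", "1/e"),
                              grid_nm = seq(180, 450, by = 1)) {
  width_convention <- match.arg(width_convention)
  stopifnot(is.numeric(width), width > 0, length(grid_nm) >= 1L)
  sigma <- if (width_convention == "half-height")
    width / (2 * sqrt(log(2))) else width
  structure(list(width = width, width_convention = width_convention,
                 sigma_cm1 = sigma, grid_nm = as.numeric(grid_nm)),
            class = "broadening_config")
}

#' Broaden stick transitions into an ECD curve
#'
#' @param transitions Data frame with columns `wavelength_nm` and `R_vel`
#'   (rotational strength in 1e-40 cgs); alternatively an `energy_cm1` or
#'   `energy_ev` column may replace `wavelength_nm`. Zero rows give an
#'   all-zero spectrum.
#' @param config A [broadening_config()].
#' @return An [ecd_spectrum()] on `config$grid_nm`.
#' @export
broaden_sticks <- function(transitions, config = broadening_config()) {
  stopifnot(inherits(config, "broadening_config"))
  transitions <- as.data.frame(transitions)
  nu_grid <- 1e7 / config$grid_nm
  if (!nrow(transitions))
    return(ecd_spectrum(config$grid_nm, rep(0, length(config$grid_nm))))
  nu_i <-
    if ("wavelength_nm" %in% names(transitions)) 1e7 / transitions$wavelength_nm
    else if ("energy_cm1" %in% names(transitions)) transitions$energy_cm1
    else if ("energy_ev" %in% names(transitions)) transitions$energy_ev * 8065.54429
    else stop("transitions need a wavelength_nm, energy_cm1 or energy_ev column")
  if (any(nu_i <= 0)) stop("transition energies must be positive")
  R <- transitions$R_vel
  if (is.null(R)) stop("transitions need an R_vel column")
  sigma <- config$sigma_cm1
  amp <- nu_i * R / (.ECD_PREFACTOR * sqrt(pi) * sigma)
  vals <- vapply(nu_grid, function(nu)
    sum(amp * exp(-((nu - nu_i) / sigma)^2)), numeric(1))
  ecd_spectrum(config$grid_nm, vals)
}

#' Population-weighted sum of per-conformer spectra
#'
#' @param spectra List of [ecd_spectrum()] objects on a common grid.
#' @param populations Weights summing to 1 (within 1e-9).
#' @return The weighted [ecd_spectrum()].
#' @export
weight_and_sum_spectra <- function(spectra, populations) {
  stopifnot(length(spectra) == length(populations), length(spectra) >= 1L)
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1 (got ", sum(populations), ")")
  grid <- spectra[[1]]$wavelength_nm
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelength_nm, grid, tolerance = 1e-12)))
      stop("spectra must share a common wavelength grid")
  vals <- Reduce(`+`, Map(function(s, p) p * s$delta_epsilon,
                          spectra, populations))
  ecd_spectrum(grid, vals)
}

#' Boltzmann-averaged ECD spectrum of an ensemble
#'
#' Broadens each conformer's transitions and sums the curves with the
#' ensemble's Boltzmann populations.
#'
#' @param ens An [ensemble()] whose conformers carry transitions.
#' @param config A [broadening_config()].
#' @return An [ecd_spectrum()].
#' @export
ensemble_ecd_spectrum <- function(ens, config = broadening_config()) {
  stopifnot(inherits(ens, "ensemble"))
  tr <- lapply(ens$conformers, `[[`, "transitions")
  if (any(vapply(tr, is.null, logical(1))))
    stop("every conformer needs transitions")
  spectra <- lapply(tr, broaden_sticks, config = config)
  weight_and_sum_spectra(spectra, unname(ensemble_populations(ens)))
}

#' Mirror-image (enantiomer) spectrum
#'
#' Enantiomers give exactly sign-flipped ECD curves; this is pointwise
#' negation and an involution.
#'
#' @param s An [ecd_spectrum()].
#' @return The negated spectrum.
#' @export
enantiomer_spectrum <- function(s) {
  stopifnot(inherits(s, "ecd_spectrum"))
  ecd_spectrum(s$wavelength_nm, -s$delta_epsilon)
}

.restrict_spectrum <- function(s, region) {
  if (is.null(region)) return(s)
  stopifnot(length(region) == 2L, region[1] < region[2])
  keep <- s$wavelength_nm >= region[1] & s$wavelength_nm <= region[2]
  if (!any(keep)) stop("region [", region[1], ", ", region[2],
                       "] nm contains no grid points")
  ecd_spectrum(s$wavelength_nm[keep], s$delta_epsilon[keep])
}

#' Cosine similarity between calculated and experimental ECD curves
#'
#' The score is the normalized inner product of the two curves on the common
#' grid (1 = identical shape, -1 = mirror image), optionally restricted to a
#' wavelength region and maximized over rigid integer-nm shifts of the
#' calculated curve (a crude stand-in for a systematic transition-energy
#' offset). A least-squares intensity scale factor is reported but does not
#' affect the score, which is scale-invariant by construction.
#'
#' @param calc,exp [ecd_spectrum()] objects with overlapping grids.
#' @param region Optional `c(min_nm, max_nm)` restriction.
#' @param shift_scan Non-negative integer: scan shifts -shift_scan..shift_scan
#'   nm in 1 nm steps (0 = no scan).
#' @return List with `score`, `best_shift_nm`, `best_scale`, `n_points`.
#' @export
similarity_score <- function(calc, exp, region = NULL, shift_scan = 0) {
  stopifnot(inherits(calc, "ecd_spectrum"), inherits(exp, "ecd_spectrum"),
            shift_scan >= 0)
  exp_r <- .restrict_spectrum(exp, region)
  shifts <- seq.int(-round(shift_scan), round(shift_scan))
  best <- list(score = -Inf, best_shift_nm = NA_real_,
               best_scale = NA_real_, n_points = 0L)
  for (s in shifts) {
    # value of the shifted calculated curve at wavelength L is calc(L - s)
    cv <- stats::approx(calc$wavelength_nm + s, calc$delta_epsilon,
                        xout = exp_r$wavelength_nm, rule = 1)$y
    ok <- !is.na(cv)
    if (sum(ok) < 2L) next
    x <- cv[ok]; y <- exp_r$delta_epsilon[ok]
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    score <- if (nx == 0 || ny == 0) 0 else sum(x * y) / (nx * ny)
    if (score > best$score)
      best <- list(score = score, best_shift_nm = s,
                   best_scale = if (nx == 0) NA_real_ else sum(x * y) / nx^2,
                   n_points = sum(ok))
  }
  if (!is.finite(best$score))
    stop("calculated and experimental grids do not overlap in the region")
  best
}

#' Rank candidate spectra against an experimental curve per region
#'
#' Computes [similarity_score()] independently in each wavelength region and
#' orders candidates by descending score within each. Ties (within `tie_tol`)
#' are flagged.
#'
#' @param candidates Named list of [ecd_spectrum()] objects (names are stereo
#'   labels), >= 2.
#' @param exp Experimental [ecd_spectrum()].
#' @param regions List of `c(min_nm, max_nm)` intervals (>= 1).
#' @param shift_scan Passed to [similarity_score()].
#' @param tie_tol Scores closer than this are reported as tied. The default
#'   0.05 treats cosine differences smaller than typical band-shape noise as
#'   meaningless — two candidates "reproduce the spectrum equally well".
#' @return Data frame with columns `region`, `stereo_label`, `score`, `rank`,
#'   `tied`, ordered by region then rank.
#' @export
region_ranking <- function(candidates, exp, regions, shift_scan = 0,
                           tie_tol = 0.05) {
  stopifnot(length(candidates) >= 2L, length(regions) >= 1L)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list (stereo labels)")
  out <- do.call(rbind, lapply(seq_along(regions), function(ri) {
    region <- regions[[ri]]
    scores <- vapply(candidates, function(sp)
      similarity_score(sp, exp, region = region,
                       shift_scan = shift_scan)$score, numeric(1))
    ord <- order(-scores, names(candidates))
    sc <- scores[ord]
    rank <- integer(length(sc)); rank[1] <- 1L
    for (i in seq_along(sc)[-1])
      rank[i] <- if (abs(sc[i] - sc[i - 1]) <= tie_tol) rank[i - 1]
                 else rank[i - 1] + 1L
    data.frame(region = paste0(region[1], "-", region[2], "nm"),
               stereo_label = names(candidates)[ord],
               score = unname(sc), rank = rank,
               tied = rank %in% rank[duplicated(rank)])
  }))
  rownames(out) <- NULL
  out
}

#' Overlay a calculated and an experimental ECD spectrum
#'
#' Base-graphics overlay in the style of calculated-vs-experimental ECD
#' figures, with optional rotational-strength bars.
#'
#' @param calc,exp [ecd_spectrum()] objects.
#' @param transitions Optional transition data frame to draw as sticks
#'   (scaled to the plot range).
#' @param main Plot title.
#' @export
plot_ecd_overlay <- function(calc, exp, transitions = NULL, main = "") {
  rng <- range(calc$delta_epsilon, exp$delta_epsilon)
  graphics::plot(exp$wavelength_nm, exp$delta_epsilon, type = "l",
                 col = "black", lwd = 2, ylim = rng,
                 xlab = "wavelength (nm)",
                 ylab = expression(Delta * epsilon ~ (M^-1 ~ cm^-1)),
                 main = main)
  graphics::lines(calc$wavelength_nm, calc$delta_epsilon, col = "red2",
                  lwd = 2, lty = 2)
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(transitions) && nrow(transitions)) {
    sc <- max(abs(rng)) / max(abs(transitions$R_vel))
    graphics::segments(transitions$wavelength_nm, 0,
                       transitions$wavelength_nm, transitions$R_vel * sc,
                       col = "blue3")
  }
  graphics::legend("topright", c("experimental", "calculated"),
                   col = c("black", "red2"), lty = c(1, 2), bty = "n")
  invisible(NULL)
}
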