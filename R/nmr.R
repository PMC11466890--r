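# Linear shielding->shift correction, Boltzmann-averaged shift prediction,
# error statistics against experimental tables, and stereoisomer ranking.

#' Linear shielding-to-shift correction
#'
#' The computed isotropic shielding sigma is modelled as an affine function of
#' the chemical shift, sigma = I + S * delta; predicting a shift inverts the
#' line: delta = (sigma - I) / S.
#'
#' @param intercept Intercept I in ppm.
#' @param slope Dimensionless slope S (non-zero; near -1 for well-behaved
#'   GIAO protocols).
#' @param solvent Free-text solvent tag carried in reports.
#' @return An object of class `shift_correction`.
#' @export
shift_correction <- function(intercept, slope, solvent = "") {
  stopifnot(is.numeric(intercept), is.numeric(slope), is.finite(slope))
  if (slope == 0) stop("correction slope must be non-zero")
  structure(list(intercept = as.numeric(intercept),
                 slope = as.numeric(slope),
                 solvent = as.character(solvent)),
            class = "shift_correction")
}

#' Built-in 13C shielding corrections
#'
#' The mPW1PW91/6-311+G(2d,p) correction pairs used for these compounds:
#' I = 185.6277, S = -1.0175 for methanol and I = 185.2853, S = -1.0267 for
#' DMSO.
#'
#' @param solvent `"meoh"` or `"dmso"`.
#' @return A [shift_correction()].
#' @export
builtin_correction <- function(solvent = c("dmso", "meoh")) {
  solvent <- match.arg(tolower(solvent), c("dmso", "meoh"))
  switch(solvent,
         meoh = shift_correction(185.6277, -1.0175, "MeOH"),
         dmso = shift_correction(185.2853, -1.0267, "DMSO"))
}

#' Convert shieldings to shifts (and back)
#'
#' @param sigma Isotropic shielding(s) in ppm.
#' @param correction A [shift_correction()].
#' @return Chemical shift(s) delta in ppm.
#' @export
shielding_to_shift <- function(sigma, correction) {
  stopifnot(inherits(correction, "shift_correction"))
  (sigma - correction$intercept) / correction$slope
}

#' @rdname shielding_to_shift
#' @param delta Chemical shift(s) in ppm.
#' @export
shift_to_shielding <- function(delta, correction) {
  stopifnot(inherits(correction, "shift_correction"))
  correction$intercept + correction$slope * delta
}

#' Build a shift table
#'
#' @param label Nucleus labels (e.g. `"C-17"`, `"H-24"`, `"H-25a"`); unique.
#' @param delta_ppm Observed or predicted shifts in ppm (finite).
#' @param nucleus Nucleus kind per row, `"13C"` or `"1H"`; inferred from the
#'   label prefix (`C-` / `H-` / `NH-`) when omitted.
#' @param ... Optional extra columns (multiplicity, J) carried verbatim.
#' @return A data frame of class `shift_table`.
#' @export
shift_table <- function(label, delta_ppm, nucleus = NULL, ...) {
  label <- as.character(label)
  if (anyDuplicated(label))
    stop("duplicate nucleus labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  if (!all(is.finite(delta_ppm))) stop("shifts must be finite")
  if (is.null(nucleus)) {
    nucleus <- ifelse(grepl("^C", label), "13C",
                      ifelse(grepl("^N?H", label), "1H", NA_character_))
    if (anyNA(nucleus))
      stop("cannot infer nucleus kind for label(s): ",
           paste(label[is.na(nucleus)], collapse = ", "))
  }
  out <- data.frame(label = label, nucleus = nucleus,
                    delta_ppm = as.numeric(delta_ppm), ...)
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Boltzmann-averaged predicted shifts for an ensemble
#'
#' Averages per-nucleus shieldings over conformers with Boltzmann weights,
#' then applies the linear correction. Because the correction is affine,
#' averaging shieldings first or converting each conformer first gives the
#' same result.
#'
#' @param ens An [ensemble()] whose conformers carry shieldings.
#' @param correction A [shift_correction()].
#' @return A [shift_table()] of predicted shifts.
#' @export
ensemble_average_shifts <- function(ens, correction) {
  stopifnot(inherits(ens, "ensemble"))
  sig <- lapply(ens$conformers, `[[`, "shieldings")
  if (any(vapply(sig, is.null, logical(1))))
    stop("every conformer needs shieldings; missing for: ",
         paste(vapply(ens$conformers[vapply(sig, is.null, logical(1))],
                      `[[`, character(1), "id"), collapse = ", "))
  labels <- names(sig[[1]])
  mat <- do.call(rbind, lapply(sig, function(s) s[labels]))
  p <- unname(ensemble_populations(ens))
  avg <- as.numeric(p %*% mat)
  shift_table(labels, shielding_to_shift(avg, correction))
}

#' Agreement statistics between predicted and observed shifts
#'
#' Computed over the label intersection restricted to one nucleus kind:
#' mean absolute error (MAE), corrected MAE after re-fitting a least-squares
#' line of observed on predicted shifts (CMAE), root-mean-square deviation,
#' maximum absolute deviation, and the fitted slope/intercept.
#'
#' @param predicted,observed [shift_table()] objects.
#' @param nucleus `"13C"` (default) or `"1H"`.
#' @param swap_tolerant If `TRUE`, diastereotopic label pairs (same label up
#'   to a trailing `a`/`b`, e.g. `H-25a`/`H-25b`) are scored with the better
#'   of the two pairings, since the a/b assignment of geminal protons is
#'   often arbitrary. Off by default: labels are trusted as given.
#' @return A list with elements `n`, `mae`, `cmae`, `rmsd`, `max_abs_dev`,
#'   `slope`, `intercept`.
#' @export
shift_error_stats <- function(predicted, observed, nucleus = "13C",
                              swap_tolerant = FALSE) {
  stopifnot(inherits(predicted, "shift_table"),
            inherits(observed, "shift_table"))
  p <- predicted[predicted$nucleus == nucleus, ]
  o <- observed[observed$nucleus == nucleus, ]
  shared <- intersect(p$label, o$label)
  if (length(shared) < 2L)
    stop("need at least 2 shared ", nucleus, " labels; got ", length(shared))
  dp <- p$delta_ppm[match(shared, p$label)]
  do_ <- o$delta_ppm[match(shared, o$label)]
  if (swap_tolerant) {
    stem <- sub("[ab]$", "", shared)
    is_ab <- grepl("[ab]$", shared)
    for (s in unique(stem[is_ab])) {
      idx <- which(stem == s & is_ab)
      if (length(idx) != 2L) next
      if (sum(abs(dp[rev(idx)] - do_[idx])) < sum(abs(dp[idx] - do_[idx])))
        dp[idx] <- dp[rev(idx)]
    }
  }
  res <- dp - do_
  fit <- stats::lm(do_ ~ dp)
  corrected <- stats::fitted(fit)
  list(n = length(shared),
       mae = mean(abs(res)),
       cmae = mean(abs(corrected - do_)),
       rmsd = sqrt(mean(res^2)),
       max_abs_dev = max(abs(res)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Rank candidate stereoisomers by NMR agreement
#'
#' Predicts Boltzmann-averaged shifts for every candidate ensemble, scores
#' each against the experimental table and orders candidates by ascending
#' error. Ties (scores equal within `tie_tol`) are reported, never silently
#' broken; tied candidates keep a stable order by stereo label.
#'
#' @param candidates List of [ensemble()] objects (>= 2).
#' @param observed Experimental [shift_table()].
#' @param correction A [shift_correction()].
#' @param metric `"mae"` (default), `"cmae"` or `"rmsd"`.
#' @param nucleus Nucleus kind driving the ranking; `"13C"` by default
#'   because carbon shifts are the standard discriminator in
#'   shielding-scaling protocols.
#' @param tie_tol Scores closer than this are flagged as tied.
#' @return Data frame with columns `stereo_label`, `mae`, `cmae`, `rmsd`,
#'   `rank`, `tied`, sorted by the chosen metric.
#' @export
rank_stereoisomers_nmr <- function(candidates, observed, correction,
                                   metric = c("mae", "cmae", "rmsd"),
                                   nucleus = "13C", tie_tol = 1e-9) {
  metric <- match.arg(metric)
  if (length(candidates) < 2L) stop("need at least 2 candidate ensembles")
  stats_list <- lapply(candidates, function(ens) {
    pred <- ensemble_average_shifts(ens, correction)
    shift_error_stats(pred, observed, nucleus)
  })
  out <- data.frame(
    stereo_label = vapply(candidates, `[[`, character(1), "stereo_label"),
    mae = vapply(stats_list, `[[`, numeric(1), "mae"),
    cmae = vapply(stats_list, `[[`, numeric(1), "cmae"),
    rmsd = vapply(stats_list, `[[`, numeric(1), "rmsd")
  )
  score <- out[[metric]]
  ord <- order(score, out$stereo_label)
  out <- out[ord, , drop = FALSE]
  score <- score[ord]
  # dense ranks with tie detection at tie_tol
  rank <- integer(nrow(out))
  rank[1] <- 1L
  for (i in seq_len(nrow(out))[-1])
    rank[i] <- if (abs(score[i] - score[i - 1]) <= tie_tol) rank[i - 1]
               else rank[i - 1] + 1L
  out$rank <- rank
  out$tied <- rank %in% rank[duplicated(rank)]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  out
}

#' Fit a shielding-to-shift correction from reference data
#'
#' Ordinary least squares of computed shieldings on observed shifts,
#' sigma = I + S * delta.
#'
#' @param sigmas Computed isotropic shieldings (ppm).
#' @param deltas_observed Observed shifts (ppm), same length, >= 3 points.
#' @param solvent Solvent tag for the fitted correction.
#' @return A [shift_correction()] with attributes `r_squared` and
#'   `residual_sd`.
#' @export
fit_correction <- function(sigmas, deltas_observed, solvent = "") {
  stopifnot(length(sigmas) == length(deltas_observed))
  if (length(sigmas) < 3L) stop("need at least 3 reference points")
  if (stats::sd(deltas_observed) == 0)
    stop("degenerate reference shifts (zero variance)")
  fit <- stats::lm(sigmas ~ deltas_observed)
  cf <- stats::coef(fit)
  out <- shift_correction(cf[[1]], cf[[2]], solvent)
  # summary.lm warns on numerically perfect fits; those are fine here
  attr(out, "r_squared") <- suppressWarnings(summary(fit))$r.squared
  attr(out, "residual_sd") <- stats::sigma(fit)
  out
}

#' Per-label shift differences between two tables
#'
#' Signed differences delta(a) - delta(b) over the label intersection, e.g.
#' for comparing the same position across epimeric compounds.
#'
#' @param a,b [shift_table()] objects.
#' @return Data frame with columns `label`, `nucleus`, `delta_a`, `delta_b`,
#'   `difference`.
#' @export
shift_difference_table <- function(a, b) {
  stopifnot(inherits(a, "shift_table"), inherits(b, "shift_table"))
  shared <- intersect(a$label, b$label)
  if (!length(shared)) stop("the two tables share no labels")
  ia <- match(shared, a$label); ib <- match(shared, b$label)
  data.frame(label = shared,
             nucleus = a$nucleus[ia],
             delta_a = a$delta_ppm[ia],
             delta_b = b$delta_ppm[ib],
             difference = a$delta_ppm[ia] - b$delta_ppm[ib])
}
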