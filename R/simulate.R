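# Seeded generators that emulate the statistical structure of
# quantum-chemistry and docking outputs, so every pipeline stage can be
# exercised against a known planted truth. The noise models are Gaussian
# throughout: a deliberate, documented simplification, not physics.

.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.paper_candidate_labels <- function(vary_values) {
  # full descriptors over the fixed octahydronaphthalene block + C-19/C-24
  vapply(vary_values, function(v) {
    stereo_candidate(c("3" = "R", "4" = "S", "5" = "R", "8" = "R",
                       "10" = "S", "19" = v[1], "24" = v[2]))$label
  }, character(1))
}

#' Generate candidate conformer ensembles with planted NMR truth
#'
#' Emulates the DFT-NMR inputs of a four-stereoisomer assignment: each
#' candidate gets conformers whose relative energies fall inside the
#' conformational-search window, and per-carbon isotropic shieldings built
#' from "true" shifts through a planted linear map sigma = I + S * delta plus
#' Gaussian noise. Candidate true shifts differ from the generating isomer by
#' planted perturbations on a few carbons near the varied centers.
#'
#' Two perturbation modes are offered. `"distinct"` (default) gives every
#' non-true candidate its own perturbation, so the generating isomer is
#' uniquely recoverable. `"relative"` perturbs by relative configuration
#' class at the varied centers (candidates differing only by global
#' inversion of the varied block share true shifts), mirroring the physical
#' fact that NMR cannot distinguish a block from its mirror image; the
#' generating isomer is then recoverable only up to that inversion.
#'
#' @param seed Integer seed; identical spec gives identical output.
#' @param n_conformers Conformers per candidate (default 8).
#' @param n_carbons Carbons in the shift table (default 24).
#' @param energy_window Conformer energies are drawn in `[0, energy_window]`
#'   kJ/mol (default 21, the search window).
#' @param perturb_carbons How many carbons differ between stereoisomer
#'   classes (default 3).
#' @param perturb_ppm Size of the planted inter-isomer shift difference in
#'   ppm (default 3).
#' @param noise_sd Gaussian shielding noise SD in ppm (default 0.5).
#' @param correction Planted linear map; default the methanol pair
#'   I = 185.6277, S = -1.0175.
#' @param true_isomer Index of the generating candidate (default 1 =
#'   (19R,24R)).
#' @param mode `"distinct"` or `"relative"` (see above).
#' @return List with `ensembles` (named list of [ensemble()]), `observed`
#'   (the experimental [shift_table()] derived from the true shifts), and
#'   `truth` (planted parameters: true label, relative class partners, I, S,
#'   true shifts, perturbed carbon labels).
#' @export
gen_nmr_ensembles <- function(seed, n_conformers = 8, n_carbons = 24,
                              energy_window = 21, perturb_carbons = 3,
                              perturb_ppm = 3, noise_sd = 0.5,
                              correction = builtin_correction("meoh"),
                              true_isomer = 1L,
                              mode = c("distinct", "relative")) {
  mode <- match.arg(mode)
  stopifnot(n_conformers >= 1, n_carbons >= perturb_carbons + 2,
            perturb_carbons >= 1, true_isomer %in% 1:4)
  .with_seed(seed, {
    vary <- list(c("R", "R"), c("R", "S"), c("S", "R"), c("S", "S"))
    labels <- .paper_candidate_labels(vary)
    carbon_labels <- paste0("C-", seq_len(n_carbons))
    base_shifts <- stats::runif(n_carbons, 10, 200)
    names(base_shifts) <- carbon_labels
    hit <- sample.int(n_carbons, perturb_carbons)
    # class key: "distinct" -> one class per candidate; "relative" ->
    # candidates equivalent under inversion of the varied block share a class
    class_of <- if (mode == "distinct") seq_along(vary) else
      vapply(vary, function(v) if (v[1] == v[2]) 1L else 2L, integer(1))
    true_class <- class_of[true_isomer]
    class_shift <- list()
    for (cl in unique(class_of)) {
      delta <- if (cl == true_class) rep(0, perturb_carbons) else
        sample(c(-1, 1), perturb_carbons, replace = TRUE) * perturb_ppm
      class_shift[[as.character(cl)]] <- delta
    }
    ensembles <- stats::setNames(vector("list", length(vary)), labels)
    true_shifts_by_label <- list()
    for (k in seq_along(vary)) {
      shifts_k <- base_shifts
      shifts_k[hit] <- shifts_k[hit] + class_shift[[as.character(class_of[k])]]
      true_shifts_by_label[[labels[k]]] <- shifts_k
      energies <- c(0, stats::runif(n_conformers - 1, 0, energy_window))
      confs <- lapply(seq_len(n_conformers), function(j) {
        sigma <- shift_to_shielding(shifts_k, correction) +
          stats::rnorm(n_carbons, 0, noise_sd)
        conformer_record(sprintf("%s_conf%02d", letters[k], j), energies[j],
                         shieldings = sigma)
      })
      ensembles[[labels[k]]] <- ensemble(labels[k], confs)
    }
    observed <- shift_table(carbon_labels,
                            true_shifts_by_label[[labels[true_isomer]]])
    partners <- labels[class_of == true_class]
    list(ensembles = ensembles,
         observed = observed,
         truth = list(true_label = labels[true_isomer],
                      relative_class = partners,
                      intercept = correction$intercept,
                      slope = correction$slope,
                      true_shifts = true_shifts_by_label,
                      perturbed_carbons = carbon_labels[hit]))
  })
}

#' Generate candidate ECD transition sets with region-coupled sign structure
#'
#' Emulates the TDDFT-ECD stage of a two-center epimer problem: the
#' experimental spectrum is governed by one stereocenter (e.g. C-19) inside
#' a reporter wavelength region and by a fixed block elsewhere. Candidates
#' that are epimeric at the reporter center flip rotational-strength signs
#' only for transitions inside the reporter region; a full enantiomer would
#' flip every sign. The "experimental" curve is the broadened spectrum of
#' the generating candidate plus Gaussian band noise.
#'
#' @param seed Integer seed.
#' @param n_conformers Conformers per candidate (default 3).
#' @param n_transitions_region Transitions inside the reporter region per
#'   conformer (default 3).
#' @param n_transitions_other Transitions below the reporter region
#'   (default 4).
#' @param reporter_region `c(min_nm, max_nm)` interval reporting the varied
#'   center (default `c(240, 450)`).
#' @param other_region Interval for the block-governed transitions (default
#'   `c(190, 239)`).
#' @param r_scale Typical |R| in 1e-40 cgs (default 20).
#' @param r_noise_sd Gaussian noise SD added to each candidate's R values
#'   (default 0.5).
#' @param exp_noise_sd Gaussian noise SD added to the experimental curve, as
#'   a fraction of its max |delta eps| (default 0.02).
#' @param true_isomer Index of the generating candidate (default 1 =
#'   (19R,24R)).
#' @param config [broadening_config()] used for the experimental curve.
#' @return List with `ensembles` (named list of [ensemble()] carrying
#'   transitions), `exp_spectrum` (an [ecd_spectrum()]), `truth` (true label,
#'   reporter center/region, per-candidate sign conventions).
#' @export
gen_ecd_ensembles <- function(seed, n_conformers = 3,
                              n_transitions_region = 3,
                              n_transitions_other = 4,
                              reporter_region = c(240, 450),
                              other_region = c(190, 239),
                              r_scale = 20, r_noise_sd = 0.5,
                              exp_noise_sd = 0.02,
                              true_isomer = 1L,
                              config = broadening_config()) {
  stopifnot(reporter_region[1] < reporter_region[2],
            other_region[1] < other_region[2],
            other_region[2] <= reporter_region[1] ||
              reporter_region[2] <= other_region[1],
            true_isomer %in% 1:4)
  .with_seed(seed, {
    vary <- list(c("R", "R"), c("R", "S"), c("S", "R"), c("S", "S"))
    labels <- .paper_candidate_labels(vary)
    true_19 <- vary[[true_isomer]][1]
    # base sticks shared by every conformer of the generating isomer; small
    # per-conformer jitter keeps conformers distinct but consistent in sign
    # sticks sit well inside their region so that Gaussian tails (sigma ~
    # 1800 cm^-1 at half-height width 3000) do not bleed across the boundary
    # -- emulating well-separated chromophore bands
    base <- data.frame(
      wavelength_nm = c(
        stats::runif(n_transitions_region,
                     reporter_region[1] + 40,
                     min(reporter_region[2] - 50, reporter_region[1] + 140)),
        stats::runif(n_transitions_other, other_region[1] + 5,
                     other_region[2] - 14)),
      R_vel = c(sample(c(-1, 1), n_transitions_region, TRUE) *
                  stats::runif(n_transitions_region, 0.5, 1) * r_scale,
                sample(c(-1, 1), n_transitions_other, TRUE) *
                  stats::runif(n_transitions_other, 0.5, 1) * r_scale),
      region = rep(c("reporter", "other"),
                   c(n_transitions_region, n_transitions_other))
    )
    ensembles <- stats::setNames(vector("list", length(vary)), labels)
    flips <- stats::setNames(logical(length(vary)), labels)
    for (k in seq_along(vary)) {
      flip <- vary[[k]][1] != true_19   # epimeric at the reporter center?
      flips[k] <- flip
      energies <- c(0, stats::runif(n_conformers - 1, 0, 10))
      confs <- lapply(seq_len(n_conformers), function(j) {
        tr <- base
        if (flip) tr$R_vel[tr$region == "reporter"] <-
            -tr$R_vel[tr$region == "reporter"]
        tr$R_vel <- tr$R_vel + stats::rnorm(nrow(tr), 0, r_noise_sd)
        conformer_record(sprintf("%s_conf%02d", letters[k], j), energies[j],
                         transitions = tr[c("wavelength_nm", "R_vel")])
      })
      ensembles[[labels[k]]] <- ensemble(labels[k], confs)
    }
    clean <- ensemble_ecd_spectrum(ensembles[[labels[true_isomer]]], config)
    noise <- stats::rnorm(length(clean$wavelength_nm), 0,
                          exp_noise_sd * max(abs(clean$delta_epsilon)))
    exp_spectrum <- ecd_spectrum(clean$wavelength_nm,
                                 clean$delta_epsilon + noise)
    list(ensembles = ensembles,
         exp_spectrum = exp_spectrum,
         truth = list(true_label = labels[true_isomer],
                      reporter_center = "19",
                      reporter_region = reporter_region,
                      other_region = other_region,
                      reporter_flipped = flips))
  })
}

#' Generate a docking pose cloud with planted clusters
#'
#' Gaussian blobs of rigid-ligand poses in 3D: one shared random ligand
#' template is translated to each blob centre plus pose-level jitter (no
#' rotational noise, so pose-pose RMSD is dominated by the translation).
#' Scores correlate with blob rank so the leader of the first blob is the
#' best-scoring pose.
#'
#' @param seed Integer seed.
#' @param n_poses Total poses (default 200).
#' @param centers k x 3 matrix of blob centres (default two blobs 10 A
#'   apart).
#' @param weights Blob membership probabilities summing to 1 (default
#'   `c(0.7, 0.3)`).
#' @param spread_sd Pose-translation SD within a blob in A (default 0.4,
#'   well inside a 2.0 A clustering cutoff).
#' @param n_atoms Ligand heavy atoms (default 10).
#' @param pocket_blob Which blob the pocket encloses (default 1); the pocket
#'   is a centroid sphere of radius `pocket_radius` at that blob's centre.
#' @param pocket_radius Pocket radius in A (default 6).
#' @return List with `poses` (a [pose_set()]), `pocket`
#'   (a [pocket_definition()]), `truth` (blob membership per pose, centres,
#'   weights).
#' @export
gen_pose_cloud <- function(seed, n_poses = 200,
                           centers = rbind(c(0, 0, 0), c(10, 0, 0)),
                           weights = c(0.7, 0.3), spread_sd = 0.4,
                           n_atoms = 10, pocket_blob = 1L,
                           pocket_radius = 6) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3L, length(weights) == nrow(centers),
            abs(sum(weights) - 1) < 1e-9, n_poses >= 1, n_atoms >= 1)
  .with_seed(seed, {
    template <- matrix(stats::rnorm(n_atoms * 3, 0, 1.5), ncol = 3)
    template <- sweep(template, 2L, colMeans(template))
    blob <- sample.int(nrow(centers), n_poses, replace = TRUE, prob = weights)
    coords <- lapply(seq_len(n_poses), function(i) {
      shift <- centers[blob[i], ] + stats::rnorm(3, 0, spread_sd)
      sweep(template, 2L, shift, `+`)
    })
    # better (lower) scores for lower-rank blobs, with jitter
    scores <- blob + stats::rnorm(n_poses, 0, 0.1)
    poses <- pose_set(coords, ids = sprintf("pose_%03d", seq_len(n_poses)),
                      scores = scores)
    pocket <- pocket_definition(centroid = centers[pocket_blob, ],
                                radius = pocket_radius)
    list(poses = poses, pocket = pocket,
         truth = list(blob = blob, centers = centers, weights = weights))
  })
}

#' Perturb a packaged experimental shift table
#'
#' Adds seeded Gaussian noise to the printed shifts of one of the packaged
#' compound tables, for robustness experiments. Zero noise returns the
#' fixture unchanged.
#'
#' @param seed Integer seed.
#' @param compound Compound number 1, 2 or 3.
#' @param noise_sd Gaussian noise SD in ppm (default 0.1).
#' @return A [shift_table()].
#' @export
gen_experimental_shift_table <- function(seed, compound = 1, noise_sd = 0.1) {
  tab <- load_compound_shifts(compound)
  .with_seed(seed, {
    tab$delta_ppm <- tab$delta_ppm + stats::rnorm(nrow(tab), 0, noise_sd)
    tab
  })
}
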