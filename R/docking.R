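# Blind-docking post-processing: pose RMSD, greedy leader clustering at a
# 2.0 A cutoff, largest-cluster occupancy, pocket membership, and the
# >= 20 % validity rule.

#' Construct a set of docking poses
#'
#' All poses share one heavy-atom ordering; RMSD uses the identity atom
#' mapping with no superposition, matching docking-engine clustering
#' semantics. Hydrogens should be excluded before construction.
#'
#' @param coords List of n_atoms x 3 numeric matrices (A), one per pose.
#' @param ids Pose identifiers (default `pose_1`, ...).
#' @param scores Engine scores, lower = better (default 0).
#' @param atoms Optional character vector of atom labels (length n_atoms).
#' @return An object of class `pose_set`.
#' @export
pose_set <- function(coords, ids = NULL, scores = NULL, atoms = NULL) {
  stopifnot(is.list(coords), length(coords) >= 1L)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3L, nrow(m) >= 1L, all(is.finite(m)))
    unname(m)
  })
  n_atoms <- nrow(coords[[1]])
  if (!all(vapply(coords, nrow, integer(1)) == n_atoms))
    stop("all poses must have the same atom count")
  n <- length(coords)
  if (is.null(ids)) ids <- paste0("pose_", seq_len(n))
  if (anyDuplicated(ids)) stop("pose ids must be unique")
  if (is.null(scores)) scores <- rep(0, n)
  stopifnot(length(ids) == n, length(scores) == n, all(is.finite(scores)))
  if (!is.null(atoms)) stopifnot(length(atoms) == n_atoms)
  structure(list(coords = coords, ids = as.character(ids),
                 scores = as.numeric(scores), atoms = atoms),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set>", length(x$coords), "poses x", nrow(x$coords[[1]]),
      "atoms\n")
  invisible(x)
}

#' In-place RMSD between two poses
#'
#' Root-mean-square deviation over atoms under the identity mapping, with no
#' superposition (docking poses live in the receptor frame, so rigid-body
#' differences are real differences).
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in A.
#' @export
pose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("poses differ in atom count: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Greedy leader clustering of docking poses
#'
#' Poses are visited best score first (ties broken by pose id); each pose
#' joins the first existing cluster whose representative (the cluster's
#' best-scoring member, i.e. its leader) lies within `cutoff` RMSD, else it
#' seeds a new cluster. This is the classic docking-engine scheme; given the
#' scores it is deterministic.
#'
#' @param poses A [pose_set()].
#' @param cutoff RMSD cutoff in A (default 2.0).
#' @return Object of class `cluster_report`: `clusters` (list of member id
#'   vectors, largest first), `representatives` (leader id per cluster),
#'   `fractions` (occupancy, sums to 1), `largest_fraction`, `assignment`
#'   (cluster index per pose, in input order).
#' @export
cluster_poses <- function(poses, cutoff = 2.0) {
  stopifnot(inherits(poses, "pose_set"), is.numeric(cutoff), cutoff > 0)
  n <- length(poses$coords)
  ord <- order(poses$scores, poses$ids)
  leaders <- integer(0)        # indices (into poses) of cluster leaders
  member_of <- integer(n)      # cluster index per pose
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (pose_rmsd(poses$coords[[i]], poses$coords[[leaders[k]]]) <= cutoff) {
        member_of[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      member_of[i] <- length(leaders)
    }
  }
  sizes <- tabulate(member_of, nbins = length(leaders))
  # order clusters by size (largest first), then by leader score
  cl_ord <- order(-sizes, poses$scores[leaders])
  remap <- integer(length(leaders)); remap[cl_ord] <- seq_along(cl_ord)
  member_of <- remap[member_of]
  leaders <- leaders[cl_ord]
  sizes <- sizes[cl_ord]
  structure(list(
    clusters = lapply(seq_along(leaders), function(k)
      poses$ids[member_of == k]),
    representatives = poses$ids[leaders],
    fractions = sizes / n,
    largest_fraction = sizes[1] / n,
    assignment = member_of
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report>", length(x$clusters), "cluster(s); largest fraction",
      signif(x$largest_fraction, 4), "\n")
  invisible(x)
}

#' Define a binding pocket
#'
#' Either a set of pocket-lining reference atom coordinates or a spherical
#' centroid + radius.
#'
#' @param coords Optional m x 3 matrix of reference atom positions (A).
#' @param centroid Optional length-3 centre (A).
#' @param radius Radius in A (required with `centroid`).
#' @return An object of class `pocket_definition`.
#' @export
pocket_definition <- function(coords = NULL, centroid = NULL, radius = NULL) {
  if (is.null(coords) && is.null(centroid))
    stop("supply pocket coords or a centroid + radius")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L, all(is.finite(coords)))
  }
  if (!is.null(centroid)) {
    stopifnot(length(centroid) == 3L, !is.null(radius), radius > 0)
  }
  structure(list(coords = coords, centroid = centroid, radius = radius),
            class = "pocket_definition")
}

#' Is a pose located in the binding pocket?
#'
#' TRUE iff at least one ligand heavy atom lies within `contact_cutoff` of at
#' least one pocket reference atom (inclusive), or — for a centroid pocket —
#' within the pocket radius of the centroid.
#'
#' @param pose n x 3 coordinate matrix.
#' @param pocket A [pocket_definition()].
#' @param contact_cutoff Heavy-atom contact distance in A (default 4.0).
#' @return Logical.
#' @export
pocket_membership <- function(pose, pocket, contact_cutoff = 4.0) {
  stopifnot(inherits(pocket, "pocket_definition"), contact_cutoff > 0)
  pose <- as.matrix(pose)
  if (!is.null(pocket$coords)) {
    d2 <- outer(rowSums(pose^2), rowSums(pocket$coords^2), `+`) -
      2 * pose %*% t(pocket$coords)
    any(d2 <= contact_cutoff^2 + 1e-12)
  } else {
    d2 <- rowSums(sweep(pose, 2L, pocket$centroid)^2)
    any(d2 <= pocket$radius^2 + 1e-12)
  }
}

#' Validate a binding mode
#'
#' A binding mode is valid iff the largest RMSD cluster comprises at least
#' `min_fraction` of all poses (inclusive) AND its representative pose is
#' located in the binding pocket.
#'
#' @param poses A [pose_set()].
#' @param pocket A [pocket_definition()].
#' @param min_fraction Minimum largest-cluster occupancy (default 0.20).
#' @param cutoff Clustering RMSD cutoff in A (default 2.0).
#' @param contact_cutoff Pocket contact distance in A (default 4.0).
#' @return List of class `binding_verdict`: `valid`, `largest_fraction`,
#'   `in_pocket`, `representative`, `reason`, `clusters` (the
#'   [cluster_poses()] report).
#' @export
validate_binding_mode <- function(poses, pocket, min_fraction = 0.20,
                                  cutoff = 2.0, contact_cutoff = 4.0) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  rep_cl <- cluster_poses(poses, cutoff)
  rep_id <- rep_cl$representatives[1]
  rep_pose <- poses$coords[[match(rep_id, poses$ids)]]
  in_pocket <- pocket_membership(rep_pose, pocket, contact_cutoff)
  frac_ok <- rep_cl$largest_fraction >= min_fraction
  reason <- if (frac_ok && in_pocket) {
    "largest cluster meets the occupancy threshold and sits in the pocket"
  } else if (!frac_ok && in_pocket) {
    sprintf("largest cluster occupancy %.3f < %.3f", rep_cl$largest_fraction,
            min_fraction)
  } else if (frac_ok) {
    "largest-cluster representative is outside the binding pocket"
  } else {
    "largest cluster is undersized and outside the binding pocket"
  }
  structure(list(valid = frac_ok && in_pocket,
                 largest_fraction = rep_cl$largest_fraction,
                 in_pocket = in_pocket,
                 representative = rep_id,
                 reason = reason,
                 clusters = rep_cl),
            class = "binding_verdict")
}

#' @export
print.binding_verdict <- function(x, ...) {
  cat("<binding_verdict>", if (x$valid) "VALID" else "INVALID", "-",
      x$reason, "\n")
  invisible(x)
}
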