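# Combining block-wise stereochemical evidence into full stereodescriptors.
#
# Molecules like these alkaloids carry "isolated blocks of chirality":
# groups of stereocenters whose relative configuration is known within the
# block (from ROE/J data) but which share no NOE or coupling connectivity
# with other blocks. NMR agreement constrains relative configuration (it
# cannot tell a block from its mirror image), while sign-sensitive ECD
# evidence pins absolute configuration of the center(s) a spectral region
# reports on.

#' Define a block of stereocenters
#'
#' @param name Block name, e.g. `"octahydronaphthalene"`.
#' @param centers Character vector of stereocenter labels (e.g.
#'   `c("3","4","5","8","10")`); non-empty.
#' @param reporter_region Optional `c(min_nm, max_nm)` ECD region whose
#'   transitions report this block's configuration.
#' @return An object of class `block_definition`.
#' @export
block_definition <- function(name, centers, reporter_region = NULL) {
  stopifnot(length(name) == 1L, length(centers) >= 1L)
  centers <- as.character(centers)
  if (anyDuplicated(centers)) stop("duplicate centers in block ", name)
  if (!is.null(reporter_region))
    stopifnot(length(reporter_region) == 2L,
              reporter_region[1] < reporter_region[2])
  structure(list(name = as.character(name), centers = centers,
                 reporter_region = reporter_region),
            class = "block_definition")
}

.check_blocks <- function(blocks) {
  stopifnot(all(vapply(blocks, inherits, logical(1), "block_definition")))
  all_centers <- unlist(lapply(blocks, `[[`, "centers"))
  if (anyDuplicated(all_centers))
    stop("blocks must be disjoint; repeated center(s): ",
         paste(unique(all_centers[duplicated(all_centers)]), collapse = ", "))
  all_centers
}

#' Build a stereocandidate from per-center R/S assignments
#'
#' @param descriptor Named character vector mapping center label to `"R"` or
#'   `"S"`, e.g. `c("3"="R","4"="S")`.
#' @return Object of class `stereo_candidate` with a derived label string
#'   such as `"(3R,4S)"` (centers ordered numerically where possible).
#' @export
stereo_candidate <- function(descriptor) {
  stopifnot(!is.null(names(descriptor)), all(descriptor %in% c("R", "S")))
  num <- suppressWarnings(as.numeric(names(descriptor)))
  ord <- if (anyNA(num)) order(names(descriptor)) else order(num)
  descriptor <- descriptor[ord]
  label <- paste0("(", paste0(names(descriptor), descriptor, collapse = ","), ")")
  structure(list(descriptor = descriptor, label = label),
            class = "stereo_candidate")
}

#' @export
format.stereo_candidate <- function(x, ...) x$label

#' @export
print.stereo_candidate <- function(x, ...) {
  cat("<stereo_candidate>", x$label, "\n"); invisible(x)
}

#' Enumerate candidate stereoisomers
#'
#' Holds `fixed` centers constant and takes the Cartesian product of R/S
#' flips over `vary`, yielding `2^length(vary)` candidates — the usual
#' design when some centers are locked by relative configuration or prior
#' knowledge and a few (here C-19 and C-24) must be tested.
#'
#' @param blocks List of [block_definition()] objects covering all centers.
#' @param fixed Named character vector of fixed assignments.
#' @param vary Character vector of center labels allowed to flip.
#' @return List of [stereo_candidate()] objects.
#' @export
enumerate_candidates <- function(blocks, fixed, vary = character()) {
  all_centers <- .check_blocks(blocks)
  vary <- as.character(vary)
  if (length(bad <- setdiff(vary, all_centers)))
    stop("vary contains unknown center(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(names(fixed), all_centers)))
    stop("fixed contains unknown center(s): ", paste(bad, collapse = ", "))
  if (length(overlap <- intersect(names(fixed), vary)))
    stop("center(s) both fixed and varying: ", paste(overlap, collapse = ", "))
  if (length(missing <- setdiff(all_centers, c(names(fixed), vary))))
    stop("center(s) neither fixed nor varying: ",
         paste(missing, collapse = ", "))
  if (!length(vary)) return(list(stereo_candidate(fixed)))
  flips <- expand.grid(rep(list(c("R", "S")), length(vary)),
                       stringsAsFactors = FALSE)
  names(flips) <- vary
  lapply(seq_len(nrow(flips)), function(i) {
    stereo_candidate(c(fixed, unlist(flips[i, , drop = FALSE])))
  })
}

#' Evidence items
#'
#' `evidence_relative()` encodes a within-block relative configuration (an
#' R*/S* pattern, e.g. from ROE data or an NMR ranking): a candidate passes
#' if its restriction to the named centers equals the pattern or its global
#' R/S inversion. `evidence_absolute()` encodes one or more accepted absolute
#' patterns (e.g. the ECD verdict on a reporter center): a candidate passes
#' if it matches any accepted pattern exactly on the named centers.
#'
#' @param pattern Named character vector center -> `"R"`/`"S"`.
#' @param source Free-text provenance carried into the trace.
#' @return An object of class `evidence_item`.
#' @export
evidence_relative <- function(pattern, source = "") {
  stopifnot(!is.null(names(pattern)), all(pattern %in% c("R", "S")))
  structure(list(kind = "relative", patterns = list(pattern),
                 source = as.character(source)),
            class = "evidence_item")
}

#' @rdname evidence_relative
#' @param patterns List of named character vectors; a candidate passes if it
#'   matches any of them.
#' @export
evidence_absolute <- function(patterns, source = "") {
  if (!is.list(patterns)) patterns <- list(patterns)
  for (p in patterns)
    stopifnot(!is.null(names(p)), all(p %in% c("R", "S")))
  structure(list(kind = "absolute", patterns = patterns,
                 source = as.character(source)),
            class = "evidence_item")
}

.invert_rs <- function(x) c(R = "S", S = "R")[x] |> stats::setNames(names(x))

.evidence_passes <- function(candidate, item) {
  desc <- candidate$descriptor
  match_one <- function(pattern) {
    centers <- names(pattern)
    if (length(setdiff(centers, names(desc))))
      stop("evidence references undefined center(s): ",
           paste(setdiff(centers, names(desc)), collapse = ", "))
    identical(unname(desc[centers]), unname(pattern))
  }
  if (item$kind == "relative") {
    p <- item$patterns[[1]]
    match_one(p) || match_one(.invert_rs(p))
  } else {
    any(vapply(item$patterns, match_one, logical(1)))
  }
}

#' Filter candidates by a set of evidence items
#'
#' A candidate survives iff it is consistent with every item. Evidence
#' combination has set semantics: the result does not depend on item order,
#' and adding items can only shrink the survivor set. Zero survivors are
#' flagged as contradictory evidence rather than silently dropped.
#'
#' @param candidates List of [stereo_candidate()] objects.
#' @param evidence List of [evidence_item()] objects (see
#'   [evidence_relative()]).
#' @return List of class `evidence_result` with `survivors` (candidates),
#'   `contradictory` (logical), and `trace` (candidate x evidence pass/fail
#'   data frame).
#' @export
combine_evidence <- function(candidates, evidence) {
  stopifnot(length(candidates) >= 1L,
            all(vapply(candidates, inherits, logical(1), "stereo_candidate")),
            all(vapply(evidence, inherits, logical(1), "evidence_item")))
  pass <- matrix(TRUE, nrow = length(candidates), ncol = length(evidence))
  for (j in seq_along(evidence))
    pass[, j] <- vapply(candidates, .evidence_passes, logical(1),
                        evidence[[j]])
  ok <- if (ncol(pass)) apply(pass, 1L, all) else rep(TRUE, length(candidates))
  trace <- data.frame(
    candidate = vapply(candidates, `[[`, character(1), "label"),
    survives = ok
  )
  for (j in seq_along(evidence)) {
    src <- evidence[[j]]$source
    nm <- if (nzchar(src)) src else paste0("evidence_", j)
    trace[[make.names(nm, unique = TRUE)]] <- pass[, j]
  }
  structure(list(survivors = candidates[ok],
                 contradictory = !any(ok),
                 trace = trace),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  if (x$contradictory) {
    cat("<evidence_result> CONTRADICTORY EVIDENCE: no candidate survives\n")
  } else {
    cat("<evidence_result>", length(x$survivors), "survivor(s):",
        paste(vapply(x$survivors, `[[`, character(1), "label"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign a configuration from NMR and region-wise ECD results
#'
#' Translates upstream results into evidence items and filters the candidate
#' set:
#' * the top-ranked NMR pattern (including ties) becomes *relative* evidence
#'   over the centers that vary among candidates — NMR agreement cannot
#'   distinguish a block from its mirror image;
#' * for every block with a reporter region present in the ECD ranking, the
#'   region winners' assignments at that block's varied centers become
#'   *absolute* evidence (accepting any winner's pattern);
#' * extra user evidence (e.g. ROE-derived relative patterns) is appended
#'   as given.
#'
#' When the evidence underdetermines the answer the full ambiguity set is
#' returned; a unique answer is never fabricated.
#'
#' @param blocks List of [block_definition()] objects.
#' @param candidates List of [stereo_candidate()] objects (as produced by
#'   [enumerate_candidates()]).
#' @param nmr_result Optional ranking from [rank_stereoisomers_nmr()]; its
#'   `stereo_label` values must equal the candidates' labels.
#' @param ecd_region_result Optional ranking from [region_ranking()], with
#'   `region` strings of the form `"240-450nm"` matching block reporter
#'   regions.
#' @param extra_evidence Optional list of evidence items to append.
#' @return List of class `assignment_report`: `assigned` (single label or
#'   NA), `ambiguity` (labels of all survivors), `result`
#'   (the [combine_evidence()] output), `evidence` (items used).
#' @export
assign_configuration <- function(blocks, candidates, nmr_result = NULL,
                                 ecd_region_result = NULL,
                                 extra_evidence = list()) {
  .check_blocks(blocks)
  labels <- vapply(candidates, `[[`, character(1), "label")
  by_label <- stats::setNames(candidates, labels)
  # centers that actually differ among candidates
  desc_mat <- do.call(rbind, lapply(candidates, `[[`, "descriptor"))
  varied <- colnames(desc_mat)[apply(desc_mat, 2L,
                                     function(col) length(unique(col)) > 1L)]
  evidence <- list()
  if (!is.null(nmr_result)) {
    top <- nmr_result$stereo_label[nmr_result$rank == 1L]
    missing <- setdiff(top, labels)
    if (length(missing))
      stop("NMR result names unknown candidate(s): ",
           paste(missing, collapse = ", "))
    pats <- lapply(by_label[top], function(cand) cand$descriptor[varied])
    # each top pattern is acceptable as a relative configuration; pool them
    rel_items <- lapply(pats, function(p)
      list(p = p, inv = .invert_rs(p)))
    accepted <- unique(unlist(lapply(rel_items, function(it)
      list(paste(it$p, collapse = ""), paste(it$inv, collapse = ""))),
      use.names = FALSE))
    patterns <- lapply(accepted, function(s) {
      stats::setNames(strsplit(s, "")[[1]], varied)
    })
    evidence <- c(evidence, list(
      evidence_absolute(patterns, source = "nmr_rank_relative")))
  }
  if (!is.null(ecd_region_result)) {
    for (blk in blocks) {
      if (is.null(blk$reporter_region)) next
      region_str <- paste0(blk$reporter_region[1], "-",
                           blk$reporter_region[2], "nm")
      sub <- ecd_region_result[ecd_region_result$region == region_str, ]
      if (!nrow(sub)) next
      winners <- sub$stereo_label[sub$rank == 1L]
      missing <- setdiff(winners, labels)
      if (length(missing))
        stop("ECD result names unknown candidate(s): ",
             paste(missing, collapse = ", "))
      centers <- intersect(blk$centers, varied)
      if (!length(centers)) next
      pats <- unique(lapply(by_label[winners],
                            function(cand) cand$descriptor[centers]))
      evidence <- c(evidence, list(evidence_absolute(
        pats, source = paste0("ecd_", blk$name, "_", region_str))))
    }
  }
  evidence <- c(evidence, extra_evidence)
  res <- combine_evidence(candidates, evidence)
  surv <- vapply(res$survivors, `[[`, character(1), "label")
  structure(list(
    assigned = if (length(surv) == 1L) surv else NA_character_,
    ambiguity = surv,
    result = res,
    evidence = evidence
  ), class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  if (!is.na(x$assigned)) {
    cat("<assignment_report> assigned configuration:", x$assigned, "\n")
  } else if (length(x$ambiguity)) {
    cat("<assignment_report> ambiguous between:",
        paste(x$ambiguity, collapse = ", "), "\n")
  } else {
    cat("<assignment_report> contradictory evidence; no survivor\n")
  }
  invisible(x)
}
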