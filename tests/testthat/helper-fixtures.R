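# Shared in-code fixtures for the test suite.

# kJ/mol gas constant, duplicated here so tests do not reach into internals
R_KJ <- 8.31446e-3

# an ensemble with given relative energies and per-conformer shieldings
make_sigma_ensemble <- function(energies, sigma_list, label = "(19R,24R)") {
  confs <- Map(function(e, s, i) {
    conformer_record(paste0("c", i), e, shieldings = s)
  }, energies, sigma_list, seq_along(energies))
  ensemble(label, unname(confs))
}

# an ensemble whose conformers carry the same transition table
make_transition_ensemble <- function(energies, transitions,
                                     label = "(19R,24R)") {
  confs <- Map(function(e, i) {
    conformer_record(paste0("c", i), e, transitions = transitions)
  }, energies, seq_along(energies))
  ensemble(label, unname(confs))
}

# unit-height Gaussian spectrum with SD sigma_nm centred at centre_nm
gaussian_spectrum <- function(centre_nm, sigma_nm,
                              grid = seq(200, 400, by = 1)) {
  ecd_spectrum(grid, exp(-(grid - centre_nm)^2 / (2 * sigma_nm^2)))
}

# the four-candidate two-block design used throughout
paper_blocks <- function() {
  list(
    block_definition("octahydronaphthalene", c("3", "4", "5", "8", "10"),
                     reporter_region = c(190, 239)),
    block_definition("thiazinone", c("19", "24"),
                     reporter_region = c(240, 450))
  )
}

paper_fixed <- c("3" = "R", "4" = "S", "5" = "R", "8" = "R", "10" = "S")

paper_candidates <- function() {
  enumerate_candidates(paper_blocks(), paper_fixed, vary = c("19", "24"))
}

# a pose set of n copies of `template` translated by the rows of `shifts`
make_poses <- function(template, shifts, scores = NULL, ids = NULL) {
  coords <- lapply(seq_len(nrow(shifts)), function(i)
    sweep(template, 2L, shifts[i, ], `+`))
  pose_set(coords, ids = ids, scores = scores)
}

toy_template <- matrix(c(0, 0, 0,
                         1.5, 0, 0,
                         0, 1.5, 0,
                         0, 0, 1.5), ncol = 3, byrow = TRUE)
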