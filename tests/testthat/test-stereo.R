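test_that("candidate enumeration covers exactly the Cartesian flips", {
  cands <- paper_candidates()
  expect_length(cands, 4L)
  labels <- vapply(cands, `[[`, character(1), "label")
  expect_setequal(labels, c("(3R,4S,5R,8R,10S,19R,24R)",
                            "(3R,4S,5R,8R,10S,19R,24S)",
                            "(3R,4S,5R,8R,10S,19S,24R)",
                            "(3R,4S,5R,8R,10S,19S,24S)"))
  one <- enumerate_candidates(paper_blocks(),
                              c(paper_fixed, "19" = "R", "24" = "R"))
  expect_length(one, 1L)
  two <- enumerate_candidates(paper_blocks(),
                              c(paper_fixed, "24" = "R"), vary = "19")
  expect_length(two, 2L)
  expect_error(enumerate_candidates(paper_blocks(),
                                    c(paper_fixed, "19" = "R"),
                                    vary = c("19", "24")),
               "both fixed and varying")
  expect_error(enumerate_candidates(paper_blocks(), paper_fixed,
                                    vary = "19"),
               "neither fixed nor varying")
  expect_error(enumerate_candidates(paper_blocks(), paper_fixed,
                                    vary = c("19", "24", "99")), "99")
})

test_that("evidence filtering reproduces the published assignments", {
  cands <- paper_candidates()
  # compound 1: ROE says cis-(19R*,24R*); ECD above 240 nm accepts 19R
  res1 <- combine_evidence(cands, list(
    evidence_relative(c("19" = "R", "24" = "R"), source = "roe_cis"),
    evidence_absolute(list(c("19" = "R")), source = "ecd_above240")
  ))
  expect_false(res1$contradictory)
  expect_length(res1$survivors, 1L)
  expect_equal(res1$survivors[[1]]$label, "(3R,4S,5R,8R,10S,19R,24R)")

  # compound 2: ECD accepts 19S; ROE gives the trans pattern
  res2 <- combine_evidence(cands, list(
    evidence_absolute(list(c("19" = "S")), source = "ecd_above260"),
    evidence_relative(c("19" = "S", "24" = "R"), source = "roe_trans")
  ))
  expect_length(res2$survivors, 1L)
  expect_equal(res2$survivors[[1]]$label, "(3R,4S,5R,8R,10S,19S,24R)")

  # mutually exclusive items flag a contradiction instead of fabricating
  res3 <- combine_evidence(cands, list(
    evidence_absolute(list(c("19" = "R"))),
    evidence_absolute(list(c("19" = "S")))
  ))
  expect_true(res3$contradictory)
  expect_length(res3$survivors, 0L)
})

test_that("evidence combination is order-independent and monotone", {
  cands <- paper_candidates()
  items <- list(
    evidence_relative(c("19" = "R", "24" = "R")),
    evidence_absolute(list(c("19" = "R"), c("19" = "S", "24" = "S"))),
    evidence_relative(c("19" = "S", "24" = "S"))
  )
  lab <- function(res) vapply(res$survivors, `[[`, character(1), "label")
  set.seed(8)
  base <- lab(combine_evidence(cands, items))
  for (i in 1:5)
    expect_setequal(lab(combine_evidence(cands, sample(items))), base)
  # adding evidence never enlarges the survivor set
  for (k in seq_along(items)) {
    sub <- lab(combine_evidence(cands, items[seq_len(k)]))
    if (k > 1)
      expect_true(all(sub %in% lab(combine_evidence(cands,
                                                    items[seq_len(k - 1)]))))
  }
})

test_that("relative evidence is invariant under global block inversion", {
  cands <- paper_candidates()
  lab <- function(res) vapply(res$survivors, `[[`, character(1), "label")
  a <- combine_evidence(cands,
                        list(evidence_relative(c("19" = "R", "24" = "S"))))
  b <- combine_evidence(cands,
                        list(evidence_relative(c("19" = "S", "24" = "R"))))
  expect_setequal(lab(a), lab(b))
  expect_setequal(lab(a), c("(3R,4S,5R,8R,10S,19R,24S)",
                            "(3R,4S,5R,8R,10S,19S,24R)"))
})

test_that("assign_configuration mirrors the two-stage published narrative", {
  blocks <- paper_blocks()
  cands <- paper_candidates()
  meoh <- builtin_correction("meoh")

  # NMR alone (relative mode): a two-candidate ambiguity, like compound 1
  simn <- gen_nmr_ensembles(55, mode = "relative")
  rk <- rank_stereoisomers_nmr(simn$ensembles, simn$observed, meoh)
  nmr_only <- assign_configuration(blocks, cands, nmr_result = rk)
  expect_true(is.na(nmr_only$assigned))
  expect_setequal(nmr_only$ambiguity, simn$truth$relative_class)

  # adding the region-wise ECD verdict pins the answer uniquely
  sime <- gen_ecd_ensembles(55)
  spectra <- lapply(sime$ensembles, ensemble_ecd_spectrum)
  rr <- region_ranking(spectra, sime$exp_spectrum,
                       list(c(240, 450), c(190, 239)))
  full <- assign_configuration(blocks, cands, nmr_result = rk,
                               ecd_region_result = rr)
  expect_equal(full$assigned, sime$truth$true_label)

  # compound-3 style: trans relative pattern + ECD 19S -> (19S,24R)
  res3 <- assign_configuration(
    blocks, cands,
    extra_evidence = list(
      evidence_relative(c("19" = "S", "24" = "R"), source = "nmr_trans"),
      evidence_absolute(list(c("19" = "S")), source = "ecd")))
  expect_equal(res3$assigned, "(3R,4S,5R,8R,10S,19S,24R)")

  # a single candidate with no evidence passes through unchanged
  solo <- assign_configuration(blocks, cands[1])
  expect_equal(solo$assigned, cands[[1]]$label)
})
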