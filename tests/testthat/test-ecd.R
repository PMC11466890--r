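test_that("stick broadening is linear, signed, and peak-faithful", {
  cfg <- broadening_config()
  zero <- broaden_sticks(data.frame(wavelength_nm = numeric(),
                                    R_vel = numeric()), cfg)
  expect_true(all(zero$delta_epsilon == 0))

  set.seed(6)
  A <- data.frame(wavelength_nm = runif(3, 210, 260), R_vel = rnorm(3, 0, 20))
  B <- data.frame(wavelength_nm = runif(4, 260, 390), R_vel = rnorm(4, 0, 20))
  sAB <- broaden_sticks(rbind(A, B), cfg)
  sA <- broaden_sticks(A, cfg)
  sB <- broaden_sticks(B, cfg)
  expect_equal(sAB$delta_epsilon, sA$delta_epsilon + sB$delta_epsilon,
               tolerance = 1e-12)
  # negating every rotational strength negates the curve
  negA <- A; negA$R_vel <- -negA$R_vel
  expect_equal(broaden_sticks(negA, cfg)$delta_epsilon, -sA$delta_epsilon)

  # single band: peak at the transition wavelength (within one grid step)
  # and height equal to direct evaluation of the Gaussian-sum formula
  single <- data.frame(wavelength_nm = 300, R_vel = 10)
  sp <- broaden_sticks(single, cfg)
  peak_at <- sp$wavelength_nm[which.max(sp$delta_epsilon)]
  expect_lte(abs(peak_at - 300), 1)
  sigma <- 3000 / (2 * sqrt(log(2)))   # FWHM -> 1/e half-width
  expect_equal(max(sp$delta_epsilon),
               (1e7 / 300) * 10 / (22.97 * sqrt(pi) * sigma),
               tolerance = 1e-10)
  for (wl in c(231.4, 287.9, 355.2)) {
    s1 <- broaden_sticks(data.frame(wavelength_nm = wl, R_vel = 5), cfg)
    pk <- s1$wavelength_nm[which.max(s1$delta_epsilon)]
    expect_lte(abs(pk - wl), 1)
  }
})

test_that("band area scales linearly with rotational strength", {
  cfg <- broadening_config(grid_nm = seq(180, 450, by = 0.5))
  area <- vapply(c(1, 2, 5), function(R) {
    sp <- broaden_sticks(data.frame(wavelength_nm = 300, R_vel = R), cfg)
    nu <- 1e7 / sp$wavelength_nm
    # integrate over wavenumber (trapezoid); sign-preserving
    sum(diff(rev(nu)) * (rev(sp$delta_epsilon)[-1] +
                           rev(sp$delta_epsilon)[-length(nu)]) / 2)
  }, numeric(1))
  expect_equal(area[2] / area[1], 2, tolerance = 1e-6)
  expect_equal(area[3] / area[1], 5, tolerance = 1e-6)
})

test_that("the width convention switch changes the exponent width", {
  tr <- data.frame(wavelength_nm = 300, R_vel = 10)
  fwhm <- broaden_sticks(tr, broadening_config(3000, "half-height"))
  one_e <- broaden_sticks(tr, broadening_config(3000 / (2 * sqrt(log(2))),
                                                "1/e"))
  expect_equal(fwhm$delta_epsilon, one_e$delta_epsilon, tolerance = 1e-12)
})

test_that("population weighting of spectra is a pointwise convex sum", {
  g <- seq(200, 400, 1)
  s1 <- ecd_spectrum(g, sin(g / 30))
  s2 <- ecd_spectrum(g, cos(g / 45))
  expect_equal(weight_and_sum_spectra(list(s1), 1)$delta_epsilon,
               s1$delta_epsilon)
  expect_equal(weight_and_sum_spectra(list(s1, s1),
                                      c(0.3, 0.7))$delta_epsilon,
               s1$delta_epsilon)
  mix <- weight_and_sum_spectra(list(s1, s2), c(0.25, 0.75))
  expect_equal(mix$delta_epsilon,
               0.25 * s1$delta_epsilon + 0.75 * s2$delta_epsilon)
  expect_error(weight_and_sum_spectra(list(s1, s2), c(0.5, 0.4)), "sum to 1")
  s3 <- ecd_spectrum(seq(210, 410, 1), sin(seq(210, 410, 1)))
  expect_error(weight_and_sum_spectra(list(s1, s3), c(0.5, 0.5)),
               "common wavelength grid")
})

test_that("cosine similarity hits its closed forms", {
  g <- seq(200, 400, 1)
  a <- gaussian_spectrum(280, 10, g)
  self <- similarity_score(a, a)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$best_shift_nm, 0)
  expect_equal(self$best_scale, 1, tolerance = 1e-12)
  expect_equal(similarity_score(a, enantiomer_spectrum(a))$score, -1,
               tolerance = 1e-12)
  # two unit Gaussians offset by 3 sigma: overlap cosine exp(-9/4)
  b <- gaussian_spectrum(310, 10, g)
  expect_equal(similarity_score(a, b)$score, exp(-9 / 4), tolerance = 0.01)
  expect_error(similarity_score(a, gaussian_spectrum(500, 5,
                                                     seq(480, 520, 1))),
               "overlap|grid points")
})

test_that("the shift scan finds a planted rigid wavelength offset", {
  g <- seq(200, 400, 1)
  a <- gaussian_spectrum(280, 12, g)
  shifted <- gaussian_spectrum(287, 12, g)  # calc red-shifted by 7 nm
  res <- similarity_score(a, shifted, shift_scan = 10)
  expect_equal(res$best_shift_nm, 7)
  expect_equal(res$score, 1, tolerance = 1e-6)
})

test_that("enantiomer spectra mirror exactly at the ensemble level", {
  expect_equal(
    enantiomer_spectrum(enantiomer_spectrum(gaussian_spectrum(300, 9))),
    gaussian_spectrum(300, 9))
  z <- ecd_spectrum(seq(200, 210, 1), rep(0, 11))
  expect_equal(enantiomer_spectrum(z), z)

  set.seed(14)
  cfg <- broadening_config()
  tr <- data.frame(wavelength_nm = runif(5, 210, 380),
                   R_vel = rnorm(5, 0, 15))
  ens <- make_transition_ensemble(c(0, 3, 6), tr)
  neg_tr <- tr; neg_tr$R_vel <- -neg_tr$R_vel
  ens_neg <- make_transition_ensemble(c(0, 3, 6), neg_tr)
  expect_equal(ensemble_ecd_spectrum(ens_neg, cfg)$delta_epsilon,
               -ensemble_ecd_spectrum(ens, cfg)$delta_epsilon)
})

test_that("region ranking separates an epimer pair only in its reporter region", {
  sim <- gen_ecd_ensembles(29, exp_noise_sd = 0)
  spectra <- lapply(sim$ensembles, ensemble_ecd_spectrum)
  rr <- region_ranking(spectra, sim$exp_spectrum,
                       list(sim$truth$reporter_region,
                            sim$truth$other_region))
  rep_rows <- rr[rr$region == paste0(sim$truth$reporter_region[1], "-",
                                     sim$truth$reporter_region[2], "nm"), ]
  oth_rows <- rr[rr$region == paste0(sim$truth$other_region[1], "-",
                                     sim$truth$other_region[2], "nm"), ]
  flipped <- names(sim$truth$reporter_flipped)[sim$truth$reporter_flipped]
  matched <- setdiff(names(sim$ensembles), flipped)
  # reporter region: the 19-epimers mirror the band and rank last
  expect_true(all(rep_rows$rank[rep_rows$stereo_label %in% matched] == 1L))
  expect_true(all(rep_rows$score[rep_rows$stereo_label %in% flipped] < 0))
  # below the boundary every candidate reproduces the curve: one big tie
  expect_true(all(oth_rows$rank == 1L))
  expect_true(all(oth_rows$score > 0.95))
})

test_that("degenerate region rankings reduce to plain similarity", {
  g <- seq(200, 400, 1)
  truth <- gaussian_spectrum(300, 15, g)
  cands <- list(
    "(19R,24R)" = truth,
    "(19S,24S)" = enantiomer_spectrum(truth),
    "(19R,24S)" = gaussian_spectrum(320, 15, g)
  )
  rr <- region_ranking(cands, truth, list(c(200, 400)), tie_tol = 1e-9)
  expect_equal(rr$stereo_label[rr$rank == 1L], "(19R,24R)")
  expect_equal(rr$score[1], 1, tolerance = 1e-12)
  scores <- vapply(cands, function(sp)
    similarity_score(sp, truth)$score, numeric(1))
  expect_equal(rr$score, unname(sort(scores, decreasing = TRUE)),
               tolerance = 1e-12)
  expect_equal(rr$stereo_label[nrow(rr)], "(19S,24S)")
})
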