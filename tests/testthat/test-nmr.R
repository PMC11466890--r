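test_that("the shielding-shift correction inverts exactly", {
  meoh <- builtin_correction("meoh")
  dmso <- builtin_correction("dmso")
  expect_equal(shielding_to_shift(185.6277, meoh), 0)
  # (100 - 185.6277) / (-1.0175) by hand
  expect_equal(shielding_to_shift(100, meoh), 84.1550, tolerance = 1e-3 / 84)
  for (corr in list(meoh, dmso)) {
    delta <- c(0, 14.1, 71.2, 122.5, 196.6)
    expect_equal(shielding_to_shift(shift_to_shielding(delta, corr), corr),
                 delta, tolerance = 1e-10)
  }
  expect_error(shift_correction(100, 0), "non-zero")
})

test_that("ensemble shift averaging is population-weighted and affine-safe", {
  meoh <- builtin_correction("meoh")
  one <- make_sigma_ensemble(0, list(c("C-1" = 100, "C-2" = 50)))
  expect_equal(ensemble_average_shifts(one, meoh)$delta_ppm,
               shielding_to_shift(c(100, 50), meoh))
  # equal populations average the shieldings
  two <- make_sigma_ensemble(c(0, 0), list(c("C-1" = 100), c("C-1" = 102)))
  expect_equal(ensemble_average_shifts(two, meoh)$delta_ppm,
               shielding_to_shift(101, meoh))
  # a conformer with (numerically) zero population is ignored
  far <- make_sigma_ensemble(c(0, 500), list(c("C-1" = 100),
                                             c("C-1" = 900)))
  expect_equal(ensemble_average_shifts(far, meoh)$delta_ppm,
               shielding_to_shift(100, meoh), tolerance = 1e-12)
  # averaging shieldings then converting == converting then averaging
  set.seed(21)
  sig <- replicate(5, stats::setNames(runif(6, 20, 180),
                                      paste0("C-", 1:6)),
                   simplify = FALSE)
  ens <- make_sigma_ensemble(runif(5, 0, 10), sig)
  p <- unname(ensemble_populations(ens))
  per_conf <- vapply(sig, function(s)
    shielding_to_shift(s[paste0("C-", 1:6)], meoh), numeric(6))
  expect_equal(ensemble_average_shifts(ens, meoh)$delta_ppm,
               unname(as.numeric(per_conf %*% p)), tolerance = 1e-10)
})

test_that("error statistics match hand arithmetic and absorb offsets", {
  obs <- shift_table(paste0("C-", 1:5), c(10, 50, 100, 150, 196))
  same <- shift_error_stats(obs, obs)
  expect_equal(same$mae, 0)
  expect_equal(same$rmsd, 0)
  expect_equal(same$max_abs_dev, 0)
  expect_equal(same$slope, 1)

  shifted <- shift_table(paste0("C-", 1:5), obs$delta_ppm + 1)
  st <- shift_error_stats(shifted, obs)
  expect_equal(st$mae, 1)
  expect_equal(st$cmae, 0, tolerance = 1e-12)

  # three-point hand oracle: errors -1, 0, +2
  pred <- shift_table(paste0("C-", 1:3), c(9, 50, 102))
  obs3 <- shift_table(paste0("C-", 1:3), c(10, 50, 100))
  st3 <- shift_error_stats(pred, obs3)
  expect_equal(st3$mae, 1)
  expect_equal(st3$rmsd, sqrt(5 / 3))
  expect_equal(st3$max_abs_dev, 2)

  expect_error(shift_error_stats(shift_table("C-1", 10),
                                 shift_table("C-1", 10)), "at least 2")
})

test_that("linear re-fitting reduces error under systematic distortion", {
  set.seed(77)
  for (i in 1:20) {
    obs <- shift_table(paste0("C-", 1:20), runif(20, 5, 200))
    slope <- runif(1, 0.9, 1.1)
    pred <- shift_table(paste0("C-", 1:20),
                        slope * obs$delta_ppm + runif(1, -5, 5) +
                          rnorm(20, 0, 0.3))
    st <- shift_error_stats(pred, obs)
    expect_lte(st$cmae, st$mae)
  }
})

test_that("fit_correction recovers a planted line", {
  delta <- seq(5, 200, length.out = 40)
  sigma_exact <- 185.6277 - 1.0175 * delta
  fit0 <- fit_correction(sigma_exact, delta)
  expect_equal(fit0$intercept, 185.6277, tolerance = 1e-9 / 186)
  expect_equal(fit0$slope, -1.0175, tolerance = 1e-9)
  expect_gt(attr(fit0, "r_squared"), 0.999999)

  set.seed(123)
  fit1 <- fit_correction(sigma_exact + rnorm(40, 0, 0.5), delta)
  expect_lt(abs(fit1$intercept - 185.6277), 1)
  expect_lt(abs(fit1$slope - (-1.0175)), 0.02)

  expect_error(fit_correction(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_correction(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("stereoisomer ranking finds the generating isomer and flags ties", {
  meoh <- builtin_correction("meoh")
  # noise-free: the generating isomer scores an exact zero
  sim <- gen_nmr_ensembles(101, noise_sd = 0)
  r <- rank_stereoisomers_nmr(sim$ensembles, sim$observed, meoh)
  expect_equal(r$stereo_label[1], sim$truth$true_label)
  expect_equal(r$mae[1], 0, tolerance = 1e-9)

  # duplicate candidates are reported as tied, not silently ordered
  dup <- sim$ensembles[[1]]
  dup2 <- dup; dup2$stereo_label <- "(copy)"
  rdup <- rank_stereoisomers_nmr(list(dup, dup2), sim$observed, meoh)
  expect_true(all(rdup$tied))
  expect_equal(rdup$rank, c(1L, 1L))

  # planted +-2 ppm perturbation on one of two candidates
  obs <- shift_table(paste0("C-", 1:10), seq(20, 180, length.out = 10))
  sig_true <- shift_to_shielding(obs$delta_ppm, meoh)
  names(sig_true) <- obs$label
  sig_bad <- sig_true + shift_to_shielding(c(rep(2, 3), rep(0, 7)), meoh) -
    shift_to_shielding(rep(0, 10), meoh)
  e1 <- make_sigma_ensemble(0, list(sig_true), label = "good")
  e2 <- make_sigma_ensemble(0, list(sig_bad), label = "bad")
  r2 <- rank_stereoisomers_nmr(list(e2, e1), obs, meoh)
  expect_equal(r2$stereo_label[1], "good")
})

test_that("shift differences between tables are signed per label", {
  a <- shift_table(c("C-1", "C-2"), c(10, 20))
  expect_equal(shift_difference_table(a, a)$difference, c(0, 0))
  b <- shift_table(c("C-2", "C-3"), c(15, 99))
  d <- shift_difference_table(a, b)
  expect_equal(d$label, "C-2")
  expect_equal(d$difference, 5)
  expect_error(shift_difference_table(a, shift_table("C-9", 1)),
               "no labels")
})

test_that("swap-tolerant scoring forgives diastereotopic a/b exchanges", {
  obs <- shift_table(c("H-25a", "H-25b", "H-6a", "H-6b"),
                     c(3.08, 3.05, 1.75, 0.68))
  swapped <- shift_table(c("H-25a", "H-25b", "H-6a", "H-6b"),
                         c(3.05, 3.08, 1.75, 0.68))
  strict <- shift_error_stats(swapped, obs, nucleus = "1H")
  expect_equal(strict$mae, 0.015)
  lenient <- shift_error_stats(swapped, obs, nucleus = "1H",
                               swap_tolerant = TRUE)
  expect_equal(lenient$mae, 0)
  # non-paired labels are never swapped
  solo <- shift_table(c("H-24", "H-13"), c(3.44, 5.03))
  solo_off <- shift_table(c("H-24", "H-13"), c(5.03, 3.44))
  st <- shift_error_stats(solo_off, solo, nucleus = "1H",
                          swap_tolerant = TRUE)
  expect_gt(st$mae, 1)
})
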