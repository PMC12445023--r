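test_that("dilution ladders enumerate constant-ratio doses above the floor", {
  # 100 uM top, 1:3 ratio, 5 nM floor: the standard 10-dose plate
  lad <- build_dilution_ladder(100e3, 3, 5)
  expect_length(lad, 10)
  expect_equal(max(lad), 100e3)
  expect_true(all(lad >= 5))
  expect_true(all(abs(diff(log(lad)) - log(3)) < 1e-9))

  expect_identical(build_dilution_ladder(5, 3, 5), 5)
  expect_equal(build_dilution_ladder(1000, 10, 1), c(1, 10, 100, 1000))
  expect_error(build_dilution_ladder(1, 3, 5), class = "invalid_ladder")
})

test_that("4PL fits recover generating parameters", {
  doses <- build_dilution_ladder(100e3, 3, 5)
  clean <- generate_plate(true_ic50 = 50, hill = 1.5, top = 1, bottom = 0,
                          doses = doses, n_replicates = 1, noise_sd = 0)
  fit <- fit_4pl(clean)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 50) / 50, 0.01)
  expect_lt(abs(fit$hill - 1.5), 0.05)

  noisy <- generate_plate(true_ic50 = 50, hill = 1.5, doses = doses,
                          n_replicates = 3, noise_sd = 0.05, seed = 21)
  fitn <- fit_4pl(noisy)
  expect_true(fitn$converged)
  expect_lt(abs(fitn$ic50 - 50) / 50, 0.15)

  flat <- plate_assay(doses, matrix(1, 2, length(doses)))
  expect_warning(ff <- fit_4pl(flat), class = "no_inhibition")
  expect_false(ff$converged)
  expect_equal(ff$ic50, max(doses) * 10)
})

test_that("normalized AUC integrates mean viability over log dose", {
  doses <- 10^(0:4)
  expect_equal(compute_auc(doses, rep(1, 5)), 1)
  expect_equal(compute_auc(doses, rep(0, 5)), 0)
  # linear decline in log10 dose from 1 to 0: exact trapezoid gives 1/2
  expect_equal(compute_auc(doses, seq(1, 0, length.out = 5)), 0.5)
  expect_error(compute_auc(10, 1), class = "invalid_plate")
  # bounded by the viability range
  v <- c(0.9, 0.4, 0.7, 0.2, 0.55)
  auc <- compute_auc(doses, v)
  expect_true(auc >= min(v) && auc <= max(v))
})

test_that("AUC z-scores have mean 0 and sample SD 1 and resist affine shifts", {
  z <- zscore_auc(c(a = 1, b = 2, c = 3))
  expect_equal(unname(z), c(-1, 0, 1))
  x <- c(m1 = 0.3, m2 = 0.8, m3 = 0.45, m4 = 0.66)
  zx <- zscore_auc(x)
  expect_lt(abs(mean(zx)), 1e-9)
  expect_lt(abs(stats::sd(zx) - 1), 1e-9)
  expect_equal(zscore_auc(2.5 * x + 0.1), zx)
  expect_error(zscore_auc(c(a = 1, b = 1, c = 1)), class = "degenerate_panel")
})

test_that("therapeutic window is the healthy/tumor mean AUC ratio", {
  expect_equal(therapeutic_window(c(0.7, 0.9), c(0.3, 0.5)), 2)
  expect_equal(therapeutic_window(0.5, 0.5), 1)
  expect_error(therapeutic_window(0.5, c(0, 0)), class = "zero_tumor_auc")
})

test_that("Bliss excess measures departure from independence", {
  inh <- matrix(0, 4, 4)
  inh[, 1] <- c(0, 0.5, 0.5, 0.5); inh[1, ] <- c(0, 0.5, 0.5, 0.5)
  inh[2:4, 2:4] <- 0.75
  b <- bliss_synergy(inh)
  expect_equal(b$score, 0)
  expect_true(all(b$bliss_excess[1, ] == 0) && all(b$bliss_excess[, 1] == 0))

  inh[2, 2] <- 0.9
  b2 <- bliss_synergy(inh)
  expect_equal(b2$bliss_excess[2, 2], 0.15)

  expect_warning(bliss_synergy(matrix(1.2, 4, 4)), class = "out_of_range")
})

test_that("morphometry and growth formulas match their definitions", {
  expect_equal(wound_closure(100, 40), 60)
  expect_equal(wound_closure(100, 100), 0)
  expect_equal(wound_closure(100, 0), 100)
  expect_error(wound_closure(0, 1), class = "invalid_measurement")

  expect_equal(circularity_index(pi, 2 * pi), 1)          # unit circle
  expect_equal(circularity_index(1, 4), pi / 4)           # unit square
  rect <- circularity_index(10, 22)                       # 10 x 1 rectangle
  expect_equal(rect, 40 * pi / 484)
  expect_lt(rect, pi / 4)                                 # elongation lowers CI

  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(2, 2), 4)
  expect_warning(tv <- tumor_volume(5, 10), class = "axis_swap")
  expect_equal(tv, 125)
  expect_error(tumor_volume(-1, 1), class = "invalid_measurement")

  expect_equal(positive_fraction(30, 100), 0.3)
  expect_equal(positive_fraction(0, 50), 0)
  expect_equal(positive_fraction(50, 50), 1)
  expect_error(positive_fraction(51, 50), class = "invalid_counts")
})
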