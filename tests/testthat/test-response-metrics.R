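curve_of <- function(viability, conc = 10^seq(-4, 4)[seq_along(viability)]) {
  twinscreen:::new_dose_response_curve(conc, viability)
}

test_that("viability score is the control-normalized signed difference", {
  expect_identical(viability_score(1, 1, 1, 1, 0.5), 1)
  # positive readout halved: S = 0, rho = 0
  expect_identical(viability_score(0.5, 1, 1, 1, 0.5), 0)
  # negative readout doubled: clipped at exactly 0
  expect_identical(viability_score(1, 2, 1, 1, 0.5), 0)
  expect_error(viability_score(1, 1, 1, 1, 1), class = "config_error")
  expect_error(viability_score(1, 1, 0, 1, 0.5), class = "invalid_control")
})

test_that("Emax and the 50 percent effectiveness cutoff are inclusive", {
  flat <- curve_of(rep(1, 5))
  e <- compute_emax(flat)
  expect_identical(e$Emax, 0)
  expect_false(e$effective)

  e70 <- compute_emax(curve_of(c(1, 0.8, 0.3, 0.4)))
  expect_equal(e70$Emax, 70)
  expect_true(e70$effective)

  e50 <- compute_emax(curve_of(c(1, 0.5)))
  expect_equal(e50$Emax, 50)
  expect_true(e50$effective)       # boundary is inclusive
})

test_that("EC50 interpolation inverts a sampled binding curve", {
  conc <- 10^seq(-4, 4)
  K <- 10
  curve <- curve_of(1 / (1 + conc / K), conc)
  emax <- compute_emax(curve)$Emax
  ec50 <- compute_ec50(curve, emax)
  # closed-form oracle: I(C) = emax/200 at C = K * t/(1-t), t = emax/200
  t <- emax / 200
  oracle <- K * t / (1 - t)
  expect_lt(abs(ec50 - oracle) / oracle, 0.05)
  expect_lt(abs(ec50 - K) / K, 0.05)

  expect_true(is.na(compute_ec50(curve_of(rep(1, 5)), 0)))

  # step curve crossing exactly at a grid point
  step <- curve_of(c(1, 1, 0.5, 0, 0), 10^(0:4))
  em <- compute_emax(step)$Emax   # 100
  expect_identical(compute_ec50(step, em), 100)

  # consistency: interpolated inhibition at EC50 equals emax/200
  i_interp <- stats::approx(log10(curve$concentrations), 1 - curve$viability,
                            xout = log10(ec50))$y
  expect_lt(abs(i_interp - emax / 200), 1e-9)
})

test_that("GR value follows the per-division closed form", {
  expect_identical(gr_value(1, 1), 1)
  expect_identical(gr_value(0.5, 1), 0)
  expect_identical(gr_value(0, 1), -1)
  expect_equal(gr_value(0.25, 2), 0)
  expect_equal(gr_value(0.75, 1), 0.5)
  # affine form at one division
  rho <- seq(0, 1, by = 0.05)
  expect_equal(gr_value(rho, 1), 2 * rho - 1)
  # strictly increasing in rho, bounded in [-1, 1]
  for (nd in c(1, 2, 3)) {
    g <- gr_value(rho, nd)
    expect_true(all(diff(g) > 0))
    expect_true(all(g >= -1 & g <= 1))
  }
})

test_that("GR50/GRmax summarize curves and invert a sampled binding curve", {
  flat <- curve_of(rep(1, 5))
  g <- gr_metrics(flat, 1)
  expect_identical(g$GRmax, 1)
  expect_true(is.na(g$GR50))

  dead <- curve_of(c(1, 0.5, 0))
  expect_identical(gr_metrics(dead, 1)$GRmax, -1)

  conc <- 10^seq(-4, 4)
  K <- 10
  curve <- curve_of(1 / (1 + conc / K), conc)
  gr50 <- gr_metrics(curve, 1)$GR50
  # closed-form oracle: GR = 0.5 at rho = 0.75, i.e. C = K/3
  expect_lt(abs(log10(gr50) - log10(K / 3)), 1)
})

test_that("drug ranking orders by tumor-minus-normal selectivity", {
  res <- rbind(
    data.frame(sample_id = c("t1", "t2", "n1"), tissue = c("tumor", "tumor", "normal"),
               drug = "selective", emax_pct = c(80, 80, 5), ec50_nM = 1,
               gr50_nM = 1, grmax = 0, effective = TRUE),
    data.frame(sample_id = c("t1", "t2", "n1"), tissue = c("tumor", "tumor", "normal"),
               drug = "broad", emax_pct = c(80, 80, 80), ec50_nM = 1,
               gr50_nM = 1, grmax = 0, effective = TRUE))
  rk <- rank_drugs(res)
  expect_identical(rk$drug, c("selective", "broad"))
  expect_equal(rk$selectivity, c(75, 0))

  # identical drugs: tie broken lexicographically
  res$emax_pct <- 50
  rk2 <- rank_drugs(res)
  expect_identical(rk2$drug, c("broad", "selective"))

  # invariant to row order
  rk3 <- rank_drugs(res[sample.int(nrow(res)), ])
  expect_identical(rk2, rk3)

  expect_error(rank_drugs(res[res$tissue == "tumor", ]), class = "no_contrast")
})
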