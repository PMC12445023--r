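test_that("normalization is CPM + log2(x+1) and scale invariant", {
  counts <- matrix(c(1000, 999000,
                     2000, 1998000), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_expression(counts)
  expect_equal(norm["g1", "s1"], log2(1001))
  # proportional libraries normalize identically
  expect_equal(norm[, "s1"], norm[, "s2"])
  # absent gene stays at 0
  counts2 <- rbind(counts, g3 = c(0, 0))
  expect_equal(unname(normalize_expression(counts2)["g3", ]), c(0, 0))
  expect_error(normalize_expression(cbind(counts, s3 = c(0, 0))),
               class = "empty_library")
})

test_that("individualization is the clipped linear-scale expression ratio", {
  m <- build_reference_network()
  genes <- unname(gene_representatives(m))
  ref <- stats::setNames(rep(log2(1001), length(genes)), genes)

  prof_eq <- patient_profile("p1", "tumor", expression = ref)
  tw <- individualize(m, prof_eq, ref)
  expect_true(all(abs(tw$synthesis_scale - 1) < 1e-12))
  expect_true(all(names(gene_representatives(m)) %in% names(tw$synthesis_scale)))

  # doubled linear expression at a high baseline gives a scale of ~2
  expr2 <- stats::setNames(log2(2 * 1000 + 1), genes[1])
  prof2 <- patient_profile("p2", "tumor",
                           expression = c(expr2, ref[genes[-1]]))
  tw2 <- individualize(m, prof2, ref)
  sid <- names(gene_representatives(m))[match(genes[1], unname(gene_representatives(m)))]
  expect_equal(unname(tw2$synthesis_scale[sid]), (2000 + 0.5) / (1000.5), tolerance = 1e-9)
  expect_lt(abs(tw2$synthesis_scale[sid] - 2), 0.01)

  # 100x expression clips at 10
  expr100 <- stats::setNames(log2(100 * 1000 + 1), genes[1])
  tw100 <- individualize(m, patient_profile("p3", "tumor",
                                            expression = c(expr100, ref[genes[-1]])),
                         ref)
  expect_identical(unname(tw100$synthesis_scale[sid]), 10)

  # missing gene: warning, scale 1
  expect_warning(
    tw_miss <- individualize(m, patient_profile("p4", "tumor",
                                                expression = ref[genes[-1]]),
                             ref),
    class = "missing_gene")
  expect_identical(unname(tw_miss$synthesis_scale[sid]), 1)

  expect_error(individualize(m, structure(list(sample_id = "p5",
                                               expression = numeric()),
                                          class = "PatientProfile"), ref),
               class = "no_expression")
})

test_that("synthesis scale is monotone in expression and always in bounds", {
  m <- build_reference_network()
  genes <- unname(gene_representatives(m))
  ref <- stats::setNames(rep(5, length(genes)), genes)
  sid <- names(gene_representatives(m))[1]
  g <- unname(gene_representatives(m))[1]
  last <- -Inf
  for (e in seq(0, 14, by = 0.5)) {
    expr <- ref; expr[g] <- e
    tw <- individualize(m, patient_profile("p", "tumor", expression = expr), ref)
    s <- unname(tw$synthesis_scale[sid])
    expect_gte(s + 1e-12, last)
    expect_true(s >= 0.1 && s <= 10)
    last <- s
  }
  # pure function: identical inputs give identical twins
  p <- patient_profile("p", "tumor", expression = ref)
  expect_identical(individualize(m, p, ref)$synthesis_scale,
                   individualize(m, p, ref)$synthesis_scale)
})

test_that("activation policy and clamping behave as specified", {
  m <- build_reference_network()
  # CTNNB1-mutant tumor -> 1.0; other tumor -> 0.6; normal -> 0.2
  mk <- function(tissue, mut) patient_profile("p", tissue,
                                              expression = c(MYC = 1),
                                              mutations = c(CTNNB1 = mut))
  expect_equal(default_activation(mk("tumor", TRUE), m)[["CTNNB1"]], 1.0)
  expect_equal(default_activation(mk("tumor", FALSE), m)[["CTNNB1"]], 0.6)
  expect_equal(default_activation(mk("normal", FALSE), m)[["CTNNB1"]], 0.2)

  tw <- as_twin(m, activation = c(CTNNB1 = 0.5, GF = 0.5))
  tw0 <- apply_activation(tw, "CTNNB1", 0)
  ss <- solve_steady_state(tw0)
  # Wnt input clamped at zero: no TCF/LEF activation above basal
  expect_equal(ss$concentrations[["CTNNB1"]], 0)
  expect_lt(ss$concentrations[["TCF_LEF_act"]], 1e-8)

  # idempotent
  t1 <- apply_activation(tw, "CTNNB1", 0.5)
  t2 <- apply_activation(t1, "CTNNB1", 0.5)
  expect_identical(t1, t2)
  expect_error(apply_activation(tw, "NOT_AN_INPUT", 1), class = "unknown_input")
})

test_that("cohort twins carry tissue provenance and tumor-specific scales", {
  fx <- default_fixture()
  expect_length(fx$twins, 21)
  tw_t <- fx$twins[["T01"]]; tw_n <- fx$twins[["N01"]]
  expect_identical(tw_t$provenance$tissue, "tumor")
  expect_identical(tw_n$provenance$tissue, "normal")
  # signature gene MYCN strongly upscaled in tumors only
  expect_gt(tw_t$synthesis_scale[["MYCN_pool"]], 2)
  expect_lt(tw_n$synthesis_scale[["MYCN_pool"]], 2)
  expect_equal(tw_t$activation[["CTNNB1"]], 1.0)
  expect_equal(tw_n$activation[["CTNNB1"]], 0.2)
})
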