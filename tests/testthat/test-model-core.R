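test_that("reference network has the curated structure and validates cleanly", {
  m <- build_reference_network()
  expect_identical(m$readout_positive, "MYC_MAX_nuc")
  expect_identical(m$readout_negative, "CASP3_act")
  expect_true(all(c("MYC_MAX_nuc", "CASP3_act") %in% m$species$id))
  expect_true(nrow(m$species) >= 25 && nrow(m$species) <= 60)
  expect_true(all(c("CTNNB1", "GF") %in% m$input_species))
  tags <- pathway_tags(m)
  for (pw in c("Wnt", "MAPK", "PI3K_AKT_MTOR", "Hedgehog", "Apoptosis"))
    expect_gte(sum(tags == pw), 1)
  expect_identical(nrow(validate_network(m)), 0L)
  reps <- gene_representatives(m)
  expect_true(all(c("MYCN", "MYC", "LGR5", "DKK1", "NKD1", "CAD", "NPM1") %in% reps))
})

test_that("validate_network reports structural defects as data", {
  m <- build_reference_network()

  bad <- m
  bad$readout_positive <- "NOPE"
  rep <- validate_network(bad)
  expect_identical(sum(rep$kind == "missing_readout"), 1L)

  bad <- m
  bad$reactions <- c(bad$reactions, list(
    reaction("ghost", "degradation", reactants = "UNKNOWN",
             params = c(k_deg = 1))))
  rep <- validate_network(bad)
  expect_identical(sum(rep$kind == "dangling_reference"), 1L)

  bad <- m
  bad$reactions[[1]]$params <- c(wrong_name = 1)
  rep <- validate_network(bad)
  expect_true(any(rep$kind == "missing_parameter"))

  bad <- m
  bad$reactions[[1]]$params <- c(k_syn = -1)
  expect_true(any(validate_network(bad)$kind == "negative_parameter"))
})

test_that("evaluate_rates reproduces the stated rate laws", {
  m <- sk_model(s = 2, k = 1)
  expect_equal(as.numeric(evaluate_rates(m, 0)$values), 2)
  expect_equal(as.numeric(evaluate_rates(m, 2)$values), 0)

  bt <- binding_toy(k_on = 1)
  expect_equal(as.numeric(evaluate_rates(bt, c(0, 0, 0))$values), c(0, 0, 0))
  # forward flux k_on * A * B, reverse k_off * C
  r <- evaluate_rates(bt, c(2, 3, 4))$values
  expect_equal(unname(r[["C"]]), 1 * 2 * 3 - 0.5 * 4)

  expect_error(evaluate_rates(m, c(1, 2)), class = "dimension_mismatch")
  expect_error(evaluate_rates(m, -1), class = "invalid_state")
  p <- network_params(m); p$k[1] <- -5
  expect_error(evaluate_rates(m, 1, p), class = "negative_parameter")
})

test_that("michaelis-menten and modifier-catalyzed rates follow their forms", {
  mmod <- network_model(
    rbind(species("E", initial_concentration = 2, degradation_rate = 0),
          species("S", initial_concentration = 3, degradation_rate = 0),
          species("Q", initial_concentration = 0, degradation_rate = 0)),
    list(reaction("cat", "michaelis_menten", reactants = "S", products = "Q",
                  modifiers = "E", params = c(k_cat = 1.5, Km = 2))),
    character(), "Q", "Q")
  r <- evaluate_rates(mmod, c(2, 3, 0))$values
  expect_equal(unname(r[["Q"]]), 1.5 * 2 * 3 / (2 + 3))
  expect_equal(unname(r[["S"]]), -1.5 * 2 * 3 / (2 + 3))
  expect_equal(unname(r[["E"]]), 0)  # modifiers are not consumed
})

test_that("closed binding pair conserves its moieties along trajectories", {
  bt <- binding_toy(k_on = 1, k_off = 0.5, A0 = 1, B0 = 0.8)
  x0 <- bt$species$initial_concentration
  rhs <- function(t, y, p) list(as.numeric(evaluate_rates(bt, pmax(y, 0))$values))
  out <- deSolve::lsoda(x0, seq(0, 50, by = 0.5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  A <- out[, 2]; B <- out[, 3]; C <- out[, 4]
  expect_lt(max(abs((A + C) - (x0[1] + x0[3]))) / (x0[1] + x0[3]), 1e-6)
  expect_lt(max(abs((B + C) - (x0[2] + x0[3]))) / (x0[2] + x0[3]), 1e-6)
})

test_that("integration never drives states materially negative", {
  for (seed in 1:5) {
    n <- 2 + (seed %% 3)
    m <- cascade_model(n_stages = n)
    params <- network_params(m)
    params$k <- with_seed_test(seed, params$k * stats::runif(length(params$k), 0.3, 3))
    tw <- as_twin(m)
    rhs <- function(t, y, p)
      list(as.numeric(evaluate_rates(m, pmax(y, 0), params,
                                     clamps = c(IN = 1))$values))
    x0 <- m$species$initial_concentration
    out <- deSolve::lsoda(x0, seq(0, 30, by = 0.25), rhs, NULL)
    expect_gte(min(out[, -1]), -1e-9)
  }
})

test_that("models round-trip exactly through SBML and YAML", {
  m <- build_reference_network()
  for (ext in c("sbml", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model(m, path)
    m2 <- read_model(path)
    expect_identical(m2$species, m$species)
    expect_identical(m2$input_species, m$input_species)
    expect_identical(m2$readout_positive, m$readout_positive)
    expect_identical(m2$readout_negative, m$readout_negative)
    expect_identical(length(m2$reactions), length(m$reactions))
    for (i in seq_along(m$reactions)) {
      expect_identical(m2$reactions[[i]]$id, m$reactions[[i]]$id)
      expect_identical(m2$reactions[[i]]$kind, m$reactions[[i]]$kind)
      expect_equal(m2$reactions[[i]]$reactants, m$reactions[[i]]$reactants)
      expect_equal(m2$reactions[[i]]$products, m$reactions[[i]]$products)
      expect_identical(m2$reactions[[i]]$modifiers, m$reactions[[i]]$modifiers)
      expect_equal(m2$reactions[[i]]$params, m$reactions[[i]]$params)
    }
    expect_identical(nrow(validate_network(m2)), 0L)
  }
})

test_that("shipped model files match the constructed reference network", {
  m <- build_reference_network()
  for (f in c("reference_network.yaml", "reference_network.sbml")) {
    shipped <- read_model(system.file("extdata", f, package = "twinscreen"))
    expect_identical(shipped$species, m$species)
    expect_identical(length(shipped$reactions), length(m$reactions))
    expect_equal(lapply(shipped$reactions, unclass),
                 lapply(m$reactions, unclass))
  }
})
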