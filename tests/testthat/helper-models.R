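# Toy networks used as analytic oracles across the suite.

# one species, synthesis s / first-order decay k: steady state s/k
sk_model <- function(s = 2, k = 1) {
  network_model(
    species("X", initial_concentration = 0, degradation_rate = k),
    list(reaction("syn_X", "synthesis", products = "X", params = c(k_syn = s))),
    input_species = character(),
    readout_positive = "X", readout_negative = "X")
}

# closed A + B <-> C binding pair with no synthesis or degradation:
# A + C and B + C are conserved moieties
binding_toy <- function(k_on = 1, k_off = 0.5, A0 = 1, B0 = 0.8) {
  network_model(
    rbind(species("A", initial_concentration = A0, degradation_rate = 0),
          species("B", initial_concentration = B0, degradation_rate = 0),
          species("C", initial_concentration = 0, degradation_rate = 0)),
    list(reaction("bind", "complex_formation", reactants = c(A = 1, B = 1),
                  products = "C", params = c(k_on = k_on)),
         reaction("unbind", "complex_dissociation", reactants = "C",
                  products = c(A = 1, B = 1), params = c(k_off = k_off))),
    input_species = character(),
    readout_positive = "C", readout_negative = "C")
}

# linear single-target chain with zero basal activity: a clamped source SRC
# feeds the readout P through one kinase K (the drug target); at steady state
# P = phi(C) exactly, so viability with lambda = 0 equals the occupancy law.
chain_model <- function() {
  network_model(
    rbind(species("SRC", initial_concentration = 1, degradation_rate = 1),
          species("K", initial_concentration = 1, degradation_rate = 1),
          species("P", initial_concentration = 1, degradation_rate = 1),
          species("NEG", initial_concentration = 1, degradation_rate = 1)),
    list(reaction("syn_K", "synthesis", products = "K", params = c(k_syn = 1)),
         reaction("syn_NEG", "synthesis", products = "NEG", params = c(k_syn = 1)),
         reaction("make_P", "mass_action_activation", reactants = "SRC",
                  products = "P", modifiers = "K", params = c(k_cat = 1))),
    input_species = "SRC",
    readout_positive = "P", readout_negative = "NEG")
}

as_twin <- function(model, activation = NULL, scale = NULL) {
  reps <- gene_representatives(model)
  sc <- stats::setNames(rep(1, length(reps)), names(reps))
  if (!is.null(scale)) sc[names(scale)] <- scale
  act <- stats::setNames(
    model$species$initial_concentration[match(model$input_species,
                                              model$species$id)],
    model$input_species)
  if (!is.null(activation)) act[names(activation)] <- activation
  structure(list(model = model, synthesis_scale = sc, activation = act,
                 provenance = list(sample_id = "toy", tissue = "tumor",
                                   histology = "HB", normalization = "none")),
            class = "DigitalTwin")
}

# activation cascade of `n` two-form stages from a clamped input; the drug
# target is the final active form, which gates production of the readout P
cascade_model <- function(n_stages = 2, k_act = 4) {
  sp <- rbind(species("IN", initial_concentration = 1),
              species("P", initial_concentration = 0),
              species("NEG", initial_concentration = 1))
  rx <- list(reaction("syn_NEG", "synthesis", products = "NEG",
                      params = c(k_syn = 1)))
  prev <- "IN"
  for (i in seq_len(n_stages)) {
    a <- sprintf("S%d", i); b <- sprintf("S%d_act", i)
    sp <- rbind(sp, species(a, initial_concentration = 1),
                species(b, initial_concentration = 0))
    rx <- c(rx, list(
      reaction(paste0("syn_", a), "synthesis", products = a,
               params = c(k_syn = 1)),
      reaction(paste0("act_", b), "mass_action_activation", reactants = a,
               products = b, modifiers = prev, params = c(k_cat = k_act)),
      reaction(paste0("deact_", b), "mass_action_activation", reactants = b,
               products = a, modifiers = character(), params = c(k_cat = 1))))
    prev <- b
  }
  rx <- c(rx, list(reaction("make_P", "mass_action_activation",
                            reactants = "IN", products = "P",
                            modifiers = prev, params = c(k_cat = 1))))
  network_model(sp, rx, input_species = "IN",
                readout_positive = "P", readout_negative = "NEG")
}

# fixed-step RK4 integration of the package right-hand side; an integration
# oracle independent of the Newton solving path
rk4_integrate <- function(model, x0, params = NULL, clamps = NULL,
                          t_end = 40, dt = 0.02) {
  x <- x0
  if (!is.null(clamps)) x[match(names(clamps), model$species$id)] <- clamps
  f <- function(y) as.numeric(evaluate_rates(model, pmax(y, 0), params, clamps)$values)
  for (i in seq_len(ceiling(t_end / dt))) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  stats::setNames(x, model$species$id)
}

# small default cohort/panel fixtures shared by the heavier tests
default_fixture <- function(cohort_seed = 7, panel_seed = 7) {
  m <- build_reference_network()
  coh <- generate_cohort(cohort_spec(seed = cohort_seed), m)
  list(model = m, cohort = coh,
       twins = build_cohort_twins(m, coh$counts, coh$metadata),
       panel = generate_panel(panel_spec(seed = panel_seed), m))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

twin_params_test <- function(tw) twinscreen:::twin_params(tw)
twin_clamps_test <- function(tw) twinscreen:::twin_clamps(tw)
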