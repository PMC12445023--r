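#' Specify a drug
#'
#' @param name Compound token.
#' @param targets Named numeric vector: names are target species ids, values
#'   the dissociation constants kD in nM (all > 0).
#' @param class_label Free-text class (e.g. `"MEK inhibitor"`).
#' @return An object of class `"DrugSpec"`.
#' @export
drug_spec <- function(name, targets, class_label = "") {
  if (!length(targets) || is.null(names(targets)) || any(!nzchar(names(targets))))
    ts_error("invalid_drug", "targets must be a named vector of kD values")
  if (any(!is.finite(targets)) || any(targets <= 0))
    ts_error("invalid_drug", "all kD values must be positive")
  structure(list(name = name, targets = targets, class_label = class_label),
            class = "DrugSpec")
}

#' Monte Carlo configuration
#'
#' @param n_runs Number of Monte Carlo steady-state repetitions (default
#'   1000, the screening depth used throughout).
#' @param sigma_log10 Log10-scale spread of the parameter perturbations
#'   (default 0.1); 0 gives the deterministic nominal model.
#' @param master_seed Integer master seed; every run's sub-seed is derived
#'   deterministically from it together with the sample, drug and run index,
#'   so one run is one parameter set shared across the doses of a drug.
#' @return An object of class `"MonteCarloConfig"`.
#' @export
mc_config <- function(n_runs = 1000, sigma_log10 = 0.1, master_seed = 1L) {
  stopifnot(n_runs >= 1, sigma_log10 >= 0)
  structure(list(n_runs = as.integer(n_runs), sigma_log10 = sigma_log10,
                 master_seed = as.integer(master_seed)),
            class = "MonteCarloConfig")
}

#' Dose grid for a screen
#'
#' Default: 9 log-spaced concentrations, one per decade from 1e-4 to 1e4 nM.
#'
#' @param concentrations Ascending positive vector in nM.
#' @return An object of class `"DoseGrid"`.
#' @export
dose_grid <- function(concentrations = 10^seq(-4, 4)) {
  concentrations <- sort(as.numeric(concentrations))
  if (any(concentrations <= 0) || anyDuplicated(concentrations))
    ts_error("invalid_grid", "grid concentrations must be strictly ascending and > 0")
  structure(list(concentrations = concentrations), class = "DoseGrid")
}

#' Apply a drug to a parameter set
#'
#' Single-site occupancy on catalytic activity: for each target `(T, kD)`,
#' every reaction in which `T` acts as a modifier has its catalytic constant
#' multiplied by `phi = 1 / (1 + C / kD)`. Multi-target drugs apply all of
#' their factors; everything else is untouched. Pure function.
#'
#' @param params Parameter set from [network_params()] (possibly
#'   twin-scaled).
#' @param drug A [drug_spec()].
#' @param concentration Drug concentration in nM (>= 0).
#' @param model The `NetworkModel` the parameters belong to (provides the
#'   modifier structure).
#' @return The perturbed parameter set; attribute `"touched"` flags whether
#'   any reaction was affected. Targets absent from the model are skipped
#'   with a warning (off-target panel members).
#' @export
apply_drug <- function(params, drug, concentration, model) {
  stopifnot(concentration >= 0)
  touched <- FALSE
  for (tg in names(drug$targets)) {
    if (!tg %in% model$species$id) {
      ts_warning("missing_target",
                 sprintf("drug '%s': target '%s' absent from model; skipped",
                         drug$name, tg))
      next
    }
    phi <- 1 / (1 + concentration / drug$targets[[tg]])
    hit <- vapply(model$reactions, function(rx) tg %in% rx$modifiers, TRUE)
    if (any(hit)) {
      params$k[hit] <- params$k[hit] * phi
      if (concentration > 0) touched <- TRUE
    }
  }
  attr(params, "touched") <- touched
  params
}

# does the drug touch any reaction of the model at positive concentration?
drug_is_active <- function(drug, model) {
  mods <- unique(unlist(lapply(model$reactions, `[[`, "modifiers")))
  any(names(drug$targets) %in% mods)
}

# twin-effective nominal parameters: k_syn of gene-representative synthesis
# reactions multiplied by the twin's synthesis scale
twin_params <- function(twin) {
  params <- network_params(twin$model)
  for (rx in twin$model$reactions) {
    if (rx$kind != "synthesis") next
    prod_id <- names(rx$products)[1L]
    if (prod_id %in% names(twin$synthesis_scale))
      params$k[[rx$id]] <- params$k[[rx$id]] * twin$synthesis_scale[[prod_id]]
  }
  params
}

twin_clamps <- function(twin) {
  lv <- twin$activation
  inputs <- twin$model$input_species
  miss <- setdiff(inputs, names(lv))
  if (length(miss)) {
    sp <- twin$model$species
    lv[miss] <- sp$initial_concentration[match(miss, sp$id)]
  }
  lv[inputs]
}

#' Solve a digital twin to steady state
#'
#' The default path runs a damped Newton iteration (with pseudo-transient
#' continuation as a safety net) on the model right-hand side from the
#' initial state, with the input species clamped at their activation levels.
#' `method = "integrate"` instead integrates the stiff ODE with
#' [deSolve::lsoda()] until the normalized residual
#' `max_i |dx_i/dt| / (|x_i| + 1e-9)` stays below `tol` over a probe window,
#' then polishes by Newton root finding — the two routes agree and are
#' cross-checked in the test suite.
#'
#' @param twin A `DigitalTwin` (or a bare `NetworkModel`, taken at nominal
#'   parameters with inputs clamped at their initial concentrations).
#' @param params Optional parameter set (default: twin-effective nominal).
#' @param clamps Optional named input levels (default: the twin activation).
#' @param method `"auto"` (Newton + fallback), `"newton"`, or `"integrate"`.
#' @param tol Residual tolerance (default 1e-8).
#' @param t_max Maximum simulated time for the integration route
#'   (default 1e6).
#' @param x0 Optional start state (defaults to the species initial
#'   concentrations).
#' @param .cm Internal: precompiled network (avoids recompiling in loops).
#' @return An object of class `"SteadyState"`: `concentrations` (named),
#'   `residual`, `converged`, `t_reached`.
#' @export
solve_steady_state <- function(twin, params = NULL, clamps = NULL,
                               method = c("auto", "newton", "integrate"),
                               tol = 1e-8, t_max = 1e6, x0 = NULL,
                               .cm = NULL) {
  method <- match.arg(method)
  if (inherits(twin, "NetworkModel"))
    twin <- structure(list(model = twin, synthesis_scale = numeric(),
                           activation = stats::setNames(
                             twin$species$initial_concentration[
                               match(twin$input_species, twin$species$id)],
                             twin$input_species),
                           provenance = list(sample_id = "model", tissue = NA)),
                      class = "DigitalTwin")
  model <- twin$model
  cm <- .cm %||% compile_network(model)
  params <- params %||% twin_params(twin)
  if (any(params$k < 0) || any(params$deg < 0))
    ts_error("negative_parameter", "kinetic parameters must be non-negative")
  clamps <- clamps %||% twin_clamps(twin)
  x0 <- x0 %||% model$species$initial_concentration
  if (length(clamps)) x0[match(names(clamps), cm$ids)] <- as.numeric(clamps)

  finish <- function(state, residual, converged, t_reached) {
    if (any(!is.finite(state)))
      ts_error("diverged", "non-finite state during steady-state solve")
    structure(list(concentrations = stats::setNames(pmax(state, 0), cm$ids),
                   residual = residual, converged = converged,
                   t_reached = t_reached), class = "SteadyState")
  }

  if (method %in% c("auto", "newton")) {
    sol <- .ss_solve(cm, as.numeric(params$k), as.numeric(params$Km),
                     as.numeric(params$deg), x0, tol, 50L)
    if (sol$converged || method == "newton")
      return(finish(sol$state, sol$residual, sol$converged, Inf))
  }

  # stiff integration with residual probes, then Newton polish
  rhs_fun <- function(t, y, p) {
    y <- pmax(y, 0)
    list(as.numeric(evaluate_rates(model, y, params, clamps)$values))
  }
  t0 <- 0
  y <- x0
  chunk <- 20
  resid <- Inf
  hits <- 0L
  while (t0 < t_max) {
    times <- c(0, chunk)
    out <- deSolve::lsoda(y, times, rhs_fun, NULL, rtol = 1e-10, atol = 1e-12)
    y <- pmax(out[nrow(out), -1], 0)
    if (any(!is.finite(y))) ts_error("diverged", "non-finite state during integration")
    t0 <- t0 + chunk
    f <- as.numeric(evaluate_rates(model, y, params, clamps)$values)
    resid <- max(abs(f) / (abs(y) + 1e-9))
    hits <- if (resid < tol) hits + 1L else 0L
    if (hits >= 2L) break           # sustained over a probe window
    chunk <- min(chunk * 2, t_max - t0 + 1)
  }
  sol <- .ss_solve(cm, as.numeric(params$k), as.numeric(params$Km),
                   as.numeric(params$deg), as.numeric(y), tol, 50L)
  if (sol$converged) finish(sol$state, sol$residual, TRUE, t0)
  else finish(y, resid, resid < tol, t0)
}

# Perturbation matrices for the Monte Carlo engine; one row per run, seeded
# by (master_seed, sample, drug, run) so results are independent of
# evaluation order. A run is one sampled parameter set, reused for the
# control and for every concentration of that drug, so dose-response ratios
# compare like with like (paired parameter sets).
mc_perturbations <- function(mc, sample_id, drug_name, n_k, n_km_mask, n_deg) {
  n_par <- n_k + sum(n_km_mask) + n_deg
  Z <- matrix(0, mc$n_runs, n_par)
  if (mc$sigma_log10 > 0) {
    for (r in seq_len(mc$n_runs)) {
      seed <- derive_seed(mc$master_seed, sample_id, drug_name, r)
      Z[r, ] <- with_seed(seed, stats::rnorm(n_par, 0, mc$sigma_log10))
    }
  }
  Z
}

#' Monte Carlo steady-state readouts
#'
#' Re-solves the twin's steady state `n_runs` times, each run multiplying
#' every kinetic parameter by `10^z` with `z ~ Normal(0, sigma_log10)` drawn
#' from a deterministic per-run stream keyed by (master seed, sample, drug,
#' run), and returns the medians of the positive and negative readout
#' species over the converged runs. A run is one sampled parameter set: the
#' same set is reused at the control and at every concentration of a drug,
#' so treated-versus-control comparisons are paired.
#'
#' @param twin A `DigitalTwin`.
#' @param drug A [drug_spec()] or `NULL` for baseline.
#' @param concentration Drug concentration in nM (ignored when `drug` is
#'   `NULL`).
#' @param mc A [mc_config()].
#' @param .cm Internal: precompiled network.
#' @return List with `pos_median`, `neg_median`, `runs` (per-run table with
#'   columns `run`, `pos`, `neg`, `converged`) and `n_dropped`.
#' @export
monte_carlo_readouts <- function(twin, drug = NULL, concentration = 0,
                                 mc = mc_config(), .cm = NULL) {
  model <- twin$model
  cm <- .cm %||% compile_network(model)
  params <- twin_params(twin)
  if (!is.null(drug)) params <- apply_drug(params, drug, concentration, model)
  clamps <- twin_clamps(twin)
  ro_idx <- match(c(model$readout_positive, model$readout_negative), cm$ids)

  # nominal solution doubles as the warm start for all runs
  nominal <- solve_steady_state(twin, params = params, clamps = clamps, .cm = cm)
  x_start <- as.numeric(nominal$concentrations)

  if (mc$sigma_log10 == 0) {
    runs <- data.frame(run = seq_len(mc$n_runs),
                       pos = rep(x_start[ro_idx[1]], mc$n_runs),
                       neg = rep(x_start[ro_idx[2]], mc$n_runs),
                       converged = nominal$converged)
  } else {
    km_mask <- is.finite(as.numeric(params$Km))
    n_k <- length(params$k); n_deg <- length(params$deg)
    Z <- mc_perturbations(mc, twin$provenance$sample_id,
                          if (is.null(drug)) ".baseline" else drug$name,
                          n_k, km_mask, n_deg)
    Kmat <- sweep(10^Z[, seq_len(n_k), drop = FALSE], 2,
                  as.numeric(params$k), "*")
    Kmmat <- matrix(rep(as.numeric(params$Km), each = mc$n_runs), mc$n_runs)
    if (any(km_mask))
      Kmmat[, km_mask] <- Kmmat[, km_mask, drop = FALSE] *
        10^Z[, n_k + seq_len(sum(km_mask)), drop = FALSE]
    Degmat <- sweep(10^Z[, n_k + sum(km_mask) + seq_len(n_deg), drop = FALSE],
                    2, as.numeric(params$deg), "*")
    sol <- .ss_solve_batch(cm, Kmat, Kmmat, Degmat, x_start, 1e-8, 50L,
                           as.integer(ro_idx - 1L))
    runs <- data.frame(run = seq_len(mc$n_runs),
                       pos = sol$readouts[, 1], neg = sol$readouts[, 2],
                       converged = sol$converged)
  }
  ok <- runs$converged
  if (!any(ok)) ts_error("no_converged_runs", "all Monte Carlo runs failed to converge")
  list(pos_median = stats::median(runs$pos[ok]),
       neg_median = stats::median(runs$neg[ok]),
       runs = runs, n_dropped = sum(!ok))
}

#' Simulate a dose-response curve
#'
#' Runs [monte_carlo_readouts()] at concentration 0 (control) and at each
#' grid concentration. Because a Monte Carlo run is one sampled parameter
#' set shared between control and treatment, relative viability is computed
#' per run with [viability_score()] (treated readouts of run r against the
#' control readouts of the same run) and the curve reports the median across
#' converged runs; the control is anchored at 1 exactly. A drug that touches
#' no reaction of the model (e.g. its only target is absent) yields a curve
#' that is identically 1: the perturbed model equals the control model, so
#' the control readouts are reused for every dose.
#'
#' @param twin A `DigitalTwin`.
#' @param drug A [drug_spec()].
#' @param grid A [dose_grid()].
#' @param mc A [mc_config()].
#' @param lambda Weight of the negative readout in [viability_score()]
#'   (default 0.5).
#' @return An object of class `"DoseResponseCurve"`.
#' @export
run_dose_response <- function(twin, drug, grid = dose_grid(),
                              mc = mc_config(), lambda = 0.5) {
  conc <- sort(grid$concentrations)
  cm <- compile_network(twin$model)
  control <- monte_carlo_readouts(twin, drug, 0, mc, .cm = cm)
  active <- drug_is_active(drug, twin$model)
  n_dropped <- control$n_dropped
  if (!active) {
    viability <- rep(1, length(conc))
    pos <- rep(control$pos_median, length(conc))
    neg <- rep(control$neg_median, length(conc))
  } else {
    pos <- neg <- viability <- numeric(length(conc))
    for (i in seq_along(conc)) {
      mcr <- monte_carlo_readouts(twin, drug, conc[i], mc, .cm = cm)
      pos[i] <- mcr$pos_median; neg[i] <- mcr$neg_median
      ok <- control$runs$converged & mcr$runs$converged &
        control$runs$pos > 0 & control$runs$neg > 0
      if (!any(ok))
        ts_error("no_converged_runs", "no run converged at both control and dose")
      rho <- vapply(which(ok), function(r)
        viability_score(mcr$runs$pos[r], mcr$runs$neg[r],
                        control$runs$pos[r], control$runs$neg[r], lambda), 0)
      viability[i] <- stats::median(rho)
      n_dropped <- n_dropped + mcr$n_dropped
    }
  }
  structure(list(concentrations = conc, viability = viability,
                 readouts_raw = data.frame(concentration = conc, pos = pos,
                                           neg = neg),
                 control = list(pos = control$pos_median,
                                neg = control$neg_median),
                 lambda = lambda, drug = drug$name,
                 sample_id = twin$provenance$sample_id,
                 tissue = twin$provenance$tissue,
                 n_dropped = n_dropped),
            class = "DoseResponseCurve")
}

#' Run an in silico drug-response screen
#'
#' Simulates the cartesian product of twins and drugs, summarizes each curve
#' with Emax, EC50, GR50 and GRmax, and returns one row per (sample, drug)
#' together with a run manifest. Deterministic for a fixed master seed and
#' independent of the order of twins or drugs.
#'
#' @param twins List of `DigitalTwin` objects.
#' @param panel List of [drug_spec()] objects.
#' @param grid A [dose_grid()].
#' @param mc A [mc_config()].
#' @param lambda Negative-readout weight (default 0.5).
#' @param n_div Control divisions per assay window for the GR metrics
#'   (default 1).
#' @return An object of class `"ScreenResult"`: `results` data frame with
#'   columns `sample_id`, `tissue`, `drug`, `emax_pct`, `ec50_nM`,
#'   `gr50_nM`, `grmax`, `effective`, plus `manifest`.
#' @export
run_screen <- function(twins, panel, grid = dose_grid(), mc = mc_config(),
                       lambda = 0.5, n_div = 1) {
  stopifnot(length(twins) >= 1, length(panel) >= 1)
  rows <- list()
  n_dropped <- 0L
  for (tw in twins) {
    for (dr in panel) {
      curve <- run_dose_response(tw, dr, grid, mc, lambda)
      s <- summarize_curve(curve, n_div = n_div)
      n_dropped <- n_dropped + curve$n_dropped
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = tw$provenance$sample_id, tissue = tw$provenance$tissue,
        drug = dr$name, emax_pct = s$Emax, ec50_nM = s$EC50, gr50_nM = s$GR50,
        grmax = s$GRmax, effective = s$effective, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$sample_id, results$drug), ]
  rownames(results) <- NULL
  cfg <- list(master_seed = mc$master_seed, n_runs = mc$n_runs,
              sigma_log10 = mc$sigma_log10, grid = grid$concentrations,
              lambda = lambda, n_div = n_div)
  structure(list(results = results,
                 manifest = c(cfg, list(config_hash = config_hash(cfg),
                                        dropped_runs = n_dropped))),
            class = "ScreenResult")
}
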