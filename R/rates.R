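# Compiled (indexed) form of a NetworkModel for fast rate evaluation.
# Species degradation is carried implicitly through the `deg` vector;
# explicit degradation-kind reactions remain available for toy models.
compile_network <- function(model) {
  ids <- model$species$id
  n <- length(ids)
  idx <- function(x) {
    i <- match(x, ids)
    if (anyNA(i)) ts_error("dangling_reference",
                           sprintf("unknown species id(s): %s",
                                   paste(x[is.na(i)], collapse = ", ")))
    i
  }
  rxs <- model$reactions
  m <- length(rxs)
  kind_code <- match(vapply(rxs, `[[`, "", "kind"), REACTION_KINDS)
  k <- vapply(rxs, function(r) unname(r$params[[KIND_PARAMS[[r$kind]][1L]]]), 0)
  Km <- vapply(rxs, function(r)
    if (r$kind == "michaelis_menten") unname(r$params[["Km"]]) else NA_real_, 0)

  flat <- function(get) {
    ptr <- integer(m + 1L); ptr[1L] <- 0L
    ix <- integer(); st <- numeric()
    for (j in seq_len(m)) {
      v <- get(rxs[[j]])
      if (length(v)) { ix <- c(ix, idx(names(v))); st <- c(st, unname(v)) }
      ptr[j + 1L] <- length(ix)
    }
    list(ptr = ptr, idx = ix, st = st)
  }
  re <- flat(function(r) r$reactants)
  pr <- flat(function(r) r$products)
  mo <- flat(function(r) stats::setNames(rep(1, length(r$modifiers)), r$modifiers))

  list(n = n, ids = ids, rxn_ids = vapply(rxs, `[[`, "", "id"),
       kind = kind_code, k = k, Km = Km,
       r_ptr = re$ptr, r_idx = re$idx, r_st = re$st,
       p_ptr = pr$ptr, p_idx = pr$idx, p_st = pr$st,
       m_ptr = mo$ptr, m_idx = mo$idx,
       deg = model$species$degradation_rate,
       clamp_idx = match(model$input_species, ids),
       clamp_idx0 = as.integer(match(model$input_species, ids) - 1L))
}

#' Nominal kinetic parameter set of a model
#'
#' The parameter set bundles one rate constant per reaction, the
#' Michaelis constants where applicable, and the per-species first-order
#' degradation rates. It is the object perturbed by the Monte Carlo engine
#' and rescaled by [apply_drug()] and by twin synthesis scales.
#'
#' @param model A `NetworkModel`.
#' @return A list with numeric vectors `k` (per reaction), `Km` (per
#'   reaction, `NA` where unused) and `deg` (per species), all named.
#' @export
network_params <- function(model) {
  cm <- compile_network(model)
  list(k = stats::setNames(cm$k, cm$rxn_ids),
       Km = stats::setNames(cm$Km, cm$rxn_ids),
       deg = stats::setNames(cm$deg, cm$ids))
}

# per-reaction flux vector (R reference implementation; the C++ solver
# mirrors this arithmetic and the two are cross-checked in the tests)
reaction_fluxes <- function(cm, state, k = cm$k, Km = cm$Km) {
  v <- numeric(length(cm$kind))
  for (j in seq_along(cm$kind)) {
    ri <- if (cm$r_ptr[j] < cm$r_ptr[j + 1L])
      (cm$r_ptr[j] + 1L):cm$r_ptr[j + 1L] else integer()
    mi <- if (cm$m_ptr[j] < cm$m_ptr[j + 1L])
      (cm$m_ptr[j] + 1L):cm$m_ptr[j + 1L] else integer()
    M <- if (length(mi)) prod(state[cm$m_idx[mi]]) else 1
    v[j] <- switch(cm$kind[j],
      k[j],                                                 # synthesis
      k[j] * state[cm$r_idx[ri[1L]]],                       # degradation
      k[j] * M * prod(state[cm$r_idx[ri]]^cm$r_st[ri]),     # mass action act.
      { S <- state[cm$r_idx[ri[1L]]]                        # michaelis-menten
        k[j] * M * S / (Km[j] + S) },
      k[j] * prod(state[cm$r_idx[ri]]^cm$r_st[ri]),         # complex formation
      k[j] * state[cm$r_idx[ri[1L]]])                       # dissociation
  }
  v
}

#' Evaluate the right-hand side of the model ODE
#'
#' Returns d[x]/dt for the given concentration state under the stated rate
#' laws, including the implicit first-order degradation of every species.
#' Species listed in `clamps` are held fixed (zero rate).
#'
#' @param model A `NetworkModel`.
#' @param state Numeric concentration vector aligned to `model$species`
#'   (optionally named).
#' @param params Parameter set from [network_params()] (default: the model's
#'   nominal parameters).
#' @param clamps Optional named numeric vector of clamped input levels.
#' @return A list of class `"RateVector"` with element `values`.
#' @export
evaluate_rates <- function(model, state, params = NULL, clamps = NULL) {
  cm <- compile_network(model)
  if (length(state) != cm$n)
    ts_error("dimension_mismatch",
             sprintf("state has length %d, model has %d species",
                     length(state), cm$n))
  if (any(!is.finite(state)) || any(state < 0))
    ts_error("invalid_state", "state must be finite and non-negative")
  params <- params %||% network_params(model)
  if (any(params$k < 0, na.rm = TRUE) || any(params$deg < 0, na.rm = TRUE) ||
      any(params$Km < 0, na.rm = TRUE))
    ts_error("negative_parameter", "kinetic parameters must be non-negative")
  state <- as.numeric(state)
  if (!is.null(clamps)) state[match(names(clamps), cm$ids)] <- clamps
  v <- reaction_fluxes(cm, state, as.numeric(params$k), as.numeric(params$Km))
  dx <- -state * as.numeric(params$deg)
  for (j in seq_along(v)) {
    if (cm$r_ptr[j] < cm$r_ptr[j + 1L]) {
      ri <- (cm$r_ptr[j] + 1L):cm$r_ptr[j + 1L]
      dx[cm$r_idx[ri]] <- dx[cm$r_idx[ri]] - cm$r_st[ri] * v[j]
    }
    if (cm$p_ptr[j] < cm$p_ptr[j + 1L]) {
      pi_ <- (cm$p_ptr[j] + 1L):cm$p_ptr[j + 1L]
      dx[cm$p_idx[pi_]] <- dx[cm$p_idx[pi_]] + cm$p_st[pi_] * v[j]
    }
  }
  if (!is.null(clamps)) dx[match(names(clamps), cm$ids)] <- 0
  structure(list(values = stats::setNames(dx, cm$ids)), class = "RateVector")
}
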