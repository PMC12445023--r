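#' Define a model species
#'
#' A species is one biochemical entity of the network (a protein form, a
#' complex, a transcript pool) with a first-order degradation rate. Species
#' marked as gene representatives are the attachment points for patient
#' individualization: their synthesis rate is scaled by the patient's
#' expression of `gene`.
#'
#' @param id Short unique token, e.g. `"ERK_act"`.
#' @param name Free-text label.
#' @param compartment Compartment token (`"cytoplasm"`, `"nucleus"`, ...).
#' @param initial_concentration Non-negative start concentration (a.u.).
#' @param is_gene_representative Logical; `TRUE` when a synthesis parameter
#'   maps to a measured gene.
#' @param gene Gene symbol tied to the species (used when
#'   `is_gene_representative`), or `NA`.
#' @param degradation_rate Non-negative first-order decay rate (1/time).
#' @param pathway Pathway label: one of `"Wnt"`, `"MAPK"`, `"PI3K_AKT_MTOR"`,
#'   `"Hedgehog"`, `"Apoptosis"`, `"Core"`.
#' @return A one-row `data.frame` describing the species.
#' @export
species <- function(id, name = id, compartment = "cytoplasm",
                    initial_concentration = 0,
                    is_gene_representative = FALSE, gene = NA_character_,
                    degradation_rate = 1, pathway = "Core") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.finite(initial_concentration) || initial_concentration < 0)
    ts_error("invalid_species", sprintf("species '%s': initial_concentration must be >= 0", id))
  if (!is.finite(degradation_rate) || degradation_rate < 0)
    ts_error("invalid_species", sprintf("species '%s': degradation_rate must be >= 0", id))
  data.frame(id = id, name = name, compartment = compartment,
             initial_concentration = initial_concentration,
             is_gene_representative = is_gene_representative,
             gene = gene, degradation_rate = degradation_rate,
             pathway = pathway, stringsAsFactors = FALSE)
}

REACTION_KINDS <- c("synthesis", "degradation", "mass_action_activation",
                    "michaelis_menten", "complex_formation",
                    "complex_dissociation")

# exact parameter names required per kind (validated)
KIND_PARAMS <- list(
  synthesis              = "k_syn",
  degradation            = "k_deg",
  mass_action_activation = "k_cat",
  michaelis_menten       = c("k_cat", "Km"),
  complex_formation      = "k_on",
  complex_dissociation   = "k_off"
)

#' Define a reaction
#'
#' Six rate-law kinds are supported; all "activation" is modifier-catalyzed
#' conversion between inactive and active species forms, with the modifier
#' activity entering the rate multiplicatively and an empty modifier list
#' meaning a spontaneous (constitutive) conversion.
#'
#' Rate laws (x denotes concentrations, M the product of modifier levels):
#' * `synthesis`: `v = k_syn` into the product.
#' * `degradation`: `v = k_deg * x[reactant]`.
#' * `mass_action_activation`: `v = k_cat * M * prod(x[reactants])`.
#' * `michaelis_menten`: `v = k_cat * M * x[S] / (Km + x[S])` (single reactant S).
#' * `complex_formation`: `v = k_on * x[A] * x[B]`.
#' * `complex_dissociation`: `v = k_off * x[C]`.
#'
#' @param id Reaction token.
#' @param kind One of `r paste0('"', REACTION_KINDS, '"', collapse = ", ")`.
#' @param reactants,products Named numeric vectors of stoichiometries
#'   (names are species ids), or `NULL`.
#' @param modifiers Character vector of catalyst species ids (not consumed).
#' @param params Named numeric vector of non-negative rate constants; the
#'   required names are fixed by `kind` (e.g. `k_cat` and `Km` for
#'   `michaelis_menten`).
#' @return An object of class `"Reaction"`.
#' @export
reaction <- function(id, kind, reactants = NULL, products = NULL,
                     modifiers = character(), params) {
  kind <- match.arg(kind, REACTION_KINDS)
  stoich <- function(x) {
    if (is.null(x)) return(numeric())
    if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
    x
  }
  structure(list(id = id, kind = kind, reactants = stoich(reactants),
                 products = stoich(products),
                 modifiers = as.character(modifiers), params = params),
            class = "Reaction")
}

#' Assemble a network model
#'
#' @param species A `data.frame` of rows built by [species()].
#' @param reactions A list of [reaction()] objects.
#' @param input_species Ids of activation handles; these species are clamped
#'   to their activation level during simulation.
#' @param readout_positive Id of the pro-viability readout (nuclear MYC:MAX
#'   complex in the reference network).
#' @param readout_negative Id of the pro-death readout (active Caspase-3).
#' @return An object of class `"NetworkModel"`.
#' @seealso [build_reference_network()], [validate_network()]
#' @export
network_model <- function(species, reactions, input_species,
                          readout_positive, readout_negative) {
  rownames(species) <- NULL
  structure(list(species = species, reactions = reactions,
                 input_species = input_species,
                 readout_positive = readout_positive,
                 readout_negative = readout_negative),
            class = "NetworkModel")
}

#' @export
print.NetworkModel <- function(x, ...) {
  cat(sprintf("NetworkModel: %d species, %d reactions\n",
              nrow(x$species), length(x$reactions)))
  cat("  pathways:", paste(sort(unique(x$species$pathway)), collapse = ", "), "\n")
  cat("  inputs:  ", paste(x$input_species, collapse = ", "), "\n")
  cat(sprintf("  readouts: + %s / - %s\n", x$readout_positive, x$readout_negative))
  invisible(x)
}

#' Pathway tags of a model
#'
#' @param model A `NetworkModel`.
#' @return Named character vector mapping species id to pathway label.
#' @export
pathway_tags <- function(model) {
  stats::setNames(model$species$pathway, model$species$id)
}

#' Gene-representative map of a model
#'
#' @param model A `NetworkModel`.
#' @return Named character vector mapping gene-representative species id to
#'   gene symbol.
#' @export
gene_representatives <- function(model) {
  sp <- model$species
  stats::setNames(sp$gene[sp$is_gene_representative],
                  sp$id[sp$is_gene_representative])
}

#' Validate a network model
#'
#' Checks structural well-formedness: unique species ids, resolvable species
#' references, the exact parameter names required by each reaction kind,
#' non-negative parameters and rates, presence and input-reachability of both
#' readouts, and that gene-representative species have a synthesis inflow.
#' Issues are returned as data, not thrown.
#'
#' @param model A `NetworkModel`.
#' @return A `data.frame` with columns `kind`, `where`, `message`; zero rows
#'   iff the model is well-formed.
#' @export
validate_network <- function(model) {
  issues <- list()
  add <- function(kind, where, message)
    issues[[length(issues) + 1L]] <<- data.frame(kind = kind, where = where,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  sp <- model$species
  ids <- sp$id
  if (anyDuplicated(ids))
    add("duplicate_species", ids[duplicated(ids)][1L], "species ids must be unique")
  if (any(sp$initial_concentration < 0))
    add("negative_parameter", ids[which(sp$initial_concentration < 0)[1L]],
        "initial_concentration < 0")
  if (any(sp$degradation_rate < 0))
    add("negative_parameter", ids[which(sp$degradation_rate < 0)[1L]],
        "degradation_rate < 0")

  for (rx in model$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    bad <- setdiff(refs, ids)
    for (b in bad) add("dangling_reference", rx$id,
                       sprintf("reaction '%s' references unknown species '%s'", rx$id, b))
    need <- KIND_PARAMS[[rx$kind]]
    miss <- setdiff(need, names(rx$params))
    if (length(miss))
      add("missing_parameter", rx$id,
          sprintf("reaction '%s' (%s) lacks parameter(s): %s", rx$id, rx$kind,
                  paste(miss, collapse = ", ")))
    extra <- setdiff(names(rx$params), need)
    if (length(extra))
      add("unknown_parameter", rx$id,
          sprintf("reaction '%s' (%s) has unexpected parameter(s): %s", rx$id,
                  rx$kind, paste(extra, collapse = ", ")))
    if (any(!is.finite(rx$params)) || any(rx$params < 0))
      add("negative_parameter", rx$id, "rate constants must be finite and >= 0")
  }

  for (ro in c(positive = model$readout_positive, negative = model$readout_negative)) {
    if (!ro %in% ids)
      add("missing_readout", ro, sprintf("readout species '%s' absent from model", ro))
  }

  # reachability: edges run from reactants and modifiers to products
  reach <- reachable_from(model, model$input_species)
  for (ro in c(model$readout_positive, model$readout_negative)) {
    if (ro %in% ids && !(ro %in% reach))
      add("unreachable_readout", ro,
          sprintf("readout '%s' not reachable from any input", ro))
  }

  # gene representatives need a synthesis inflow (or an input clamp)
  syn_targets <- unlist(lapply(model$reactions, function(rx)
    if (rx$kind == "synthesis") names(rx$products) else NULL))
  for (g in sp$id[sp$is_gene_representative]) {
    if (!(g %in% syn_targets) && !(g %in% model$input_species))
      add("missing_synthesis", g,
          sprintf("gene representative '%s' has no synthesis reaction", g))
  }

  if (length(issues)) do.call(rbind, issues)
  else data.frame(kind = character(), where = character(), message = character(),
                  stringsAsFactors = FALSE)
}

reachable_from <- function(model, sources) {
  ids <- model$species$id
  reach <- intersect(sources, ids)
  repeat {
    new <- character()
    for (rx in model$reactions) {
      inputs <- c(names(rx$reactants), rx$modifiers)
      if (any(inputs %in% reach))
        new <- c(new, names(rx$products))
    }
    new <- setdiff(intersect(new, ids), reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  reach
}
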