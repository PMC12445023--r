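#' Build the curated reference signaling network
#'
#' Constructs the reduced mechanistic network used for digital-twin
#' simulations: a Wnt arm (clamped CTNNB1 input driving TCF/LEF activity and
#' MYC supply), a RAS/MAPK arm (growth-factor tone through RTK, RAS and ERK),
#' a PI3K/AKT/MTOR arm (suppressing caspase activation), a Hedgehog arm
#' (SHH/GLI1, present but not a default readout), an apoptosis arm
#' (pro-caspase to active Caspase-3), and a nuclear MYC:MAX complex formed
#' from MYC and MAX. The positive readout is `MYC_MAX_nuc`, the negative
#' readout `CASP3_act`.
#'
#' Inducible MYC supply is deliberately split into an MTOR-gated half
#' (cap-dependent translation of Wnt/MYCN-driven transcripts) and an
#' ERK-gated half (ERK-stabilized protein), so collapsing the oncogenic MYC
#' program requires hitting more than one kinase node — the behavior a
#' multi-kinase inhibitor exploits while single-node inhibitors stay partial.
#'
#' Nominal parameterization: all degradation rates are 1/time and synthesis
#' rates of gene representatives are chosen so the unactivated steady state
#' of each representative is 1 a.u.; activation/deactivation constants put
#' baseline cascade activities near one half at the default growth-factor
#' tone. Units are arbitrary (a.u., 1/time); only drug concentrations carry
#' nM units.
#'
#' @return A validated `NetworkModel` (33 species).
#' @export
build_reference_network <- function() {
  sp <- rbind(
    # inputs (clamped during simulation)
    species("CTNNB1", "beta-catenin (Wnt input)", "cytoplasm", 0, pathway = "Wnt"),
    species("GF", "growth-factor tone (input)", "extracellular", 0, pathway = "Core"),
    # Wnt arm
    species("TCF_LEF", "TCF/LEF (inactive)", "nucleus", 1, pathway = "Wnt"),
    species("TCF_LEF_act", "TCF/LEF (active)", "nucleus", 0, pathway = "Wnt"),
    species("LGR5", "LGR5", "cytoplasm", 1, TRUE, "LGR5", pathway = "Wnt"),
    species("DKK1", "DKK1", "extracellular", 1, TRUE, "DKK1", pathway = "Wnt"),
    species("NKD1", "NKD1", "cytoplasm", 1, TRUE, "NKD1", pathway = "Wnt"),
    # MYC module
    species("MYC_pool", "MYC transcript/protein pool", "cytoplasm", 1, TRUE, "MYC", pathway = "Core"),
    species("MYCN_pool", "MYCN transcript/protein pool", "cytoplasm", 1, TRUE, "MYCN", pathway = "Core"),
    species("MYC_nuc", "nuclear MYC", "nucleus", 0.8, pathway = "Core"),
    species("MAX", "MAX", "nucleus", 1, TRUE, "MAX", pathway = "Core"),
    species("MYC_MAX_nuc", "nuclear MYC:MAX complex", "nucleus", 0.3, pathway = "Core"),
    species("CAD", "CAD (MYC target)", "cytoplasm", 1, TRUE, "CAD", pathway = "Core"),
    species("NPM1", "NPM1 (MYC target)", "nucleus", 1, TRUE, "NPM1", pathway = "Core"),
    # RAS/MAPK arm
    species("RTK", "RTK (inactive)", "membrane", 1, pathway = "MAPK"),
    species("RTK_act", "RTK (active)", "membrane", 0, pathway = "MAPK"),
    species("RAS", "RAS (GDP)", "membrane", 1, pathway = "MAPK"),
    species("RAS_act", "RAS (GTP)", "membrane", 0, pathway = "MAPK"),
    species("ERK", "ERK1/2 (inactive)", "cytoplasm", 1, pathway = "MAPK"),
    species("ERK_act", "ERK1/2 (phospho)", "cytoplasm", 0, pathway = "MAPK"),
    # PI3K/AKT/MTOR arm
    species("FAK", "FAK (inactive)", "cytoplasm", 1, pathway = "PI3K_AKT_MTOR"),
    species("FAK_act", "FAK (phospho)", "cytoplasm", 0, pathway = "PI3K_AKT_MTOR"),
    species("PI3K", "PI3K (inactive)", "membrane", 1, pathway = "PI3K_AKT_MTOR"),
    species("PI3K_act", "PI3K (active)", "membrane", 0, pathway = "PI3K_AKT_MTOR"),
    species("AKT", "AKT (inactive)", "cytoplasm", 1, pathway = "PI3K_AKT_MTOR"),
    species("AKT_act", "AKT (phospho)", "cytoplasm", 0, pathway = "PI3K_AKT_MTOR"),
    species("MTOR", "MTOR (inactive)", "cytoplasm", 1, pathway = "PI3K_AKT_MTOR"),
    species("MTOR_act", "MTORC1 (active)", "cytoplasm", 0, pathway = "PI3K_AKT_MTOR"),
    # Hedgehog arm
    species("SHH", "SHH ligand", "extracellular", 1, TRUE, "SHH", pathway = "Hedgehog"),
    species("GLI1", "GLI1 (inactive)", "cytoplasm", 1, TRUE, "GLI1", pathway = "Hedgehog"),
    species("GLI1_act", "GLI1 (active)", "nucleus", 0, pathway = "Hedgehog"),
    # apoptosis arm
    species("CASP3_pro", "pro-Caspase-3", "cytoplasm", 1, TRUE, "CASP3", pathway = "Apoptosis"),
    species("CASP3_act", "active Caspase-3", "cytoplasm", 0.3, pathway = "Apoptosis")
  )

  syn <- function(id, k) reaction(paste0("syn_", id), "synthesis",
                                  products = id, params = c(k_syn = k))
  act <- function(from, to, mods, k, tag = NULL) {
    rid <- paste0("act_", to, if (!is.null(tag)) paste0("_", tag))
    reaction(rid, "mass_action_activation", reactants = from, products = to,
             modifiers = mods, params = c(k_cat = k))
  }
  deact <- function(from, to, k = 1)
    reaction(paste0("deact_", from), "mass_action_activation", reactants = from,
             products = to, modifiers = character(), params = c(k_cat = k))
  mm <- function(id, from, to, mods, k, Km = 1)
    reaction(id, "michaelis_menten", reactants = from, products = to,
             modifiers = mods, params = c(k_cat = k, Km = Km))

  rx <- list(
    # constitutive synthesis of gene representatives (unactivated steady state 1)
    syn("TCF_LEF", 1), syn("LGR5", 1), syn("DKK1", 1), syn("NKD1", 1),
    syn("MYC_pool", 1), syn("MYCN_pool", 1), syn("MAX", 1),
    syn("CAD", 1), syn("NPM1", 1),
    syn("RTK", 1), syn("RAS", 1), syn("ERK", 1),
    syn("FAK", 1), syn("PI3K", 1), syn("AKT", 1), syn("MTOR", 1),
    syn("SHH", 1), syn("GLI1", 1),
    # pro-caspase synthesis balances the constitutive activation tone
    syn("CASP3_pro", 1.3),

    # Wnt arm
    act("TCF_LEF", "TCF_LEF_act", "CTNNB1", 1.5), deact("TCF_LEF_act", "TCF_LEF"),

    # RAS/MAPK cascade
    act("RTK", "RTK_act", "GF", 4), deact("RTK_act", "RTK"),
    act("RAS", "RAS_act", "RTK_act", 4), deact("RAS_act", "RAS"),
    act("ERK", "ERK_act", "RAS_act", 4), deact("ERK_act", "ERK"),

    # PI3K/AKT/MTOR cascade (PI3K and MTOR each have two activation routes)
    act("FAK", "FAK_act", "GF", 4), deact("FAK_act", "FAK"),
    act("PI3K", "PI3K_act", "RTK_act", 2, "rtk"),
    act("PI3K", "PI3K_act", "FAK_act", 2, "fak"), deact("PI3K_act", "PI3K"),
    act("AKT", "AKT_act", "PI3K_act", 4), deact("AKT_act", "AKT"),
    act("MTOR", "MTOR_act", "AKT_act", 2, "akt"),
    act("MTOR", "MTOR_act", "PI3K_act", 2, "pi3k"), deact("MTOR_act", "MTOR"),

    # Hedgehog arm
    act("GLI1", "GLI1_act", "SHH", 1.5), deact("GLI1_act", "GLI1"),

    # nuclear MYC supply: basal plus gated inducible routes
    reaction("syn_MYC_nuc_basal", "synthesis", products = "MYC_nuc",
             params = c(k_syn = 0.8)),
    mm("myc_wnt_mtor", "MYC_pool", "MYC_nuc", c("TCF_LEF_act", "MTOR_act"), 0.3),
    mm("myc_wnt_erk",  "MYC_pool", "MYC_nuc", c("TCF_LEF_act", "ERK_act"),  0.3),
    mm("myc_gf_erk",   "MYC_pool", "MYC_nuc", "ERK_act", 0.25),
    mm("mycn_wnt_mtor", "MYCN_pool", "MYC_nuc", c("TCF_LEF_act", "MTOR_act"), 1),
    mm("mycn_wnt_erk",  "MYCN_pool", "MYC_nuc", c("TCF_LEF_act", "ERK_act"),  1),

    # MYC:MAX complex
    reaction("bind_myc_max", "complex_formation",
             reactants = c(MYC_nuc = 1, MAX = 1), products = "MYC_MAX_nuc",
             params = c(k_on = 0.5)),
    reaction("unbind_myc_max", "complex_dissociation",
             reactants = "MYC_MAX_nuc", products = c(MYC_nuc = 1, MAX = 1),
             params = c(k_off = 0.2)),

    # apoptosis: constitutive caspase tone, AKT/MTOR-driven re-inactivation
    deact("CASP3_pro", "CASP3_act", 0.3),
    act("CASP3_act", "CASP3_pro", "AKT_act", 0.15, "akt"),
    act("CASP3_act", "CASP3_pro", "MTOR_act", 0.15, "mtor")
  )
  # deact_CASP3_pro is really the spontaneous activation step; rename for clarity
  rx <- lapply(rx, function(r) {
    if (r$id == "deact_CASP3_pro") r$id <- "act_CASP3_spont"
    r
  })

  model <- network_model(sp, rx,
                         input_species = c("CTNNB1", "GF"),
                         readout_positive = "MYC_MAX_nuc",
                         readout_negative = "CASP3_act")
  model
}
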