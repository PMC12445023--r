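#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the study conditions: 13 tumor and 8 normal expression
#' profiles, CTNNB1 mutations in 11 of the 13 tumors, and a Wnt/MYC
#' signature (LGR5, DKK1, NKD1, MYCN, CAD, NPM1) upregulated in tumors by a
#' mean log2 fold change of 3 with 0.5 log2 units of per-sample noise.
#'
#' @param n_tumor,n_normal Sample counts (defaults 13 and 8).
#' @param n_ctnnb1 Number of CTNNB1-mutant tumors (default 11).
#' @param signature_genes_up Genes upregulated in tumors.
#' @param effect_log2fc Mean tumor-vs-normal log2 fold change of the
#'   signature genes (default 3).
#' @param noise_sd_log2 Per-sample log2 noise SD (default 0.5).
#' @param n_genes Total gene count including fillers (default 200).
#' @param seed Generator seed.
#' @return An object of class `"CohortSpec"`.
#' @export
cohort_spec <- function(n_tumor = 13, n_normal = 8, n_ctnnb1 = 11,
                        signature_genes_up = c("LGR5", "DKK1", "NKD1",
                                               "MYCN", "CAD", "NPM1"),
                        effect_log2fc = 3, noise_sd_log2 = 0.5,
                        n_genes = 200, seed = 1L) {
  stopifnot(n_ctnnb1 <= n_tumor, effect_log2fc >= 0, noise_sd_log2 >= 0)
  structure(list(n_tumor = n_tumor, n_normal = n_normal, n_ctnnb1 = n_ctnnb1,
                 signature_genes_up = signature_genes_up,
                 effect_log2fc = effect_log2fc, noise_sd_log2 = noise_sd_log2,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic expression cohort
#'
#' Baseline per-gene mean counts are drawn once (log-normal); tumor samples
#' multiply the signature genes by `2^effect_log2fc` (with per-sample
#' jitter); every count gets Gaussian log2 noise and is back-transformed to
#' a non-negative integer. The first `n_ctnnb1` tumors carry the CTNNB1
#' flag. Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param model A `NetworkModel` whose gene representatives are guaranteed
#'   a row in the matrix (default: the reference network).
#' @return List with `counts` (gene-by-sample integer matrix) and
#'   `metadata` (data frame: `sample_id`, `tissue`, `histology`, `CTNNB1`,
#'   `NFE2L2`, `TERT`).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            model = build_reference_network()) {
  genes <- unique(c(spec$signature_genes_up, unname(gene_representatives(model))))
  n_fill <- max(0, spec$n_genes - length(genes))
  genes <- c(genes, sprintf("FILLER%03d", seq_len(n_fill)))
  samples <- c(sprintf("T%02d", seq_len(spec$n_tumor)),
               sprintf("N%02d", seq_len(spec$n_normal)))
  tissue <- rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal))

  counts <- with_seed(derive_seed(spec$seed, "cohort"), {
    base_mean <- stats::rlnorm(length(genes), meanlog = log(500), sdlog = 1)
    names(base_mean) <- genes
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      mu <- base_mean
      if (tissue[j] == "tumor" && spec$effect_log2fc > 0) {
        lfc <- spec$effect_log2fc +
          stats::rnorm(length(spec$signature_genes_up), 0, spec$noise_sd_log2 / 2)
        mu[spec$signature_genes_up] <- mu[spec$signature_genes_up] * 2^lfc
      } else if (tissue[j] == "tumor") {
        stats::rnorm(length(spec$signature_genes_up))  # keep stream aligned
      }
      noise <- if (spec$noise_sd_log2 > 0)
        stats::rnorm(length(genes), 0, spec$noise_sd_log2) else 0
      m[, j] <- as.integer(round(pmax(mu * 2^noise, 0)))
    }
    m
  })

  histology <- c(rep("HB", min(10, spec$n_tumor)),
                 rep("HCC", max(0, min(2, spec$n_tumor - 10))),
                 rep("TLCT", max(0, spec$n_tumor - 12)))
  metadata <- data.frame(
    sample_id = samples, tissue = tissue,
    histology = c(histology[seq_len(spec$n_tumor)], rep("normal", spec$n_normal)),
    CTNNB1 = c(seq_len(spec$n_tumor) <= spec$n_ctnnb1, rep(FALSE, spec$n_normal)),
    NFE2L2 = c(seq_len(spec$n_tumor) %in% c(12, 13), rep(FALSE, spec$n_normal)),
    TERT = c(seq_len(spec$n_tumor) == 11 + 1 & spec$n_tumor >= 12,
             rep(FALSE, spec$n_normal)),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

#' Panel specification for the synthetic generator
#'
#' @param n_drugs Panel size (default 20).
#' @param ceritinib_kd_nM kD (nM) of the multi-kinase compound at each of
#'   its FAK/MTOR/AKT/ERK targets (default 50).
#' @param kd_range_nM Log-uniform kD sampling range for the comparators
#'   (default 1 to 1000 nM).
#' @param seed Generator seed.
#' @return An object of class `"PanelSpec"`.
#' @export
panel_spec <- function(n_drugs = 20, ceritinib_kd_nM = 50,
                       kd_range_nM = c(1, 1000), seed = 1L) {
  stopifnot(n_drugs >= 2)
  structure(list(n_drugs = n_drugs, ceritinib_kd_nM = ceritinib_kd_nM,
                 kd_range_nM = kd_range_nM, seed = as.integer(seed)),
            class = "PanelSpec")
}

# fixed panel composition: (name, class label, target species, truth class)
panel_catalog <- function() {
  rbind(
    data.frame(name = "ceritinib", class_label = "multi-kinase inhibitor (ALK class)",
               target = NA, truth = "multi_kinase"),
    data.frame(name = c("lorlatinib"), class_label = "ALK inhibitor",
               target = "ALK", truth = "inert_absent_target"),
    data.frame(name = c("erlotinib", "gefitinib", "cabozantinib"),
               class_label = "RTK inhibitor",
               target = "RTK_act", truth = "single_kinase"),
    data.frame(name = "tipifarnib", class_label = "RAS-pathway inhibitor",
               target = "RAS_act", truth = "single_kinase"),
    data.frame(name = c("trametinib", "cobimetinib"), class_label = "MEK/ERK inhibitor",
               target = "ERK_act", truth = "single_kinase"),
    data.frame(name = c("capivasertib", "ipatasertib"), class_label = "AKT inhibitor",
               target = "AKT_act", truth = "single_kinase"),
    data.frame(name = c("rapamycin", "everolimus"), class_label = "MTOR inhibitor",
               target = "MTOR_act", truth = "single_kinase"),
    data.frame(name = c("alpelisib", "buparlisib"), class_label = "PI3K inhibitor",
               target = "PI3K_act", truth = "single_kinase"),
    data.frame(name = "defactinib", class_label = "FAK inhibitor",
               target = "FAK_act", truth = "single_kinase"),
    data.frame(name = c("vismodegib", "sonidegib"), class_label = "SMO/SHH inhibitor",
               target = "SHH", truth = "single_kinase"),
    data.frame(name = "GANT61", class_label = "GLI antagonist",
               target = "GLI1_act", truth = "pathway_node"),
    data.frame(name = "olaparib", class_label = "PARP inhibitor",
               target = "NPM1", truth = "inert_nonmodifier"),
    data.frame(name = "palbociclib", class_label = "CDK4/6 inhibitor",
               target = "CAD", truth = "inert_nonmodifier"))
}

#' Generate a synthetic drug panel
#'
#' Builds the default 20-compound panel: one multi-target ceritinib-like
#' compound spanning the FAK, MTOR, AKT and ERK nodes at low-nM kD, a set of
#' single-target comparators with log-uniform kDs, one deliberate
#' absent-target compound (an ALK surrogate, expected inert on the
#' reference network), and two present-but-noncatalytic decoys. A
#' ground-truth table records the intended effect class of every compound.
#'
#' @param spec A [panel_spec()].
#' @param model The `NetworkModel` the targets must belong to.
#' @return List with `drugs` (list of [drug_spec()]) and `truth`
#'   (data frame: `name`, `class_label`, `targets`, `kd_nM`, `truth_class`,
#'   `ceritinib_like`).
#' @export
generate_panel <- function(spec = panel_spec(),
                           model = build_reference_network()) {
  cat_ <- panel_catalog()
  cat_ <- cat_[seq_len(min(nrow(cat_), spec$n_drugs)), ]
  known <- c(model$species$id, "ALK")
  bad <- setdiff(stats::na.omit(cat_$target), known)
  if (length(bad))
    ts_error("unknown_target", paste("unknown target(s):", paste(bad, collapse = ", ")))

  kds <- with_seed(derive_seed(spec$seed, "panel"), {
    r <- log10(spec$kd_range_nM)
    10^stats::runif(nrow(cat_), r[1], r[2])
  })
  drugs <- vector("list", nrow(cat_))
  truth <- vector("list", nrow(cat_))
  for (i in seq_len(nrow(cat_))) {
    if (cat_$truth[i] == "multi_kinase") {
      targets <- stats::setNames(rep(spec$ceritinib_kd_nM, 4),
                                 c("FAK_act", "MTOR_act", "AKT_act", "ERK_act"))
    } else {
      targets <- stats::setNames(kds[i], cat_$target[i])
    }
    drugs[[i]] <- drug_spec(cat_$name[i], targets, cat_$class_label[i])
    truth[[i]] <- data.frame(
      name = cat_$name[i], class_label = cat_$class_label[i],
      targets = paste(names(targets), collapse = ";"),
      kd_nM = paste(signif(targets, 6), collapse = ";"),
      truth_class = cat_$truth[i],
      ceritinib_like = cat_$truth[i] == "multi_kinase",
      stringsAsFactors = FALSE)
  }
  list(drugs = stats::setNames(drugs, cat_$name), truth = do.call(rbind, truth))
}

#' Generate a synthetic viability plate
#'
#' Samples viability from a four-parameter logistic curve plus Gaussian
#' noise, clipped at 0; the generating parameters are kept as ground truth.
#'
#' @param true_ic50,hill,top,bottom Generating 4PL parameters.
#' @param doses Ascending dose vector.
#' @param n_replicates Replicates per dose (default 3).
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param seed Seed.
#' @param ... Passed to [plate_assay()] (`compound`, `model_id`, `class`,
#'   `dose_unit`).
#' @return A [plate_assay()] with attribute `"truth"`.
#' @export
generate_plate <- function(true_ic50, hill = 1, top = 1, bottom = 0,
                           doses = build_dilution_ladder(1e5, 3, 5),
                           n_replicates = 3, noise_sd = 0.05, seed = 1L, ...) {
  mu <- bottom + (top - bottom) / (1 + (doses / true_ic50)^hill)
  v <- with_seed(derive_seed(seed, "plate", signif(true_ic50, 12)), {
    matrix(pmax(rep(mu, each = n_replicates) +
                  stats::rnorm(n_replicates * length(doses), 0, noise_sd), 0),
           nrow = n_replicates)
  })
  plate <- plate_assay(doses, v, ...)
  attr(plate, "truth") <- list(ic50 = true_ic50, hill = hill, top = top,
                               bottom = bottom, noise_sd = noise_sd)
  plate
}

#' Generate a synthetic 4x4 synergy grid
#'
#' Combination inhibition is placed exactly at the Bliss expectation
#' (`independent` mode), or shifted by `+delta` (`synergistic`) or `-delta`
#' (`antagonistic`), with optional Gaussian noise.
#'
#' @param mode `"independent"`, `"synergistic"` or `"antagonistic"`.
#' @param margins_a,margins_b Single-agent inhibition at the three nonzero
#'   doses of each drug (values in \[0, 1\]).
#' @param delta Constructed excess magnitude (default 0.15).
#' @param noise Gaussian noise SD (default 0).
#' @param seed Seed.
#' @param doses_a,doses_b Dose vectors (first element 0).
#' @return List with `inhibition` (4x4), `doses_a`, `doses_b`, `truth`.
#' @export
generate_synergy_grid <- function(mode = c("independent", "synergistic",
                                           "antagonistic"),
                                  margins_a = c(0.2, 0.4, 0.6),
                                  margins_b = c(0.15, 0.35, 0.55),
                                  delta = 0.15, noise = 0, seed = 1L,
                                  doses_a = c(0, 10, 30, 100),
                                  doses_b = c(0, 10, 30, 100)) {
  mode <- match.arg(mode)
  stopifnot(all(margins_a >= 0 & margins_a <= 1),
            all(margins_b >= 0 & margins_b <= 1))
  ya <- c(0, margins_a); yb <- c(0, margins_b)
  inh <- outer(ya, yb, function(a, b) a + b - a * b)
  shift <- switch(mode, independent = 0, synergistic = delta,
                  antagonistic = -delta)
  inh[2:4, 2:4] <- inh[2:4, 2:4] + shift
  if (noise > 0)
    inh <- inh + with_seed(derive_seed(seed, "synergy"),
                           matrix(stats::rnorm(16, 0, noise), 4))
  list(inhibition = inh, doses_a = doses_a, doses_b = doses_b,
       truth = list(mode = mode, delta = shift * 100))
}
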