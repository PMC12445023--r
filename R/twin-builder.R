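#' Normalize an expression count matrix
#'
#' Per-sample scaling to counts-per-million followed by `log2(x + 1)`.
#'
#' @param counts Non-negative gene-by-sample matrix (genes as rows).
#' @return Matrix of the same shape on the log2(CPM+1) scale.
#' @export
normalize_expression <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    ts_error("invalid_counts", "counts must be finite and non-negative")
  libs <- colSums(counts)
  if (any(libs == 0))
    ts_error("empty_library",
             sprintf("sample(s) with zero total counts: %s",
                     paste(colnames(counts)[libs == 0], collapse = ", ")))
  log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
}

#' Per-gene reference baseline from normal samples
#'
#' The reference used for individualization is the per-gene median of the
#' normalized expression over the cohort's normal samples.
#'
#' @param norm Normalized matrix from [normalize_expression()].
#' @param normal_samples Column names of the normal samples.
#' @return Named vector of per-gene baselines on the log2(CPM+1) scale.
#' @export
reference_baseline <- function(norm, normal_samples) {
  missing <- setdiff(normal_samples, colnames(norm))
  if (length(missing))
    ts_error("unknown_sample", paste("unknown samples:", paste(missing, collapse = ", ")))
  apply(norm[, normal_samples, drop = FALSE], 1, stats::median)
}

#' Construct a patient profile
#'
#' @param sample_id Sample token.
#' @param tissue `"tumor"` or `"normal"`.
#' @param expression Named vector of normalized expression (log2(CPM+1)).
#' @param mutations Named logical vector of mutation flags (`CTNNB1`,
#'   `NFE2L2`, `TERT`).
#' @param histology `"HB"`, `"HCC"`, `"TLCT"` or `"normal"`.
#' @return An object of class `"PatientProfile"`.
#' @export
patient_profile <- function(sample_id, tissue, expression,
                            mutations = c(CTNNB1 = FALSE),
                            histology = if (tissue == "normal") "normal" else "HB") {
  tissue <- match.arg(tissue, c("tumor", "normal"))
  if (any(!is.finite(expression)) || any(expression < 0))
    ts_error("invalid_expression", "expression must be finite and non-negative")
  structure(list(sample_id = sample_id, tissue = tissue, histology = histology,
                 expression = expression, mutations = mutations),
            class = "PatientProfile")
}

#' Individualize a model into a digital twin
#'
#' Sets one synthesis multiplier per gene-representative species as the
#' ratio of the patient's expression to the cohort reference, computed after
#' back-transforming the log2(CPM+1) values to the linear scale, with a
#' pseudocount of `epsilon` added to numerator and denominator, and clipped
#' to `bounds`. The effective synthesis rate during simulation is the
#' nominal `k_syn` times this multiplier. Activation inputs default to the
#' cohort policy of [default_activation()].
#'
#' @param model A `NetworkModel`.
#' @param profile A [patient_profile()].
#' @param reference Named per-gene baseline from [reference_baseline()]
#'   (same scale as the profile expression).
#' @param epsilon Pseudocount on the linear (CPM) scale. Default 0.5.
#' @param bounds Length-2 clipping interval for the multiplier.
#'   Default `c(0.1, 10)`.
#' @param activation Optional named activation levels for the model inputs;
#'   defaults to [default_activation()] for the profile.
#' @return An object of class `"DigitalTwin"`.
#' @export
individualize <- function(model, profile, reference, epsilon = 0.5,
                          bounds = c(0.1, 10), activation = NULL) {
  if (!length(profile$expression))
    ts_error("no_expression", sprintf("profile '%s' has an empty expression map",
                                      profile$sample_id))
  reps <- gene_representatives(model)
  missing_ref <- setdiff(unname(reps), names(reference))
  if (length(missing_ref))
    ts_error("missing_reference",
             paste("reference lacks gene(s):", paste(missing_ref, collapse = ", ")))
  back <- function(v) 2^v - 1
  scale <- vapply(names(reps), function(sid) {
    g <- reps[[sid]]
    if (!g %in% names(profile$expression)) {
      ts_warning("missing_gene",
                 sprintf("sample '%s': gene '%s' absent from profile; scale set to 1",
                         profile$sample_id, g))
      return(1)
    }
    clip((back(profile$expression[[g]]) + epsilon) /
           (back(reference[[g]]) + epsilon), bounds[1], bounds[2])
  }, 0)
  activation <- activation %||% default_activation(profile, model)
  structure(list(model = model, synthesis_scale = scale,
                 activation = activation,
                 provenance = list(sample_id = profile$sample_id,
                                   tissue = profile$tissue,
                                   histology = profile$histology,
                                   normalization = "log2(CPM+1), normal-median reference")),
            class = "DigitalTwin")
}

#' Default activation policy
#'
#' CTNNB1/Wnt input: 1.0 for CTNNB1-mutant tumors, 0.6 for other tumors,
#' 0.2 baseline tone for normal tissue. Any other input (the growth-factor
#' tone `GF` in the reference network) sits at 0.5 for every twin.
#'
#' @param profile A [patient_profile()].
#' @param model A `NetworkModel` (for the list of input species).
#' @return Named numeric vector of activation levels in `[0, 1]`.
#' @export
default_activation <- function(profile, model = build_reference_network()) {
  lv <- stats::setNames(rep(0.5, length(model$input_species)), model$input_species)
  if ("CTNNB1" %in% names(lv)) {
    lv[["CTNNB1"]] <-
      if (profile$tissue == "normal") 0.2
      else if (isTRUE(profile$mutations[["CTNNB1"]])) 1.0 else 0.6
  }
  lv
}

#' Set an activation input of a twin
#'
#' During simulation the input species is clamped at `level` times its
#' reference maximum (1 a.u.). Idempotent and pure.
#'
#' @param twin A `DigitalTwin`.
#' @param driver Input species id (e.g. `"CTNNB1"`).
#' @param level Activation level in `[0, 1]`.
#' @return The modified twin.
#' @export
apply_activation <- function(twin, driver, level) {
  if (!driver %in% twin$model$input_species)
    ts_error("unknown_input", sprintf("'%s' is not an input species", driver))
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0, level <= 1)
  twin$activation[[driver]] <- level
  twin
}

#' @export
print.DigitalTwin <- function(x, ...) {
  cat(sprintf("DigitalTwin '%s' (%s): %d synthesis scales, inputs %s\n",
              x$provenance$sample_id, x$provenance$tissue,
              length(x$synthesis_scale),
              paste(sprintf("%s=%.2g", names(x$activation), x$activation),
                    collapse = ", ")))
  invisible(x)
}

#' Build digital twins for a whole cohort
#'
#' Convenience wrapper: normalizes counts, takes the normal-median reference,
#' and individualizes one twin per sample with the default activation policy.
#'
#' @param model A `NetworkModel`.
#' @param counts Gene-by-sample count matrix.
#' @param metadata Data frame with columns `sample_id`, `tissue`,
#'   `histology`, and mutation flag columns (`CTNNB1`, ...).
#' @return Named list of `DigitalTwin` objects.
#' @export
build_cohort_twins <- function(model, counts, metadata) {
  norm <- normalize_expression(counts)
  normals <- metadata$sample_id[metadata$tissue == "normal"]
  if (!length(normals)) ts_error("no_normals", "metadata contains no normal samples")
  ref <- reference_baseline(norm, normals)
  twins <- lapply(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    mut_cols <- intersect(c("CTNNB1", "NFE2L2", "TERT"), names(metadata))
    prof <- patient_profile(md$sample_id, md$tissue,
                            expression = stats::setNames(norm[, md$sample_id],
                                                         rownames(norm)),
                            mutations = stats::setNames(as.logical(md[mut_cols]),
                                                        mut_cols),
                            histology = md$histology)
    individualize(model, prof, ref)
  })
  stats::setNames(twins, metadata$sample_id)
}
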