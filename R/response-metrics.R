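#' Relative viability from readout medians
#'
#' Combines the positive (nuclear MYC:MAX) and negative (active Caspase-3)
#' readouts into a control-normalized viability score: the signed difference
#' `S(C) = pos_C/pos_0 - lambda * neg_C/neg_0`, rescaled so the control is 1
#' and clipped at 0: `rho = max(0, S(C) / (1 - lambda))`.
#'
#' @param pos_C,neg_C Readout medians under treatment (a.u.).
#' @param pos_0,neg_0 Readout medians of the control simulation (> 0).
#' @param lambda Weight of the negative readout, in `[0, 1)`. Default 0.5.
#' @return Relative viability `rho` (dimensionless, control = 1).
#' @export
viability_score <- function(pos_C, neg_C, pos_0, neg_0, lambda = 0.5) {
  if (lambda < 0 || lambda >= 1)
    ts_error("config_error", "lambda must be in [0, 1)")
  if (pos_0 <= 0 || neg_0 <= 0)
    ts_error("invalid_control", "control readouts must be positive")
  S <- pos_C / pos_0 - lambda * neg_C / neg_0
  max(0, S / (1 - lambda))
}

new_dose_response_curve <- function(concentrations, viability) {
  structure(list(concentrations = concentrations, viability = viability),
            class = "DoseResponseCurve")
}

#' Maximal growth inhibition (Emax)
#'
#' `Emax = 100 * (1 - min_C rho(C))`, in percent; a drug is flagged
#' potentially effective when Emax reaches 50% (inclusive cutoff).
#'
#' @param curve A `DoseResponseCurve`.
#' @return List with `Emax` (percent) and `effective` (logical).
#' @export
compute_emax <- function(curve) {
  stopifnot(length(curve$viability) >= 1)
  emax <- 100 * (1 - min(curve$viability))
  list(Emax = emax, effective = emax >= 50)
}

# first crossing of `target` by `y` over log10(conc), linearly interpolated;
# NA when never crossed
log_interp_crossing <- function(conc, y, target) {
  at <- which(y >= target)
  if (!length(at)) return(NA_real_)
  i <- at[1L]
  if (i == 1L) return(conc[1L])
  x1 <- log10(conc[i - 1L]); x2 <- log10(conc[i])
  y1 <- y[i - 1L]; y2 <- y[i]
  if (y2 == y1) return(conc[i])
  10^(x1 + (target - y1) / (y2 - y1) * (x2 - x1))
}

#' Half-maximal effective concentration (EC50)
#'
#' The smallest concentration at which the inhibition `I(C) = 1 - rho(C)`
#' crosses half of the maximal inhibition (`emax / 200` as a fraction),
#' located by linear interpolation in log10 concentration between the
#' bracketing grid points. Undefined (`NA`) when `emax` is 0.
#'
#' @param curve A `DoseResponseCurve`.
#' @param emax Emax percent from [compute_emax()] of the same curve.
#' @return EC50 in nM, or `NA`.
#' @export
compute_ec50 <- function(curve, emax) {
  if (emax <= 0) return(NA_real_)
  log_interp_crossing(curve$concentrations, 1 - curve$viability, emax / 200)
}

#' Normalized growth-rate inhibition value
#'
#' Interprets relative viability `rho` as the treated/control cell-count
#' ratio with control fold-growth `2^n_div` over the assay window, giving
#' the per-division metric `GR = 2 * rho^(1/n_div) - 1`; for `n_div = 1`
#' this is the affine form `GR = 2*rho - 1`. Maps `rho = 1` to 1, perfect
#' cytostasis (`rho = 2^-n_div` per division) to 0, and `rho = 0` to -1.
#'
#' @param rho Relative viability (>= 0).
#' @param n_div Control divisions per assay window (> 0). Default 1.
#' @return GR value in `[-1, 1]` for `rho` in `[0, 1]`.
#' @export
gr_value <- function(rho, n_div = 1) {
  stopifnot(all(rho >= 0), n_div > 0)
  2 * rho^(1 / n_div) - 1
}

#' GR50 and GRmax of a curve
#'
#' `GRmax` is the minimum GR over the dose range; `GR50` is the first
#' log-interpolated concentration at which GR drops to 0.5, `NA` when GR
#' never reaches 0.5.
#'
#' @param curve A `DoseResponseCurve`.
#' @param n_div Control divisions per assay window. Default 1.
#' @return List with `GR50` (nM or `NA`) and `GRmax`.
#' @export
gr_metrics <- function(curve, n_div = 1) {
  gr <- gr_value(curve$viability, n_div)
  list(GR50 = log_interp_crossing(curve$concentrations, -gr, -0.5),
       GRmax = min(gr))
}

#' Summarize a dose-response curve
#'
#' @param curve A `DoseResponseCurve`.
#' @param n_div Control divisions per assay window. Default 1.
#' @return A `DrugResponseSummary` list: `Emax` (percent), `EC50` (nM or
#'   `NA`), `GR50` (nM or `NA`), `GRmax`, `effective`.
#' @export
summarize_curve <- function(curve, n_div = 1) {
  em <- compute_emax(curve)
  grm <- gr_metrics(curve, n_div)
  structure(list(Emax = em$Emax, EC50 = compute_ec50(curve, em$Emax),
                 GR50 = grm$GR50, GRmax = grm$GRmax,
                 effective = em$effective),
            class = "DrugResponseSummary")
}

#' Rank drugs by tumor-versus-normal selectivity
#'
#' Per drug, selectivity is the mean Emax over tumor twins minus the mean
#' Emax over normal twins; drugs are sorted by selectivity descending, with
#' ties broken by mean tumor Emax and then lexicographic name. The per-sample
#' GR50 heatmap table is attached as attribute `"gr50_matrix"` (drugs as
#' rows, samples as columns, `NA` where GR50 is undefined).
#'
#' @param screen A `ScreenResult` from [run_screen()] (or its `results`
#'   data frame) containing both tumor and normal rows.
#' @return Data frame with columns `drug`, `selectivity`, `mean_emax_tumor`,
#'   `mean_emax_normal`, `rank`.
#' @export
rank_drugs <- function(screen) {
  res <- if (inherits(screen, "ScreenResult")) screen$results else screen
  if (!all(c("tumor", "normal") %in% res$tissue))
    ts_error("no_contrast", "screen must contain both tumor and normal twins")
  drugs <- sort(unique(res$drug))
  tab <- do.call(rbind, lapply(drugs, function(d) {
    rd <- res[res$drug == d, ]
    mt <- mean(rd$emax_pct[rd$tissue == "tumor"])
    mn <- mean(rd$emax_pct[rd$tissue == "normal"])
    data.frame(drug = d, selectivity = mt - mn, mean_emax_tumor = mt,
               mean_emax_normal = mn, stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$selectivity, -tab$mean_emax_tumor, tab$drug)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  samples <- sort(unique(res$sample_id))
  gr50 <- matrix(NA_real_, length(drugs), length(samples),
                 dimnames = list(drugs, samples))
  for (i in seq_len(nrow(res)))
    gr50[res$drug[i], res$sample_id[i]] <- res$gr50_nM[i]
  attr(tab, "gr50_matrix") <- gr50[tab$drug, , drop = FALSE]
  tab
}
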