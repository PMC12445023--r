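#' Serial dilution ladder
#'
#' Repeated constant-ratio dilution from a top concentration down to a
#' floor: `top, top/ratio, top/ratio^2, ...`, keeping every dose at or above
#' the floor. The standard plate layout (100 µM top, 1:3 ratio, 5 nM floor)
#' gives 10 doses.
#'
#' @param top Highest concentration.
#' @param ratio Dilution ratio (> 1).
#' @param floor Lowest admissible concentration (same unit as `top`).
#' @return Ascending dose vector (for plating).
#' @export
build_dilution_ladder <- function(top, ratio, floor) {
  if (top < floor) ts_error("invalid_ladder", "top must be >= floor")
  if (ratio <= 1) ts_error("invalid_ladder", "ratio must be > 1")
  n <- base::floor(log(top / floor) / log(ratio) * (1 + 1e-12)) + 1
  sort(top / ratio^(seq_len(n) - 1))
}

#' Assemble a viability plate
#'
#' @param doses Strictly ascending concentration vector.
#' @param viability Replicate-by-dose matrix of control-normalized viability
#'   fractions (a plain vector is treated as a single replicate).
#' @param compound,model_id Tokens identifying compound and cell model.
#' @param class `"tumor"` or `"healthy"`.
#' @param dose_unit Unit label recorded with the doses (default `"nM"`).
#' @return An object of class `"PlateAssay"`.
#' @export
plate_assay <- function(doses, viability, compound = "drug",
                        model_id = "model", class = c("tumor", "healthy"),
                        dose_unit = "nM") {
  class <- match.arg(class)
  if (is.vector(viability)) viability <- matrix(viability, nrow = 1)
  if (any(diff(doses) <= 0))
    ts_error("invalid_plate", "doses must be strictly ascending")
  if (ncol(viability) != length(doses))
    ts_error("invalid_plate", "viability must have one column per dose")
  if (any(!is.finite(viability)))
    ts_error("invalid_plate", "viability must be finite")
  structure(list(doses = doses, viability = viability, compound = compound,
                 model_id = model_id, class = class, dose_unit = dose_unit),
            class = "PlateAssay")
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of `V(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)`
#' to all replicate points, initialized from the data (top = max mean
#' viability, bottom = min, ic50 = dose nearest half-range, hill = 1) and
#' bounded (`top` in \[0.5, 1.5\], `bottom` in \[0, 1\], `hill` in
#' \[0.1, 10\], `ic50` within \[min dose/10, max dose*10\]). The reported
#' IC50 is the 4PL midpoint (relative IC50); `ic50_absolute` additionally
#' gives the concentration where the fitted curve crosses viability 0.5
#' (`NA` when it never does).
#'
#' @param plate A [plate_assay()].
#' @return An object of class `"FitResult"`: `ic50`, `hill`, `top`,
#'   `bottom`, `auc`, `rss`, `converged`, `ic50_absolute`.
#' @export
fit_4pl <- function(plate) {
  doses <- plate$doses
  if (length(doses) < 4) ts_error("invalid_plate", "need >= 4 distinct doses")
  means <- colMeans(plate$viability)
  lower <- c(top = 0.5, bottom = 0, ic50 = min(doses) / 10, hill = 0.1)
  upper <- c(top = 1.5, bottom = 1, ic50 = max(doses) * 10, hill = 10)
  if (means[length(means)] >= means[1]) {
    ts_warning("no_inhibition", sprintf(
      "plate %s/%s shows no viability decrease", plate$model_id, plate$compound))
    fit <- list(top = clip(max(means), 0.5, 1.5), bottom = clip(min(means), 0, 1),
                ic50 = unname(upper["ic50"]), hill = 1, rss = NA_real_,
                converged = FALSE)
    return(finish_4pl(fit, plate))
  }
  start <- c(top = clip(max(means), 0.5, 1.5), bottom = clip(min(means), 0, 1),
             ic50 = doses[which.min(abs(means - (max(means) + min(means)) / 2))],
             hill = 1)
  df <- data.frame(c = rep(doses, each = nrow(plate$viability)),
                   v = as.vector(plate$viability))
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + (c / ic50)^hill), data = df,
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- as.list(stats::coef(m))
    c(cf, list(rss = sum(stats::residuals(m)^2), converged = TRUE))
  }, error = function(e) {
    c(as.list(start), list(rss = NA_real_, converged = FALSE))
  })
  finish_4pl(fit, plate)
}

finish_4pl <- function(fit, plate) {
  pred <- function(c) fit$bottom + (fit$top - fit$bottom) / (1 + (c / fit$ic50)^fit$hill)
  abs50 <- if (fit$bottom < 0.5 && fit$top > 0.5)
    fit$ic50 * ((fit$top - fit$bottom) / (0.5 - fit$bottom) - 1)^(1 / fit$hill)
  else NA_real_
  structure(list(ic50 = unname(fit$ic50), hill = unname(fit$hill),
                 top = unname(fit$top), bottom = unname(fit$bottom),
                 auc = compute_auc(plate), rss = fit$rss,
                 converged = fit$converged, ic50_absolute = abs50,
                 dose_unit = plate$dose_unit, compound = plate$compound,
                 model_id = plate$model_id, class = plate$class,
                 fitted = pred),
            class = "FitResult")
}

#' Normalized dose-response AUC
#'
#' Trapezoidal integral of the mean viability over log10 dose, divided by
#' the log10 span, so a flat plate at viability `v` has AUC `v` and values
#' are comparable across compounds with different dose ranges. Lower AUC
#' means greater sensitivity.
#'
#' @param plate A [plate_assay()], or an ascending dose vector.
#' @param viability Mean viability per dose (when `plate` is a dose vector).
#' @return Normalized AUC.
#' @export
compute_auc <- function(plate, viability = NULL) {
  if (inherits(plate, "PlateAssay")) {
    doses <- plate$doses
    viability <- colMeans(plate$viability)
  } else doses <- plate
  if (length(doses) < 2) ts_error("invalid_plate", "AUC needs >= 2 doses")
  x <- log10(doses)
  sum(diff(x) * (utils::head(viability, -1) + utils::tail(viability, -1)) / 2) /
    (max(x) - min(x))
}

#' AUC z-scores across a model panel
#'
#' `z_i = (AUC_i - mean AUC) / SD` with the sample (n-1) standard deviation.
#'
#' @param aucs Named numeric vector mapping model id to AUC (>= 2 entries).
#' @return Named vector of z-scores (mean 0, sample SD 1).
#' @export
zscore_auc <- function(aucs) {
  if (length(aucs) < 2) ts_error("degenerate_panel", "need >= 2 models")
  s <- stats::sd(aucs)
  if (!is.finite(s) || s == 0)
    ts_error("degenerate_panel", "AUCs are identical; z-scores undefined")
  (aucs - mean(aucs)) / s
}

#' Therapeutic window score
#'
#' `TWS = mean(AUC of healthy controls) / mean(AUC of tumor models)`;
#' values above 1 indicate tumor selectivity.
#'
#' @param aucs_healthy,aucs_tumor Non-empty AUC vectors.
#' @return TWS (dimensionless).
#' @export
therapeutic_window <- function(aucs_healthy, aucs_tumor) {
  stopifnot(length(aucs_healthy) >= 1, length(aucs_tumor) >= 1)
  mt <- mean(aucs_tumor)
  if (mt == 0) ts_error("zero_tumor_auc", "mean tumor AUC is zero")
  mean(aucs_healthy) / mt
}

#' Bliss independence synergy analysis
#'
#' For a 4x4 inhibition grid whose first row and column hold the
#' single-agent responses (with the (0,0) control), the Bliss reference for
#' a combination is `expected = y_a + y_b - y_a*y_b` from the single-agent
#' margins; the excess is `observed - expected` on the 3x3 combination
#' block (0 on the margins by definition) and the summary score is
#' `100 * mean(excess)`. Positive scores indicate synergy.
#'
#' @param inhibition 4x4 matrix of fractional inhibition, dose A in rows,
#'   dose B in columns, first row/column the single agents. Values outside
#'   \[-0.05, 1.05\] trigger an `out_of_range` warning before clipping to
#'   \[0, 1\].
#' @param doses_a,doses_b Optional 4-point dose vectors (first element 0).
#' @return An object of class `"SynergyMatrix"`: `inhibition` (clipped),
#'   `expected`, `bliss_excess`, `score`.
#' @export
bliss_synergy <- function(inhibition, doses_a = NULL, doses_b = NULL) {
  inhibition <- as.matrix(inhibition)
  if (!all(dim(inhibition) == c(4, 4)))
    ts_error("invalid_grid", "inhibition must be a 4x4 matrix")
  if (any(inhibition < -0.05) || any(inhibition > 1.05))
    ts_warning("out_of_range", "inhibition outside [-0.05, 1.05]; clipping")
  inh <- clip(inhibition, 0, 1)
  ya <- inh[, 1]; yb <- inh[1, ]
  expected <- outer(ya, yb, function(a, b) a + b - a * b)
  excess <- inh - expected
  excess[1, ] <- 0; excess[, 1] <- 0
  structure(list(doses_a = doses_a, doses_b = doses_b, inhibition = inh,
                 expected = expected, bliss_excess = excess,
                 score = 100 * mean(excess[2:4, 2:4])),
            class = "SynergyMatrix")
}

#' Wound closure percentage
#'
#' `closure = 100 * (gap0 - gap1) / gap0`, the percentage of the initial
#' wound gap closed by the follow-up time point.
#'
#' @param gap0 Initial wound gap width (µm, > 0).
#' @param gap1 Follow-up gap width (µm, >= 0).
#' @return Percent closure.
#' @export
wound_closure <- function(gap0, gap1) {
  if (any(gap0 <= 0)) ts_error("invalid_measurement", "gap0 must be > 0")
  if (any(gap1 < 0)) ts_error("invalid_measurement", "gap1 must be >= 0")
  100 * (gap0 - gap1) / gap0
}

#' Nuclear circularity index
#'
#' `CI = 4 * pi * area / perimeter^2`: 1 for a circle, smaller for
#' elongated or irregular contours.
#'
#' @param area Contour area (µm^2, > 0).
#' @param perimeter Contour perimeter (µm, > 0).
#' @return Circularity index.
#' @export
circularity_index <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    ts_error("invalid_measurement", "area and perimeter must be > 0")
  4 * pi * area / perimeter^2
}

#' Xenograft tumor volume
#'
#' `TV (mm^3) = length * width^2 / 2`, with length the longer caliper axis;
#' inputs given the other way around are swapped with a warning.
#'
#' @param length,width Caliper measurements in mm (> 0).
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    ts_error("invalid_measurement", "length and width must be > 0")
  if (any(width > length)) {
    ts_warning("axis_swap", "width > length; axes swapped")
    swap <- width > length
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Positive-fraction count readout
#'
#' Fraction of positively stained nuclei among all counted nuclei (e.g.
#' EdU- or Ki67-positive over Hoechst-counterstained).
#'
#' @param n_positive,n_total Counts with `0 <= n_positive <= n_total`,
#'   `n_total > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0) || any(n_positive < 0) || any(n_positive > n_total))
    ts_error("invalid_counts", "need 0 <= n_positive <= n_total, n_total > 0")
  n_positive / n_total
}
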