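#' Fit a run-order drift curve on BQC areas
#'
#' Instrument response drifts slowly over an LC-MS batch; the pooled batch
#' QC (BQC) injections, being replicates of one material, expose that drift
#' directly. The curve is a loess fit (span 0.75, degree 1, tricube weights)
#' of log2 BQC areas on run order. Prediction is defined for every run order
#' in the batch: inside the BQC range the loess surface is evaluated on a
#' unit grid, and beyond the first/last BQC the curve continues linearly
#' with the boundary slope.
#'
#' At least 4 non-missing BQC points are required; with fewer, no curve can
#' be anchored and `NULL` is returned (the species then keeps its
#' uncorrected values). Constant input yields a constant curve and exactly
#' collinear input is reproduced by the degree-1 fit.
#'
#' @param run_order run-order positions of the BQC injections.
#' @param log2_area log2 peak areas at those positions (NA allowed).
#' @param span loess span; default 0.75.
#' @return a function mapping run order to fitted log2 area, or `NULL` when
#'   fewer than 4 usable points exist.
#' @export
fit_drift_curve <- function(run_order, log2_area, span = 0.75) {
  keep <- !is.na(log2_area) & !is.na(run_order)
  run_order <- run_order[keep]
  log2_area <- log2_area[keep]
  if (any(!is.finite(log2_area)) || any(!is.finite(run_order)))
    stop("drift fitting requires finite run orders and log2 areas",
         call. = FALSE)
  if (length(run_order) < 4) return(NULL)
  ord <- order(run_order)
  run_order <- run_order[ord]
  log2_area <- log2_area[ord]
  # near-collinear neighbourhoods on few BQC points make loess warn while
  # still returning the correct local fit; degenerate outcomes are caught
  # by the CV acceptance rule downstream
  fit <- suppressWarnings(
    stats::loess(log2_area ~ run_order, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  lo <- min(run_order)
  hi <- max(run_order)
  grid <- seq(floor(lo), ceiling(hi), by = 1)
  grid_fit <- suppressWarnings(
    stats::predict(fit, data.frame(run_order = grid)))
  # boundary slopes for linear extrapolation beyond the BQC range
  slope_lo <- if (length(grid) > 1)
    (grid_fit[2] - grid_fit[1]) / (grid[2] - grid[1]) else 0
  slope_hi <- if (length(grid) > 1)
    (grid_fit[length(grid)] - grid_fit[length(grid) - 1]) /
      (grid[length(grid)] - grid[length(grid) - 1]) else 0
  function(x) {
    y <- stats::approx(grid, grid_fit, xout = x, rule = 2)$y
    below <- !is.na(x) & x < grid[1]
    above <- !is.na(x) & x > grid[length(grid)]
    y[below] <- grid_fit[1] + slope_lo * (x[below] - grid[1])
    y[above] <- grid_fit[length(grid)] + slope_hi * (x[above] - grid[length(grid)])
    y
  }
}

#' BQC-anchored drift correction with a CV acceptance rule
#'
#' Per species: fit the BQC drift curve, subtract it from every injection's
#' log2 area, and re-centre so the median BQC level is exactly preserved
#' and corrected areas stay on the original scale (the correction removes
#' the shape of the drift, not the signal level, so downstream raw-area
#' thresholds keep their meaning). The
#' correction is kept only where it earns its keep: the study-sample CV
#' (linear scale) must drop by more than `cv_gain_percent` percentage points
#' (default 2, strict inequality); otherwise the species reverts to its
#' uncorrected values. Non-positive and missing areas are excluded from
#' fitting and stay missing after correction.
#'
#' @param areas an `area_matrix` at stage `"isotope_corrected"` (a `"raw"`
#'   matrix is accepted when no isotopic correction applies).
#' @param samples a `sample_sheet` covering the matrix rows.
#' @param span loess span.
#' @param cv_gain_percent required CV reduction in percentage points.
#' @return list with `areas` (stage `"drift_corrected"`) and `decisions`, a
#'   data frame per species: `cv_before_percent`, `cv_after_percent`,
#'   `applied`, `span`, `flag` (`""`, or `"too_few_bqcs"`).
#' @export
apply_drift_correction <- function(areas, samples, span = 0.75,
                                   cv_gain_percent = 2) {
  m <- advance_stage(areas, from = c("raw", "isotope_corrected"),
                     to = "drift_corrected")
  idx <- match(rownames(m), samples$sample_id)
  if (anyNA(idx))
    stop("area matrix contains samples absent from the annotation",
         call. = FALSE)
  run_order <- samples$run_order[idx]
  is_bqc <- samples$sample_type[idx] == "BQC"
  is_spl <- samples$sample_type[idx] == "SPL"

  out <- m
  decisions <- data.frame(
    species_id = colnames(m), cv_before_percent = NA_real_,
    cv_after_percent = NA_real_, applied = FALSE, span = span,
    flag = "", stringsAsFactors = FALSE)

  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    usable <- !is.na(v) & v > 0
    log2v <- ifelse(usable, log2(v), NA_real_)
    cv_before <- cv_percent(v[is_spl & usable])
    decisions$cv_before_percent[j] <- cv_before
    curve <- fit_drift_curve(run_order[is_bqc], log2v[is_bqc], span = span)
    if (is.null(curve)) {
      decisions$flag[j] <- "too_few_bqcs"
      next
    }
    # recentre so the BQC median level is preserved exactly: the
    # correction removes the drift's shape, not the signal level
    bqc_use <- is_bqc & usable
    resid_bqc <- log2v[bqc_use] - curve(run_order[bqc_use])
    centre <- stats::median(log2v[bqc_use]) - stats::median(resid_bqc)
    corrected <- 2^(log2v - curve(run_order) + centre)
    cv_after <- cv_percent(corrected[is_spl])
    decisions$cv_after_percent[j] <- cv_after
    keep <- !is.na(cv_before) && !is.na(cv_after) &&
      (cv_before - cv_after) > cv_gain_percent
    decisions$applied[j] <- keep
    if (keep) out[, j] <- corrected  # zeros became NA via log2 masking
  }
  list(areas = area_matrix(out, stage = "drift_corrected"),
       decisions = decisions)
}
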