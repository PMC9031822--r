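#' Normalize analyte areas to class-specific internal standards
#'
#' Default (per-sample) mode divides each analyte area by the area of its
#' class ISTD in the same injection, cancelling injection-to-injection
#' response variation the ISTD shares with its class. When the ISTD signal
#' is itself noisy, per-sample division injects that noise instead of
#' removing any, so a fallback divides by the average ISTD area over the
#' BQC injections. The mode is chosen per lipid class: per-sample
#' normalization is kept unless it increases the study-sample CV relative
#' to the fallback, judged by the median SPL CV across the class's species
#' (ties go to per-sample).
#'
#' @param areas an `area_matrix` at stage `"drift_corrected"`.
#' @param panel a `lipid_panel` (ISTD columns must be present in `areas`).
#' @param samples a `sample_sheet`.
#' @return list with `areas` (stage `"normalized"`, analyte columns only),
#'   `decisions` (per class: `mode`, `spl_cv_per_sample_percent`,
#'   `spl_cv_fallback_percent`), and `n_missing_istd` (cells dropped
#'   because the per-sample ISTD area was zero or missing).
#' @export
normalize_to_istd <- function(areas, panel, samples) {
  m <- advance_stage(areas, from = "drift_corrected", to = "normalized")
  istds <- panel_istds(panel)
  analytes <- panel_analytes(panel)
  analytes <- analytes[analytes$species_id %in% colnames(m), , drop = FALSE]
  idx <- match(rownames(m), samples$sample_id)
  is_spl <- samples$sample_type[idx] == "SPL"
  is_bqc <- samples$sample_type[idx] == "BQC"

  out <- matrix(NA_real_, nrow(m), nrow(analytes),
                dimnames = list(rownames(m), analytes$species_id))
  decisions <- data.frame(lipid_class = character(0), mode = character(0),
                          spl_cv_per_sample_percent = numeric(0),
                          spl_cv_fallback_percent = numeric(0),
                          stringsAsFactors = FALSE)
  n_missing_istd <- 0L

  for (cls in unique(analytes$lipid_class)) {
    sp_ids <- analytes$species_id[analytes$lipid_class == cls]
    istd_id <- unique(analytes$istd_id[analytes$lipid_class == cls])
    if (!istd_id %in% colnames(m))
      stop("ISTD '", istd_id, "' for class '", cls,
           "' is absent from the area matrix", call. = FALSE)
    istd_area <- m[, istd_id]
    istd_bqc_mean <- mean(istd_area[is_bqc], na.rm = TRUE)
    if (sum(!is.na(istd_area[is_bqc])) < 3)
      stop("class '", cls, "': ISTD needs non-missing areas in >= 3 BQCs",
           call. = FALSE)
    istd_ps <- istd_area
    bad <- is.na(istd_ps) | istd_ps <= 0
    istd_ps[bad] <- NA_real_

    per_sample <- m[, sp_ids, drop = FALSE] / istd_ps
    fallback <- m[, sp_ids, drop = FALSE] / istd_bqc_mean
    cv_ps <- stats::median(apply(per_sample[is_spl, , drop = FALSE], 2,
                                 cv_percent), na.rm = TRUE)
    cv_fb <- stats::median(apply(fallback[is_spl, , drop = FALSE], 2,
                                 cv_percent), na.rm = TRUE)
    use_fallback <- is.finite(cv_ps) && is.finite(cv_fb) && cv_ps > cv_fb
    if (use_fallback) {
      out[, sp_ids] <- fallback
    } else {
      out[, sp_ids] <- per_sample
      n_missing_istd <- n_missing_istd +
        sum(bad & rowSums(!is.na(m[, sp_ids, drop = FALSE])) > 0)
    }
    decisions <- rbind(decisions, data.frame(
      lipid_class = cls,
      mode = if (use_fallback) "bqc_average_istd" else "per_sample_istd",
      spl_cv_per_sample_percent = cv_ps, spl_cv_fallback_percent = cv_fb,
      stringsAsFactors = FALSE))
  }
  if (n_missing_istd > 0)
    warning(n_missing_istd,
            " sample(s) had zero/missing ISTD area under per-sample ",
            "normalization; affected cells set to missing", call. = FALSE)
  list(areas = area_matrix(out, stage = "normalized"),
       decisions = decisions, n_missing_istd = n_missing_istd)
}

#' Convert ISTD ratios to concentrations in micromol/L serum
#'
#' One-point class calibration: the analyte/ISTD ratio times the spiked ISTD
#' amount gives pmol analyte per processed sample, and dividing by the serum
#' volume gives pmol/uL, which is numerically umol/L. Response factors are
#' assumed to be 1 (the class ISTD is taken as representative of its class),
#' so, as in any one-point ISTD scheme, the results are relative
#' quantifications on a concentration scale rather than absolute amounts.
#'
#' @param normalized an `area_matrix` at stage `"normalized"`.
#' @param panel a `lipid_panel`.
#' @param samples a `sample_sheet` providing `serum_volume_uL` per sample.
#' @return an `area_matrix` at stage `"concentration"` (umol/L serum).
#' @export
to_concentration <- function(normalized, panel, samples) {
  m <- advance_stage(normalized, from = "normalized", to = "concentration")
  analytes <- panel_analytes(panel)
  amount <- panel$amount_pmol_per_sample[match(analytes$istd_id,
                                               panel$species_id)]
  names(amount) <- analytes$species_id
  idx <- match(rownames(m), samples$sample_id)
  vol <- samples$serum_volume_uL[idx]
  if (any(is.na(vol)) || any(vol <= 0))
    stop("every sample needs a positive serum_volume_uL", call. = FALSE)
  for (sp in colnames(m))
    m[, sp] <- m[, sp] * amount[[sp]] / vol
  area_matrix(m, stage = "concentration")
}
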