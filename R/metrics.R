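#' Lipid-class totals and derived ratio metrics
#'
#' Per sample: the total concentration of each lipid class (sum over its
#' QC-passing species, umol/L), total cholesteryl esters, the ratio of
#' esterified to total cholesterol (total CE converted to mmol/L over the
#' clinical total-cholesterol value), and the three ceramide risk ratios
#' used in cardiovascular scoring — Cer d18:1/16:0, /18:0 and /24:1, each
#' divided by Cer d18:1/24:0. Species removed by QC contribute nothing to a
#' class total; the number of species actually summed per class is reported
#' so totals built from different survivor sets are never compared blindly.
#' Ratios are reported missing when the denominator species is absent from
#' the panel or not positive in a sample.
#'
#' @param conc filtered `area_matrix` at stage `"concentration"`.
#' @param panel a `lipid_panel`.
#' @param samples a `sample_sheet` (clinical TC in mmol/L feeds the CE/TC
#'   ratio).
#' @return list with `class_totals` (samples x classes data frame, umol/L),
#'   `metrics` (per-sample CE total, CE/TC ratio, ceramide ratios),
#'   `n_species_summed` (per class).
#' @export
derive_metrics <- function(conc, panel, samples) {
  stopifnot(area_stage(conc) == "concentration")
  analytes <- panel_analytes(panel)
  analytes <- analytes[analytes$species_id %in% colnames(conc), , drop = FALSE]
  classes <- sort(unique(analytes$lipid_class))
  m <- unclass(conc)

  totals <- sapply(classes, function(cls) {
    sp <- analytes$species_id[analytes$lipid_class == cls]
    rowSums(m[, sp, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = nrow(m),
                                             dimnames = list(rownames(m), classes))
  n_summed <- vapply(classes, function(cls)
    sum(analytes$lipid_class == cls), integer(1))

  class_totals <- data.frame(sample_id = rownames(m), totals,
                             check.names = FALSE, stringsAsFactors = FALSE)

  ce_cols <- analytes$species_id[analytes$lipid_class == "CE"]
  total_ce <- if (length(ce_cols))
    rowSums(m[, ce_cols, drop = FALSE], na.rm = TRUE) else rep(NA_real_, nrow(m))
  tc <- samples$clinical_tc_mmolL[match(rownames(m), samples$sample_id)]
  ce_tc_ratio <- ifelse(!is.na(tc) & tc > 0, (total_ce / 1000) / tc, NA_real_)

  cer_ratio <- function(num_id, den_id) {
    if (!num_id %in% colnames(m) || !den_id %in% colnames(m))
      return(rep(NA_real_, nrow(m)))
    den <- m[, den_id]
    ifelse(!is.na(den) & den > 0, m[, num_id] / den, NA_real_)
  }
  metrics <- data.frame(
    sample_id = rownames(m),
    total_ce_umolL = total_ce,
    ce_tc_ratio = ce_tc_ratio,
    cer_ratio_16_24 = cer_ratio("Cer d18:1/16:0", "Cer d18:1/24:0"),
    cer_ratio_18_24 = cer_ratio("Cer d18:1/18:0", "Cer d18:1/24:0"),
    cer_ratio_241_24 = cer_ratio("Cer d18:1/24:1", "Cer d18:1/24:0"),
    stringsAsFactors = FALSE)

  list(class_totals = class_totals, metrics = metrics,
       n_species_summed = n_summed)
}
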