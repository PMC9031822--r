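#' Four-criterion QC filter for lipid species
#'
#' A species is kept for analysis only if all four hold:
#' \enumerate{
#'   \item signal-to-blank ratio > 5, where the ratio is the median BQC raw
#'     area over the median process-blank raw area (a blank median of zero
#'     means no detectable background, the ratio is infinite and the
#'     criterion passes);
#'   \item median BQC raw peak area > 500 (area counts);
#'   \item analytical CV < 25 percent, computed on normalized BQC values;
#'   \item linear response over the RQC dilution ladder: R-squared of an
#'     ordinary least-squares fit of (drift-corrected) RQC area on the
#'     dilution fraction > 0.8. Without RQC injections this criterion
#'     cannot be evaluated; the species is flagged and the criterion does
#'     not count against it.
#' }
#' Criteria (i)-(ii) are judged on raw areas (background and detector counts
#' are area-domain quantities), (iii) on normalized values as the analytical
#' precision the data carry into analysis, and (iv) on drift-corrected areas
#' so slow sensitivity changes do not mask true response linearity.
#'
#' @param raw `area_matrix`, stage `"raw"`.
#' @param corrected `area_matrix`, stage `"drift_corrected"`.
#' @param normalized `area_matrix`, stage `"normalized"`.
#' @param conc `area_matrix`, stage `"concentration"`.
#' @param samples a `sample_sheet`; needs >= 3 BQC and >= 1 PBLK.
#' @param min_signal_blank,min_raw_area,max_bqc_cv,min_rqc_r2 thresholds;
#'   defaults 5, 500, 25, 0.8.
#' @param raw_area_basis `"bqc_median"` (default) or `"spl_min"` for
#'   criterion (ii).
#' @return list with `decisions` (per species: criterion values,
#'   `passed`, `failed_criteria` as a comma-separated string) and `conc`,
#'   the concentration matrix restricted to passing species.
#' @export
qc_filter <- function(raw, corrected, normalized, conc, samples,
                      min_signal_blank = 5, min_raw_area = 500,
                      max_bqc_cv = 25, min_rqc_r2 = 0.8,
                      raw_area_basis = c("bqc_median", "spl_min")) {
  raw_area_basis <- match.arg(raw_area_basis)
  stopifnot(area_stage(raw) == "raw",
            area_stage(corrected) == "drift_corrected",
            area_stage(normalized) == "normalized",
            area_stage(conc) == "concentration")
  bqc <- ids_of_type(samples, "BQC")
  pblk <- ids_of_type(samples, "PBLK")
  rqc <- ids_of_type(samples, "RQC")
  spl <- ids_of_type(samples, "SPL")
  if (length(bqc) < 3)
    stop("QC filtering needs at least 3 BQC injections", call. = FALSE)
  if (length(pblk) < 1)
    stop("QC filtering needs at least one process blank", call. = FALSE)

  species <- colnames(conc)
  dec <- data.frame(
    species_id = species, signal_to_blank = NA_real_,
    median_bqc_raw_area = NA_real_, bqc_cv_percent = NA_real_,
    rqc_r2 = NA_real_, passed = FALSE, failed_criteria = "",
    stringsAsFactors = FALSE)
  dil <- samples$dilution_fraction[match(rqc, samples$sample_id)]

  for (k in seq_along(species)) {
    sp <- species[k]
    med_bqc <- stats::median(raw[bqc, sp], na.rm = TRUE)
    med_blank <- stats::median(raw[pblk, sp], na.rm = TRUE)
    s2b <- if (!is.na(med_blank) && med_blank == 0) Inf else med_bqc / med_blank
    raw_crit <- if (raw_area_basis == "bqc_median") med_bqc
                else suppressWarnings(min(raw[spl, sp], na.rm = TRUE))
    bqc_cv <- cv_percent(normalized[bqc, sp])
    r2 <- if (length(rqc) >= 3) rqc_linearity_r2(corrected[rqc, sp], dil)
          else NA_real_

    fails <- character(0)
    if (!isTRUE(s2b > min_signal_blank)) fails <- c(fails, "signal_to_blank")
    if (!isTRUE(raw_crit > min_raw_area)) fails <- c(fails, "raw_area")
    if (!isTRUE(bqc_cv < max_bqc_cv)) fails <- c(fails, "bqc_cv")
    if (!is.na(r2) && !isTRUE(r2 > min_rqc_r2)) fails <- c(fails, "rqc_r2")

    dec$signal_to_blank[k] <- s2b
    dec$median_bqc_raw_area[k] <- med_bqc
    dec$bqc_cv_percent[k] <- bqc_cv
    dec$rqc_r2[k] <- r2
    dec$failed_criteria[k] <- paste(fails, collapse = ",")
    dec$passed[k] <- length(fails) == 0
  }
  keep <- dec$species_id[dec$passed]
  list(decisions = dec,
       conc = area_matrix(unclass(conc)[, keep, drop = FALSE],
                          stage = "concentration"))
}

# coefficient of determination of OLS area ~ dilution fraction (with
# intercept, so R^2 reduces to the squared correlation)
rqc_linearity_r2 <- function(area, dilution) {
  ok <- !is.na(area) & !is.na(dilution)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(area[ok]) == 0 || stats::sd(dilution[ok]) == 0)
    return(NA_real_)
  stats::cor(area[ok], dilution[ok])^2
}
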