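#' Run the full post-processing pipeline on one batch
#'
#' Chains the processing stages in their fixed order: isotopic
#' co-integration correction, BQC-anchored drift correction (optional),
#' class-ISTD normalization with the conditional BQC-average fallback,
#' conversion to micromol/L serum, four-criterion QC filtering, and the
#' derived class totals and ratio metrics. Inputs can be a simulated batch
#' (`lipid_sim`) or the three tables read from disk.
#'
#' @param areas raw `area_matrix`, or a `lipid_sim` (then `panel` and
#'   `samples` are taken from it).
#' @param panel a `lipid_panel` (ignored for a `lipid_sim`).
#' @param samples a `sample_sheet` (ignored for a `lipid_sim`).
#' @param drift_correction apply the drift-correction stage; when `FALSE`
#'   the stage is skipped (every species keeps its uncorrected areas) but
#'   the stage label still advances.
#' @param span,cv_gain_percent drift-correction parameters, see
#'   [apply_drift_correction()].
#' @param qc_thresholds named list overriding [qc_filter()] thresholds
#'   (`min_signal_blank`, `min_raw_area`, `max_bqc_cv`, `min_rqc_r2`).
#' @return list of class `lipid_pipeline`: the matrices of every stage
#'   (`raw`, `isotope_corrected`, `drift_corrected`, `normalized`, `conc`,
#'   `conc_filtered`), the decision tables (`isotope_records`,
#'   `drift_decisions`, `normalization_decisions`, `qc_decisions`),
#'   `class_totals`, `metrics`, `n_species_summed`, `panel`, `samples`.
#' @export
run_pipeline <- function(areas, panel = NULL, samples = NULL,
                         drift_correction = TRUE, span = 0.75,
                         cv_gain_percent = 2, qc_thresholds = list()) {
  if (inherits(areas, "lipid_sim")) {
    panel <- areas$panel
    samples <- areas$samples
    areas <- areas$areas
  }
  iso <- correct_isotopes(areas, panel)
  if (drift_correction) {
    dr <- apply_drift_correction(iso$areas, samples, span = span,
                                 cv_gain_percent = cv_gain_percent)
  } else {
    dr <- list(areas = area_matrix(unclass(iso$areas),
                                   stage = "drift_corrected"),
               decisions = NULL)
  }
  nr <- normalize_to_istd(dr$areas, panel, samples)
  conc <- to_concentration(nr$areas, panel, samples)
  qc_args <- c(list(raw = areas, corrected = dr$areas,
                    normalized = nr$areas, conc = conc, samples = samples),
               qc_thresholds)
  qc <- do.call(qc_filter, qc_args)
  dm <- derive_metrics(qc$conc, panel, samples)
  structure(list(
    raw = areas, isotope_corrected = iso$areas, drift_corrected = dr$areas,
    normalized = nr$areas, conc = conc, conc_filtered = qc$conc,
    isotope_records = iso$records, drift_decisions = dr$decisions,
    normalization_decisions = nr$decisions, qc_decisions = qc$decisions,
    class_totals = dm$class_totals, metrics = dm$metrics,
    n_species_summed = dm$n_species_summed,
    panel = panel, samples = samples), class = "lipid_pipeline")
}

#' Relative error of recovered concentrations against simulation truth
#'
#' Compares the pipeline's filtered study-sample concentrations with the
#' generator's ground truth, pairing on sample and species ids. Used for
#' parameter-recovery validation.
#'
#' @param pipeline a `lipid_pipeline` from [run_pipeline()].
#' @param sim the `lipid_sim` the pipeline was run on.
#' @return numeric vector of |recovered - true| / true over all paired
#'   study-sample cells with positive truth.
#' @export
recovery_errors <- function(pipeline, sim) {
  truth <- sim$truth$true_conc_umolL
  conc <- pipeline$conc_filtered
  spl <- intersect(ids_of_type(sim$samples, "SPL"), rownames(conc))
  sp <- intersect(colnames(truth), colnames(conc))
  tr <- truth[spl, sp, drop = FALSE]
  rc <- unclass(conc)[spl, sp, drop = FALSE]
  ok <- !is.na(rc) & !is.na(tr) & tr > 0
  abs(rc[ok] - tr[ok]) / tr[ok]
}
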