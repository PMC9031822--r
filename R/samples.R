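#' Read and validate a sample annotation sheet
#'
#' One row per injection. `sample_type` uses the run-design vocabulary:
#' `SPL` study sample, `BQC` pooled batch quality control, `RQC` response QC
#' (serial dilution of pooled extract), `PBLK` process blank. Run order must
#' be unique within a batch, every RQC needs a `dilution_fraction` in (0, 1],
#' every study sample needs a `group` (`HB` healthy, `HT` hypothyroid,
#' `CS` Cushing's syndrome), and blanks carry no group. Records are returned
#' sorted by `(batch_id, run_order)`.
#'
#' @param path CSV with columns `sample_id, sample_type, run_order, batch_id,
#'   dilution_fraction, group, serum_volume_uL, clinical_tc_mmolL,
#'   clinical_tg_mmolL`.
#' @return a `sample_sheet` data frame.
#' @export
read_samples <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "sample_type", "run_order", "batch_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("sample annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(tab$dilution_fraction)) tab$dilution_fraction <- NA_real_
  if (is.null(tab$group)) tab$group <- NA_character_
  if (is.null(tab$serum_volume_uL)) tab$serum_volume_uL <- 10
  if (is.null(tab$clinical_tc_mmolL)) tab$clinical_tc_mmolL <- NA_real_
  if (is.null(tab$clinical_tg_mmolL)) tab$clinical_tg_mmolL <- NA_real_
  tab$group[!nzchar(trimws(ifelse(is.na(tab$group), "", tab$group)))] <-
    NA_character_
  validate_samples(tab)
}

SAMPLE_TYPES <- c("SPL", "BQC", "RQC", "PBLK")
GROUPS <- c("HB", "HT", "CS")

validate_samples <- function(tab) {
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in annotation", call. = FALSE)
  bad_type <- setdiff(unique(tab$sample_type), SAMPLE_TYPES)
  if (length(bad_type))
    stop("unknown sample_type (expected SPL/BQC/RQC/PBLK): ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  dup_ro <- tapply(tab$run_order, tab$batch_id, anyDuplicated)
  if (any(dup_ro > 0))
    stop("duplicate run_order within batch: ",
         paste(names(dup_ro)[dup_ro > 0], collapse = ", "), call. = FALSE)
  rqc <- tab$sample_type == "RQC"
  if (any(is.na(tab$dilution_fraction[rqc])))
    stop("every RQC needs a dilution_fraction", call. = FALSE)
  if (any(tab$dilution_fraction[rqc] <= 0 | tab$dilution_fraction[rqc] > 1))
    stop("RQC dilution_fraction must lie in (0, 1]", call. = FALSE)
  tab$dilution_fraction[!rqc] <- 1
  spl <- tab$sample_type == "SPL"
  if (any(is.na(tab$group[spl])))
    stop("every study sample (SPL) needs a group", call. = FALSE)
  bad_grp <- setdiff(unique(tab$group[spl]), GROUPS)
  if (length(bad_grp))
    stop("unknown group (expected HB/HT/CS): ",
         paste(bad_grp, collapse = ", "), call. = FALSE)
  if (any(!is.na(tab$group[tab$sample_type == "PBLK"])))
    stop("process blanks must not carry a group", call. = FALSE)
  if (any(tab$serum_volume_uL <= 0))
    stop("serum_volume_uL must be positive", call. = FALSE)
  tab <- tab[order(tab$batch_id, tab$run_order), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("sample_sheet", "data.frame")
  tab
}

#' @rdname read_samples
#' @param samples a `sample_sheet`.
#' @param path output CSV file.
#' @export
write_samples <- function(samples, path) {
  write_csv_full(as.data.frame(samples), path)
  invisible(path)
}

# sample ids of one type, in run order
ids_of_type <- function(samples, type) {
  samples$sample_id[samples$sample_type == type]
}
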