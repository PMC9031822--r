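#' Peak-area matrices with a processing stage
#'
#' An `area_matrix` is a numeric samples-by-species matrix carrying a `stage`
#' attribute that records how far along the processing chain the values are.
#' Stages move forward only, in the order
#' `raw -> isotope_corrected -> drift_corrected -> normalized -> concentration`.
#' Values are non-negative; `NA` marks a missing (non-integrated) area.
#' Units are area counts up to `drift_corrected`, a dimensionless
#' analyte/ISTD ratio at `normalized`, and micromol/L serum at
#' `concentration`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   species in columns (colnames = species ids).
#' @param stage one of `"raw"`, `"isotope_corrected"`, `"drift_corrected"`,
#'   `"normalized"`, `"concentration"`.
#' @return `values` with class `area_matrix` and the stage recorded.
#' @export
area_matrix <- function(values, stage = "raw") {
  stage <- match.arg(stage, AREA_STAGES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("area_matrix values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("area_matrix needs sample ids as rownames and species ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("area_matrix sample and species ids must be unique", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("area_matrix values must be non-negative (use NA for missing)",
         call. = FALSE)
  structure(values, stage = stage, class = c("area_matrix", "matrix", "array"))
}

AREA_STAGES <- c("raw", "isotope_corrected", "drift_corrected",
                 "normalized", "concentration")

#' @rdname area_matrix
#' @param x an `area_matrix`.
#' @export
area_stage <- function(x) attr(x, "stage")

# checks the stage transition moves forward; returns a plain matrix copy
advance_stage <- function(x, from, to) {
  if (!inherits(x, "area_matrix"))
    stop("expected an area_matrix", call. = FALSE)
  cur <- area_stage(x)
  if (!cur %in% from)
    stop(sprintf("expected stage %s, got '%s'",
                 paste(sQuote(from), collapse = " or "), cur), call. = FALSE)
  if (match(to, AREA_STAGES) <= min(match(cur, AREA_STAGES)))
    stop("stage transitions must move forward", call. = FALSE)
  unclass(x)
}

#' @export
print.area_matrix <- function(x, ...) {
  cat(sprintf("area_matrix [%s]: %d samples x %d species\n",
              area_stage(x), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE]))
  invisible(x)
}

#' Read a wide peak-area table
#'
#' The expected layout is one row per injection and one column per species:
#' first column `sample_id`, remaining column names matching panel species
#' ids. Empty cells become missing values. Columns not present in the panel
#' are dropped with a warning; samples absent from the annotation are an
#' error (areas without run metadata cannot be processed).
#'
#' @param path CSV file.
#' @param panel a `lipid_panel` (see [read_panel()]).
#' @param samples a `sample_sheet` (see [read_samples()]).
#' @return an `area_matrix` at stage `"raw"`, rows ordered like `samples`,
#'   columns ordered like `panel`.
#' @export
read_area_matrix <- function(path, panel, samples) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("area table must have 'sample_id' as its first column", call. = FALSE)
  unknown_samples <- setdiff(tab$sample_id, samples$sample_id)
  if (length(unknown_samples))
    stop("area table contains samples absent from the annotation: ",
         paste(unknown_samples, collapse = ", "), call. = FALSE)
  species <- setdiff(names(tab), "sample_id")
  extra <- setdiff(species, panel$species_id)
  if (length(extra)) {
    warning("dropping columns not in the panel: ",
            paste(extra, collapse = ", "), call. = FALSE)
    species <- setdiff(species, extra)
  }
  m <- as.matrix(tab[species])
  storage.mode(m) <- "double"
  rownames(m) <- tab$sample_id
  if (any(m < 0, na.rm = TRUE))
    stop("negative peak areas found; areas must be non-negative",
         call. = FALSE)
  keep_samples <- intersect(samples$sample_id, rownames(m))
  keep_species <- intersect(panel$species_id, species)
  area_matrix(m[keep_samples, keep_species, drop = FALSE], stage = "raw")
}

#' Write an area matrix as a wide CSV
#'
#' Inverse of [read_area_matrix()]: values round-trip bit-exactly (areas are
#' written with full precision) and index order is preserved.
#'
#' @param x an `area_matrix`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_area_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer shared by all emitters (17 significant digits
# keeps doubles exact through a read.csv round trip)
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Coefficient of variation, in percent
#'
#' CV = 100 * sd / mean on linear-scale values. Missing values are dropped
#' pairwise. The statistic is undefined (returns `NA`) when fewer than 3
#' values remain or the mean is not positive, matching the convention used
#' by the analytical CV filter.
#'
#' @param x numeric vector.
#' @return CV in percent, or `NA_real_` when undefined.
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}
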