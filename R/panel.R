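#' Read and validate a lipid panel
#'
#' The panel declares every monitored transition: analyte species with their
#' lipid class, carbon and double-bond counts (of the intact molecule, used
#' for isotopologue arithmetic), the class-specific internal standard each is
#' quantified against, and, where chromatography does not separate them, the
#' species whose M+2 isotopologue is co-integrated with their signal.
#' Internal-standard rows are flagged by `is_istd` and carry the amount
#' spiked per processed sample in pmol.
#'
#' Validation is total: the file either loads into a fully cross-referenced
#' panel or a typed error is raised; no partially constructed panel escapes.
#' Checks: unique species ids; every analyte's `istd_id` resolves to an ISTD
#' row; each lipid class maps to exactly one ISTD; every `interferer_id`
#' resolves to a same-class species with exactly one more double bond (the
#' M+2 geometry: one double bond fewer means two mass units more than the
#' interferer's monoisotopic peak); carbon counts at least 2.
#'
#' @param path CSV with columns `species_id, lipid_class, n_carbons,
#'   n_double_bonds, istd_id, interferer_id, is_istd,
#'   amount_pmol_per_sample`.
#' @return a `lipid_panel` data frame (analytes and ISTD rows together).
#' @export
read_panel <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "lipid_class", "n_carbons", "n_double_bonds",
                "istd_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(tab$interferer_id)) tab$interferer_id <- NA_character_
  if (is.null(tab$is_istd)) tab$is_istd <- FALSE
  if (is.null(tab$amount_pmol_per_sample))
    tab$amount_pmol_per_sample <- NA_real_
  tab$is_istd <- as.logical(tab$is_istd)
  tab$interferer_id[!nzchar(trimws(ifelse(is.na(tab$interferer_id), "",
                                          tab$interferer_id)))] <- NA_character_
  validate_panel(tab)
}

validate_panel <- function(tab) {
  dup <- tab$species_id[duplicated(tab$species_id)]
  if (length(dup))
    stop("duplicate species_id in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(tab$n_carbons < 2))
    stop("n_carbons must be >= 2 for isotopologue arithmetic", call. = FALSE)
  if (any(tab$n_double_bonds < 0))
    stop("n_double_bonds must be non-negative", call. = FALSE)

  istd <- tab[tab$is_istd, , drop = FALSE]
  analytes <- tab[!tab$is_istd, , drop = FALSE]
  if (any(is.na(istd$amount_pmol_per_sample)) ||
      any(istd$amount_pmol_per_sample <= 0))
    stop("every ISTD needs a positive amount_pmol_per_sample", call. = FALSE)

  bad_istd <- setdiff(analytes$istd_id, istd$species_id)
  if (length(bad_istd))
    stop("istd_id not found among ISTD rows: ",
         paste(bad_istd, collapse = ", "),
         " (every lipid class needs its internal standard)", call. = FALSE)
  multi <- tapply(analytes$istd_id, analytes$lipid_class,
                  function(v) length(unique(v)))
  if (any(multi > 1))
    stop("lipid class mapped to more than one ISTD: ",
         paste(names(multi)[multi > 1], collapse = ", "), call. = FALSE)

  has_int <- !is.na(tab$interferer_id)
  if (any(has_int)) {
    dangling <- setdiff(tab$interferer_id[has_int], tab$species_id)
    if (length(dangling))
      stop("interferer_id not found in panel: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    idx <- match(tab$interferer_id[has_int], tab$species_id)
    same_class <- tab$lipid_class[has_int] == tab$lipid_class[idx]
    db_plus1 <- tab$n_double_bonds[idx] == tab$n_double_bonds[has_int] + 1L
    bad <- which(has_int)[!(same_class & db_plus1)]
    if (length(bad))
      stop("interferer must be a same-class species with one more double ",
           "bond (M+2 overlap): ",
           paste(tab$species_id[bad], collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("lipid_panel", "data.frame")
  tab
}

#' @rdname read_panel
#' @param panel a `lipid_panel`.
#' @param path output CSV file.
#' @export
write_panel <- function(panel, path) {
  write_csv_full(as.data.frame(panel), path)
  invisible(path)
}

#' Internal-standard table of a panel
#'
#' @param panel a `lipid_panel`.
#' @return data frame of the ISTD rows (`species_id`, `lipid_class`,
#'   `amount_pmol_per_sample`).
#' @export
panel_istds <- function(panel) {
  out <- panel[panel$is_istd,
               c("species_id", "lipid_class", "amount_pmol_per_sample")]
  rownames(out) <- NULL
  out
}

#' @rdname panel_istds
#' @export
panel_analytes <- function(panel) {
  out <- panel[!panel$is_istd, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carbon count of an intact lipid from class shorthand
#'
#' Derives the total carbon number of the intact molecule from the acyl/alkyl
#' carbon total in the species shorthand (e.g. the 34 in "PC 34:1") plus the
#' backbone and head-group carbons of the class. Intended as a convenience
#' when building panels; panel `n_carbons` values always take precedence
#' because shorthand parsing is unreliable for ether and plasmalogen species.
#'
#' @param lipid_class class shorthand (e.g. `"PC"`, `"LPE"`, `"CE"`,
#'   `"Cer d18:1"`, `"SM"`, `"TG"`).
#' @param chain_carbons total carbons in the radyl chains (for sphingolipids,
#'   the sphingoid base plus N-acyl chain).
#' @return total carbon count of the intact molecule.
#' @export
carbons_for_species <- function(lipid_class, chain_carbons) {
  base <- strsplit(lipid_class, " ")[[1]][1]
  head_c <- switch(base,
    "PC" = , "PC-O" = , "PC-P" = , "LPC" = , "LPC-O" = , "LPC-P" = 8L,
    "PE" = , "PE-O" = , "PE-P" = , "LPE" = , "LPE-P" = 5L,
    "PG" = , "LPG" = 6L,
    "PI" = , "LPI" = 9L,
    "PS" = , "LPS" = 6L,
    "SM" = 5L,   # phosphocholine head on the ceramide backbone
    "Cer" = 0L,
    "Hex1Cer" = 6L, "Hex2Cer" = 12L, "Hex3Cer" = 18L,
    "GM3" = 23L, # two hexoses + one sialic acid
    "S1P" = 0L,
    "CE" = 27L,  # cholesterol backbone
    "DG" = , "TG" = , "MG" = 3L,
    stop("unknown lipid class shorthand: ", lipid_class, call. = FALSE))
  as.integer(chain_carbons + head_c)
}
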