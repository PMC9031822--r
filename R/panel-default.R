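#' Built-in serum lipid panel
#'
#' Constructs the default targeted panel: 301 analyte species spanning the
#' diacyl, ether and plasmalogen phospholipids, lysophospholipids,
#' sphingolipids (ceramides by sphingoid base, hexosylceramides, GM3,
#' sphingomyelin, S1P), cholesteryl esters and glycerolipids, plus one
#' internal standard per lipid class. Interference links are declared for
#' every species pair within a class that shares the intact-molecule carbon
#' count and differs by exactly one double bond (the more unsaturated
#' species' M+2 isotopologue overlaps the more saturated species'
#' monoisotopic peak). The four ceramide species used in cardiovascular
#' risk ratios (Cer d18:1/16:0, /18:0, /24:1, /24:0) are always present.
#'
#' The class composition can be overridden (or reduced, e.g. for fast
#' simulation studies) with a named count vector.
#'
#' @param n_species_per_class named integer vector mapping class to analyte
#'   count; `NULL` uses the default 301-species composition.
#' @return a validated `lipid_panel`.
#' @export
default_panel <- function(n_species_per_class = NULL) {
  if (is.null(n_species_per_class)) n_species_per_class <- default_panel_counts()
  rows <- list()
  for (cls in names(n_species_per_class)) {
    k <- n_species_per_class[[cls]]
    if (k <= 0) next
    rows[[cls]] <- panel_species_for_class(cls, k)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # interference: same class, same carbons, one more double bond
  tab$interferer_id <- NA_character_
  for (i in seq_len(nrow(tab))) {
    j <- which(tab$lipid_class == tab$lipid_class[i] &
                 tab$n_carbons == tab$n_carbons[i] &
                 tab$n_double_bonds == tab$n_double_bonds[i] + 1L &
                 !tab$is_istd)
    if (length(j) && !tab$is_istd[i]) tab$interferer_id[i] <- tab$species_id[j[1]]
  }
  validate_panel(tab)
}

# default class composition; sums to 301 analyte species
default_panel_counts <- function() {
  c("PC" = 40, "PC-O" = 15, "PC-P" = 10, "PE" = 25, "PE-O" = 8, "PE-P" = 10,
    "PG" = 8, "PI" = 12,
    "LPC" = 15, "LPC-O" = 5, "LPC-P" = 4, "LPE" = 8, "LPE-P" = 3,
    "LPI" = 5, "LPS" = 4,
    "SM" = 25, "Cer d18:0" = 8, "Cer d18:1" = 12, "Cer d18:2" = 8,
    "Hex1Cer" = 8, "Hex2Cer" = 5, "Hex3Cer" = 4, "GM3" = 6, "S1P" = 3,
    "CE" = 15, "DG" = 15, "TG" = 20)
}

# typical per-species serum concentration (umol/L) by class; anchors the
# simulator's concentration scale and the ISTD spike amounts
class_typical_conc <- function() {
  c("PC" = 30, "PC-O" = 5, "PC-P" = 3, "PE" = 4, "PE-O" = 1, "PE-P" = 1.5,
    "PG" = 0.5, "PI" = 2,
    "LPC" = 10, "LPC-O" = 1, "LPC-P" = 0.5, "LPE" = 1, "LPE-P" = 0.3,
    "LPI" = 0.5, "LPS" = 0.3,
    "SM" = 10, "Cer d18:0" = 0.2, "Cer d18:1" = 1, "Cer d18:2" = 0.3,
    "Hex1Cer" = 0.5, "Hex2Cer" = 0.2, "Hex3Cer" = 0.15, "GM3" = 0.5,
    "S1P" = 0.5,
    "CE" = 100, "DG" = 5, "TG" = 30)
}

# deterministic species list (ids, composition, ISTD) for one class
panel_species_for_class <- function(cls, k) {
  sphingo <- grepl("^(Cer|Hex|GM3|S1P|SM)", cls)
  if (cls == "S1P") {
    bases <- c("d18:1", "d18:0", "d17:1", "d16:1", "d20:1")[seq_len(min(k, 5))]
    ids <- paste0("S1P ", bases)
    carbons <- as.integer(sub("^d(\\d+):.*$", "\\1", bases))
    dbs <- as.integer(sub("^d\\d+:(\\d+)$", "\\1", bases))
    df <- data.frame(species_id = ids, lipid_class = cls,
                     n_carbons = carbons, n_double_bonds = dbs,
                     stringsAsFactors = FALSE)
  } else if (grepl("^(Cer|Hex|GM3)", cls)) {
    base <- if (grepl("^Cer", cls)) sub("^Cer ", "", cls) else "d18:1"
    base_c <- 18L
    base_db <- as.integer(sub("^d\\d+:(\\d+)$", "\\1", base))
    acyl <- list(c(16, 0), c(18, 0), c(20, 0), c(22, 0), c(24, 1), c(24, 0),
                 c(26, 1), c(26, 0), c(22, 1), c(23, 0), c(25, 0), c(18, 1),
                 c(20, 1), c(21, 0))
    acyl <- acyl[seq_len(min(k, length(acyl)))]
    prefix <- if (grepl("^Cer", cls)) "Cer" else cls
    ids <- vapply(acyl, function(a)
      sprintf("%s %s/%d:%d", prefix, base, a[1], a[2]), character(1))
    head_c <- switch(sub(" .*$", "", cls), "Cer" = 0L, "Hex1Cer" = 6L,
                     "Hex2Cer" = 12L, "Hex3Cer" = 18L, "GM3" = 23L)
    df <- data.frame(
      species_id = ids, lipid_class = cls,
      n_carbons = vapply(acyl, function(a) base_c + a[1] + head_c, numeric(1)),
      n_double_bonds = vapply(acyl, function(a) base_db + a[2], numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    lyso <- grepl("^L", cls)
    c_range <- if (cls == "CE") seq(14, 24, by = 2)
      else if (cls %in% c("TG", "DG")) seq(44, 58, by = 2)
      else if (lyso) seq(16, 24, by = 2)
      else if (cls == "SM") seq(30, 44, by = 2)
      else seq(30, 42, by = 2)
    db_range <- if (lyso || cls == "CE") 0:2 else if (cls == "SM") 0:3 else 0:5
    combos <- expand.grid(db = db_range, cc = c_range)
    combos <- combos[order(combos$cc, combos$db), ][seq_len(k), , drop = FALSE]
    ids <- sprintf("%s %d:%d", cls, combos$cc, combos$db)
    df <- data.frame(
      species_id = ids, lipid_class = cls,
      n_carbons = vapply(seq_len(k), function(i)
        carbons_for_species(cls, combos$cc[i]), integer(1)),
      n_double_bonds = combos$db,
      stringsAsFactors = FALSE)
  }
  if (nrow(df) < k)
    stop("class ", cls, " supports at most ", nrow(df), " species",
         call. = FALSE)
  istd_id <- paste0("ISTD ", cls)
  df$istd_id <- istd_id
  df$is_istd <- FALSE
  df$amount_pmol_per_sample <- NA_real_
  typical <- class_typical_conc()
  amt <- if (cls %in% names(typical)) typical[[cls]] * 10 else 100
  istd_row <- data.frame(
    species_id = istd_id, lipid_class = cls,
    n_carbons = max(2L, as.integer(stats::median(df$n_carbons)) - 6L),
    n_double_bonds = 0, istd_id = istd_id, is_istd = TRUE,
    amount_pmol_per_sample = amt, stringsAsFactors = FALSE)
  rbind(df, istd_row)
}

#' Stylized group fold-change map
#'
#' Multiplicative effects of the hypothyroid (HT) and Cushing's-syndrome
#' (CS) groups versus healthy beagles (HB), used by the batch simulator.
#' Directions follow the disease biology the pipeline is meant to resolve:
#' hyperlipidemia with glycerolipid, diacyl-phospholipid, ceramide,
#' sphingomyelin and lysophosphatidylcholine increases dominated by HT;
#' lower LPC, LPC-P, PC-O and PC-P in CS; S1P elevated in both diseases and
#' highest in CS. Magnitudes are stylized defaults (roughly 1.5-3x), not
#' measurements, so downstream checks assert direction rather than size.
#' Species-level overrides (e.g. a larger HT effect on Cer d18:1/24:0 than
#' on the rest of its class) shape the ceramide risk ratios.
#'
#' @return data frame with columns `level` (`"class"` or `"species"`),
#'   `id`, `group`, `fold`; HB is the implicit reference (fold 1).
#' @export
default_fold_change_map <- function() {
  cls_ht <- c("TG" = 3.0, "DG" = 2.5, "PC" = 2.0, "PE" = 2.0, "PG" = 1.8,
              "PI" = 1.8, "LPC" = 2.2, "LPC-O" = 1.8, "LPC-P" = 1.8,
              "LPE" = 1.8, "LPE-P" = 1.8, "LPS" = 1.8, "LPI" = 0.7,
              "Cer d18:0" = 2.0, "Cer d18:1" = 2.0, "Cer d18:2" = 2.0,
              "Hex1Cer" = 2.0, "GM3" = 1.8, "SM" = 1.8,
              "PC-O" = 0.8, "S1P" = 1.5, "CE" = 1.8)
  cls_cs <- c("TG" = 1.8, "PC" = 1.4, "PE" = 1.4, "PG" = 1.3,
              "LPC" = 0.6, "LPC-P" = 0.65, "PC-O" = 0.6, "PC-P" = 0.6,
              "LPE" = 1.3, "LPI" = 0.5, "Hex1Cer" = 1.4,
              "S1P" = 2.5, "CE" = 1.4)
  sp_over <- data.frame(
    level = "species",
    id = c("Cer d18:1/24:0", "Cer d18:1/18:0"),
    group = c("HT", "CS"),
    fold = c(3.0, 1.4),
    stringsAsFactors = FALSE)
  rbind(
    data.frame(level = "class", id = names(cls_ht), group = "HT",
               fold = unname(cls_ht), stringsAsFactors = FALSE),
    data.frame(level = "class", id = names(cls_cs), group = "CS",
               fold = unname(cls_cs), stringsAsFactors = FALSE),
    sp_over)
}

#' @rdname default_fold_change_map
#' @export
null_fold_change_map <- function() {
  data.frame(level = character(0), id = character(0), group = character(0),
             fold = numeric(0), stringsAsFactors = FALSE)
}

# fold for one species in one group; species override beats class; HB is 1
fold_for <- function(map, species_id, lipid_class, group) {
  if (group == "HB" || is.null(map) || nrow(map) == 0) return(1)
  hit <- map$fold[map$level == "species" & map$id == species_id &
                    map$group == group]
  if (length(hit)) return(hit[1])
  hit <- map$fold[map$level == "class" & map$id == lipid_class &
                    map$group == group]
  if (length(hit)) hit[1] else 1
}
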