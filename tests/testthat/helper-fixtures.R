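# Small in-code fixtures shared across the suite.

# three-species PC chain with an ISTD; interference runs
# PC 34:2 -> PC 34:1 -> PC 34:0 (most unsaturated first)
tiny_panel <- function() {
  lipidq:::validate_panel(data.frame(
    species_id = c("PC 34:2", "PC 34:1", "PC 34:0", "ISTD PC"),
    lipid_class = "PC",
    n_carbons = c(42L, 42L, 42L, 36L),
    n_double_bonds = c(2L, 1L, 0L, 0L),
    istd_id = "ISTD PC",
    interferer_id = c(NA, "PC 34:2", "PC 34:1", NA),
    is_istd = c(FALSE, FALSE, FALSE, TRUE),
    amount_pmol_per_sample = c(NA, NA, NA, 100),
    stringsAsFactors = FALSE))
}

# minimal annotation: n_spl study samples, n_bqc BQCs interleaved, one
# blank, an RQC ladder
tiny_samples <- function(n_spl = 6, n_bqc = 5, dilutions = c(1, .5, .25, .125)) {
  ids <- c(sprintf("BQC_%02d", seq_len(n_bqc)),
           sprintf("SPL_%02d", seq_len(n_spl)),
           sprintf("RQC_%02d", seq_along(dilutions)),
           "PBLK_01")
  type <- c(rep("BQC", n_bqc), rep("SPL", n_spl),
            rep("RQC", length(dilutions)), "PBLK")
  grp <- c(rep(NA, n_bqc),
           rep(c("HB", "HT", "CS"), length.out = n_spl),
           rep(NA, length(dilutions) + 1))
  lipidq:::validate_samples(data.frame(
    sample_id = ids, sample_type = type,
    run_order = seq_along(ids), batch_id = "B1",
    dilution_fraction = c(rep(NA, n_bqc + n_spl), dilutions, NA),
    group = grp, serum_volume_uL = 10,
    clinical_tc_mmolL = NA_real_, clinical_tg_mmolL = NA_real_,
    stringsAsFactors = FALSE))
}

# writes a data.frame to a temp CSV and returns the path
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Engineered 20-species QC fixture: 16 clean species plus one designed
# failure per criterion (signal-to-blank, raw area, BQC CV, RQC linearity).
# Returns the four stage matrices and the annotation.
qc_fixture <- function() {
  samples <- tiny_samples(n_spl = 5, n_bqc = 5)
  ids <- samples$sample_id
  bqc <- ids[samples$sample_type == "BQC"]
  pblk <- ids[samples$sample_type == "PBLK"]
  rqc <- ids[samples$sample_type == "RQC"]
  dil <- samples$dilution_fraction[match(rqc, samples$sample_id)]

  species <- c(sprintf("OK_%02d", 1:16),
               "FAIL_S2B", "FAIL_AREA", "FAIL_CV", "FAIL_R2")
  raw <- matrix(0, length(ids), length(species),
                dimnames = list(ids, species))
  norm <- corr <- raw

  base_area <- 10000
  for (sp in species) {
    raw[, sp] <- base_area
    raw[pblk, sp] <- 10                      # s2b = 1000
    corr[, sp] <- base_area
    corr[rqc, sp] <- base_area * dil         # perfectly linear ladder
    norm[, sp] <- 1
    norm[bqc, sp] <- c(0.98, 1.00, 1.02, 1.00, 1.00)   # BQC CV ~ 1.5%
  }
  raw[pblk, "FAIL_S2B"] <- base_area / 2     # s2b = 2 < 5
  raw[bqc, "FAIL_AREA"] <- 400               # median BQC raw area < 500
  raw[pblk, "FAIL_AREA"] <- 1                # keep its s2b passing (400 > 5)
  norm[bqc, "FAIL_CV"] <- c(0.5, 1.0, 1.5, 0.7, 1.3)   # CV ~ 40%
  corr[rqc, "FAIL_R2"] <- c(5000, 5200, 4800, 5100)    # flat: no response

  conc <- norm                               # scale is irrelevant to the QC
  list(samples = samples,
       raw = area_matrix(raw, "raw"),
       corrected = area_matrix(corr, "drift_corrected"),
       normalized = area_matrix(norm, "normalized"),
       conc = area_matrix(conc, "concentration"))
}
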