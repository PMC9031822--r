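# builds a drift_corrected-stage matrix for the tiny PC panel
tiny_corrected <- function(samples, analyte = 5000, istd = 8000) {
  ids <- samples$sample_id
  m <- matrix(analyte, length(ids), 4,
              dimnames = list(ids, tiny_panel()$species_id))
  m[, "ISTD PC"] <- istd
  area_matrix(m, "drift_corrected")
}

test_that("constant ISTD areas keep per-sample normalization (tie to per-sample)", {
  samples <- tiny_samples()
  res <- normalize_to_istd(tiny_corrected(samples), tiny_panel(), samples)
  expect_equal(res$decisions$mode, "per_sample_istd")
  expect_true(all(res$areas == 5000 / 8000))
  expect_equal(area_stage(res$areas), "normalized")
  expect_false("ISTD PC" %in% colnames(res$areas))
})

test_that("ISTD sharing the analytes' variation favours per-sample mode; corrupted ISTD forces the fallback", {
  cfg <- sim_config(n_hb = 10, n_ht = 10, n_cs = 10,
                    n_species_per_class = c("PC" = 5),
                    drift_model = "sine", drift_amplitude = 1,
                    drift_species_sd = 0.01, seed = 41)
  sim <- simulate_batch(cfg)
  # skip drift correction: analytes and ISTD carry the same drift, which
  # only per-sample division can cancel
  areas <- area_matrix(unclass(sim$areas), "drift_corrected")
  res <- normalize_to_istd(areas, sim$panel, sim$samples)
  expect_equal(res$decisions$mode, "per_sample_istd")
  expect_lt(res$decisions$spl_cv_per_sample_percent,
            res$decisions$spl_cv_fallback_percent)

  # corrupt the ISTD of a drift-free batch with independent 50% CV noise:
  # dividing by it now injects noise, so the BQC-average fallback must win
  sim2 <- simulate_batch(sim_config(n_hb = 10, n_ht = 10, n_cs = 10,
                                    n_species_per_class = c("PC" = 5),
                                    drift_model = "none", seed = 42))
  m <- unclass(sim2$areas)
  set.seed(42)
  m[, "ISTD PC"] <- m[, "ISTD PC"] *
    stats::rlnorm(nrow(m), 0, lipidq:::cv_to_sdlog(50))
  res2 <- normalize_to_istd(area_matrix(m, "drift_corrected"),
                            sim2$panel, sim2$samples)
  expect_equal(res2$decisions$mode, "bqc_average_istd")
})

test_that("concentration conversion is plain unit arithmetic", {
  samples <- tiny_samples()
  norm <- normalize_to_istd(tiny_corrected(samples, analyte = 8000),
                            tiny_panel(), samples)$areas
  conc <- to_concentration(norm, tiny_panel(), samples)
  # ratio 1, 100 pmol ISTD, 10 uL serum -> 10 umol/L
  expect_true(all(conc == 10))
  norm0 <- normalize_to_istd(tiny_corrected(samples, analyte = 0),
                             tiny_panel(), samples)$areas
  expect_true(all(to_concentration(norm0, tiny_panel(), samples) == 0))
})

test_that("per-sample-mode concentrations are invariant to a per-sample scale factor", {
  samples <- tiny_samples()
  base <- tiny_corrected(samples)
  scaled <- unclass(base) * seq(0.5, 3, length.out = nrow(base))
  conc_a <- to_concentration(
    normalize_to_istd(base, tiny_panel(), samples)$areas,
    tiny_panel(), samples)
  conc_b <- to_concentration(
    normalize_to_istd(area_matrix(scaled, "drift_corrected"),
                      tiny_panel(), samples)$areas,
    tiny_panel(), samples)
  expect_equal(unclass(conc_a), unclass(conc_b))
})

test_that("the engineered 20-species fixture fails exactly one species per criterion", {
  fx <- qc_fixture()
  res <- qc_filter(fx$raw, fx$corrected, fx$normalized, fx$conc, fx$samples)
  dec <- res$decisions
  expect_equal(sum(dec$passed), 16)
  expect_equal(ncol(res$conc), 16)
  failed <- dec[!dec$passed, c("species_id", "failed_criteria")]
  expect_equal(failed$failed_criteria[failed$species_id == "FAIL_S2B"],
               "signal_to_blank")
  expect_equal(failed$failed_criteria[failed$species_id == "FAIL_AREA"],
               "raw_area")
  expect_equal(failed$failed_criteria[failed$species_id == "FAIL_CV"],
               "bqc_cv")
  expect_equal(failed$failed_criteria[failed$species_id == "FAIL_R2"],
               "rqc_r2")
})

test_that("QC boundaries are strict and a clean blank passes criterion (i)", {
  fx <- qc_fixture()
  raw <- unclass(fx$raw)
  # median BQC raw area exactly 500 must fail the > 500 rule
  bqc <- fx$samples$sample_id[fx$samples$sample_type == "BQC"]
  raw[bqc, "OK_01"] <- 500
  res <- qc_filter(area_matrix(raw, "raw"), fx$corrected, fx$normalized,
                   fx$conc, fx$samples)
  expect_false(res$decisions$passed[res$decisions$species_id == "OK_01"])
  # blank median zero -> infinite signal-to-blank, criterion passes
  pblk <- fx$samples$sample_id[fx$samples$sample_type == "PBLK"]
  raw[pblk, "OK_02"] <- 0
  res2 <- qc_filter(area_matrix(raw, "raw"), fx$corrected, fx$normalized,
                    fx$conc, fx$samples)
  d <- res2$decisions[res2$decisions$species_id == "OK_02", ]
  expect_true(is.infinite(d$signal_to_blank))
  expect_true(d$passed)
})

test_that("raising any QC threshold never enlarges the survivor set", {
  sim <- simulate_batch(sim_config(n_hb = 6, n_ht = 6, n_cs = 6, seed = 19))
  pl <- run_pipeline(sim)
  base <- pl$qc_decisions$species_id[pl$qc_decisions$passed]
  harder <- list(list(min_signal_blank = 50), list(min_raw_area = 5000),
                 list(max_bqc_cv = 10), list(min_rqc_r2 = 0.95))
  for (th in harder) {
    res <- do.call(qc_filter, c(list(pl$raw, pl$drift_corrected,
                                     pl$normalized, pl$conc, sim$samples),
                                th))
    expect_true(all(res$decisions$species_id[res$decisions$passed] %in% base))
  }
})

test_that("class totals sum member species and ceramide ratios follow their definition", {
  samples <- tiny_samples()
  panel <- lipidq:::validate_panel(data.frame(
    species_id = c("PC 34:0", "PC 34:1", "Cer d18:1/16:0", "Cer d18:1/24:0",
                   "ISTD PC", "ISTD Cer"),
    lipid_class = c("PC", "PC", "Cer d18:1", "Cer d18:1", "PC", "Cer d18:1"),
    n_carbons = c(42, 42, 34, 42, 36, 30),
    n_double_bonds = c(0, 1, 1, 1, 0, 1),
    istd_id = c("ISTD PC", "ISTD PC", "ISTD Cer", "ISTD Cer",
                "ISTD PC", "ISTD Cer"),
    interferer_id = NA, is_istd = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    amount_pmol_per_sample = c(NA, NA, NA, NA, 100, 100)))
  m <- matrix(0, nrow(samples), 4,
              dimnames = list(samples$sample_id,
                              panel$species_id[!panel$is_istd]))
  m[, "PC 34:0"] <- 3; m[, "PC 34:1"] <- 7
  m[, "Cer d18:1/16:0"] <- 0.4; m[, "Cer d18:1/24:0"] <- 0.4
  conc <- area_matrix(m, "concentration")
  samples$clinical_tc_mmolL <- 5
  dm <- derive_metrics(conc, panel, samples)
  expect_equal(dm$class_totals[["PC"]], rep(10, nrow(samples)))
  expect_equal(dm$class_totals[["Cer d18:1"]], rep(0.8, nrow(samples)))
  expect_equal(dm$metrics$cer_ratio_16_24, rep(1, nrow(samples)))
  expect_true(all(is.na(dm$metrics$cer_ratio_18_24)))  # species absent
  expect_equal(dm$n_species_summed[["PC"]], 2L)

  # totals are additive under panel splitting / permutation invariant
  perm <- conc[, c(3, 1, 4, 2)]
  dm2 <- derive_metrics(area_matrix(perm, "concentration"), panel, samples)
  expect_equal(dm2$class_totals[["PC"]], dm$class_totals[["PC"]])
})

test_that("parameter recovery holds at default noise and improves with drift correction", {
  sim <- simulate_batch(sim_config(seed = 1))
  on <- stats::median(recovery_errors(run_pipeline(sim), sim))
  off <- stats::median(recovery_errors(
    run_pipeline(sim, drift_correction = FALSE), sim))
  expect_lt(on, 0.15)
  expect_lt(on, off)
})
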