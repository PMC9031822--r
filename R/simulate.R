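#' Configuration for a synthetic MRM batch
#'
#' Captures the run design of a pooled-QC targeted lipidomics batch:
#' cohort sizes for the three dog groups (10 healthy beagles, 45
#' hypothyroid, 39 Cushing's syndrome by default), a BQC injected after
#' every `bqc_interval` study samples plus a lead-in and lead-out BQC, a
#' response-QC dilution ladder (1, 1/2, 1/4, 1/8 of pooled extract) placed
#' at batch start and end, process blanks split between batch start and
#' end, smooth instrument drift in log2 space shared within a lipid class,
#' log-normal analytical noise, and multiplicative group effects versus the
#' healthy reference.
#'
#' @param n_hb,n_ht,n_cs study-sample counts per group.
#' @param n_species_per_class named class-to-count vector for
#'   [default_panel()]; `NULL` for the full 301-species panel.
#' @param bqc_interval one BQC after every this many study samples.
#' @param rqc_dilutions dilution fractions, strictly decreasing from 1.
#' @param n_blanks number of process blanks.
#' @param drift_model `"none"`, `"linear"`, `"sine"` or `"spline"`.
#' @param drift_amplitude drift amplitude in log2 units (peak deviation of
#'   the class drift curve).
#' @param drift_species_sd per-species phase jitter (standard deviation in
#'   radians) around the class drift curve, plus a fixed modest amplitude
#'   jitter: species of a class share the drift pattern but not its exact
#'   size or timing, so ISTD normalization cancels drift only partly and
#'   per-species correction has real work to do.
#' @param noise_cv_percent analytical CV of the log-normal area noise.
#' @param biological_cv_percent between-animal CV of true concentrations.
#' @param blank_background_fraction blank signal as a fraction of the
#'   median BQC signal.
#' @param isotope_crosstalk add M+2 co-integration between linked species.
#' @param fold_change_map data frame from [default_fold_change_map()] (or
#'   [null_fold_change_map()] for a no-effect batch).
#' @param serum_volume_uL serum volume processed per sample.
#' @param seed integer RNG seed; identical config and seed give
#'   bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_hb = 10, n_ht = 45, n_cs = 39,
                       n_species_per_class = NULL,
                       bqc_interval = 10,
                       rqc_dilutions = c(1, 1 / 2, 1 / 4, 1 / 8),
                       n_blanks = 3,
                       drift_model = c("sine", "none", "linear", "spline"),
                       drift_amplitude = 0.5,
                       drift_species_sd = 0.5,
                       noise_cv_percent = 8,
                       biological_cv_percent = 30,
                       blank_background_fraction = 0.01,
                       isotope_crosstalk = TRUE,
                       fold_change_map = default_fold_change_map(),
                       serum_volume_uL = 10,
                       seed = 1L) {
  drift_model <- match.arg(drift_model)
  if (any(c(n_hb, n_ht, n_cs, n_blanks) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (length(rqc_dilutions)) {
    if (rqc_dilutions[1] != 1 || any(diff(rqc_dilutions) >= 0) ||
        any(rqc_dilutions <= 0))
      stop("rqc_dilutions must start at 1 and be strictly decreasing in (0, 1]",
           call. = FALSE)
  }
  if (bqc_interval < 1) stop("bqc_interval must be positive", call. = FALSE)
  if (noise_cv_percent < 0 || biological_cv_percent < 0)
    stop("CV parameters must be non-negative", call. = FALSE)
  if (blank_background_fraction < 0 || blank_background_fraction >= 1)
    stop("blank_background_fraction must lie in [0, 1)", call. = FALSE)
  if (!is.null(fold_change_map) && nrow(fold_change_map) &&
      any(fold_change_map$fold <= 0))
    stop("fold changes must be positive", call. = FALSE)
  n_spl <- n_hb + n_ht + n_cs
  if (n_spl == 0 && drift_model != "none")
    stop("drift simulation needs at least one study sample", call. = FALSE)
  structure(list(
    n_hb = n_hb, n_ht = n_ht, n_cs = n_cs,
    n_species_per_class = n_species_per_class,
    bqc_interval = bqc_interval, rqc_dilutions = rqc_dilutions,
    n_blanks = n_blanks, drift_model = drift_model,
    drift_amplitude = drift_amplitude, drift_species_sd = drift_species_sd,
    noise_cv_percent = noise_cv_percent,
    biological_cv_percent = biological_cv_percent,
    blank_background_fraction = blank_background_fraction,
    isotope_crosstalk = isotope_crosstalk,
    fold_change_map = fold_change_map,
    serum_volume_uL = serum_volume_uL, seed = as.integer(seed)),
    class = "sim_config")
}

# lognormal sdlog for a target linear-scale CV (in percent)
cv_to_sdlog <- function(cv_percent) sqrt(log1p((cv_percent / 100)^2))

#' Simulate a complete targeted-lipidomics batch
#'
#' Generates a panel, a run-ordered sample annotation, a raw peak-area
#' matrix and the ground truth behind it. True study-sample concentrations
#' are drawn log-normally around class-typical medians scaled by the group
#' fold map; the pooled BQC truth is the mean of the study-sample truths
#' (equal-volume pooling), RQC truths are the BQC truth times the dilution
#' fraction (the dilution also thins the internal standards, which enter
#' the extract before pooling), and blanks carry only background. Raw area
#' = truth x class response factor x drift factor(run order) x log-normal
#' noise; when isotope cross-talk is on, each species with a declared
#' interferer additionally receives `p_m2(interferer)` times the
#' interferer's clean (pre-cross-talk) area.
#'
#' @param config a [sim_config()].
#' @return list of class `lipid_sim` with `panel`, `samples`, `areas`
#'   (stage `"raw"`), and `truth` (list: `true_conc_umolL` samples x
#'   species, `drift_log2` samples x species, `fold_change_map`, `seed`).
#' @export
simulate_batch <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- default_panel(config$n_species_per_class)
  if (!config$isotope_crosstalk) {
    # no co-integration is simulated, so the emitted panel declares none
    panel$interferer_id <- NA_character_
  }
  analytes <- panel_analytes(panel)
  istds <- panel_istds(panel)
  samples <- build_run_sequence(config)
  n_smp <- nrow(samples)
  spl <- samples$sample_type == "SPL"

  # per-species true median concentration: class-typical x fixed spread
  typical <- class_typical_conc()
  base_conc <- vapply(seq_len(nrow(analytes)), function(i) {
    t0 <- if (analytes$lipid_class[i] %in% names(typical))
      typical[[analytes$lipid_class[i]]] else 1
    t0 * exp(stats::rnorm(1, 0, 0.5))
  }, numeric(1))
  names(base_conc) <- analytes$species_id

  # study-sample truths: group fold x biological log-normal variation
  sdlog_bio <- cv_to_sdlog(config$biological_cv_percent)
  fold_by_group <- sapply(GROUPS, function(g)
    vapply(seq_len(nrow(analytes)), function(k)
      fold_for(config$fold_change_map, analytes$species_id[k],
               analytes$lipid_class[k], g), numeric(1)))
  if (is.null(dim(fold_by_group)))
    fold_by_group <- matrix(fold_by_group, nrow = 1,
                            dimnames = list(NULL, GROUPS))
  truth <- matrix(0, n_smp, nrow(analytes),
                  dimnames = list(samples$sample_id, analytes$species_id))
  for (i in which(spl)) {
    truth[i, ] <- base_conc * fold_by_group[, samples$group[i]] *
      exp(stats::rnorm(nrow(analytes), 0, sdlog_bio))
  }
  bqc_truth <- if (any(spl)) colMeans(truth[spl, , drop = FALSE]) else base_conc
  for (i in which(samples$sample_type == "BQC")) truth[i, ] <- bqc_truth
  for (i in which(samples$sample_type == "RQC"))
    truth[i, ] <- bqc_truth * samples$dilution_fraction[i]

  # clinical chemistry: TC tracks the true CE pool (CE/TC ratio near 0.9),
  # TG tracks the true TG pool
  ce_ids <- analytes$species_id[analytes$lipid_class == "CE"]
  tg_ids <- analytes$species_id[analytes$lipid_class == "TG"]
  samples$clinical_tc_mmolL <- NA_real_
  samples$clinical_tg_mmolL <- NA_real_
  if (length(ce_ids))
    samples$clinical_tc_mmolL[spl] <-
      rowSums(truth[spl, ce_ids, drop = FALSE]) / 1000 /
      stats::rnorm(sum(spl), 0.9, 0.03)
  if (length(tg_ids))
    samples$clinical_tg_mmolL[spl] <-
      rowSums(truth[spl, tg_ids, drop = FALSE]) / 1000 *
      stats::rnorm(sum(spl), 1, 0.05)

  # response factor per class (area counts per umol/L), shared by the ISTD
  classes <- unique(panel$lipid_class)
  rf <- stats::setNames(20000 * exp(stats::rnorm(length(classes), 0, 0.3)),
                        classes)

  # drift curves: shape per class, amplitude jittered per species
  all_ids <- panel$species_id
  drift_log2 <- matrix(0, n_smp, length(all_ids),
                       dimnames = list(samples$sample_id, all_ids))
  if (config$drift_model != "none") {
    run_len <- max(samples$run_order)
    x <- samples$run_order / run_len
    phase_cls <- stats::setNames(stats::runif(length(classes), 0, 2 * pi),
                                 classes)
    spline_cls <- list()
    if (config$drift_model == "spline") {
      for (cls in classes) {
        ky <- stats::rnorm(6)
        spline_cls[[cls]] <- ky / max(abs(ky))
      }
    }
    # species of a class share the drift pattern but not its exact size or
    # timing: ionization drift is analyte-specific, which is why ISTD
    # normalization alone cannot cancel it and per-species correction pays
    amp <- config$drift_amplitude *
      exp(stats::rnorm(length(all_ids), 0, 0.15))
    dphase <- stats::rnorm(length(all_ids), 0, config$drift_species_sd)
    for (j in seq_along(all_ids)) {
      cls <- panel$lipid_class[j]
      drift_log2[, j] <- switch(config$drift_model,
        linear = amp[j] * x,
        sine = amp[j] * sin(2 * pi * x + phase_cls[[cls]] + dphase[j]),
        spline = amp[j] * stats::spline(seq(0, 1, length.out = 6),
                                        spline_cls[[cls]], xout = x)$y)
    }
  }

  # assemble areas: analytes from truth, ISTDs from spike amount; blanks
  # carry full-strength ISTD (added with the extraction mix) but only
  # background analyte signal
  sdlog_noise <- cv_to_sdlog(config$noise_cv_percent)
  area <- matrix(NA_real_, n_smp, length(all_ids),
                 dimnames = list(samples$sample_id, all_ids))
  for (j in seq_along(all_ids)) {
    id <- all_ids[j]
    cls <- panel$lipid_class[j]
    if (panel$is_istd[j]) {
      conc <- rep(panel$amount_pmol_per_sample[j] / config$serum_volume_uL,
                  n_smp)
      conc[samples$sample_type == "RQC"] <-
        conc[samples$sample_type == "RQC"] *
        samples$dilution_fraction[samples$sample_type == "RQC"]
    } else {
      conc <- truth[, id]
    }
    clean <- conc * rf[[cls]] * 2^drift_log2[, j]
    blank <- samples$sample_type == "PBLK"
    if (any(blank) && !panel$is_istd[j]) {
      bqc_med <- stats::median(clean[samples$sample_type == "BQC"])
      clean[blank] <- config$blank_background_fraction * bqc_med
    }
    area[, j] <- clean
  }
  if (config$isotope_crosstalk) {
    clean_area <- area
    for (j in seq_along(all_ids)) {
      intf <- panel$interferer_id[j]
      if (is.na(intf)) next
      p_m2 <- isotope_m2_fraction(
        panel$n_carbons[panel$species_id == intf])
      area[, j] <- area[, j] + p_m2 * clean_area[, intf]
    }
  }
  if (sdlog_noise > 0)
    area <- area * exp(matrix(stats::rnorm(length(area), 0, sdlog_noise),
                              nrow(area)))

  list_out <- list(
    panel = panel,
    samples = validate_samples(as.data.frame(samples)),
    areas = area_matrix(area, stage = "raw"),
    truth = list(true_conc_umolL = truth, drift_log2 = drift_log2,
                 fold_change_map = config$fold_change_map,
                 seed = config$seed),
    config = config)
  class(list_out) <- "lipid_sim"
  list_out
}

# run-ordered annotation implementing the batch layout:
# BQC | RQC ladder | blanks(first half) | [k SPL, BQC]* | RQC ladder |
# blanks(rest) | BQC
build_run_sequence <- function(config) {
  n_spl <- config$n_hb + config$n_ht + config$n_cs
  groups <- sample(rep(c("HB", "HT", "CS"),
                       c(config$n_hb, config$n_ht, config$n_cs)))
  spl_ids <- sprintf("SPL_%03d", seq_len(n_spl))
  rows <- list()
  bqc_i <- 0L; rqc_i <- 0L; blk_i <- 0L
  add <- function(type, id, dil = NA_real_, grp = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, sample_type = type, run_order = length(rows) + 1L,
      batch_id = "B1", dilution_fraction = dil, group = grp,
      serum_volume_uL = config$serum_volume_uL,
      clinical_tc_mmolL = NA_real_, clinical_tg_mmolL = NA_real_,
      stringsAsFactors = FALSE)
  }
  add_bqc <- function() { bqc_i <<- bqc_i + 1L
    add("BQC", sprintf("BQC_%02d", bqc_i)) }
  add_ladder <- function() for (d in config$rqc_dilutions) {
    rqc_i <<- rqc_i + 1L
    add("RQC", sprintf("RQC_%02d", rqc_i), dil = d)
  }
  n_blk_head <- ceiling(config$n_blanks / 2)

  add_bqc()                                   # lead-in
  add_ladder()
  for (b in seq_len(n_blk_head)) { blk_i <- blk_i + 1L
    add("PBLK", sprintf("PBLK_%02d", blk_i)) }
  k <- 0L
  for (i in seq_len(n_spl)) {
    add("SPL", spl_ids[i], grp = groups[i])
    k <- k + 1L
    if (k == config$bqc_interval || i == n_spl) { add_bqc(); k <- 0L }
  }
  add_ladder()
  for (b in seq_len(config$n_blanks - n_blk_head)) { blk_i <- blk_i + 1L
    add("PBLK", sprintf("PBLK_%02d", blk_i)) }
  add_bqc()                                   # lead-out
  validate_samples(do.call(rbind, rows))
}

#' Write a simulated batch to disk
#'
#' Emits the three pipeline input CSVs (panel, sample annotation, raw area
#' matrix), a long-format truth table (`sample_id, species_id,
#' true_conc_umolL`), and a YAML echo of the configuration from which
#' [simulate_batch()] reproduces the batch exactly. All files re-load
#' losslessly.
#'
#' @param sim a `lipid_sim` from [simulate_batch()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_batch <- function(sim, dir) {
  stopifnot(inherits(sim, "lipid_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(panel = file.path(dir, "panel.csv"),
             samples = file.path(dir, "samples.csv"),
             areas = file.path(dir, "areas.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  write_panel(sim$panel, files[["panel"]])
  write_samples(sim$samples, files[["samples"]])
  write_area_matrix(sim$areas, files[["areas"]])
  tr <- sim$truth$true_conc_umolL
  truth_long <- data.frame(
    sample_id = rep(rownames(tr), times = ncol(tr)),
    species_id = rep(colnames(tr), each = nrow(tr)),
    true_conc_umolL = as.vector(tr), stringsAsFactors = FALSE)
  write_csv_full(truth_long, files[["truth"]])
  cfg <- sim$config
  cfg_list <- unclass(cfg)
  cfg_list$fold_change_map <- if (is.null(cfg$fold_change_map)) NULL
    else as.list(as.data.frame(cfg$fold_change_map))
  if (!is.null(cfg_list$n_species_per_class))
    cfg_list$n_species_per_class <- as.list(cfg_list$n_species_per_class)
  yaml::write_yaml(cfg_list, files[["config"]])
  invisible(files)
}

#' Rebuild a simulation configuration from its YAML echo
#'
#' @param path the `config.yaml` written by [write_batch()].
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fmap <- if (is.null(cfg$fold_change_map)) null_fold_change_map()
    else as.data.frame(cfg$fold_change_map, stringsAsFactors = FALSE)
  nspc <- if (is.null(cfg$n_species_per_class)) NULL
    else unlist(cfg$n_species_per_class)
  sim_config(
    n_hb = cfg$n_hb, n_ht = cfg$n_ht, n_cs = cfg$n_cs,
    n_species_per_class = nspc,
    bqc_interval = cfg$bqc_interval,
    rqc_dilutions = as.numeric(cfg$rqc_dilutions),
    n_blanks = cfg$n_blanks, drift_model = cfg$drift_model,
    drift_amplitude = cfg$drift_amplitude,
    drift_species_sd = cfg$drift_species_sd,
    noise_cv_percent = cfg$noise_cv_percent,
    biological_cv_percent = cfg$biological_cv_percent,
    blank_background_fraction = cfg$blank_background_fraction,
    isotope_crosstalk = cfg$isotope_crosstalk,
    fold_change_map = fmap,
    serum_volume_uL = cfg$serum_volume_uL, seed = cfg$seed)
}
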