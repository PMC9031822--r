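test_that("M+2 fraction matches closed-form corner cases and limits", {
  expect_equal(isotope_m2_fraction(2, 0.4999999), choose(2, 2) *
                 (0.4999999 / 0.5000001)^2)
  expect_equal(isotope_m2_fraction(2, 1e-12), (1e-12 / (1 - 1e-12))^2)
  expect_error(isotope_m2_fraction(1), "n_carbons")
  expect_error(isotope_m2_fraction(10, 0.7), "p13c")
})

test_that("M+2 and M+1 fractions agree with brute-force isotopologue enumeration", {
  # oracle: binomial isotopologue abundances P(k heavy) for k = 0..n,
  # interference fraction = P(2)/P(0) (resp. P(1)/P(0))
  oracle <- function(n, k, p) {
    probs <- stats::dbinom(0:n, n, p)
    probs[k + 1] / probs[1]
  }
  p <- 0.0107
  for (n in c(2:20, 40, 80, 120)) {
    expect_equal(isotope_m2_fraction(n, p), oracle(n, 2, p),
                 tolerance = 1e-12)
    expect_equal(isotope_m1_fraction(n, p), oracle(n, 1, p),
                 tolerance = 1e-12)
  }
})

test_that("isotope correction follows chains interferer-first and clamps at zero", {
  panel <- tiny_panel()
  samples <- tiny_samples(n_spl = 2, n_bqc = 3)
  p42 <- isotope_m2_fraction(42)
  # hand-worked chain: PC 34:2 (untouched) -> PC 34:1 -> PC 34:0
  m <- matrix(0, nrow(samples), 4,
              dimnames = list(samples$sample_id, panel$species_id))
  m[, "PC 34:2"] <- 10000
  m[, "PC 34:1"] <- 5000
  m[, "PC 34:0"] <- 2000
  m[, "ISTD PC"] <- 8000
  res <- correct_isotopes(area_matrix(m, "raw"), panel)
  b <- 5000 - p42 * 10000
  c0 <- 2000 - p42 * b
  expect_equal(unname(res$areas[1, "PC 34:2"]), 10000)  # head of chain
  expect_equal(unname(res$areas[1, "PC 34:1"]), b)
  expect_equal(unname(res$areas[1, "PC 34:0"]), c0)
  expect_equal(unname(res$areas[1, "ISTD PC"]), 8000)   # ISTD never corrected
  expect_equal(area_stage(res$areas), "isotope_corrected")
  expect_equal(res$records$p_m2, rep(p42, 2))
  expect_equal(res$records$n_clamped, c(0L, 0L))

  # clamping engages when the subtraction would go negative
  m2 <- m
  m2[, "PC 34:1"] <- 50   # far below p_m2 * 10000
  res2 <- correct_isotopes(area_matrix(m2, "raw"), panel)
  expect_true(all(res2$areas[, "PC 34:1"] == 0))
  expect_equal(res2$records$n_clamped[res2$records$species_id == "PC 34:1"],
               nrow(samples))

  # zero interferer signal leaves the target unchanged
  m3 <- m
  m3[, "PC 34:2"] <- 0
  res3 <- correct_isotopes(area_matrix(m3, "raw"), panel)
  expect_equal(unname(res3$areas[1, "PC 34:1"]), 5000)
})

test_that("isotope correction is conservative and the identity without links", {
  sim <- simulate_batch(sim_config(n_species_per_class = c("PC" = 6),
                                   n_hb = 4, n_ht = 4, n_cs = 4, seed = 21))
  res <- correct_isotopes(sim$areas, sim$panel)
  expect_true(all(res$areas <= unclass(sim$areas) + 1e-9, na.rm = TRUE))

  panel_nolink <- sim$panel
  panel_nolink$interferer_id <- NA_character_
  res2 <- correct_isotopes(sim$areas, panel_nolink)
  expect_equal(unclass(res2$areas), unclass(sim$areas), ignore_attr = TRUE)
  expect_equal(nrow(res2$records), 0)
})

test_that("cyclic interference chains are a configuration error", {
  panel <- tiny_panel()
  panel$interferer_id <- c("PC 34:0", "PC 34:2", "PC 34:1", NA)
  m <- matrix(1000, 4, 4, dimnames = list(letters[1:4], panel$species_id))
  samples <- NULL
  expect_error(lipidq:::isotope_topo_order(panel), "cyclic")
})

test_that("drift curve fitting is exact on constant and collinear BQCs", {
  ro <- seq(2, 100, by = 9)
  const <- fit_drift_curve(ro, rep(3.5, length(ro)))
  expect_equal(const(c(1, 17, 50, 120)), rep(3.5, 4), tolerance = 1e-9)

  lin <- fit_drift_curve(ro, 2 + 0.03 * ro)
  at <- c(5, 30.5, 77)
  expect_equal(lin(at), 2 + 0.03 * at, tolerance = 1e-6)
  # linear extrapolation beyond the BQC range continues the line
  expect_equal(lin(c(-10, 150)), 2 + 0.03 * c(-10, 150), tolerance = 1e-6)

  expect_null(fit_drift_curve(ro[1:3], rep(1, 3)))  # too few points
  expect_error(fit_drift_curve(ro, c(Inf, rep(1, length(ro) - 1))),
               "finite")
})

test_that("loess drift fit tracks a smooth sine within an independent local-fit tolerance", {
  # independent oracle: dense weighted local linear regression with tricube
  # weights implemented from first principles
  local_fit <- function(x0, x, y, span) {
    n <- length(x)
    q <- max(4, ceiling(span * n))
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- (1 - pmin(d / dq, 1)^3)^3
    fit <- stats::lm(y ~ x, weights = w)
    unname(stats::predict(fit, data.frame(x = x0)))
  }
  set.seed(4)
  ro <- seq(1, 110, length.out = 12)
  truth <- 0.5 * sin(2 * pi * ro / 110)
  y <- truth + stats::rnorm(12, 0, 0.02)
  curve <- fit_drift_curve(ro, y)
  oracle <- vapply(ro, local_fit, numeric(1), x = ro, y = y, span = 0.75)
  # both smoothers see the same data; they must agree closely at the knots
  expect_lt(max(abs(curve(ro) - oracle)), 0.05)
  # and deviate from the true drift no more than the independent local fit
  # does (plus a margin for implementation differences in the weighting)
  expect_lt(max(abs(curve(ro) - truth)), 1.5 * max(abs(oracle - truth)))
})

test_that("drift correction preserves the BQC median level and only helps", {
  sim <- simulate_batch(sim_config(seed = 31))
  iso <- correct_isotopes(sim$areas, sim$panel)
  res <- apply_drift_correction(iso$areas, sim$samples)
  bqc <- sim$samples$sample_id[sim$samples$sample_type == "BQC"]
  applied <- res$decisions$applied
  expect_true(any(applied))
  for (sp in sample(res$decisions$species_id[applied], 10)) {
    before <- stats::median(log2(iso$areas[bqc, sp]), na.rm = TRUE)
    after <- stats::median(log2(res$areas[bqc, sp]), na.rm = TRUE)
    expect_equal(after, before, tolerance = 1e-6)
  }
  # acceptance rule: CV strictly improves by construction where applied
  d <- res$decisions[applied, ]
  expect_true(all(d$cv_before_percent - d$cv_after_percent > 2))
})

test_that("a second pass of drift correction finds almost nothing left to remove", {
  sim <- simulate_batch(sim_config(seed = 13))
  iso <- correct_isotopes(sim$areas, sim$panel)
  first <- apply_drift_correction(iso$areas, sim$samples)
  again <- area_matrix(unclass(first$areas), stage = "isotope_corrected")
  second <- apply_drift_correction(again, sim$samples)
  # residual structure is mostly fit noise; only a marginal few species can
  # clear the >2-point rule again, and typical CV change sits near zero
  expect_lt(mean(second$decisions$applied), 0.1)
  drop2 <- second$decisions$cv_before_percent -
    second$decisions$cv_after_percent
  expect_lt(stats::median(drop2, na.rm = TRUE), 1)
  drop1 <- first$decisions$cv_before_percent -
    first$decisions$cv_after_percent
  expect_gt(stats::median(drop1, na.rm = TRUE),
            stats::median(drop2, na.rm = TRUE))
})

test_that("a batch without drift leaves every species uncorrected", {
  sim <- simulate_batch(sim_config(drift_model = "none", seed = 8))
  res <- apply_drift_correction(
    correct_isotopes(sim$areas, sim$panel)$areas, sim$samples)
  expect_equal(sum(res$decisions$applied), 0)
})

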