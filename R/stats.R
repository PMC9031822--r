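#' Two-tailed Welch's t-test with figure-style significance tiers
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom) with
#' the star tiers used in the group-comparison figures: `***` for p <=
#' 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns` otherwise (boundaries
#' inclusive). Degenerate inputs are resolved explicitly rather than
#' erroring: when both groups have zero variance, equal means give t = 0
#' and p = 1, differing means give p = 0 with a `degenerate` flag.
#'
#' @param x,y numeric vectors (group a and group b); NAs dropped.
#' @return one-row data frame: `mean_a`, `mean_b`, `welch_t`, `dof_welch`,
#'   `p_two_sided`, `tier`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("welch_test needs at least 2 non-missing values per group",
         call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  degenerate <- FALSE
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      t <- 0; dof <- length(x) + length(y) - 2; p <- 1
    } else {
      t <- Inf * sign(mean(x) - mean(y))
      dof <- length(x) + length(y) - 2; p <- 0; degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    t <- unname(ht$statistic); dof <- unname(ht$parameter)
    p <- ht$p.value
  }
  data.frame(mean_a = mean(x), mean_b = mean(y), welch_t = t,
             dof_welch = dof, p_two_sided = p, tier = p_tier(p),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' @rdname welch_test
#' @param p a p-value (vectorized).
#' @export
p_tier <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
}

#' All pairwise group comparisons for the reporting surface
#'
#' Runs two-tailed Welch's t-tests for every variable of the reporting
#' surface — each lipid-class total, each individually reported species,
#' the CE/TC ratio and the three ceramide ratios — across the three group
#' pairs HB-HT, HB-CS, HT-CS, on linear-scale concentrations. Raw p-values
#' drive the star tiers (matching the figure convention); a
#' Benjamini-Hochberg adjusted column is emitted alongside for
#' transparency.
#'
#' @param conc filtered `area_matrix` at stage `"concentration"`.
#' @param class_totals,metrics tables from [derive_metrics()].
#' @param samples a `sample_sheet`.
#' @param species_of_interest species tested individually; defaults to the
#'   four risk-score ceramides and the S1P species present.
#' @param log_scale test log2-transformed values instead of linear.
#' @return data frame of comparisons: `variable`, `variable_type`, `pair`,
#'   Welch columns, `p_bh`, and `flag` (`"insufficient_n"` when a group
#'   has fewer than 2 values).
#' @export
run_all_comparisons <- function(conc, class_totals, metrics, samples,
                                species_of_interest = NULL,
                                log_scale = FALSE) {
  spl <- samples[samples$sample_type == "SPL", ]
  if (length(unique(spl$group)) < 2)
    stop("group comparisons need at least two groups", call. = FALSE)
  if (is.null(species_of_interest)) {
    cers <- c("Cer d18:1/16:0", "Cer d18:1/18:0", "Cer d18:1/24:0",
              "Cer d18:1/24:1")
    species_of_interest <- intersect(c(cers, grep("^S1P ", colnames(conc),
                                                  value = TRUE)),
                                     colnames(conc))
  }

  vars <- list()
  for (cls in setdiff(names(class_totals), "sample_id"))
    vars[[cls]] <- list(type = "class_total",
                        value = stats::setNames(class_totals[[cls]],
                                                class_totals$sample_id))
  for (sp in species_of_interest)
    vars[[sp]] <- list(type = "species",
                       value = stats::setNames(conc[, sp], rownames(conc)))
  for (mt in c("ce_tc_ratio", "cer_ratio_16_24", "cer_ratio_18_24",
               "cer_ratio_241_24"))
    if (mt %in% names(metrics))
      vars[[mt]] <- list(type = "ratio",
                         value = stats::setNames(metrics[[mt]],
                                                 metrics$sample_id))

  pairs <- list(c("HB", "HT"), c("HB", "CS"), c("HT", "CS"))
  out <- list()
  for (vn in names(vars)) {
    v <- vars[[vn]]$value[spl$sample_id]
    if (log_scale) v <- ifelse(!is.na(v) & v > 0, log2(v), NA_real_)
    for (pr in pairs) {
      a <- v[spl$group == pr[1]]
      b <- v[spl$group == pr[2]]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
        row <- data.frame(mean_a = NA_real_, mean_b = NA_real_,
                          welch_t = NA_real_, dof_welch = NA_real_,
                          p_two_sided = NA_real_, tier = NA_character_,
                          degenerate = NA, stringsAsFactors = FALSE)
        flag <- "insufficient_n"
      } else {
        row <- welch_test(a, b)
        flag <- ""
      }
      out[[length(out) + 1L]] <- cbind(
        data.frame(variable = vn, variable_type = vars[[vn]]$type,
                   pair = paste(pr, collapse = "-"),
                   stringsAsFactors = FALSE),
        row, data.frame(flag = flag, stringsAsFactors = FALSE))
    }
  }
  res <- do.call(rbind, out)
  res$p_bh <- stats::p.adjust(res$p_two_sided, method = "BH")
  res
}

#' PCA on scaled, centered log2 abundances
#'
#' Study samples only. Values are log2-transformed, each variable centered
#' and scaled to unit variance, and the decomposition taken by singular
#' values (equivalently, eigendecomposition of the correlation matrix).
#' Variables with any missing or non-positive study-sample value are
#' dropped (listwise deletion, logged in `dropped`), as are variables that
#' are constant after transformation. Loading signs follow a fixed
#' convention: within each component, the loading entry largest in absolute
#' value is made positive. `top_loadings` ranks variables by their loading
#' norm in the PC1-PC2 plane, the vectors usually overlaid on a biplot.
#'
#' @param conc `area_matrix` at stage `"concentration"` (or any positive
#'   abundance matrix).
#' @param samples a `sample_sheet`.
#' @param top_k how many top loading variables to report (default 30).
#' @return list of class `lipid_pca`: `scores`, `loadings`,
#'   `explained_variance_fraction`, `top_loadings`, `groups`, `dropped`.
#' @export
run_pca <- function(conc, samples, top_k = 30) {
  spl_ids <- intersect(ids_of_type(samples, "SPL"), rownames(conc))
  if (length(spl_ids) < 3)
    stop("PCA needs at least 3 study samples", call. = FALSE)
  m <- unclass(conc)[spl_ids, , drop = FALSE]
  bad <- apply(m, 2, function(v) any(is.na(v) | v <= 0))
  l2 <- log2(m[, !bad, drop = FALSE])
  const <- apply(l2, 2, function(v) stats::sd(v) == 0)
  dropped <- c(colnames(m)[bad], colnames(l2)[const])
  l2 <- l2[, !const, drop = FALSE]
  if (ncol(l2) < 2)
    stop("fewer than 2 usable variables for PCA", call. = FALSE)
  pc <- stats::prcomp(l2, center = TRUE, scale. = TRUE)
  # sign convention: largest-|entry| loading positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  norm12 <- if (ncol(pc$rotation) >= 2)
    sqrt(rowSums(pc$rotation[, 1:2]^2)) else abs(pc$rotation[, 1])
  top <- names(sort(norm12, decreasing = TRUE))[seq_len(min(top_k,
                                                            ncol(l2)))]
  structure(list(
    scores = pc$x, loadings = pc$rotation,
    explained_variance_fraction = ev / sum(ev),
    top_loadings = top,
    groups = samples$group[match(spl_ids, samples$sample_id)],
    dropped = dropped), class = "lipid_pca")
}
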