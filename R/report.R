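#' Write the analysis report to disk
#'
#' Emits `comparisons.csv`, `pca_scores.csv`, `pca_loadings.csv`, one
#' box/dot plot per lipid class total with star annotations for each group
#' pair, and a PC1-PC2 biplot overlaying the top loading vectors. File
#' names are deterministic (`class_<name>.png`, `pca_biplot.png`). An empty
#' comparison table yields a header-only CSV and no plots.
#'
#' @param comparisons table from [run_all_comparisons()] (may have 0 rows).
#' @param pca a `lipid_pca` from [run_pca()], or `NULL` to skip PCA output.
#' @param class_totals class-totals table from [derive_metrics()].
#' @param samples a `sample_sheet`.
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(comparisons, pca, class_totals, samples, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  cmp_path <- file.path(out_dir, "comparisons.csv")
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    empty <- data.frame(variable = character(0), variable_type = character(0),
                        pair = character(0), mean_a = numeric(0),
                        mean_b = numeric(0), welch_t = numeric(0),
                        dof_welch = numeric(0), p_two_sided = numeric(0),
                        tier = character(0), p_bh = numeric(0))
    utils::write.csv(empty, cmp_path, row.names = FALSE)
    return(invisible(cmp_path))
  }
  write_csv_full(comparisons, cmp_path)
  files <- c(files, cmp_path)

  spl <- samples[samples$sample_type == "SPL", ]
  for (cls in setdiff(names(class_totals), "sample_id")) {
    df <- data.frame(
      group = factor(spl$group[match(class_totals$sample_id,
                                     spl$sample_id)], levels = GROUPS),
      value = class_totals[[cls]])
    df <- df[!is.na(df$group), ]
    stars <- comparisons[comparisons$variable == cls &
                           comparisons$variable_type == "class_total", ]
    subtitle <- if (nrow(stars))
      paste(sprintf("%s: %s", stars$pair, stars$tier), collapse = "   ")
      else NULL
    p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
      ggplot2::labs(title = paste("Total", cls), subtitle = subtitle,
                    y = "concentration (µmol/L)", x = NULL) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, paste0("class_", sanitize_filename(cls), ".png"))
    ggplot2::ggsave(f, p, width = 4, height = 4, dpi = 120)
    files <- c(files, f)
  }

  if (!is.null(pca)) {
    sc <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE)
    ld <- data.frame(species_id = rownames(pca$loadings), pca$loadings,
                     check.names = FALSE)
    f_sc <- file.path(out_dir, "pca_scores.csv")
    f_ld <- file.path(out_dir, "pca_loadings.csv")
    write_csv_full(sc, f_sc)
    write_csv_full(ld, f_ld)
    files <- c(files, f_sc, f_ld)
    if (ncol(pca$scores) >= 2) {
      sco <- data.frame(PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                        group = factor(pca$groups, levels = GROUPS))
      scale_f <- max(abs(sco$PC1), abs(sco$PC2)) /
        max(sqrt(rowSums(pca$loadings[pca$top_loadings, 1:2]^2)))
      arr <- data.frame(species = pca$top_loadings,
                        x = pca$loadings[pca$top_loadings, 1] * scale_f,
                        y = pca$loadings[pca$top_loadings, 2] * scale_f)
      pct <- round(100 * pca$explained_variance_fraction[1:2], 1)
      p <- ggplot2::ggplot(sco, ggplot2::aes(x = PC1, y = PC2,
                                             colour = group)) +
        ggplot2::geom_point() +
        ggplot2::geom_segment(
          data = arr, ggplot2::aes(x = 0, y = 0, xend = x, yend = y),
          inherit.aes = FALSE, linewidth = 0.2, colour = "grey40",
          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
        ggplot2::geom_text(data = arr,
                           ggplot2::aes(x = x, y = y, label = species),
                           inherit.aes = FALSE, size = 2, colour = "grey30") +
        ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                      y = sprintf("PC2 (%.1f%%)", pct[2])) +
        ggplot2::theme_minimal()
      f <- file.path(out_dir, "pca_biplot.png")
      ggplot2::ggsave(f, p, width = 6, height = 5, dpi = 120)
      files <- c(files, f)
    }
  }
  invisible(files)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
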