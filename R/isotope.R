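#' Isotopologue interference fractions
#'
#' In triple-quadrupole lipidomics at unit resolution, a lipid with one more
#' double bond elutes close to its saturated neighbour and its two-heavy-
#' isotope (M+2) peak falls on the neighbour's monoisotopic mass, so the two
#' signals are co-integrated. The inflation is the ratio of the interferer's
#' M+2 carbon isotopologue abundance to its monoisotopic abundance. With
#' `n` carbons and a 13C abundance `p`, the isotopologue count is binomial,
#' so
#' \deqn{p_{M2} = \binom{n}{2} \left(\frac{p}{1-p}\right)^2}
#' (carbon-only; contributions of H/N/O heavy isotopes to M+2 are
#' negligible at this resolution). The analogous single-heavy-isotope
#' fraction is \eqn{p_{M1} = n\, p/(1-p)}.
#'
#' @param n_carbons carbon count of the intact interfering molecule
#'   (at least 2 for M+2).
#' @param p13c natural 13C abundance; default 0.0107.
#' @return interference fraction (dimensionless, >= 0).
#' @export
isotope_m2_fraction <- function(n_carbons, p13c = 0.0107) {
  if (any(n_carbons < 2))
    stop("n_carbons must be >= 2 for an M+2 isotopologue", call. = FALSE)
  if (p13c <= 0 || p13c >= 0.5)
    stop("p13c must lie in (0, 0.5)", call. = FALSE)
  choose(n_carbons, 2) * (p13c / (1 - p13c))^2
}

#' @rdname isotope_m2_fraction
#' @export
isotope_m1_fraction <- function(n_carbons, p13c = 0.0107) {
  if (any(n_carbons < 1))
    stop("n_carbons must be >= 1 for an M+1 isotopologue", call. = FALSE)
  if (p13c <= 0 || p13c >= 0.5)
    stop("p13c must lie in (0, 0.5)", call. = FALSE)
  n_carbons * p13c / (1 - p13c)
}

#' Correct isotopic co-integration
#'
#' For every analyte whose panel entry names an interferer, the co-integrated
#' M+2 contribution is subtracted:
#' `corrected(target) = area(target) - p_m2(interferer) * corrected(interferer)`,
#' clamped at zero. Interference links form chains within a lipid class
#' ordered by descending double-bond count; chains are processed
#' interferer-first so each subtraction uses the interferer's already
#' corrected area. Species without an interferer pass through unchanged and
#' internal standards are never corrected.
#'
#' @param areas an `area_matrix` at stage `"raw"`.
#' @param panel a `lipid_panel`.
#' @param p13c natural 13C abundance used for the interference fraction.
#' @return list with `areas` (stage `"isotope_corrected"`) and `records`,
#'   a data frame with one row per corrected species: `species_id`,
#'   `interferer_id`, `p_m2`, and `n_clamped` (samples clamped to zero).
#' @export
correct_isotopes <- function(areas, panel, p13c = 0.0107) {
  m <- advance_stage(areas, from = "raw", to = "isotope_corrected")
  targets <- panel$species_id[!is.na(panel$interferer_id) & !panel$is_istd]
  order_ids <- isotope_topo_order(panel)
  records <- data.frame(species_id = character(0), interferer_id = character(0),
                        p_m2 = numeric(0), n_clamped = integer(0),
                        stringsAsFactors = FALSE)
  for (sp in order_ids) {
    if (!sp %in% targets || !sp %in% colnames(m)) next
    row <- panel[panel$species_id == sp, ]
    interferer <- row$interferer_id
    if (!interferer %in% colnames(m)) next
    p_m2 <- isotope_m2_fraction(
      panel$n_carbons[panel$species_id == interferer], p13c)
    corrected <- m[, sp] - p_m2 * m[, interferer]
    n_clamped <- sum(corrected < 0, na.rm = TRUE)
    corrected[!is.na(corrected) & corrected < 0] <- 0
    m[, sp] <- corrected
    records <- rbind(records, data.frame(
      species_id = sp, interferer_id = interferer, p_m2 = p_m2,
      n_clamped = n_clamped, stringsAsFactors = FALSE))
  }
  list(areas = area_matrix(m, stage = "isotope_corrected"), records = records)
}

# topological order of the interference graph, interferer-first;
# cycles are a configuration error
isotope_topo_order <- function(panel) {
  ids <- panel$species_id
  parent <- panel$interferer_id                 # edge interferer -> target
  order_ids <- character(0)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(invisible())
    if (state[[id]] == 1L)
      stop("cyclic interference chain involving ", id, call. = FALSE)
    state[[id]] <<- 1L
    p <- parent[match(id, ids)]
    if (!is.na(p)) visit(p)
    state[[id]] <<- 2L
    order_ids <<- c(order_ids, id)
  }
  for (id in ids) visit(id)
  order_ids
}
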