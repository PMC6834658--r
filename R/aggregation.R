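#' Site and species-by-site selection frequencies over bootstraps
#'
#' Counts, for every site, the number of bootstrap best solutions containing
#' it (sites never selected are present with 0), and for every
#' (species, site) pair, the number of best solutions in which the species
#' was assigned to that site (declared or added origin). Proportions of
#' bootstraps are reported alongside the raw counts.
#'
#' @param result a [run_scenario()] result.
#' @return object of class `selection_frequency_table`: list with `site_freq`
#'   (data frame site_id, count, proportion), `species_site_freq` (data frame
#'   species_id, site_id, count, proportion) and `n_bootstraps`.
#' @export
selection_frequencies <- function(result) {
  nb <- length(result$best_solutions)
  if (nb == 0) stop("empty scenario result", call. = FALSE)
  counts <- stats::setNames(integer(length(result$site_ids)), result$site_ids)
  for (sol in result$best_solutions) {
    counts[sol$selected] <- counts[sol$selected] + 1L
  }
  site_freq <- data.frame(site_id = names(counts),
                          count = as.integer(counts),
                          proportion = as.numeric(counts) / nb,
                          stringsAsFactors = FALSE)
  asg <- result$assignments
  if (nrow(asg)) {
    key <- paste(asg$species_id, asg$site_id, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    species_site_freq <- data.frame(
      species_id = vapply(parts, `[`, character(1), 1),
      site_id = vapply(parts, `[`, character(1), 2),
      count = as.integer(tab),
      proportion = as.integer(tab) / nb,
      stringsAsFactors = FALSE)
    species_site_freq <- species_site_freq[
      order(species_site_freq$species_id, species_site_freq$site_id), ]
    rownames(species_site_freq) <- NULL
  } else {
    species_site_freq <- data.frame(species_id = character(0),
                                    site_id = character(0),
                                    count = integer(0), proportion = numeric(0),
                                    stringsAsFactors = FALSE)
  }
  structure(list(site_freq = site_freq,
                 species_site_freq = species_site_freq,
                 n_bootstraps = nb),
            class = "selection_frequency_table")
}

#' Association between site richness and selection frequency
#'
#' Rank (Spearman) correlation between per-site species richness (restricted
#' to a species subset, typically the threatened or the threatened-and-listed
#' species) and bootstrap selection frequency, with its two-sided p-value.
#' The statistic is reported, not thresholded: the original analysis uses it
#' as a diagnostic that selection is driven by species identity rather than
#' local richness. Constant inputs make the correlation undefined; a warning
#' is raised and the statistic reported as NA.
#'
#' @param freq_table a [selection_frequencies()] result.
#' @param occurrence binary site x species occurrence matrix.
#' @param species_subset character vector of species to count in richness.
#' @return list with `statistic` (Spearman's rho), `p_value`, and `richness`
#'   (named per-site vector).
#' @export
richness_frequency_association <- function(freq_table, occurrence,
                                           species_subset) {
  sf <- freq_table$site_freq
  if (nrow(sf) < 3) stop("need at least 3 sites", call. = FALSE)
  sub <- intersect(species_subset, colnames(occurrence))
  richness <- rowSums(occurrence[sf$site_id, sub, drop = FALSE])
  if (length(unique(richness)) < 2 || length(unique(sf$count)) < 2) {
    warning("constant richness or frequency vector: correlation undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, richness = richness))
  }
  ct <- suppressWarnings(cor.test(richness, sf$count, method = "spearman",
                                  exact = FALSE))
  list(statistic = unname(ct$estimate), p_value = ct$p.value,
       richness = richness)
}

#' Gini concentration of site selection frequencies
#'
#' Gini coefficient of the per-site selection-frequency vector: 0 when all
#' sites are selected equally often, approaching 1 as selection concentrates
#' on few sites. Computed by the sorted-vector formula, equivalent to half
#' the mean absolute difference divided by the mean.
#'
#' @param freq_table a [selection_frequencies()] result, or a bare numeric
#'   vector of frequencies.
#' @return Gini coefficient in `[0, 1]`.
#' @export
concentration_index <- function(freq_table) {
  f <- if (inherits(freq_table, "selection_frequency_table")) {
    freq_table$site_freq$count
  } else {
    freq_table
  }
  if (length(f) == 0 || any(f < 0)) {
    stop("frequencies must be a nonempty non-negative vector", call. = FALSE)
  }
  if (sum(f) == 0) stop("all-zero frequency vector", call. = FALSE)
  k <- length(f)
  f <- sort(as.numeric(f))
  sum((2 * seq_len(k) - k - 1) * f) / (k * sum(f))
}
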