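#' Is an IUCN status a threat category?
#'
#' Threatened means CR, EN, VU or NT — the Red List categories that
#' approximately correspond to "unfavourable" conservation status under the
#' EU directives. LC, NE and DD are never threatened.
#'
#' @param status character vector of IUCN categories.
#' @return logical vector.
#' @export
is_threatened <- function(status) {
  check_status(status)
  status %in% THREAT_STATUSES
}

#' Published cross-tabulation of EU vertebrates by taxon, status and listing
#'
#' Reads the packaged counts of EU terrestrial and freshwater vertebrate
#' species per taxon and IUCN category, each split into a total and the number
#' listed in the directives' annexes. The printed grand-total row of the
#' source table is internally inconsistent with its per-taxon cells for
#' directive-listed counts (the per-taxon listed cells sum to 404 and the
#' LC-listed cells to 281, against printed totals of 400 and 277); both are
#' returned verbatim, so callers use `cells` for taxon-level arithmetic and
#' `total_row` for total-level arithmetic, without reconciling them.
#'
#' @return list with data frames `cells` (per-taxon rows) and `total_row`
#'   (the published totals), both with columns taxon, status, total, listed.
#' @export
vertebrate_status_counts <- function() {
  path <- system.file("extdata", "eu_vertebrate_status_counts.csv",
                      package = "n2kprior", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  list(cells = tab[tab$taxon != "Total", , drop = FALSE],
       total_row = tab[tab$taxon == "Total", , drop = FALSE])
}

#' Expand a taxon-by-status count table into pseudo-species records
#'
#' Creates one species record per counted individual species: for each
#' (taxon, status) cell with `total` species of which `listed` are
#' annex-listed, emits `listed` records with `annex_listed = TRUE` and
#' `total - listed` with `FALSE`. Useful for driving the gap analysis with a
#' published summary table in place of a full species list.
#'
#' @param cells data frame with columns taxon, status, total, listed.
#' @return species data frame (species_id, taxon, iucn_status, annex_listed).
#' @export
pseudo_species_from_counts <- function(cells) {
  stopifnot(all(c("taxon", "status", "total", "listed") %in% names(cells)))
  if (any(cells$listed > cells$total)) {
    stop("listed count exceeds total in at least one cell", call. = FALSE)
  }
  n <- sum(cells$total)
  taxon <- rep(cells$taxon, cells$total)
  status <- rep(cells$status, cells$total)
  listed <- unlist(lapply(seq_len(nrow(cells)), function(k) {
    c(rep(TRUE, cells$listed[k]), rep(FALSE, cells$total[k] - cells$listed[k]))
  }))
  data.frame(species_id = sprintf("PS%04d", seq_len(n)), taxon = taxon,
             iucn_status = status, annex_listed = listed,
             stringsAsFactors = FALSE)
}

#' Gap summary: taxon-by-status counts and threatened coverage
#'
#' Cross-tabulates a species table by taxon and IUCN status, counting total
#' species and annex-listed species per cell, and derives the threatened
#' totals, the threatened species not listed in the annexes, and (when a
#' declared-target list is supplied) the threatened species that are a
#' declared target of no site.
#'
#' @param species_table data frame with columns species_id, taxon,
#'   iucn_status, annex_listed.
#' @param declared optional named list (site_id -> character vector) of
#'   declared target species per site.
#' @return object of class `gap_summary`: list with `counts` (data frame
#'   taxon, status, total, listed over all taxon x status cells),
#'   `threatened_total`, `threatened_listed`, `n_species`,
#'   `unlisted_threatened_ids`, and `undeclared_threatened_ids` (NULL when
#'   `declared` is not supplied).
#' @export
summarize_gaps <- function(species_table, declared = NULL) {
  if (anyDuplicated(species_table$species_id)) {
    stop("duplicate species_id in species table", call. = FALSE)
  }
  check_status(species_table$iucn_status)
  taxa <- sort(unique(species_table$taxon))
  tax_f <- factor(species_table$taxon, levels = taxa)
  st_f <- factor(species_table$iucn_status, levels = IUCN_STATUSES)
  total <- table(tax_f, st_f)
  listed <- table(tax_f[species_table$annex_listed],
                  factor(species_table$iucn_status[species_table$annex_listed],
                         levels = IUCN_STATUSES))
  counts <- data.frame(
    taxon = rep(taxa, each = length(IUCN_STATUSES)),
    status = rep(IUCN_STATUSES, times = length(taxa)),
    total = as.integer(t(total)),
    listed = as.integer(t(listed)),
    stringsAsFactors = FALSE)

  thr <- is_threatened(species_table$iucn_status)
  res <- list(
    counts = counts,
    n_species = nrow(species_table),
    threatened_total = sum(thr),
    threatened_listed = sum(thr & species_table$annex_listed),
    unlisted_threatened_ids = species_table$species_id[thr & !species_table$annex_listed],
    undeclared_threatened_ids = NULL)
  if (!is.null(declared)) {
    res$undeclared_threatened_ids <-
      undeclared_threatened(species_table, declared)
  }
  class(res) <- "gap_summary"
  res
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("Gap summary: %d species, %d threatened (%d annex-listed)\n",
              x$n_species, x$threatened_total, x$threatened_listed))
  wide <- do.call(rbind, lapply(split(x$counts, x$counts$taxon), function(d) {
    stats::setNames(sprintf("%d/%d", d$total, d$listed), d$status)
  }))
  print(wide, quote = FALSE)
  if (!is.null(x$undeclared_threatened_ids)) {
    cat(sprintf("%d threatened species declared as a target in no site\n",
                length(x$undeclared_threatened_ids)))
  }
  invisible(x)
}

percent_int <- function(x, rounding = c("round", "truncate")) {
  rounding <- match.arg(rounding)
  if (rounding == "round") as.integer(floor(x + 0.5)) else as.integer(floor(x))
}

#' Directive coverage of a taxon's threatened species, as an integer percent
#'
#' 100 x (threatened annex-listed) / (threatened total) for one taxon,
#' reported as an integer percentage. Default rounding is half-up; a
#' truncation mode is exposed because published percentages are not always
#' consistently rounded.
#'
#' @param summary a [summarize_gaps()] result.
#' @param taxon taxon name present in the summary.
#' @param rounding `"round"` (half-up, default) or `"truncate"`.
#' @return integer percent.
#' @export
coverage_percent <- function(summary, taxon, rounding = c("round", "truncate")) {
  d <- summary$counts[summary$counts$taxon == taxon &
                        summary$counts$status %in% THREAT_STATUSES, ]
  if (nrow(d) == 0) stop(sprintf("unknown taxon '%s'", taxon), call. = FALSE)
  tot <- sum(d$total)
  if (tot == 0) {
    stop(sprintf("taxon '%s' has no threatened species; coverage undefined",
                 taxon), call. = FALSE)
  }
  percent_int(100 * sum(d$listed) / tot, rounding)
}

#' Threatened species that are a declared target of no site
#'
#' @param species_table species data frame (species_id, iucn_status, ...).
#' @param declared named list site_id -> character vector of declared targets.
#' @return character vector of species identifiers.
#' @export
undeclared_threatened <- function(species_table, declared) {
  thr_ids <- species_table$species_id[is_threatened(species_table$iucn_status)]
  declared_any <- unique(unlist(declared, use.names = FALSE))
  setdiff(thr_ids, declared_any)
}
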