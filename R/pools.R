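#' Species -> habitat lookup from a habitat-association table
#'
#' @param habitat_links data frame (species_id, habitat, preference).
#' @param classes which preference classes to keep (default both).
#' @return named list: species_id -> character vector of habitats.
#' @export
species_habitats <- function(habitat_links,
                             classes = c("preferred", "suitable")) {
  keep <- habitat_links[habitat_links$preference %in% classes, , drop = FALSE]
  split(keep$habitat, factor(keep$species_id, levels = unique(keep$species_id)))
}

#' Habitats currently managed in a site
#'
#' Habitats on which a site's declared target species depend are assumed to be
#' managed as part of the conservation effort for those species; the managed
#' set is the union of preferred and suitable habitats over all declared
#' targets (threatened or not: every declared target defines current
#' management). Sites with empty declared lists manage no habitats.
#'
#' @param declared_targets character vector of the site's declared targets.
#' @param habitats named list from [species_habitats()].
#' @return character vector of habitat identifiers (possibly empty).
#' @export
managed_habitats <- function(declared_targets, habitats) {
  h <- unlist(habitats[declared_targets], use.names = FALSE)
  if (is.null(h)) character(0) else unique(h)
}

#' Build a site's candidate-species pool for one bootstrap replicate
#'
#' The pool offered to the optimiser at a site is its declared targets
#' (always kept: current management is never dropped) plus at most
#' `threshold` additional eligible species occurring there. When the eligible
#' non-declared candidates number at most `threshold`, all are included with
#' no randomness. Otherwise a random subset is drawn without replacement,
#' exhausting candidates that share at least one (preferred or suitable)
#' habitat with the site's managed habitats before drawing from the rest —
#' the co-management priority. Uses the current R RNG stream; seed externally
#' for reproducibility.
#'
#' @param declared_targets character vector, the site's declared targets.
#' @param eligible character vector of eligible species occurring in the site
#'   (the caller intersects the scenario species filter with the occurrence
#'   row); may overlap `declared_targets`.
#' @param habitats named list from [species_habitats()].
#' @param threshold maximum number of non-declared additions (>= 0).
#' @return list of class `candidate_pool`: `available` (ordered ids: declared
#'   first, then habitat-sharing additions, then others, each group sorted),
#'   `origin` (parallel vector in {declared, habitat, other}), `n_added`.
#' @export
build_pool <- function(declared_targets, eligible, habitats, threshold) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold < 0) {
    stop("threshold must be a single count >= 0", call. = FALSE)
  }
  declared_targets <- sort(unique(declared_targets))
  cand <- sort(setdiff(eligible, declared_targets))
  managed <- managed_habitats(declared_targets, habitats)
  shares <- vapply(habitats[cand], function(h) any(h %in% managed), logical(1))
  # species with no habitat-link entry never habitat-share
  shares[is.na(shares)] <- FALSE
  if (length(cand) == 0) shares <- logical(0)
  H <- cand[shares]
  O <- cand[!shares]
  if (length(cand) <= threshold) {
    add_h <- H
    add_o <- O
  } else {
    n_h <- min(threshold, length(H))
    add_h <- sort(H[sample.int(length(H), n_h)])
    n_o <- threshold - n_h
    add_o <- if (n_o > 0) sort(O[sample.int(length(O), n_o)]) else character(0)
  }
  available <- c(declared_targets, add_h, add_o)
  structure(list(
    available = available,
    origin = c(rep("declared", length(declared_targets)),
               rep("habitat", length(add_h)),
               rep("other", length(add_o))),
    n_added = length(add_h) + length(add_o)
  ), class = "candidate_pool")
}

#' Build candidate pools for every site of a dataset
#'
#' One [build_pool()] call per site, in site order, under a single seeded RNG
#' stream, so the full pool map is deterministic given `seed`. Eligibility at
#' a site is the scenario species set intersected with the site's occurrence
#' row.
#'
#' @param dataset an `n2k_dataset`.
#' @param scenario_species character vector of species eligible for addition.
#' @param threshold maximum non-declared additions per site.
#' @param seed integer seed for the pool-drawing stream.
#' @return named list site_id -> `candidate_pool`.
#' @export
build_all_pools <- function(dataset, scenario_species, threshold, seed) {
  habitats <- species_habitats(dataset$habitat_links)
  occ <- dataset$occurrence
  set.seed(seed)
  pools <- vector("list", nrow(dataset$sites))
  names(pools) <- dataset$sites$site_id
  for (i in seq_along(pools)) {
    sid <- dataset$sites$site_id[i]
    present <- colnames(occ)[occ[sid, ] == 1L]
    eligible <- intersect(scenario_species, present)
    declared <- intersect(dataset$declared[[sid]], present)
    pools[[i]] <- build_pool(declared, eligible, habitats, threshold)
  }
  pools
}

#' Export a pool map as a long-form data frame
#'
#' @param pools named list from [build_all_pools()].
#' @param bootstrap_id optional replicate label to prepend as a column.
#' @return data frame (bootstrap_id?, site_id, species_id, origin).
#' @export
pools_long <- function(pools, bootstrap_id = NULL) {
  rows <- lapply(names(pools), function(sid) {
    p <- pools[[sid]]
    if (length(p$available) == 0) return(NULL)
    data.frame(site_id = sid, species_id = p$available, origin = p$origin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_id = character(0), species_id = character(0),
                      origin = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(bootstrap_id)) out <- cbind(bootstrap_id = bootstrap_id, out)
  rownames(out) <- NULL
  out
}
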