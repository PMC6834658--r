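# Shared fixture builders: everything is generated in code at test time.

# Small but structurally complete synthetic dataset.
small_config <- function(seed = 1, n_sites = 120, ...) {
  synthetic_config(
    n_sites = n_sites,
    n_species_per_taxon = c(amphibian = 8, bird = 20, fish = 20,
                            mammal = 10, reptile = 10),
    seed = seed, ...)
}

small_dataset <- function(seed = 1, ...) generate_dataset(small_config(seed, ...))

# Hand-built dataset: full control over occupancy, declared lists and habitats.
manual_dataset <- function(occurrence, declared = NULL, species = NULL,
                           habitat_links = NULL, latitude = NULL) {
  site_ids <- rownames(occurrence)
  species_ids <- colnames(occurrence)
  if (is.null(species)) {
    species <- data.frame(species_id = species_ids, taxon = "fish",
                          iucn_status = "VU", annex_listed = TRUE,
                          stringsAsFactors = FALSE)
  }
  if (is.null(declared)) {
    declared <- stats::setNames(rep(list(character(0)), length(site_ids)),
                                site_ids)
  }
  if (is.null(habitat_links)) {
    habitat_links <- data.frame(species_id = species_ids, habitat = "H01",
                                preference = "preferred",
                                stringsAsFactors = FALSE)
  }
  if (is.null(latitude)) latitude <- seq_along(site_ids)
  structure(list(
    species = species,
    sites = data.frame(site_id = site_ids, latitude = latitude,
                       stringsAsFactors = FALSE),
    declared = declared,
    occurrence = occurrence,
    habitat_links = habitat_links
  ), class = "n2k_dataset")
}

# Random small solver instance; each species guaranteed >= 1 site.
random_problem <- function(m, n, density = 0.35, target_max = 2, spf = 50,
                           cost = 1) {
  benefit <- matrix(as.integer(runif(m * n) < density), nrow = m)
  for (j in seq_len(n)) {
    if (sum(benefit[, j]) == 0) benefit[sample.int(m, 1), j] <- 1L
  }
  target <- pmin(sample.int(target_max, n, replace = TRUE), colSums(benefit))
  n2k_problem(benefit, cost = cost, target = pmax(target, 1), spf = spf)
}
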