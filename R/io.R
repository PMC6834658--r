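#' Write a dataset as four CSV tables
#'
#' Emits `species.csv`, `sites.csv` (declared target lists joined with `;`),
#' `occurrence.csv` (long form: site_id, species_id) and
#' `habitat_links.csv` into `dir`. Writers are deterministic: rows follow
#' the dataset's identifier order.
#'
#' @param dataset an `n2k_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$species, file.path(dir, "species.csv"), row.names = FALSE)
  sites <- dataset$sites
  sites$declared_targets <- vapply(dataset$declared[sites$site_id],
                                   paste, character(1), collapse = ";")
  write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  occ <- dataset$occurrence
  idx <- which(occ == 1L, arr.ind = TRUE)
  long <- data.frame(site_id = rownames(occ)[idx[, 1]],
                     species_id = colnames(occ)[idx[, 2]],
                     stringsAsFactors = FALSE)
  long <- long[order(long$site_id, long$species_id), , drop = FALSE]
  write.csv(long, file.path(dir, "occurrence.csv"), row.names = FALSE)
  write.csv(dataset$habitat_links, file.path(dir, "habitat_links.csv"),
            row.names = FALSE)
  invisible(dir)
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read a dataset written by [write_dataset()]
#'
#' Reconstructs and validates the dataset. Invariant violations (a declared
#' target not occurring in its site, a species occupying no site, a species
#' with no habitat link, occurrence rows citing unknown identifiers) are
#' errors; with `lenient = TRUE`, declared-target inconsistencies are
#' downgraded to warnings and the offending records kept, which accommodates
#' real-world inputs where target lists and occurrence layers disagree.
#'
#' @param dir directory containing the four CSV files.
#' @param lenient downgrade declared-target inconsistencies to warnings.
#' @return an `n2k_dataset`.
#' @export
read_dataset <- function(dir, lenient = FALSE) {
  species <- read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE)
  require_columns(species, c("species_id", "taxon", "iucn_status",
                             "annex_listed"), "species.csv")
  sites <- read.csv(file.path(dir, "sites.csv"), stringsAsFactors = FALSE)
  require_columns(sites, c("site_id", "declared_targets"), "sites.csv")
  long <- read.csv(file.path(dir, "occurrence.csv"), stringsAsFactors = FALSE)
  require_columns(long, c("site_id", "species_id"), "occurrence.csv")
  links <- read.csv(file.path(dir, "habitat_links.csv"),
                    stringsAsFactors = FALSE)
  require_columns(links, c("species_id", "habitat", "preference"),
                  "habitat_links.csv")

  bad_site <- setdiff(long$site_id, sites$site_id)
  if (length(bad_site) > 0) {
    stop(sprintf("occurrence.csv cites unknown site id(s): %s",
                 paste(bad_site, collapse = ", ")), call. = FALSE)
  }
  bad_sp <- setdiff(long$species_id, species$species_id)
  if (length(bad_sp) > 0) {
    stop(sprintf("occurrence.csv cites unknown species id(s): %s",
                 paste(bad_sp, collapse = ", ")), call. = FALSE)
  }
  occ <- matrix(0L, nrow = nrow(sites), ncol = nrow(species),
                dimnames = list(sites$site_id, species$species_id))
  occ[cbind(long$site_id, long$species_id)] <- 1L

  declared <- lapply(sites$declared_targets, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  names(declared) <- sites$site_id

  for (sid in sites$site_id) {
    missing_occ <- declared[[sid]][occ[sid, declared[[sid]]] != 1L]
    if (length(missing_occ) > 0) {
      msg <- sprintf("site %s declares target(s) not occurring there: %s",
                     sid, paste(missing_occ, collapse = ", "))
      if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
    }
  }
  orphan <- species$species_id[colSums(occ) == 0]
  if (length(orphan) > 0) {
    stop(sprintf("species occupying no site: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  unlinked <- setdiff(species$species_id, links$species_id)
  if (length(unlinked) > 0) {
    stop(sprintf("species with no habitat link: %s",
                 paste(unlinked, collapse = ", ")), call. = FALSE)
  }
  sites$declared_targets <- NULL
  structure(list(species = species, sites = sites, declared = declared,
                 occurrence = occ, habitat_links = links),
            class = "n2k_dataset")
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

read_marxan_table <- function(dir, file, required) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop(sprintf("missing Marxan input file: %s", file), call. = FALSE)
  }
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = detect_sep(path),
               stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("%s: malformed table (%s)", file,
                                     conditionMessage(e)), call. = FALSE))
  require_columns(tab, required, file)
  tab
}

#' Read Marxan-dialect input files into a problem
#'
#' Parses `spec.dat` (id, target, spf, optional name), `pu.dat` (id, cost,
#' optional status) and `puvspr.dat` (species, pu, amount) from `dir`,
#' auto-detecting tab- or comma-separated variants, and assembles an
#' [n2k_problem()]. Any `amount > 0` is treated as binary presence. Unknown
#' species or planning-unit ids in `puvspr.dat`, duplicated ids, and
#' malformed rows are errors naming the offenders.
#'
#' @param dir directory holding the three files.
#' @return an `n2k_problem`; the `pu.dat` status column, if present, is
#'   attached as attribute `pu_status`.
#' @export
read_marxan_inputs <- function(dir) {
  spec <- read_marxan_table(dir, "spec.dat", c("id", "target", "spf"))
  pu <- read_marxan_table(dir, "pu.dat", c("id", "cost"))
  puvspr <- read_marxan_table(dir, "puvspr.dat", c("species", "pu", "amount"))
  if (anyDuplicated(spec$id)) {
    stop(sprintf("spec.dat: duplicate id(s): %s",
                 paste(unique(spec$id[duplicated(spec$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(pu$id)) {
    stop(sprintf("pu.dat: duplicate id(s): %s",
                 paste(unique(pu$id[duplicated(pu$id)]), collapse = ", ")),
         call. = FALSE)
  }
  bad_pu <- which(!(puvspr$pu %in% pu$id))
  if (length(bad_pu) > 0) {
    stop(sprintf("puvspr.dat: unknown pu id(s) %s (row %s)",
                 paste(unique(puvspr$pu[bad_pu]), collapse = ", "),
                 paste(bad_pu + 1, collapse = ", ")), call. = FALSE)
  }
  bad_sp <- which(!(puvspr$species %in% spec$id))
  if (length(bad_sp) > 0) {
    stop(sprintf("puvspr.dat: unknown species id(s) %s (row %s)",
                 paste(unique(puvspr$species[bad_sp]), collapse = ", "),
                 paste(bad_sp + 1, collapse = ", ")), call. = FALSE)
  }
  site_ids <- as.character(pu$id)
  species_ids <- if ("name" %in% names(spec)) as.character(spec$name)
                 else as.character(spec$id)
  benefit <- matrix(0L, nrow = nrow(pu), ncol = nrow(spec),
                    dimnames = list(site_ids, species_ids))
  keep <- puvspr$amount > 0
  benefit[cbind(match(puvspr$pu[keep], pu$id),
                match(puvspr$species[keep], spec$id))] <- 1L
  prob <- n2k_problem(benefit, cost = pu$cost, target = spec$target,
                      spf = spec$spf)
  if ("status" %in% names(pu)) attr(prob, "pu_status") <- pu$status
  prob
}

#' Write a problem as Marxan-dialect input files
#'
#' @param problem an `n2k_problem`.
#' @param dir output directory (created if missing).
#' @param sep field separator: `","` (default) or `"\t"`.
#' @return `dir`, invisibly.
#' @export
write_marxan <- function(problem, dir, sep = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(problem$species_ids)
  m <- length(problem$site_ids)
  spec <- data.frame(id = seq_len(n), target = problem$target,
                     spf = problem$spf, name = problem$species_ids)
  pu <- data.frame(id = seq_len(m), cost = problem$cost, status = 0L)
  idx <- which(problem$benefit == 1L, arr.ind = TRUE)
  puvspr <- data.frame(species = idx[, 2], pu = idx[, 1], amount = 1L)
  puvspr <- puvspr[order(puvspr$species, puvspr$pu), , drop = FALSE]
  write.table(spec, file.path(dir, "spec.dat"), sep = sep, row.names = FALSE,
              quote = FALSE)
  write.table(pu, file.path(dir, "pu.dat"), sep = sep, row.names = FALSE,
              quote = FALSE)
  write.table(puvspr, file.path(dir, "puvspr.dat"), sep = sep,
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write scenario results as CSV tables plus a JSON manifest
#'
#' Emits `solutions.csv` (bootstrap, site_id of each selected site),
#' `assignments.csv` (bootstrap, site_id, species_id, origin),
#' `bootstrap_summary.csv` (bootstrap, selected_sites, updated_sites,
#' objective decomposition) and `manifest.json` (config echo, seeds, record
#' counts). CSV row order is deterministic for a fixed result.
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sols <- do.call(rbind, lapply(seq_along(result$best_solutions), function(b) {
    sel <- result$best_solutions[[b]]$selected
    if (length(sel) == 0) return(NULL)
    data.frame(bootstrap = b, site_id = sort(sel), stringsAsFactors = FALSE)
  }))
  if (is.null(sols)) {
    sols <- data.frame(bootstrap = integer(0), site_id = character(0))
  }
  write.csv(sols, file.path(dir, "solutions.csv"), row.names = FALSE)
  write.csv(result$assignments, file.path(dir, "assignments.csv"),
            row.names = FALSE)
  summary <- data.frame(
    bootstrap = seq_along(result$best_solutions),
    selected_sites = result$selected_site_counts,
    updated_sites = result$updated_site_counts,
    total = vapply(result$best_solutions, function(s) s$objective$total,
                   numeric(1)),
    cost_term = vapply(result$best_solutions,
                       function(s) s$objective$cost_term, numeric(1)),
    penalty_term = vapply(result$best_solutions,
                          function(s) s$objective$penalty_term, numeric(1)))
  write.csv(summary, file.path(dir, "bootstrap_summary.csv"),
            row.names = FALSE)
  manifest <- list(
    tool = "n2kprior",
    version = as.character(utils::packageVersion("n2kprior")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(result$config_echo),
    n_sites = length(result$site_ids),
    n_species = length(result$species_ids),
    n_bootstraps = length(result$best_solutions),
    n_assignment_records = nrow(result$assignments))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write selection-frequency tables as CSV
#'
#' `site_frequencies.csv` gains per-site richness columns
#' (`richness_listed`, `richness_threatened`) when a dataset is supplied.
#'
#' @param freq_table a [selection_frequencies()] result.
#' @param dir output directory (created if missing).
#' @param dataset optional `n2k_dataset` for the richness columns.
#' @return `dir`, invisibly.
#' @export
write_frequencies <- function(freq_table, dir, dataset = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sf <- freq_table$site_freq
  if (!is.null(dataset)) {
    thr <- dataset$species$species_id[is_threatened(dataset$species$iucn_status)]
    lst <- dataset$species$species_id[dataset$species$annex_listed]
    occ <- dataset$occurrence[sf$site_id, , drop = FALSE]
    sf$richness_listed <- as.integer(rowSums(occ[, intersect(lst, colnames(occ)),
                                                 drop = FALSE]))
    sf$richness_threatened <- as.integer(rowSums(occ[, intersect(thr, colnames(occ)),
                                                     drop = FALSE]))
  }
  write.csv(sf, file.path(dir, "site_frequencies.csv"), row.names = FALSE)
  write.csv(freq_table$species_site_freq,
            file.path(dir, "species_site_frequencies.csv"), row.names = FALSE)
  invisible(dir)
}
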