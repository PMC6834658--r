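#' Species eligible under a planning scenario
#'
#' The policy-driven scenario considers threatened species listed in the
#' directives' annexes; the conservation-driven scenario considers all
#' threatened species, listed or not (set `unlisted_only = TRUE` to restrict
#' it to the unlisted threatened species instead).
#'
#' @param dataset an `n2k_dataset`.
#' @param scenario `"policy"` or `"conservation"`.
#' @param unlisted_only for the conservation scenario, keep only species not
#'   annex-listed (default FALSE: all threatened species).
#' @return character vector of species identifiers.
#' @export
scenario_species <- function(dataset, scenario, unlisted_only = FALSE) {
  sp <- dataset$species
  thr <- is_threatened(sp$iucn_status)
  switch(scenario,
    policy = sp$species_id[thr & sp$annex_listed],
    conservation = if (unlisted_only) sp$species_id[thr & !sp$annex_listed]
                   else sp$species_id[thr],
    stop(sprintf("unknown scenario '%s' (use 'policy' or 'conservation')",
                 scenario), call. = FALSE))
}

#' Configuration of one prioritisation experiment
#'
#' Desk-scale defaults (50 bootstraps, 10 annealing restarts of 1e5
#' iterations) keep a full experiment tractable on one core; the full-scale
#' design of the original analysis (1000 bootstraps, 100 restarts of 5e6
#' iterations) is reachable by configuration.
#'
#' @param scenario `"policy"` or `"conservation"`.
#' @param threshold maximum non-declared additions per site (sensitivity
#'   sweep in the original design: 2, 5, 10, 20, 50).
#' @param n_bootstraps number of bootstrap replicates of the pool draw.
#' @param n_runs annealing restarts per bootstrap.
#' @param iterations annealing iterations per run.
#' @param target per-species representation target (sites).
#' @param spf species penalty factor.
#' @param cost per-site cost.
#' @param master_seed integer master seed; all replicate and run streams are
#'   derived from it with [subseed()].
#' @param count_declared_as_locked when TRUE, sites where a species is
#'   already declared count toward its representation without being selected
#'   (locked contributions); default FALSE (pure masked-benefit objective).
#' @param unlisted_only passed to [scenario_species()].
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(scenario, threshold = 10, n_bootstraps = 50,
                            n_runs = 10, iterations = 1e5, target = 10,
                            spf = 10, cost = 1, master_seed = 1L,
                            count_declared_as_locked = FALSE,
                            unlisted_only = FALSE) {
  if (!scenario %in% c("policy", "conservation")) {
    stop_config("scenario", "must be 'policy' or 'conservation'")
  }
  for (f in c("threshold", "n_bootstraps", "n_runs", "iterations", "target")) {
    v <- get(f)
    if (length(v) != 1 || !is.finite(v) || v < 1) {
      stop_config(f, "must be a count >= 1")
    }
  }
  if (spf < 0) stop_config("spf", "must be >= 0")
  if (cost <= 0) stop_config("cost", "must be > 0")
  structure(list(scenario = scenario, threshold = as.integer(threshold),
                 n_bootstraps = as.integer(n_bootstraps),
                 n_runs = as.integer(n_runs),
                 iterations = as.integer(iterations),
                 target = target, spf = spf, cost = cost,
                 master_seed = as.integer(master_seed),
                 count_declared_as_locked = isTRUE(count_declared_as_locked),
                 unlisted_only = isTRUE(unlisted_only)),
            class = "scenario_config")
}

#' Run a full bootstrap prioritisation experiment
#'
#' For each bootstrap replicate: draws candidate pools for every site on a
#' replicate-specific sub-seeded stream, assembles the masked benefit matrix
#' (`a_ij = 1` iff species j is in site i's pool), clamps targets to
#' achievable representation, solves by best-of-`n_runs` simulated annealing,
#' and assigns species to the selected sites (with greedy trimming of
#' vacuous additions). Deterministic for a fixed `master_seed`. Species that
#' occur in no site are excluded up front with a warning; species that enter
#' no pool in a given replicate are excluded from that replicate's problem.
#'
#' @param dataset an `n2k_dataset`.
#' @param config a [scenario_config()].
#' @return object of class `scenario_result`: list with `best_solutions`
#'   (one `n2k_solution` per bootstrap), `assignments` (long data frame:
#'   bootstrap, site_id, species_id, origin in {declared, added}),
#'   `updated_site_counts`, `selected_site_counts`, `targets` (per-bootstrap
#'   named clamped-target vectors), `availability` (bootstrap x species
#'   matrix of pool-availability counts), `pools_digest` (data frame:
#'   bootstrap, site_id, pool_size, n_added), `site_ids`, `species_ids`,
#'   and `config_echo`.
#' @export
run_scenario <- function(dataset, config) {
  stopifnot(inherits(config, "scenario_config"))
  sp <- scenario_species(dataset, config$scenario, config$unlisted_only)
  if (length(sp) == 0) {
    stop("scenario species set is empty", call. = FALSE)
  }
  occ_counts <- colSums(dataset$occurrence[, sp, drop = FALSE])
  if (any(occ_counts == 0)) {
    warning(sprintf("excluding %d species occurring in no site: %s",
                    sum(occ_counts == 0),
                    paste(sp[occ_counts == 0], collapse = ", ")),
            call. = FALSE)
    sp <- sp[occ_counts > 0]
    if (length(sp) == 0) stop("no feasible scenario species", call. = FALSE)
  }
  site_ids <- dataset$sites$site_id
  nb <- config$n_bootstraps

  declared_counts <- vapply(sp, function(j) {
    sum(vapply(dataset$declared, function(d) j %in% d, logical(1)))
  }, integer(1))

  best_solutions <- vector("list", nb)
  assignments <- vector("list", nb)
  targets <- vector("list", nb)
  availability <- matrix(0L, nrow = nb, ncol = length(sp),
                         dimnames = list(NULL, sp))
  pools_digest <- vector("list", nb)
  updated <- integer(nb)
  selected <- integer(nb)

  for (b in seq_len(nb)) {
    pools <- build_all_pools(dataset, sp, config$threshold,
                             seed = subseed(config$master_seed, b, 0))
    benefit <- vapply(pools, function(p) as.integer(sp %in% p$available),
                      integer(length(sp)))
    benefit <- t(matrix(benefit, nrow = length(sp)))  # robust to 1 species
    dimnames(benefit) <- list(site_ids, sp)
    offset <- rep(0, length(sp))
    if (config$count_declared_as_locked) {
      offset <- declared_counts
      for (i in site_ids) {
        dec <- intersect(dataset$declared[[i]], sp)
        if (length(dec)) benefit[i, dec] <- 0L
      }
    }
    availability[b, ] <- colSums(benefit)
    keep <- colSums(benefit) + offset > 0
    prob <- n2k_problem(benefit[, keep, drop = FALSE], cost = config$cost,
                        target = config$target, spf = config$spf,
                        rep_offset = offset[keep])
    prob <- clamp_targets(prob, warn = FALSE)
    sol <- best_of_runs(prob, n_runs = config$n_runs,
                        iterations = config$iterations,
                        seed = subseed(config$master_seed, b, 1))
    asg <- assign_species(sol, pools, dataset$declared, prob,
                          include_declared = !config$count_declared_as_locked)
    best_solutions[[b]] <- sol
    targets[[b]] <- stats::setNames(prob$target, prob$species_ids)
    assignments[[b]] <- if (nrow(asg)) cbind(bootstrap = b, asg) else NULL
    pools_digest[[b]] <- data.frame(
      bootstrap = b, site_id = site_ids,
      pool_size = vapply(pools, function(p) length(p$available), integer(1)),
      n_added = vapply(pools, function(p) p$n_added, integer(1)),
      stringsAsFactors = FALSE)
    updated[b] <- length(unique(asg$site_id[asg$origin == "added"]))
    selected[b] <- length(sol$selected)
  }
  asg_all <- do.call(rbind, assignments)
  if (is.null(asg_all)) {
    asg_all <- data.frame(bootstrap = integer(0), site_id = character(0),
                          species_id = character(0), origin = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(asg_all) <- NULL
  structure(list(
    best_solutions = best_solutions,
    assignments = asg_all,
    updated_site_counts = updated,
    selected_site_counts = selected,
    targets = targets,
    availability = availability,
    pools_digest = do.call(rbind, pools_digest),
    site_ids = site_ids,
    species_ids = sp,
    config_echo = config
  ), class = "scenario_result")
}

#' Assign species to the selected sites of one solution
#'
#' For every selected site, the species counted toward representation are the
#' problem species available in its pool; those not already declared there
#' are proposed additions to the site's target list. Surplus additions are
#' then trimmed greedily: processing sites in descending redundancy (number
#' of droppable additions), an addition is dropped whenever the species'
#' remaining assignment count still meets its (clamped) target without it.
#' Declared-origin assignments are never dropped. A selected site whose
#' additions are all trimmed away requires no list update.
#'
#' @param solution an `n2k_solution`.
#' @param pools pool map the solution was solved against.
#' @param declared named list site_id -> declared target species.
#' @param problem the (clamped) `n2k_problem` of the same bootstrap.
#' @param include_declared keep declared-origin assignments (default TRUE);
#'   set FALSE when declared sites are already credited through the
#'   problem's `rep_offset` (locked-contribution mode), where listing them
#'   again would double-count representation during trimming.
#' @return data frame (site_id, species_id, origin in {declared, added}).
#' @export
assign_species <- function(solution, pools, declared, problem,
                           include_declared = TRUE) {
  empty <- data.frame(site_id = character(0), species_id = character(0),
                      origin = character(0), stringsAsFactors = FALSE)
  if (length(solution$selected) == 0) return(empty)
  rows <- lapply(solution$selected, function(i) {
    avail <- intersect(pools[[i]]$available, problem$species_ids)
    if (!include_declared) avail <- setdiff(avail, declared[[i]])
    if (length(avail) == 0) return(NULL)
    data.frame(site_id = i, species_id = avail,
               origin = ifelse(avail %in% declared[[i]], "declared", "added"),
               stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, rows)
  if (is.null(asg)) return(empty)
  tgt <- stats::setNames(pmax(problem$target - problem$rep_offset, 0),
                         problem$species_ids)
  count <- table(factor(asg$species_id, levels = problem$species_ids))
  repeat {
    droppable <- asg$origin == "added" &
      as.vector(count[asg$species_id]) > tgt[asg$species_id]
    if (!any(droppable)) break
    red <- tapply(droppable, asg$site_id, sum)
    site <- names(red)[which.max(red)]
    idx <- which(droppable & asg$site_id == site)
    drop_rows <- integer(0)
    for (k in idx) {
      j <- asg$species_id[k]
      if (count[j] > tgt[j]) {
        drop_rows <- c(drop_rows, k)
        count[j] <- count[j] - 1
      }
    }
    if (length(drop_rows) == 0) break
    asg <- asg[-drop_rows, , drop = FALSE]
    count <- table(factor(asg$species_id, levels = problem$species_ids))
  }
  asg <- asg[order(asg$site_id, asg$species_id), , drop = FALSE]
  rownames(asg) <- NULL
  asg
}
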