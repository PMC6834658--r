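test_that("scenario species filters follow the policy/conservation split", {
  ps <- pseudo_species_from_counts(vertebrate_status_counts()$cells)
  ds <- list(species = ps)
  expect_length(scenario_species(ds, "policy"), 113)
  expect_length(scenario_species(ds, "conservation"), 322)
  expect_length(scenario_species(ds, "conservation", unlisted_only = TRUE),
                322 - 113)
  expect_error(scenario_species(ds, "bau"), "unknown scenario")

  none <- list(species = data.frame(species_id = "a", taxon = "fish",
                                    iucn_status = "LC", annex_listed = TRUE))
  expect_length(scenario_species(none, "policy"), 0)
  expect_length(scenario_species(none, "conservation"), 0)
})

test_that("scenario configs are validated", {
  expect_error(scenario_config("neither"), "scenario")
  expect_error(scenario_config("policy", n_bootstraps = 0), "n_bootstraps")
  expect_error(scenario_config("policy", spf = -1), "spf")
  cfg <- scenario_config("policy", threshold = 5)
  expect_s3_class(cfg, "scenario_config")
})

test_that("a full run is deterministic for a fixed master seed", {
  ds <- small_dataset(8, n_sites = 60)
  cfg <- scenario_config("conservation", threshold = 8, n_bootstraps = 2,
                         n_runs = 2, iterations = 5000, master_seed = 13)
  r1 <- run_scenario(ds, cfg)
  r2 <- run_scenario(ds, cfg)
  expect_equal(r1, r2)
})

test_that("feasible instances meet every clamped target in every bootstrap", {
  ds <- small_dataset(10, n_sites = 100,
                      range_size_distribution = c(log(40), 0.5))
  for (scen in c("policy", "conservation")) {
    cfg <- scenario_config(scen, threshold = 50, n_bootstraps = 2,
                           n_runs = 3, iterations = 20000, target = 5,
                           master_seed = 3)
    res <- run_scenario(ds, cfg)
    for (b in seq_along(res$best_solutions)) {
      sol <- res$best_solutions[[b]]
      expect_equal(sol$objective$penalty_term, 0)
      expect_true(all(sol$representation >= res$targets[[b]]))
    }
    expect_true(all(res$updated_site_counts <= res$selected_site_counts))
    expect_true(all(res$selected_site_counts <= nrow(ds$sites)))
  }
})

test_that("species assignment covers targets and trims vacuous additions", {
  # no selected sites -> empty assignment
  pools <- list(A = structure(list(available = "sp1",
                                   origin = "habitat", n_added = 1L),
                              class = "candidate_pool"))
  pr <- n2k_problem(matrix(1L, 1, 1, dimnames = list("A", "sp1")), target = 1,
                    spf = 10)
  none <- list(selected = character(0))
  expect_equal(nrow(assign_species(none, pools, list(A = character(0)), pr)), 0)

  # single selected site whose pool adds one species beyond the declared list
  pools2 <- list(A = structure(list(available = c("d1", "sp9"),
                                    origin = c("declared", "habitat"),
                                    n_added = 1L), class = "candidate_pool"))
  pr2 <- n2k_problem(matrix(1L, 1, 1, dimnames = list("A", "sp9")),
                     target = 1, spf = 10)
  asg <- assign_species(list(selected = "A"), pools2, list(A = "d1"), pr2)
  expect_equal(asg$species_id, "sp9")
  expect_equal(asg$origin, "added")

  # a redundant selected site loses its vacuous addition
  benefit <- matrix(1L, 2, 1, dimnames = list(c("A", "B"), "sp1"))
  pr3 <- n2k_problem(benefit, target = 1, spf = 10)
  pools3 <- list(
    A = structure(list(available = "sp1", origin = "habitat", n_added = 1L),
                  class = "candidate_pool"),
    B = structure(list(available = "sp1", origin = "habitat", n_added = 1L),
                  class = "candidate_pool"))
  dec <- list(A = character(0), B = character(0))
  asg3 <- assign_species(list(selected = c("A", "B")), pools3, dec, pr3)
  expect_equal(nrow(asg3), 1)  # the exhaustive minimal assignment uses one site
})

test_that("locked declared contributions reduce the selection burden", {
  # one species declared in 3 sites; target 3 is already met without selection
  occ <- matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "SP1"))
  ds <- manual_dataset(occ, declared = list(A = "SP1", B = "SP1", C = "SP1"))
  cfg <- scenario_config("conservation", threshold = 5, n_bootstraps = 1,
                         n_runs = 2, iterations = 2000, target = 3,
                         master_seed = 1, count_declared_as_locked = TRUE)
  res <- run_scenario(ds, cfg)
  expect_equal(res$selected_site_counts, 0L)
  expect_equal(res$updated_site_counts, 0L)

  cfg_off <- scenario_config("conservation", threshold = 5, n_bootstraps = 1,
                             n_runs = 2, iterations = 2000, target = 3,
                             master_seed = 1)
  res_off <- run_scenario(ds, cfg_off)
  expect_equal(res_off$selected_site_counts, 3L)
  # declared species need no list update even when their sites are selected
  expect_true(all(res_off$assignments$origin == "declared"))
  expect_equal(res_off$updated_site_counts, 0L)
})

test_that("species occurring nowhere are excluded with a warning", {
  occ <- matrix(c(1L, 1L, 0L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("SP1", "SP2")))
  sp <- data.frame(species_id = c("SP1", "SP2"), taxon = "fish",
                   iucn_status = "EN", annex_listed = TRUE,
                   stringsAsFactors = FALSE)
  ds <- manual_dataset(occ, species = sp)
  cfg <- scenario_config("conservation", threshold = 5, n_bootstraps = 1,
                         n_runs = 1, iterations = 1000, target = 1,
                         master_seed = 1)
  expect_warning(res <- run_scenario(ds, cfg), "SP2")
  expect_equal(res$species_ids, "SP1")
})
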