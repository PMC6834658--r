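run_small <- function(seed = 1, nb = 4, scen = "conservation", target = 3) {
  ds <- small_dataset(seed, n_sites = 60,
                      range_size_distribution = c(log(15), 0.8))
  cfg <- scenario_config(scen, threshold = 10, n_bootstraps = nb,
                         n_runs = 2, iterations = 8000, target = target,
                         master_seed = seed)
  list(ds = ds, res = run_scenario(ds, cfg))
}

test_that("site selection frequencies count bootstrap membership", {
  rs <- run_small(2, nb = 1)
  ft <- selection_frequencies(rs$res)
  expect_true(all(ft$site_freq$count %in% c(0L, 1L)))
  expect_setequal(ft$site_freq$site_id[ft$site_freq$count == 1L],
                  rs$res$best_solutions[[1]]$selected)

  rs4 <- run_small(3, nb = 4)
  ft4 <- selection_frequencies(rs4$res)
  # conservation identity: total site-frequency mass = total selected sites
  expect_equal(sum(ft4$site_freq$count), sum(rs4$res$selected_site_counts))
  expect_true(all(ft4$site_freq$count <= 4))
  # a pair frequency never exceeds its site frequency
  sfreq <- stats::setNames(ft4$site_freq$count, ft4$site_freq$site_id)
  expect_true(all(ft4$species_site_freq$count <=
                    sfreq[ft4$species_site_freq$site_id]))
})

test_that("assignments cover each species' target in target-met bootstraps", {
  rs <- run_small(5, nb = 4)
  ft <- selection_frequencies(rs$res)
  pair_sum <- tapply(ft$species_site_freq$count, ft$species_site_freq$species_id,
                     sum)
  for (j in rs$res$species_ids) {
    met_targets <- vapply(seq_along(rs$res$best_solutions), function(b) {
      t_j <- rs$res$targets[[b]][j]
      if (is.na(t_j)) return(0)  # species dropped from this bootstrap's problem
      r_j <- rs$res$best_solutions[[b]]$representation[j]
      if (!is.na(r_j) && r_j >= t_j) t_j else 0
    }, numeric(1))
    s <- pair_sum[j]
    if (is.na(s)) s <- 0
    expect_gte(s, sum(met_targets))
  }
})

test_that("a narrow-range species is assigned to all its sites in every bootstrap", {
  # SPN occupies exactly 3 sites with target 3; SPW is widespread
  occ <- matrix(0L, 8, 2, dimnames = list(sprintf("S%d", 1:8), c("SPN", "SPW")))
  occ[1:3, "SPN"] <- 1L
  occ[, "SPW"] <- 1L
  sp <- data.frame(species_id = c("SPN", "SPW"), taxon = "mammal",
                   iucn_status = c("CR", "VU"), annex_listed = TRUE,
                   stringsAsFactors = FALSE)
  ds <- manual_dataset(occ, species = sp)
  cfg <- scenario_config("conservation", threshold = 10, n_bootstraps = 5,
                         n_runs = 3, iterations = 5000, target = 3,
                         master_seed = 2)
  res <- run_scenario(ds, cfg)
  ft <- selection_frequencies(res)
  narrow <- ft$species_site_freq[ft$species_site_freq$species_id == "SPN", ]
  expect_setequal(narrow$site_id, c("S1", "S2", "S3"))
  expect_true(all(narrow$count == 5L))
})

test_that("richness-frequency association handles defined and degenerate cases", {
  # identical ranks: rho = 1
  occ <- matrix(0L, 5, 5, dimnames = list(paste0("S", 1:5), paste0("sp", 1:5)))
  for (i in 1:5) occ[i, seq_len(i)] <- 1L
  ft <- structure(list(site_freq = data.frame(
    site_id = paste0("S", 1:5), count = c(1L, 2L, 3L, 4L, 5L),
    proportion = c(1, 2, 3, 4, 5) / 5)), class = "selection_frequency_table")
  out <- richness_frequency_association(ft, occ, paste0("sp", 1:5))
  expect_equal(out$statistic, 1)

  # constant frequencies: undefined, warned, NA
  ftc <- structure(list(site_freq = data.frame(
    site_id = paste0("S", 1:5), count = rep(2L, 5),
    proportion = rep(0.5, 5))), class = "selection_frequency_table")
  expect_warning(outc <- richness_frequency_association(ftc, occ, paste0("sp", 1:4)),
                 "undefined")
  expect_true(is.na(outc$statistic))
})

test_that("the permutation null of the rank statistic is centred on zero", {
  set.seed(77)
  n <- 30
  richness <- sample.int(20, n, replace = TRUE)
  freq <- sample.int(10, n, replace = TRUE)
  stats <- replicate(1000, cor(richness, sample(freq), method = "spearman"))
  # null sd of Spearman's rho is ~ 1/sqrt(n - 1)
  mc_se <- (1 / sqrt(n - 1)) / sqrt(1000)
  expect_lt(abs(mean(stats)), 4 * mc_se)
})

test_that("the Gini concentration index matches its closed forms and oracle", {
  expect_equal(concentration_index(rep(5, 8)), 0)
  for (k in c(2, 5, 10)) {
    degenerate <- c(rep(0, k - 1), 7)
    expect_equal(concentration_index(degenerate), (k - 1) / k)
  }
  gini_oracle <- function(f) {
    k <- length(f)
    sum(outer(f, f, function(a, b) abs(a - b))) / (2 * k^2 * mean(f))
  }
  set.seed(12)
  for (rep in 1:10) {
    f <- rpois(20, 3)
    if (sum(f) == 0) f[1] <- 1
    expect_equal(concentration_index(f), gini_oracle(f), tolerance = 1e-12)
  }
  expect_error(concentration_index(rep(0, 4)), "all-zero")
  expect_error(concentration_index(numeric(0)), "nonempty")
})
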