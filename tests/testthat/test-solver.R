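test_that("objective evaluates the penalty-factor formula exactly", {
  # empty selection: every species fully short, s/t = 1, penalty = SPF per species
  benefit <- matrix(1L, nrow = 5, ncol = 4)
  ov0 <- objective(rep(0, 5), n2k_problem(benefit, cost = 1, target = 10, spf = 10))
  expect_equal(ov0$cost_term, 0)
  expect_equal(ov0$penalty_term, 10 * 4)
  expect_equal(ov0$total, 40)

  # all sites selected, all (clamped) targets met: pure cost
  ov1 <- objective(rep(1, 5), n2k_problem(benefit, cost = 1, target = 5, spf = 10))
  expect_equal(ov1$penalty_term, 0)
  expect_equal(ov1$total, 5)

  # hand-built 4-site, 2-species toy: r = (2, 1), total = 2 + 10 * (1/2) = 7
  a <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 1L, 1L), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("sp1", "sp2")))
  toy <- n2k_problem(a, cost = 1, target = 2, spf = 10)
  ov <- objective(c(1, 1, 0, 0), toy)
  expect_equal(unname(ov$representation), c(2L, 1L))
  expect_equal(ov$total, 7)

  expect_error(objective(c(1, 0), toy), "length")
})

test_that("the objective decomposes exactly on random states", {
  set.seed(21)
  for (k in 1:25) {
    pr <- random_problem(m = 10, n = 6)
    x <- as.integer(runif(10) < 0.5)
    ov <- objective(x, pr)
    expect_identical(ov$total, ov$cost_term + ov$penalty_term)
    expect_true(all(ov$shortfalls / pr$target <= 1 + 1e-12))
  }
})

test_that("incremental flip deltas equal from-scratch recomputation", {
  set.seed(31)
  for (k in 1:10) {
    pr <- random_problem(m = 12, n = 8)
    x <- as.integer(runif(12) < 0.5)
    for (f in 1:100) {
      i <- sample.int(12, 1)
      x2 <- x
      x2[i] <- 1L - x2[i]
      expect_equal(objective_delta(x, i, pr),
                   objective(x2, pr)$total - objective(x, pr)$total,
                   tolerance = 1e-12)
      x <- x2
    }
  }
})

test_that("exhaustive enumeration handles trivial and toy instances", {
  # no sites: total is the penalty of the empty selection
  pr0 <- n2k_problem(matrix(0L, 0, 2), target = 1, spf = 10)
  s0 <- solve_exact(pr0)
  expect_equal(s0$objective$total, 20)

  # two sites, one exclusive species each: both must be selected
  a <- diag(2)
  pr <- n2k_problem(a, cost = 1, target = 1, spf = 10)
  s <- solve_exact(pr)
  expect_equal(unname(s$x), c(1L, 1L))
  expect_equal(s$objective$total, 2)

  expect_error(solve_exact(n2k_problem(matrix(1L, 21, 1), target = 1)),
               "20 sites")
})

test_that("penalty-dominant exact optima meet every target", {
  set.seed(41)
  for (k in 1:15) {
    pr <- random_problem(m = 10, n = 6, spf = 200)  # SPF/t >> m * max cost
    s <- solve_exact(pr)
    expect_equal(s$objective$penalty_term, 0)
    expect_true(all(s$representation >= pr$target))
  }
})

test_that("greedy solves the set-cover toy and never beats the exact optimum", {
  # one site covers both species; two others cover one each
  a <- matrix(c(1L, 1L, 0L,
                1L, 0L, 1L), nrow = 3)
  pr <- n2k_problem(a, cost = 1, target = 1, spf = 10)
  g <- solve_greedy(pr)
  expect_equal(unname(g$x), c(1L, 0L, 0L))
  expect_equal(g$objective$total, 1)

  # nothing to gain: all-zero benefit with zero penalty weight
  pr0 <- n2k_problem(matrix(0L, 3, 2), target = 1, spf = 0)
  expect_equal(sum(solve_greedy(pr0)$x), 0)

  set.seed(51)
  for (k in 1:20) {
    pr <- random_problem(m = 9, n = 6)
    expect_gte(solve_greedy(pr)$objective$total,
               solve_exact(pr)$objective$total - 1e-9)
  }
})

test_that("annealing is deterministic and solves the single-site instance", {
  pr1 <- n2k_problem(matrix(1L, 1, 3), cost = 1, target = 1, spf = 10)
  s <- solve_sa(pr1, iterations = 500, seed = 5)
  expect_equal(sum(s$x), 1)
  expect_equal(s$objective$total, 1)

  pr <- random_problem(m = 12, n = 8)
  a <- solve_sa(pr, iterations = 5000, seed = 17)
  b <- solve_sa(pr, iterations = 5000, seed = 17)
  expect_identical(a$x, b$x)
  expect_identical(a$objective$total, b$objective$total)
})

test_that("annealing is competitive with greedy and bounded by the exact optimum", {
  set.seed(61)
  wins <- 0
  for (k in 1:20) {
    pr <- random_problem(m = 12, n = 8)
    sa <- solve_sa(pr, iterations = 20000, seed = 100 + k)
    ex <- solve_exact(pr)
    gr <- solve_greedy(pr)
    expect_gte(sa$objective$total, ex$objective$total - 1e-9)
    if (sa$objective$total <= gr$objective$total + 1e-9) wins <- wins + 1
  }
  expect_gte(wins, 10)
})

test_that("best-of-runs returns the lowest-total run and is monotone", {
  pr <- random_problem(m = 12, n = 8)
  one <- best_of_runs(pr, n_runs = 1, iterations = 2000, seed = 9)
  direct <- solve_sa(pr, iterations = 2000, seed = subseed(9, 1))
  expect_identical(one$x, direct$x)

  ten <- best_of_runs(pr, n_runs = 10, iterations = 2000, seed = 9)
  totals <- attr(ten, "run_totals")
  expect_equal(ten$objective$total, min(totals))

  # nested seed sequences: adding runs never raises the returned total
  prev <- Inf
  for (r in c(1, 3, 5, 10)) {
    tot <- best_of_runs(pr, n_runs = r, iterations = 2000, seed = 9)$objective$total
    expect_lte(tot, prev + 1e-12)
    prev <- tot
  }
})

test_that("target clamping lowers unattainable targets with a warning", {
  a <- matrix(c(1L, 0L, 1L, 1L), nrow = 2)
  pr <- n2k_problem(a, target = 2, spf = 10)
  expect_warning(clamped <- clamp_targets(pr), "clamped")
  expect_equal(clamped$target, c(1, 2))
  expect_silent(clamp_targets(n2k_problem(a, target = 1)))
})
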