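#' Construct a minimum-set selection problem
#'
#' Bundles the inputs of the reserve-selection objective: a binary benefit
#' matrix (site x species; 1 iff the species is available at the site, i.e.
#' is in its candidate pool), per-site costs, per-species representation
#' targets and species penalty factors (SPF). The objective minimised is
#' `sum_i c_i x_i + sum_j SPF_j H(s_j) s_j / t_j` with shortfall
#' `s_j = max(0, t_j - r_j)` and representation `r_j = sum_i x_i a_ij`; the
#' normalised shortfall `s_j / t_j` is 1 when a species is unrepresented and
#' approaches 0 as representation approaches the target. A species' target
#' counts as met when `r_j >= t_j`.
#'
#' @param benefit binary matrix, sites in rows, species in columns.
#' @param cost per-site cost, recycled to the number of sites; default 1
#'   (constant management-effort units).
#' @param target per-species representation target, recycled; default 10.
#' @param spf per-species penalty factor, recycled; default 10.
#' @param rep_offset per-species representation credited regardless of
#'   selection (e.g. sites where the species is already a declared target,
#'   when those are treated as locked contributions); default 0.
#' @return object of class `n2k_problem`.
#' @export
n2k_problem <- function(benefit, cost = 1, target = 10, spf = 10,
                        rep_offset = 0) {
  benefit <- as.matrix(benefit)
  if (!all(benefit %in% c(0, 1))) {
    stop("benefit matrix must be binary", call. = FALSE)
  }
  m <- nrow(benefit)
  n <- ncol(benefit)
  cost <- rep_len(as.numeric(cost), m)
  target <- rep_len(as.numeric(target), n)
  spf <- rep_len(as.numeric(spf), n)
  rep_offset <- rep_len(as.numeric(rep_offset), n)
  if (m > 0 && any(cost <= 0)) stop("cost must be > 0", call. = FALSE)
  if (n > 0 && any(target < 1)) stop("target must be >= 1", call. = FALSE)
  if (n > 0 && any(spf < 0)) stop("spf must be >= 0", call. = FALSE)
  storage.mode(benefit) <- "integer"
  structure(list(
    site_ids = if (is.null(rownames(benefit))) as.character(seq_len(m)) else rownames(benefit),
    species_ids = if (is.null(colnames(benefit))) as.character(seq_len(n)) else colnames(benefit),
    benefit = benefit, cost = cost, target = target, spf = spf,
    rep_offset = rep_offset
  ), class = "n2k_problem")
}

#' Clamp targets to achievable representation
#'
#' Replaces each target by `min(t_j, rep_offset_j + number of sites where the
#' species is available)`, so that instances where a species cannot reach its
#' nominal target remain meaningfully scored. Emits one warning naming the
#' number of clamped species.
#'
#' @param problem an `n2k_problem`.
#' @param warn warn when any target is lowered (default TRUE).
#' @return the problem with clamped targets.
#' @export
clamp_targets <- function(problem, warn = TRUE) {
  avail <- problem$rep_offset + colSums(problem$benefit)
  clamped <- pmin(problem$target, avail)
  if (warn && any(clamped < problem$target)) {
    warning(sprintf("target clamped for %d species to available representation",
                    sum(clamped < problem$target)), call. = FALSE)
  }
  problem$target <- clamped
  problem
}

penalty_terms <- function(r_total, target, spf) {
  s <- pmax(0, target - r_total)
  ifelse(target > 0, spf * s / target, 0)
}

#' Evaluate the objective of a site-selection vector
#'
#' @param x binary vector over the problem's sites.
#' @param problem an `n2k_problem`.
#' @return object of class `objective_value`: list with `cost_term`,
#'   `penalty_term`, `total` (their exact sum), `shortfalls` and
#'   `representation` (named per-species vectors).
#' @export
objective <- function(x, problem) {
  if (length(x) != nrow(problem$benefit)) {
    stop("selection vector length does not match number of sites", call. = FALSE)
  }
  x <- as.numeric(x)
  r <- as.vector(crossprod(problem$benefit, x))
  r_total <- problem$rep_offset + r
  s <- pmax(0, problem$target - r_total)
  cost_term <- sum(problem$cost * x)
  penalty_term <- sum(penalty_terms(r_total, problem$target, problem$spf))
  structure(list(
    cost_term = cost_term, penalty_term = penalty_term,
    total = cost_term + penalty_term,
    shortfalls = stats::setNames(s, problem$species_ids),
    representation = stats::setNames(as.integer(r), problem$species_ids)
  ), class = "objective_value")
}

#' Objective change from flipping one site
#'
#' The exact difference `objective(flip(x, i)) - objective(x)` computed
#' incrementally (only the species present at site `i` are touched); this is
#' the move evaluation the annealer uses.
#'
#' @param x binary selection vector.
#' @param i site index to flip.
#' @param problem an `n2k_problem`.
#' @return numeric scalar.
#' @export
objective_delta <- function(x, i, problem) {
  dir <- if (x[i] > 0) -1 else 1
  js <- which(problem$benefit[i, ] != 0)
  r <- as.vector(crossprod(problem$benefit[, js, drop = FALSE], as.numeric(x)))
  r_total <- problem$rep_offset[js] + r
  dpen <- sum(penalty_terms(r_total + dir, problem$target[js], problem$spf[js]) -
                penalty_terms(r_total, problem$target[js], problem$spf[js]))
  dir * problem$cost[i] + dpen
}

as_solution <- function(x, problem) {
  x <- as.integer(x)
  obj <- objective(x, problem)
  structure(list(
    x = stats::setNames(x, problem$site_ids),
    selected = problem$site_ids[x == 1L],
    objective = obj,
    representation = obj$representation
  ), class = "n2k_solution")
}

#' @export
print.n2k_solution <- function(x, ...) {
  cat(sprintf("Solution: %d/%d sites selected; total %.4f (cost %.4f + penalty %.4f)\n",
              sum(x$x), length(x$x), x$objective$total,
              x$objective$cost_term, x$objective$penalty_term))
  invisible(x)
}

#' Exhaustive enumeration solver (oracle)
#'
#' Enumerates all `2^m` site subsets and returns the minimum-total solution;
#' ties are broken by fewer selected sites, then by lexicographically
#' smallest selection vector. Intended as a ground-truth oracle on small
#' instances.
#'
#' @param problem an `n2k_problem` with at most 20 sites.
#' @return an `n2k_solution`.
#' @export
solve_exact <- function(problem) {
  m <- nrow(problem$benefit)
  if (m > 20) stop("solve_exact is limited to 20 sites", call. = FALSE)
  if (m == 0) return(as_solution(integer(0), problem))
  subsets <- seq_len(2^m) - 1L
  # bit i of the subset index is x_i with site 1 most significant, so the
  # enumeration order is lexicographic in x
  X <- matrix(0, nrow = 2^m, ncol = m)
  for (i in seq_len(m)) {
    X[, i] <- bitwAnd(subsets, bitwShiftL(1L, m - i)) != 0
  }
  R <- X %*% problem$benefit
  r_total <- sweep(R, 2, problem$rep_offset, "+")
  S <- pmax(sweep(-r_total, 2, problem$target, "+"), 0)
  ratio <- sweep(S, 2, ifelse(problem$target > 0, problem$target, 1), "/")
  pen <- as.vector(ratio %*% problem$spf)
  total <- as.vector(X %*% problem$cost) + pen
  cand <- which(total <= min(total) + 1e-9)
  nsel <- rowSums(X[cand, , drop = FALSE])
  cand <- cand[nsel == min(nsel)]
  best <- cand[1]  # lowest enumeration index = lexicographically smallest x
  as_solution(X[best, ], problem)
}

#' Greedy baseline solver
#'
#' Starts from the empty selection and repeatedly adds the unselected site
#' with the largest decrease in total objective per unit cost, stopping when
#' no addition strictly decreases the total. Ties are broken by lowest site
#' index. A fast baseline and companion oracle to [solve_exact()].
#'
#' @param problem an `n2k_problem`.
#' @return an `n2k_solution`.
#' @export
solve_greedy <- function(problem) {
  m <- nrow(problem$benefit)
  x <- integer(m)
  r_total <- problem$rep_offset + 0
  repeat {
    pen_cur <- penalty_terms(r_total, problem$target, problem$spf)
    pen_next <- penalty_terms(r_total + 1, problem$target, problem$spf)
    gain <- as.vector(problem$benefit %*% (pen_next - pen_cur))
    delta <- problem$cost + gain
    delta[x == 1L] <- Inf
    if (!any(delta < -1e-12)) break
    score <- delta / problem$cost
    score[delta >= -1e-12] <- Inf
    i <- which.min(score)
    x[i] <- 1L
    r_total <- r_total + problem$benefit[i, ]
  }
  as_solution(x, problem)
}

#' Simulated-annealing solver
#'
#' Minimises the species-penalty-factor objective by single-site bit flips:
#' a move is accepted when it does not increase the total, or with
#' probability `exp(-delta / T)` otherwise, with `T` following a geometric
#' cooling schedule. The starting temperature, unless given, is set so the
#' median absolute objective change of 100 sampled random flips would be
#' accepted with probability 0.8. The best state visited is returned
#' (preferring, among equal totals, the state with lower penalty, i.e. the
#' one closer to meeting all targets). Deterministic for a fixed `seed`.
#'
#' @param problem an `n2k_problem`.
#' @param iterations number of flip attempts (default 1e5).
#' @param seed optional integer seed (set before any draw).
#' @param t0 starting temperature; estimated from the instance when NULL.
#' @param t_final_frac final temperature as a fraction of `t0` (default 1e-4).
#' @return an `n2k_solution`.
#' @export
solve_sa <- function(problem, iterations = 1e5, seed = NULL, t0 = NULL,
                     t_final_frac = 1e-4) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(problem$benefit)
  if (m == 0) return(as_solution(integer(0), problem))
  if (is.null(t0)) {
    deltas <- vapply(seq_len(100), function(k) {
      xs <- as.integer(runif(m) < 0.5)
      abs(objective_delta(xs, sample.int(m, 1), problem))
    }, numeric(1))
    med <- median(deltas)
    t0 <- if (med <= 0) 1 else med / -log(0.8)
  }
  res <- sa_core(problem$benefit, problem$cost, problem$target, problem$spf,
                 problem$rep_offset, as.integer(iterations), t0,
                 t0 * t_final_frac)
  as_solution(res$x, problem)
}

#' Best solution over repeated annealing runs
#'
#' Runs [solve_sa()] `n_runs` times on independently sub-seeded streams
#' (`subseed(seed, run)`) and returns the solution with the lowest objective
#' total; ties are broken by fewer selected sites, then by earlier run. The
#' per-run totals are attached as attribute `run_totals`.
#'
#' @param problem an `n2k_problem`.
#' @param n_runs number of restarts (>= 1).
#' @param iterations iterations per run.
#' @param seed integer master seed for the run sub-seeds.
#' @param ... further arguments to [solve_sa()].
#' @return an `n2k_solution`.
#' @export
best_of_runs <- function(problem, n_runs, iterations = 1e5, seed = 1L, ...) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  best <- NULL
  totals <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    sol <- solve_sa(problem, iterations = iterations,
                    seed = subseed(seed, run), ...)
    totals[run] <- sol$objective$total
    if (is.null(best) ||
        sol$objective$total < best$objective$total - 1e-12 ||
        (abs(sol$objective$total - best$objective$total) <= 1e-12 &&
         sum(sol$x) < sum(best$x))) {
      best <- sol
    }
  }
  attr(best, "run_totals") <- totals
  best
}
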