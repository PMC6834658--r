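---
title: "Prioritising updates to protected-area target-species lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising updates to protected-area target-species lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protected-area networks such as Natura 2000 attach to each site a list of
*target species* — the species the site is formally managed for. Those lists
are drawn from the annexes of the Birds and Habitats Directives, which cover
only part of the species that the IUCN Red List classifies as threatened
(CR, EN, VU or NT). `n2kprior` implements an analysis pipeline that asks:
which sites should update their target lists, and with which species, so
that every threatened species is a managed target in at least $t$ sites —
without designating any new protected area?

The pipeline has four stages, each usable on its own:

1. **Gap analysis** (`summarize_gaps()`, `coverage_percent()`,
   `undeclared_threatened()`): cross-tabulate species by taxon, Red List
   status and annex listing, and list the threatened species that are a
   declared target of no site.
2. **Candidate pools** (`build_all_pools()`): per site and per bootstrap
   replicate, the species the optimiser may add to the site's list.
3. **Minimum-set solver** (`solve_sa()`, with `solve_greedy()` and
   `solve_exact()` as baseline and oracle): select the cheapest set of sites
   meeting all representation targets.
4. **Aggregation** (`selection_frequencies()`, `concentration_index()`,
   `richness_frequency_association()`): summarise the bootstrap replicates
   into selection frequencies, a proxy for site irreplaceability.

## The optimisation model

With sites $i = 1 \dots m$ and species $j = 1 \dots n$, binary decision
$x_i$, cost $c_i$, availability $a_{ij} \in \{0, 1\}$ and target $t_j$, the
solver minimises

$$\sum_{i=1}^{m} c_i x_i \;+\; \sum_{j=1}^{n} \mathrm{SPF}_j \, H(s_j)\,
\frac{s_j}{t_j}, \qquad s_j = \max\!\Big(0,\; t_j - \sum_i x_i a_{ij}\Big),$$

where $H$ is the Heaviside step and $\mathrm{SPF}_j$ a species penalty
factor. The normalised shortfall $s_j / t_j$ is 1 for an unrepresented
species and approaches 0 as representation approaches the target; a target
counts as met when representation is at least $t_j$ (the "at least $t$
sites" reading, which is also the Marxan convention). The study conditions
are constant $c_i = 1$ (no usable cost data at network scale), $t_j = 10$
and $\mathrm{SPF}_j = 10$; no boundary-length term is used because spatial
clumping is not wanted.

**Masked benefit.** $a_{ij}$ is not raw occurrence: it is 1 only when
species $j$ is in site $i$'s *candidate pool* for the current bootstrap.
Pools contain the site's declared targets (current management is never
dropped) plus at most `threshold` additions drawn from the eligible species
occurring there — the sweep {2, 5, 10, 20, 50} spans strategies from
dispersing effort across many sites to concentrating it on few. When more
candidates are available than the threshold, a uniform random subset is
drawn, exhausting first the species that share at least one preferred or
suitable habitat with the site's *managed habitats* (the union of habitat
links over all declared targets — all of them, not only the threatened
ones, since every declared target indicates ongoing management). Habitat
sharing is operationalised as non-empty set overlap; no graded similarity
metric is defined by the source material, and binary overlap is
transparent. Repeating the pool draw over bootstraps and recording how
often each site enters the best solution turns an arbitrary subsetting step
into a robustness estimate.

**Target clamping.** A species occupying (or entering pools in) fewer than
$t_j$ sites can never meet the nominal target; targets are clamped to
achievable representation (with a warning) so that solutions can reach zero
penalty and shortfall ratios remain in $[0, 1]$. The unclamped behaviour
remains available by skipping `clamp_targets()`.

**Locked declared contributions.** Whether sites where a species is already
declared should count toward its representation *without being selected* is
genuinely open; the default is no (the pure masked-benefit objective above),
and `count_declared_as_locked = TRUE` switches to crediting those sites
through a representation offset, with the benefit matrix zeroed at declared
cells to avoid double counting.

## The annealer and its numerical choices

`solve_sa()` performs single-site bit flips with incremental evaluation
(the flip delta touches only the species present at the flipped site; its
equality with from-scratch recomputation is property-tested). Temperature
follows a geometric schedule from $T_0$ to $10^{-4} T_0$; $T_0$ is set so
the median absolute delta of 100 sampled random flips would be accepted
with probability 0.8, which adapts the schedule to the instance's scale.

One plateau artifact deserves note. At the study conditions
($\mathrm{SPF}_j / t_j = 10/10 = 1 = c_i$), removing a site and absorbing
one unit of shortfall is *exactly* objective-neutral, and a Metropolis rule
accepts neutral moves with probability $e^{0} = 1$, so the chain drifts
among equal-score states of which many are infeasible. Two coupled choices
resolve this in favour of the target-meeting states: objective-neutral
moves are accepted only when they do not increase the penalty term, and the
best-state tracker prefers, among equal totals, the state with lower
penalty. `best_of_runs()` then keeps the lowest total across restarts,
breaking ties by fewer selected sites. Remaining tie-breaks (greedy site
choice, exhaustive enumeration) use lowest site index, then lexicographic
order, for reproducibility.

The exhaustive back-end enumerates all $2^m$ subsets (guarded at
$m \le 20$) and is the ground truth for the solver tests: best-of-10
annealing at 50 000 iterations is required to match the enumerated optimum
on at least 45 of 50 random penalty-dominant instances, and the greedy
baseline may never beat it.

**Scale.** The original analysis ran 1000 bootstraps × 100 restarts × 5
million iterations on 27 510 sites. The package defaults are desk-scale —
50 bootstraps, 10 restarts, $10^5$ iterations — and the bundled analysis
scripts use 25 bootstraps × 5 restarts × $5 \times 10^4$ iterations on
1000 sites, sizes at which every bootstrap reaches zero penalty in a few
minutes on one core; the full-scale design is reachable purely through
`scenario_config()`.

## Randomness and reproducibility

All randomness flows from one master seed through `subseed()`, a
multiplicative congruential hash mixing the seed with stream indices:
generator stages (statuses, ranges, habitats, declared lists), bootstrap
pool draws, and annealing restarts each get independent derived streams.
Re-running any pipeline invocation with the same master seed reproduces
byte-identical CSV outputs, which the test suite asserts with file
checksums.

## What the synthetic generator does and does not emulate

`generate_dataset()` reproduces the *statistical structure* the analysis
assumes: five taxa with the published 1282-species status mixture
(322/1282 threatened), annex listing imperfectly correlated with threat
(per-status listing probabilities from the published totals), a
right-skewed log-normal range-size distribution truncated to
$[1, n_\text{sites}]$, threatened species' range centres biased toward low
latitudes through a $\mathrm{Beta}(1, 1 + g)$ quantile draw (gradient
strength $g = 2$ by default; the real gradient is not quantified anywhere,
so $g$ is a free parameter), habitat links with one preferred plus up to
three suitable habitats from a pool of 12 (mirroring the MAES-style
preferred/suitable dichotomy), and declared lists sampling annex-listed
occupants with probability 0.5 (sites designated for habitats only appear
naturally as sites with empty lists when few listed species occur there).

It does **not** emulate: two-dimensional geography (ranges are contiguous
latitude intervals, so range overlap is far more structured than real
polygon overlap), population-based target declaration, spatial
autocorrelation beyond the single gradient, or realistic habitat
co-occurrence. Consequences worth keeping in mind: the real-data result
that selection frequency is unrelated to local threatened-species richness
does *not* transfer — on 1-D interval ranges, southern sites are
simultaneously rich and irreplaceable, and the diagnostic typically shows a
positive rank correlation here. The diagnostic is therefore reported, never
asserted. Likewise the real-data headline counts (updating ~231 and ~845
of 27 510 sites) require the real network and range data and are out of
scope; what the tests do show is the *structural* claims: all clamped
targets met in every bootstrap, habitat-sharing candidates exhausted before
others, narrow-range species assigned to every site they occupy, and
selection frequency concentrating (rising Gini) as the threshold grows.

## Degenerate inputs and edge policies

Empty species sets are an error for `run_scenario()` (there is nothing to
prioritise) but fine for the generator and the gap summary. Species
occurring in no site are excluded with a warning naming them; species
entering no pool in a bootstrap are dropped from that bootstrap's problem.
Integer coverage percentages use round-half-up by default with a truncation
switch, because published percentages are not consistently rounded (81%
for birds is a truncation of 81.6; 13% for fish rounds either way). The
published cross-tabulation's grand-total row is internally inconsistent
with its per-taxon cells for directive-listed counts (404 vs 400 summed);
both are carried verbatim — cells for taxon-level arithmetic, the total row
for total-level arithmetic — and never reconciled.

## Assigning species to sites

A solution is a set of sites; the deliverable is a list update per site.
`assign_species()` credits each selected site with the problem species in
its pool, then greedily trims surplus *additions* (never declared targets):
processing sites in descending redundancy, an addition is dropped whenever
the species still meets its clamped target without it. A selected site
whose additions are all trimmed needs no list update, which is why
"updated sites" can be smaller than "selected sites" — the quantity
reported as the cost of the recommendation is the number of sites gaining
at least one species.
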