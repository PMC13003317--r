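---
title: "Finding combined phenotypes associated with a genetic variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding combined phenotypes associated with a genetic variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnfgwas)
```

## The problem

A conventional GWAS fixes one phenotype and scans variants.  Biobank
cohorts measure hundreds of binary phenotypes on the same subjects,
which makes the reverse question well posed: given one variant, which
*combination* of phenotypes is most strongly associated with it?
`cnfgwas` answers this for logical combinations in conjunctive normal
form (CNF): a combined phenotype with $K$ clauses of up to $L$
phenotypes each, where a subject is a case iff in *every* clause they
carry at least one of the clause's phenotypes — e.g.
$(\mathrm{A} \lor \mathrm{B}) \land (\mathrm{C} \lor \mathrm{D})$.
Logical combinations carry no weights, so they transfer between
cohorts verbatim and read like clinical definitions, unlike linear
phenotype scores.

The search space is large — with distinct clauses and in-clause
phenotypes there are $\binom{\binom{P}{L}}{K}$ shapes, and allowing
repetitions embeds all smaller shapes — so the package solves the
selection problem exactly as a mixed-integer linear programme (MILP)
rather than by enumeration.  Enumeration is retained as an independent
oracle (`enumerate_cnf_oracle()`) and the test suite requires the two
routes to agree exactly on hundreds of seeded instances.

## Statistics on the 2×2 table

For a combined phenotype $u$ and a variant $v$ over $M$ subjects,
every supported association statistic depends only on
$(n_u, n_v, n_{uv}, M)$: the case count $S = n_u$, the carrier count
$n_v$, and the co-occurrence count $T = n_{uv}$.  `compute_stat()`
implements agreement, Hamming distance, covariance, correlation, the
$\chi^2$ coefficient, the odds ratio, Cohen's kappa and the one-sided
Fisher exact p-value (upper hypergeometric tail, computed through R's
log-scale `phyper` so that the very small tails that drive
genome-wide thresholds are stable; no normal approximation is used).

Two structural facts organise the whole design:

* agreement, Hamming distance and covariance are *linear* in $(S, T)$
  and can be MILP objectives directly (agreement is maximised as the
  integer expression $2T - S$, covariance as $MT - n_v S$, both
  order-equivalent to the statistic);
* all statistics except $\chi^2$ are *monotone* in $T$ at fixed
  margins.  For the Fisher tail this monotone decrease is checked
  empirically by `fisher_p_monotone_check()` over the attainable range
  of $T$ for every margin tested.  Monotonicity is what turns a
  significance threshold into a geometric constraint (next section).

The odds ratio uses no continuity (Haldane) correction; an infinite
ratio is propagated as `Inf` and undefined cases (degenerate margins)
as `NA`.  The Cochran–Mantel–Haenszel check (`cmh_test()`) is the
textbook 1-df statistic without continuity correction — the canonical
definition — with zero-margin strata contributing nothing; it is
cross-checked in the tests against `stats::mantelhaen.test()`.

## The MILP

For one variant, binary variables $U_{jk}$ select phenotype $j$ into
clause $k$; $P_{ik}$ records whether subject (profile) $i$ satisfies
clause $k$; $P_i$ is the combined phenotype; integer $S$ and $T$
accumulate the counts.  *Or*-constraints tie $U$ and $P_{ik}$
($U_{jk} \le P_{ik}$ for carriers of $j$, and $P_{ik}$ at most the
number of selected phenotypes the subject carries), *and*-constraints
tie $P_{ik}$ and $P_i$, and count constraints define $S$ and $T$ with
clause sizes bounded by $L$.  On uncollapsed input this is exactly
$K(M+P)+M+2$ variables and $K(2M+O+1)+M$ inequalities plus two
equalities, where $O$ is the number of 1s in the phenotype matrix; the
tests assert these closed forms.  Each clause is additionally required
to be non-empty ($\sum_j U_{jk} \ge 1$): an empty OR would make the
conjunction vacuously false in an ill-defined way, and a repeated
clause already emulates fewer clauses, so no generality is lost.

Solutions are post-processed to distinct set-minimal clauses
(duplicates removed, superset clauses dropped — a superset clause is
implied by its subset) and canonicalised (indices sorted within
clauses, clauses sorted lexicographically) so that ties among equally
optimal CNFs are reported stably.

### Subject collapse

Because all statistics depend only on counts, subjects with identical
phenotype rows are interchangeable.  `collapse_subjects()` sorts the
phenotype rows lexicographically (first column most significant —
deterministic and seed-free), run-length encodes them into $U \le
\min(M, 2^P)$ distinct profiles with multiplicities, and accumulates
per-profile carrier counts for every SNP at once.  $S$ and $T$ are
then weighted sums of the profile indicators.  With 11 phenotypes and
thousands of subjects this shrinks the MILP by one to two orders of
magnitude; the tests verify count-losslessness on random instances and
that collapsed and uncollapsed formulations reach identical optima.
Subject ids are carried through per profile for traceability.  Missing
phenotype values are not supported: any non-binary token is an input
error, on the view that missingness handling belongs upstream.

### Encoding a significance threshold

A constraint "Fisher $p \le p_0$" is non-linear in $(S, T)$, but by
monotonicity it is equivalent, for every case count $S$, to a lower
bound $T \ge g(S)$ where $g(S)$ is the smallest attainable
co-occurrence count that passes.  `threshold_curve()` computes $g$ by
binary search per column (verified against a linear scan).  The curve
is then compressed in two stages:

1. `prune_boundary()` keeps the leftmost feasible point and, per
   boundary level, the point with the largest $S$ — the classic
   non-redundant skeleton of a monotone staircase;
2. `simplify_boundary()` fits the minimum number of line segments such
   that at every integer $S$ the segment value lies in
   $(g(S) - 1 + \delta,\; g(S)]$, a corridor of width $w = 1 - \delta$
   *ending at* the boundary.  Integer points then satisfy
   $T \ge \hat g(S)$ exactly when $T \ge g(S)$: the simplified
   boundary separates the lattice exactly as the full one does, which
   is the property the whole pipeline is tested against.  Internally
   the pruned skeleton is augmented with each level's entry point
   before fitting, because the skeleton alone does not pin a fitted
   line down at the start of a long level run; a final vectorised
   verification over every integer $S$ guards the exact-separation
   contract, with a per-level staircase as an always-exact fallback.

Segment fitting is a greedy maximal-run partition; feasibility of a
run is a two-variable linear feasibility problem solved by ternary
search on the convex support function, and greedy is optimal for
partitions because sub-runs of feasible runs stay feasible.  The
default $\delta = 0.001$ trades segment count against the numerical
margin separating the two integer classes; smaller $\delta$ widens
the corridor and never increases the segment count.

`encode_lower_bound()` turns the $k$ segments into MILP material: one
binary selector per segment with aggregated range constraints gives
$k$ new variables and $k+3$ constraints; when the max-of-lines
envelope of the segments happens to classify every integer column
correctly (a convex boundary), the selector-free encoding with $k$
constraints and no new variables is used instead.  Big-M constants
are the tightest valid bounds derived from the $S$-domain.  Values of
$S$ for which no attainable $T$ passes are excluded by the bounds on
the $S$ variable rather than by extra constraints.  Only the
over-representation direction is supported by the curve; protective
associations are found by negating the variant ($1 - x$), mirroring
how protective alleles are handled in practice.

### Optimising a non-linear statistic

`optimize_variant()` finds the minimum attainable Fisher p-value by
iterating feasibility MILPs: starting from the best single phenotype
(always inside the search space), the target $-\log_{10} p$ is
doubled while probes stay feasible, bracketed by binary search until
the bracket ratio drops below 1.05, and then closed exactly — a final
probe strictly below the incumbent's p either improves it or proves
optimality.  The reported p is always recomputed exactly from the
counts of the returned CNF, so the search tolerance only influences
which CNF is returned among near-ties.  Probes use a *zero* objective:
with the HiGHS engine the first incumbent then terminates a feasible
probe and the full effort goes into infeasibility proofs, which
measured several-fold faster than optimising a surrogate objective
during probes.  `triage()` is the same feasibility machinery applied
once per variant at a crude bound — by default the final significance
threshold itself, so that triage-pass and candidacy coincide — and its
feasibility certificate seeds the optimiser.

## Two-stage testing and the baseline

`two_stage()` splits subjects into equal discovery and validation
halves (uniform seeded permutation; an odd subject joins validation).
CNFs are fitted on discovery only; each discovered CNF is evaluated
*unchanged* on validation, and an association is validated iff both
halves pass the threshold.  The threshold is Bonferroni over the
variant panel (`0.05 / n` in the simulations); no FDR machinery is
used.  On the validation half the CMH p-value stratified by the best
single phenotype (chosen on discovery) flags associations that might
be driven by a single phenotype rather than a genuine combination.
`gwas_baseline()` runs the standard single-phenotype scan on the same
split, which for $K = L = 1$ coincides exactly with the CNF search —
a property the tests assert.

## The simulation generator

`generate_dataset()` emulates a biobank-style line-up experiment:

* $P = 11$ phenotypes, independent Bernoulli with prevalences drawn
  once per dataset uniformly from $[0.01, 0.2]$ — the range typical of
  common diagnosis codes.  Real disease codes are correlated; drawing
  them independently makes planted structure the *only* structure, so
  detection results are conservative about confounding between
  phenotypes but silent about it.
* a planted CNF drawn uniformly over $(K, L)$ shapes with distinct
  in-clause phenotypes, redrawn (up to 100 times) if its evaluation is
  constant;
* a pseudo-SNP equal to the planted evaluation with exactly
  $\mathrm{round}(\varepsilon M)$ uniformly chosen entries logically
  negated — adversarial noise in which presence and absence are
  swapped, not mere dilution;
* $49$ decoy SNPs, i.i.d. Bernoulli at frequencies drawn within
  $\pm 20\%$ of the pseudo-SNP's frequency.  (A randomised real SNP is
  distributionally an independent frequency-matched draw as far as
  association testing is concerned, which is what the band emulates;
  linkage structure among decoys is deliberately absent.)  Column
  positions are shuffled; everything is bit-reproducible from the
  seed, with per-trial seeds derived by a counter so any trial can be
  re-run alone.

The full design crosses $K, L \in \{1,2,3\}$,
$M \in \{2000, 20000, 200000\}$ and $\varepsilon \in \{0, 0.1, 0.2\}$ —
81 settings (`simulation_grid()`), classically run at 10 trials each.
`run_grid()` executes any subset, classifies each SNP (pseudo-SNP
passing both stages: true positive; failing discovery: false
negative; any decoy passing a stage: false positive for that stage)
and `summarize_grid()` aggregates rates by any facet;
`autoplot()` draws the faceted true-positive-rate panel.
Within `run_grid()` the optimiser runs with `exact = FALSE` by
default: classification compares p-values to the threshold only, so
the proven-optimality refinement is skipped for speed without
changing any pass/fail label.

### Problem sizes used by the shipped checks

The package's own checks run the full machinery at deliberately
reduced sizes chosen to keep them reproducible on a single CPU: the
oracle-equivalence suite uses 200 instances with $M \le 50$,
$P \le 5$, $K, L \le 2$; the boundary suite 100 margins with
$M \le 60$; and the pilot power comparison uses the smallest grid
cohort ($M = 2000$, 11 phenotypes) with a line-up shortened to 24
decoys but judged at the full-design threshold $0.05/50$ — per-decoy
false-positive fractions and per-pseudo-SNP rates are unchanged in
expectation, only the number of decoy tests shrinks — at one to three
trials per setting.  At pilot scale only the *ordering* of the two methods
and the near-absence of validated decoys are asserted; rate levels
are meaningful only under the full 81-setting, 10-trial design, which
is hours of CPU rather than minutes and is available through
`run_grid()` unchanged.  Passing pilots demonstrate correct mechanics
and the expected direction of the power difference, not the precise
rates, and none of the synthetic results speak to cohort phenomena
the generator omits: phenotype correlation, population structure,
relatedness, or linkage among variants.

## Numerical and degenerate-input policy

* Fisher tails via `phyper` (log-scale internally); thresholds are
  compared as plain inequalities with no epsilon, since both sides are
  exact tail sums.
* A constant variant ($n_v \in \{0, M\}$) has $p = 1$ against every
  phenotype; the optimiser returns the trivial fit without invoking
  the solver.
* An unattainable threshold is detected from the empty boundary before
  any solve (`triage` reports `fail`, a probe reports infeasible).
* Solver results are never trusted blindly: the extracted CNF is
  re-evaluated against the solution's combined-phenotype variables and
  any mismatch or empty clause raises an error.
* HiGHS (via `scipy.optimize.milp` through reticulate) is
  single-threaded and deterministic here; the `seed` argument of
  `solve_milp()` exists for interface stability with stochastic
  backends.  Any backend function passing the enumeration-oracle suite
  is acceptable as a drop-in.

## Defaults worth knowing

| parameter | default | why |
|---|---|---|
| `K`, `L` | 2, 2 | richest shape that validated well without overfitting; `(3,1)` and `(1,3)` are worth exploring |
| `delta` | 0.001 | corridor margin; smaller = fewer segments, thinner numerical separation |
| `p0` | `0.05 / n` | Bonferroni over the variant panel (`5e-8` genome-wide) |
| `negate_snps` | `TRUE` (workflow) | protective associations via variant complement |
| `tol_ratio` | 1.05 | p-bracket ratio ending the binary search; final p is exact regardless |
| triage bound | `p0` | triage-pass equals candidacy; configurable |

## Limitations

Binary genotypes only (dominant coding): dosage would need 2×3-table
statistics.  Binary phenotypes only: quantitative traits must be
binarized first.  No covariates, population-structure adjustment or
relatedness handling — the intended use is exploratory combination
finding with external replication, not effect estimation.  Runtime
grows with the number of *phenotypes* faster than with subjects
(collapse caps the profile count at $2^P$), so very large phenotype
sets will slow the solver.
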