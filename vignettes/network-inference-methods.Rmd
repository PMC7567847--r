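---
title: "Dependency networks from zero-inflated abundance surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependency networks from zero-inflated abundance surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecobnet)
```

## The problem

Photographic seafloor surveys yield counts of coarse taxonomic groups per
photograph, together with physical covariates (depth, substrate type,
region) and derived quantities (percent cover of encrusting organisms).
These tables are heavily zero-inflated, the taxa interact non-linearly,
and the scientific question is usually structural: which taxa and physical
factors *depend* on which, how strongly, and what happens to the rest of
the community if one group declines or disappears.

`ecobnet` treats the community as a discrete Bayesian network. Variables
("nodes") are discretized, a directed acyclic graph (DAG) over them is
learned by score-based search, a bootstrap consensus filters unstable
edges, each surviving dependency gets a signed influence score, and a
chain-propagation step turns the fitted network into quantitative
what-if statements ("if sponges go from high abundance to absent, how do
the state probabilities of every connected taxon shift?").

## Discretization

Count variables get three states — zero, low, high — because absence is
ecologically different in kind from low abundance, and three bins balance
information retention against statistical power in data of this size.
The low/high boundary is the **median of the positive counts only**; a
count equal to the boundary is "low". Two points are worth making
explicit:

* *Positive-only medians.* Since zeros form their own state, including
  them in the median would collapse the boundary to zero for any variable
  that is mostly absent. Computing the median over positive values keeps
  both positive bins populated whenever the variable has enough positive
  support. Whether to include zeros is a genuine fork; the positive-only
  reading follows from treating zero as a separate entity.
* *Ties map downward.* `value <= boundary` is "low". With a constant
  positive vector every entry is "low" and the variable is flagged
  degenerate.

Continuous variables (depth, percent encrusting) have no zero state, and
two states would waste most of their information, so they get four states
cut at the empirical quartiles (type-7 interpolated; values equal to a cut
map downward). Fewer than four distinct values is degenerate — three
discrete sampling depths, for example, should be declared categorical
instead. Categorical variables map observed categories to states by a
stable lexicographic order, so the map never depends on row order.

Two analysis scales are supported. At photo scale each photograph is a
sample. At event scale photographs are grouped by a transect-event key:
counts are summed, continuous variables averaged, and categorical
variables take the mode with ties broken lexicographically. Degenerate
variables at either scale (e.g. an event-scale depth with fewer than four
distinct means) are dropped with a warning rather than crashing the
pipeline, since an unconnected physical covariate is an expected outcome,
not an error.

## Pre-filtering

Zero inflation produces spurious co-absence associations. Two filters
run before any search:

* **Rare-taxon filter.** Count variables present in strictly fewer than a
  third of samples are removed. Physical variables are never removed by
  this rule. Occupancy is judged at the scale of the table being
  analysed.
* **Contingency filter.** For every remaining unordered pair, a Pearson
  chi-squared test (no continuity correction; zero-margin rows/columns
  dropped before computing the (r−1)(c−1) degrees of freedom) compares
  the joint state distribution against the product of the marginals.
  Pairs with p > 0.25 are barred as edges for the rest of the analysis.
  The threshold is deliberately anti-conservative — under independence it
  removes 75% of pairs by p-value uniformity, while leaving essentially
  no chance of discarding a genuinely dependent pair. No multiple-testing
  correction is applied, on purpose: the filter's job is to delete
  obvious artefacts, not to test hypotheses.

## Structure learning

Structures are scored by the BDeu marginal likelihood (Dirichlet
pseudo-counts `ess / (q r)` per cell, `ess = 1` by default) with a uniform
structure prior, so candidate DAGs compare by likelihood alone. The score
decomposes per family, which the search exploits by caching family
scores.

The search is steepest-ascent hill climbing over single-edge moves (add,
delete, reverse) under three constraints: acyclicity, the excluded-pair
set, and a parent cap of 3, which limits artefactual dense families in
small discrete data sets. Only strictly improving moves are accepted;
ties are broken by lexicographic (source, target, move-type) order so the
whole search is reproducible bit-for-bit from its seed. Random restarts
draw an initial DAG by proposing each legal edge with probability 0.1 and
repairing cycles; the first restart always begins at the empty DAG, so
the returned optimum can never score below independence. The
`n_iterations` setting is a total budget of proposal evaluations across
restarts; production analyses of this kind historically used budgets in
the millions, while the package defaults are sized for interactive runs
and are configurable upward. At desk scale, greedy search with 25-50
restarts recovers the exhaustively enumerated optimum on essentially all
three-node problems, which the test suite checks against a 25-DAG
enumeration oracle.

## Bootstrap consensus

A single best DAG is brittle in data this noisy. The package therefore
re-learns the network on `B = 100` subsamples, each holding 95% of the
samples drawn *without replacement* (subsampling, not a classical
with-replacement bootstrap — the aim is outlier robustness rather than
variance estimation). Each replicate has its own seed derived from the
master seed, so ensembles are exactly reproducible.

For each unordered pair the **occurrence** is the fraction of replicates
containing the edge in either direction. Empirically this distribution is
bimodal — a low mode of search noise and a high mode of well-supported
dependencies — so the cutoff between them is estimated by fitting one-
and two-component Gaussian mixtures by EM (via `mclust`) and comparing
BIC. If two components win, the threshold is the density-crossing point
between the component means (midpoint of the means if the densities do
not cross there); otherwise, or if EM fails, a simple majority of 0.5 is
used. Edge direction follows the majority orientation among replicates
containing the edge: at least 60% one way is directed, at most 40% is
directed the other way, and anything between is a **mutual** dependency,
drawn double-headed. The orientation fraction is computed among
edge-containing replicates, not among all B replicates — with a
thresholded edge the two denominators differ little, and the former is
the one the orientation evidence actually lives in.

Summary statistics use the standard definitions: connectance
E/(N(N−1)) and link density E/N over the N connected nodes, and chain
statistics where a *chain* is a maximal simple path (not extendable at
either end) of at least two connections in the undirected consensus
graph, counted per distinct endpoint pair with the longest such path per
pair. The counting rule for chains is genuinely open in the field's
summary tables; this one is recorded here and enforced by an
igraph-based path-enumeration oracle in the tests.

## Influence scores

The influence score (IS) grades each dependency in [−1, 1] by
cumulative-distribution dominance. For an edge P → C, for every
configuration of C's other parents and every parent-state pair p < p′,
the child-state CDFs under p and p′ are compared: +1 if the higher
parent state shifts the child toward higher states (strict first-order
dominance), −1 for the reverse, 0 if the CDFs cross. Votes are weighted
by the probability of the other-parent configuration and normalized by
the total weighted vote count. Strictly monotone tables score exactly
±1; independence scores 0; and IS = 0 does *not* imply independence — a
V-shaped (non-monotone) dependency also scores 0 while the chi-squared
filter still detects it. Two details are choices rather than forced:

* Other-parent configurations are weighted by the product of the parents'
  empirical marginals (the same independence approximation the
  propagation step uses), since the CPT container carries per-node
  marginals rather than joint configuration frequencies.
* The per-connection IS reported in a consensus network is the mean over
  the replicates *containing* that edge, with CPTs refitted on each
  replicate's subsample.

CPTs are fitted with a pseudo-count `alpha = 1` in every cell, which
keeps all entries positive; the Bayes inversion below divides by
CPT-weighted sums and relies on this.

## Chain inference

To infer how forcing node A changes node B, the package propagates a
point mass along the unique shortest undirected chain between them in
the consensus network (lexicographically smallest node sequence on
ties; one deterministic chain, no averaging over paths). Each step is a
conditional distribution between adjacent chain nodes:

* edge pointing **along** the traversal: the child's CPT row, with its
  other parents marginalized by their empirical marginals;
* edge pointing **against** the traversal: Bayes inversion,
  P(parent | child) = P(child | parent) P(parent) / Σₘ P(child | m) P(m).

The target distribution is the composition of the step conditionals.
On directed trees this is exactly the joint-enumeration conditional (the
test suite checks agreement to 1e−10 over random trees); on graphs where
chains pass through colliders or other parents carry information it is a
deliberate approximation, matching the single-chain semantics of the
method rather than full junction-tree inference, which is out of scope
as a primary path. A Δp report contrasts two forced source states:
Δp = P(target states | source = to) − P(target states | source = from),
with the scalar summary `mean_delta_p` the mean of |Δp| over all states
of all connected targets. Unconnected targets are reported with zero
shift but excluded from the mean. On homogeneous noisy-copy chains the
maximal |Δp| is non-increasing in chain length — effects attenuate with
network distance.

## The synthetic community generator

Real survey data cannot ship with the package, so the generator produces
the study conditions: a categorical 3-state substrate root, an optional
4-state latent depth covariate, and three-state taxa whose CPT rows are
mixtures `lambda * monotone + (1 - lambda) * uniform`. The monotone
component shrinks the child's zero state multiplicatively in each
sign-adjusted parent level — `p0 = zero_hi * (zero_lo/zero_hi)^sum(levels)` —
and moves the high-state share of the non-zero mass with the mean level.
Both responses are strictly monotone in every individual parent level, so
each edge's true IS sign is known by construction (`lambda = 0` gives
uniform rows and true IS 0; `lambda = 1` gives strict dominance and IS
±1), and each edge's marginal signal does not dilute with the child's
parent count. The multiplicative form replaced an earlier mean-of-parents
drive precisely because dilution under the parent cap contradicted the
generator's contract that `lambda` sets per-edge signal strength.

Emission makes discretization testable: latent state 0 *always* emits
count 0, state 1 a uniform draw from 1-4, state 2 from 5-20. The ranges
are disjoint, so when low and high are balanced the positive median lands
between them and discretization recovers the latent states exactly.
Substrate and depth are drawn once per transect event (default 25
photographs per event) and shared within it, mimicking transect-level
habitat homogeneity; taxa are drawn per photograph.

Two zero-inflation regimes matter. The default `zero_hi = 0.70`,
`zero_lo = 0.25` describes *analyzed* coarse taxonomic groups: every
taxon's occupancy stays above the 1/3 rare-taxon threshold, as it must
for the generator to exercise the full pipeline (the analyzed nodes in a
real survey are precisely the groups coarse enough to survive that
filter). Pushing both parameters up (e.g. a 0.849 zero-state marginal)
reproduces the far heavier zero inflation of raw fine-taxonomy tables,
and the tests verify that an 0.85 state-0 marginal emits ~85% zero cells.
What the generator deliberately does **not** model: spatial
autocorrelation beyond event-level sharing, patchiness, overdispersed
count emission (a disjoint-uniform emission is used so recovery tests are
deterministic), or observation error. Passing recovery tests therefore
demonstrates correctness of the machinery under the stated model, not
robustness to every property of field data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full synthetic study
at 8 taxa + substrate, 8 edges, `lambda = 0.8`, 2000 photographs in 80
events, B = 100 bootstrap replicates with a 20,000-proposal search budget
per replicate — sizes chosen so a complete run takes seconds per seed on
one core while leaving the consensus F1 comfortably measurable; the
structure-recovery check repeats this over 20 seeds. Every stochastic
stage takes an explicit seed; the pipeline derives stage seeds from a
single master seed by fixed offsets (+1/+2 simulation, +10 single
search, +20 bootstrap) so stages can be rerun in isolation and full runs
are byte-identical.

## Known limitations

* Consensus networks describe co-localization dependence, not mechanism;
  a dependency is not evidence of predation, facilitation, or any
  specific interaction.
* Chain inference is observational conditioning along one chain, not an
  interventional (do-operator) quantity, and approximates away collider
  openings and other-parent information off the chain.
* The BDeu `ess` and the smoothing `alpha` are fixed defaults (1 and 1);
  sensitivity to them is not explored automatically.
* Mode ties, mixture non-convergence, and multiple shortest chains are
  resolved by documented deterministic rules; other conventions are
  defensible and would change numbers slightly.
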