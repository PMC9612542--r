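---
title: "Mining and structuring association rules in severe-crash data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and structuring association rules in severe-crash data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crashrules)
```

## The problem and the model

Severe road crashes — here, crashes causing three or more deaths — are rarely
attributable to one factor. The analytical object of this package is the set
of *association rules* `X → Y` over boolean crash descriptors: `X` is an
antecedent itemset (e.g. `{down-curve, improper operations}`) and `Y` a
single consequent item (e.g. `single-vehicle crash`). Over a transaction
table of `N` records the rule is scored by

* support `Supp(X→Y) = #(X ∪ Y) / N` — how much of the data the pattern
  covers;
* confidence `Conf(X→Y) = Supp(X→Y) / Supp(X)` — the conditional frequency
  of the consequent given the antecedent;
* lift `Lift(X→Y) = Conf(X→Y) / Supp(Y)` — the multiplicative deviation
  from independence. Lift 1 means `X` carries no information about `Y`;
  lift above 1, positive association.

Mining is a plain Apriori level-wise search: frequent itemsets are
enumerated bottom-up, a size-`k` candidate being counted only when all its
`(k−1)`-subsets are frequent (downward closure), and rules are generated
from each frequent itemset by designating each member in turn as the
consequent. This is deliberately mechanical: every item is eligible on
either side at mining time, and domain judgement is deferred entirely to the
filter stage so that it stays declarative and auditable.

Support thresholds alone over-generate. The filter applies three screens in
a fixed order, each only removing rules:

1. **Lift increase (LIC).** For a rule with `n+1` antecedent items,
   `LIC = Lift(X_{n+1}→Y) / Lift(X_n→Y)` against a base rule with one item
   removed. If adding the item does not raise lift by at least the
   threshold, the longer rule restates the shorter one. We require the bound
   against *every* immediate base rule (the strictest reading; `lic_mode =
   "any"` relaxes it), and we recompute base-rule lifts from the data when
   the base rule itself failed the mining thresholds — a base rule does not
   have to be "interesting" to expose its extension as redundant. The
   reported `lic` value is the minimum over base rules, i.e. the binding
   comparison.
2. **Significance.** The confidence of a rule is inflated by frequent
   antecedents, so each surviving rule is tested with a one-sided Fisher's
   exact test — the upper hypergeometric tail of the co-occurrence count
   with 2×2 margins fixed. One-sided "greater" is the only direction
   consistent with screening on lift > 1. With `m` rules entering the stage
   the Bonferroni criterion keeps `p < α/m`; we take `m` to be the post-LIC
   survivor count (the tests actually performed at this stage). Degenerate
   margins give `p = 1` by convention. A Benjamini–Hochberg option exists
   behind `correction = "BH"` for sensitivity checks.
3. **Meaningfulness.** Some rules are true by construction — early-morning
   hours imply darkness; a posted limit above 80 km/h implies a freeway
   administratively. These carry perfect confidence and no safety content.
   The blacklist is declarative (category- or item-level `lhs`/`rhs` pairs,
   both directions of time↔light and speed-limit↔road-category by default)
   and matches only when *all* antecedent items fall under the entry's
   left side: a multi-item antecedent in which one item is informative is
   not a tautology, and rejecting on any-item matching would discard such
   rules.

## The rules graph

Kept rules are cast into a directed graph with one node per factor and one
node per rule; each antecedent factor points into its rule node and the rule
node points to its consequent. Structural identities (checked as invariants):
nodes = factors + rules, edges = Σ(|antecedent| + 1), every rule node has
out-degree exactly 1.

* **Degrees.** A factor's in-degree counts the rules concluding in it (a
  common *background* of crashes); its out-degree counts the rules using it
  as a condition (a *driver* of patterns).
* **Closeness** `C(x) = N / Σ_y d(y,x)` with `N` the total node count, on
  the **undirected projection**. The raw directed graph leaves most node
  pairs mutually unreachable (consequent-only factors cannot reach any rule
  node), which would make the directed formula mostly undefined; the
  undirected projection is the reading under which closeness ranks factor
  centrality meaningfully. Disconnected graphs use per-node reachable-set
  rescaling by `(r−1)/(N−1)` (`r` = component size); isolated nodes score 0.
* **PageRank** is implemented exactly in its raw recursive form
  `PR(v) = (1−d) + d Σ_u PR(u)/O(u)` with damping `d = 0.85`: scores do not
  sum to one, a source node scores exactly `1−d`, and dangling-node rank is
  not redistributed. This variant admits clean fixed-point checks (cycle
  nodes score exactly 1). The conventional probability-normalised PageRank
  is available via `normalized = TRUE` (delegating to igraph) as a
  cross-check. Iteration stops when the max-norm change falls below `tol`
  (default 1e-10); non-convergence is an explicit error, not a silent
  result.
* **Modularity and communities.** Newman modularity
  `Q = 1/(2m) Σ_vw [A_vw − k_v k_w/(2m)] δ(c_v, c_w)` on the undirected
  projection, with `m` the undirected **edge count** (one sometimes sees
  `m` glossed as a module count; only the edge-count reading yields
  `Q ∈ [−0.5, 1]` and the usual `Q > 0.3` convention for significant
  structure). Partitions come from Louvain greedy agglomeration
  (igraph), made deterministic by fixing the RNG seed; across seeds the Q of
  a structured rules graph is stable to well under 0.02, and only `Q > 0.3`
  — not any particular partition — should be treated as a reproducible
  statement.
* **Factor contributions.** Within each system-level construct (driver,
  vehicle, roadway, environment, crash), a factor's contribution is its
  closeness as a percentage of the construct's total closeness.

## The factor catalog

The default catalog describes multi-fatality crash records with 84 boolean
items in 18 descriptive categories. Two readings deserve a note. First, the
descriptive tables this catalog mirrors list a bare "Curve" alignment row
alongside up-curve, down-curve and three curve-radius classes; since every
published rule uses the specific alignment items and never bare "Curve", we
treat it as an aggregate label, not an item — that is what makes the count
84. Second, category and construct are different axes: passenger overload
and travelling over/under speed are recorded under driving violations but
are vehicle-state facts, so they map to the vehicle construct; the "normal"
driver condition, severity and time-of-day items are *context* and excluded
from contributing-factor constructs. Construct-combination profiles
(`combination_profile()`) therefore count records by the exact subset of
{driver, vehicle, roadway, environment} with at least one true item —
disjoint Venn cells summing to at most 1.

Reference marginal frequencies ship with the catalog for use as synthetic
defaults. Where the source descriptive table is internally inconsistent
(e.g. a count column contradicting its percent column for passenger
overload), we store both printed values and use the percent column, which is
the one consistent with the published rule supports; the loader reports
observed marginals and never forces agreement with printed tables.

Missing categorical values one-hot expand to all-false across the category's
items: the record count is preserved and no value is invented. Exclusivity
violations (two severity levels true at once) warn by default and fail only
under `strict = TRUE`, because published encodings contain coding noise.

## The synthetic generator

`generate_with_planted_rules()` is the package's ground-truth instrument.
Background items are independent Bernoulli draws. A planted rule makes its
antecedent block jointly true with probability `p_lhs`; otherwise the
antecedent items are drawn from their background marginals *conditioned on
not being jointly true* (rejection sampling). The consequent is Bernoulli
with `conf_true` on the block and `conf_false` off it. The conditioning is
what makes the planted metrics exact closed forms:

```{r}
spec <- planted_rule(c("A", "B"), "Y", p_lhs = 0.3,
                     conf_true = 0.8, conf_false = 0.2)
expected_metrics(spec)
```

`P(all LHS) = p_lhs` exactly, confidence `= conf_true` exactly,
`P(Y) = conf_true·p_lhs + conf_false·(1−p_lhs)`, lift `= conf_true / P(Y)`.
Recovery tests compare mined metrics to these at n = 20,000 within 3
binomial standard errors. Planted consequents must be distinct across specs,
must not appear in any antecedent or background list, and antecedent sets
must be disjoint across specs — compounded conditionals would have no closed
form, and the generator refuses to produce data it cannot account for.

What the generator does *not* emulate: the real joint distribution of crash
items (correlated backgrounds, exclusive-group structure, item hierarchies).
Passing recovery tests therefore demonstrates correctness of the mining and
filtering machinery, not fidelity of any particular crash dataset; on real
tables the thresholds remain subject-matter choices.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_support` | 0.06 | minimum rule support (fraction of records; inclusive) |
| `min_confidence` | 0.75 | minimum conditional frequency (inclusive) |
| `min_lift` | 1.3 | lift bound (strict `>`) |
| `max_lhs_size` | 3 | maximum antecedent size |
| `min_lic` | 1.03 | minimum lift-increase over every base rule |
| `alpha` | 0.01 | Fisher significance level before correction |
| `d` (PageRank) | 0.85 | damping factor |
| `k_groups` | 20 | k-means antecedent groups |

The support/confidence defaults sit at the operating point where severe-crash
tables of ~1000 records yield interpretable rule sets (a 6 % support floor
corresponds to a meaningful absolute number of crashes); loose settings
(2 %/50 %) flood the output with tens of thousands of rules and tight ones
(10 %/80 %) leave almost none — `threshold_sweep()` reproduces exactly this
calibration narrative on any table. The strict-vs-inclusive reading of the
bounds matters at boundaries (lift exactly 1.3 is excluded; support exactly
6 % is kept) and is fixed as stated. Metric-band summaries
(`rule_value_distribution()`) use inclusive bounds for the 6–10 % support
band and strict bounds for confidence > 80 % and lift > 2.

## Numerical and determinism choices

Support, confidence and lift are computed from integer co-occurrence counts
divided once at the end, so the identity `support = confidence × supp(lhs)`
holds to floating-point exactness for every emitted rule (and is asserted).
Itemsets are canonicalised by sorting item labels; all orderings (frequent
itemsets, rules, graph nodes) are by size then lexicographic label, making
every artifact byte-reproducible. Ties in `top_rules()` break by the other
two metrics, then the rule label. K-means grouping uses binary
antecedent-membership vectors (consequents excluded — the grouping is *of
antecedents*), a fixed seed and 10 restarts; `k` equal to the rule count
degenerates to singleton groups directly, since an iterative refinement with
zero free points is vacuous. Fisher p-values use the hypergeometric
upper-tail (`phyper`) rather than enumerating tables, and are
oracle-verified against exhaustive fixed-margin enumeration for all n ≤ 60.

## Problem sizes used for verification

The self-contained suites run Apriori-vs-exhaustive-oracle equivalence on
random tables up to 12 items × 300 records, Fisher-vs-enumeration on 2×2
tables up to n = 60, planted-rule recovery at n = 20,000, and
independence-null retention at n = 800–2,000 over repeated seeds. The
acceptance script uses n = 20,000 for single-rule recovery, a 10,000-record
84-item synthetic crash table with six planted crash-pattern dependencies
for the end-to-end pipeline, and n = 2,000 for the null. These sizes put
sampling error well below the tested tolerances while keeping a full run in
seconds.

## Known limitations

* Reproduction tests against the originating study's deposited crash and
  rule files require those files under `inst/extdata/`; they are not
  redistributed here, so those three specific checks cannot pass out of the
  box (all closed-form and property checks are self-contained).
* Apriori only; no FP-growth or approximate mining. The miner's cost grows
  with the number of frequent itemsets, which the support threshold governs.
* The LIC stage compares immediate base rules only (one item removed), not
  all ancestors; a rule can in principle pass against its parents while
  adding little over a grandparent, though the parents would then have been
  pruned themselves.
* Betweenness centrality and force-directed layout coordinates are
  presentation-layer concerns of external tools (the GraphML/GEXF exports
  carry all node attributes needed) and are intentionally not computed.
* The meaningfulness blacklist is declarative, not semantic: it encodes
  known tautologies and does not discover new ones.
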