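# crashrules

Association rule mining and rules-graph structures for multivariate analysis
of severe road-crash records.

Multi-fatality crashes (three or more deaths) arise from interactions among
driver, vehicle, roadway, environment and crash-dynamic factors that
single-factor rankings cannot expose. `crashrules` implements a complete
pipeline for finding and structuring those interactions:

1. **Encode** — crash records become an N × M boolean *transaction table*
   over a factor catalog (the package ships a default catalog of 84 items in
   18 categories, each item mapped to a system-level construct and to
   mutual-exclusivity groups).
2. **Mine** — Apriori level-wise search enumerates frequent itemsets and
   emits rules *X → Y* (single-item consequent) scored by

   - support `Supp(X→Y) = #(X ∪ Y) / N`
   - confidence `Conf(X→Y) = Supp(X→Y) / Supp(X)`
   - lift `Lift(X→Y) = Conf(X→Y) / Supp(Y)` (1 = independence)

   with default thresholds S ≥ 6 %, C ≥ 75 %, L > 1.3 and at most three
   antecedent items.
3. **Filter** — a three-stage screen removes what mining lets through:
   *lift-increase* pruning `LIC(X_{n+1}→Y) = Lift(X_{n+1}→Y) / Lift(X_n→Y)`
   ≥ 1.03 against every immediate base rule; a one-sided Fisher's exact test
   (positive association) with Bonferroni correction at α = 0.01; and a
   declarative *meaningfulness* blacklist for tautological category pairs
   (time ↔ light condition, speed limit ↔ road category).
4. **Structure** — kept rules become a directed *rules graph*: factor nodes
   and rule nodes, antecedents pointing into each rule node, the rule node
   pointing to its consequent. Degree, closeness `C(x) = N / Σ_y d(y,x)`,
   the raw recursive PageRank `PR(v) = (1−d) + d Σ PR(u)/O(u)` (d = 0.85),
   Louvain community detection and Newman modularity Q then rank factors and
   expose crash patterns.
5. **Report** — top rules by lift/support/confidence, consequent-conditioned
   subsets, k-means antecedent grouping, metric-band distributions, and
   construct-combination (Venn-cell) profiles of the records themselves.

A synthetic transaction generator with *planted* rules closes the loop:
planted dependencies have closed-form support/confidence/lift, so every
stage is verifiable against analytic ground truth without any external data.

## Worked example

Plant one known dependency — *down-curve + improper operations → single
vehicle* with block probability 0.12 and conditional confidences 0.85/0.12 —
on top of independent background items at the default catalog marginals,
then run the pipeline:

```r
library(crashrules)

cat84 <- default_catalog()
spec <- planted_rule(c("Segment: down-curve", "Violation: improper operations"),
                     "Veh num = 1", p_lhs = 0.12,
                     conf_true = 0.85, conf_false = 0.12)
round(expected_metrics(spec), 3)
#>    support confidence       lift
#>      0.102      0.850      4.094

bg <- setNames(cat84$marginal, cat84$item)
cfg <- generator_config(10000, background_items = bg[names(bg) != "Veh num = 1"],
                        planted = list(spec), seed = 42)
tab <- generate_with_planted_rules(cfg)
tab$catalog <- cat84

res <- run_pipeline(tab, mining = mining_config(), seed = 1, k_groups = NULL)
#> [encode] 10000 records x 84 items
#> [mine] 12 candidate rules (S>=0.06, C>=0.75, L>1.3)
#> [filter] 3 kept / 12 candidates (lic 9, significance 0, meaningfulness 0 rejected)
#> [graph] 6 nodes (3 factors), 9 edges; 3 modules, Q = 0.000
res$kept[, c("lhs", "rhs", "lift", "lic")]
#>                                                  lhs                            rhs  lift   lic
#> 1                    Segment: down-curve;Veh num = 1 Violation: improper operations 3.008 1.460
#> 2 Segment: down-curve;Violation: improper operations                    Veh num = 1 4.161 1.866
#> 3         Veh num = 1;Violation: improper operations            Segment: down-curve 3.256 1.460
```

The planted rule is recovered with lift 4.161 against the closed-form 4.094
(sampling error at n = 10,000), together with its two metric rotations; the
nine redundant sub- and super-rules are pruned by the LIC stage. On real
crash tables the same call produces the kept rule set, the rules graph with
centralities and module partition (`res$graph`, `res$partition`,
`res$closeness`, `res$pagerank`), per-construct factor contributions
(`res$contributions`) and the construct-combination profile (`res$profile`).

A thin command-line surface over the same functions lives at
`inst/cli/crashrules.R` (`simulate`, `mine`, `filter`, `graph`, `report`,
`run` subcommands).

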