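test_that("a single rule {A,B} -> C builds 4 nodes and 3 edges", {
  g <- build_rules_graph(rule_df("A;B", "C"))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(factor_nodes(g)), c("A", "B", "C"))
  expect_error(build_rules_graph(rule_df(character(), character())),
               "empty rule list")
})

test_that("structural identities hold on random rule sets", {
  for (seed in 1:4) {
    rules <- random_rules(30, n_factors = 8, seed = seed)
    g <- build_rules_graph(rules)
    lhs_sizes <- lengths(strsplit(rules$lhs, ";", fixed = TRUE))
    n_factors <- length(unique(c(unlist(strsplit(rules$lhs, ";")), rules$rhs)))
    expect_equal(igraph::vcount(g), n_factors + nrow(rules))
    expect_equal(igraph::ecount(g), sum(lhs_sizes + 1))
    rule_v <- igraph::V(g)$name[igraph::V(g)$kind == "rule"]
    expect_true(all(igraph::degree(g, rule_v, mode = "out") == 1))
    expect_equal(unname(igraph::degree(g, rule_v, mode = "in")),
                 unname(lhs_sizes))
  }
})

test_that("two rules sharing all factors add one rule node and additive edges", {
  r1 <- rule_df("A;B", "C")
  r2 <- rule_df(c("A;B", "A;C"), c("C", "B"))
  g1 <- build_rules_graph(r1)
  g2 <- build_rules_graph(r2)
  expect_equal(length(factor_nodes(g2)), length(factor_nodes(g1)))
  expect_equal(igraph::vcount(g2), igraph::vcount(g1) + 1)
  expect_equal(igraph::ecount(g2), igraph::ecount(g1) + 3)
})

test_that("factor degrees count LHS and RHS appearances", {
  g <- build_rules_graph(rule_df("A;B", "C"))
  d <- factor_degrees(g)
  expect_equal(d$out_degree[d$item == "A"], 1)
  expect_equal(d$out_degree[d$item == "B"], 1)
  expect_equal(d$in_degree[d$item == "C"], 1)
  expect_equal(d$in_degree[d$item == "A"], 0)
  # no zero-degree factor nodes: factors absent from rules are not nodes
  expect_false("Z" %in% d$item)
})

test_that("factor degrees equal a direct recount from the rule list", {
  rules <- random_rules(50, n_factors = 10, seed = 9)
  g <- build_rules_graph(rules)
  d <- factor_degrees(g)
  lhs_list <- strsplit(rules$lhs, ";", fixed = TRUE)
  for (i in seq_len(nrow(d))) {
    f <- d$item[i]
    expect_equal(d$out_degree[i], sum(vapply(lhs_list, function(l) f %in% l, TRUE)))
    expect_equal(d$in_degree[i], sum(rules$rhs == f))
  }
})

test_that("closeness matches hand-computed shortest paths", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "l1", "l2", "l3", "l4")
  cl <- closeness_rgs(star)
  expect_equal(unname(cl["c"]), 5 / 4)     # center: four distance-1 paths
  expect_equal(unname(cl["l1"]), 5 / 7)    # leaf: 1 + 2 + 2 + 2
  expect_equal(which.max(cl), c(c = 1L))

  path <- igraph::make_graph(~ a - b - c)
  clp <- closeness_rgs(path)
  expect_gt(clp["b"], clp["a"])
  expect_equal(unname(clp["a"]), unname(clp["c"]))

  # two disconnected dyads: symmetric, all four equal, rescaled per component
  dyads <- igraph::make_graph(~ a - b, c - d)
  cld <- closeness_rgs(dyads)
  expect_equal(length(unique(round(cld, 12))), 1)

  # isolated node scores 0
  iso <- igraph::make_graph(~ a - b) + igraph::vertices("z")
  expect_equal(unname(closeness_rgs(iso)["z"]), 0)
})

test_that("unnormalised PageRank hits the printed fixed points", {
  # source node with no incoming edges: PR = 1 - d
  chain <- igraph::make_graph(~ a -+ b)
  pr <- pagerank_rgs(chain)
  expect_equal(unname(pr["a"]), 0.15, tolerance = 1e-8)
  expect_equal(unname(pr["b"]), 0.15 + 0.85 * 0.15, tolerance = 1e-8)
  # cycles: PR = 1 for every node (PR = 0.15 + 0.85 * PR)
  two <- igraph::make_graph(~ a -+ b, b -+ a)
  expect_equal(unname(pagerank_rgs(two)), c(1, 1), tolerance = 1e-8)
  three <- igraph::make_graph(~ a -+ b, b -+ c, c -+ a)
  expect_equal(unname(pagerank_rgs(three)), c(1, 1, 1), tolerance = 1e-8)
})

test_that("PageRank satisfies its fixed-point equation at every node", {
  rules <- random_rules(40, n_factors = 9, seed = 13)
  g <- build_rules_graph(rules)
  pr <- pagerank_rgs(g, tol = 1e-12)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  outdeg <- igraph::degree(g, mode = "out")
  for (v in seq_along(pr)) {
    inc <- which(adj[, v] == 1)
    rhs <- 0.15 + 0.85 * sum(pr[inc] / outdeg[inc])
    expect_equal(unname(pr[v]), rhs, tolerance = 1e-8)
  }
  expect_true(all(pr >= 0.15 - 1e-12))
  expect_error(pagerank_rgs(g, max_iter = 1), "did not converge")
  expect_error(pagerank_rgs(g, d = 1.2), "damping")
})

test_that("normalised PageRank option matches igraph", {
  rules <- random_rules(25, n_factors = 7, seed = 15)
  g <- build_rules_graph(rules)
  expect_equal(pagerank_rgs(g, normalized = TRUE),
               igraph::page_rank(g, damping = 0.85)$vector)
})

test_that("modularity has its closed-form values on canonical partitions", {
  tri2 <- igraph::make_graph(~ a - b - c - a, d - e - f - d)
  expect_equal(modularity_rgs(tri2, rep(1, 6)), 0)          # one module
  expect_equal(modularity_rgs(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)  # by triangle
  expect_error(modularity_rgs(tri2, c(1, 1, 1)), "every node")
})

test_that("random partitions of a random graph have modularity near zero", {
  set.seed(19)
  g <- igraph::sample_gnp(60, 0.15)
  qs <- replicate(30, modularity_rgs(g, sample(1:3, 60, replace = TRUE)))
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("Louvain recovers planted communities deterministically", {
  tri2 <- igraph::make_graph(~ a - b - c - a, d - e - f - d)
  part <- detect_communities(tri2, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 0.5)
  expect_equal(length(unique(part$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$membership[c("d", "e", "f")])), 1)
  # complete graph: no divisible structure
  k6 <- igraph::make_full_graph(6)
  pk <- detect_communities(k6, seed = 1)
  expect_equal(pk$n_modules, 1)
  expect_equal(pk$Q, 0)
  # determinism under a fixed seed
  expect_identical(detect_communities(tri2, seed = 4)$membership,
                   detect_communities(tri2, seed = 4)$membership)
})

test_that("Louvain Q is stable (spread < 0.02) over 10 seeds and beats trivial Q", {
  # rules-graph with community structure: two rule families over disjoint
  # factor alphabets, the shape real kept rule sets take
  fam <- function(n, facs, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n), function(i) {
      pick <- sample(facs, sample(2:4, 1))
      data.frame(lhs = paste(sort(pick[-1]), collapse = ";"), rhs = pick[1],
                 support = 0.1, confidence = 0.9, lift = 2,
                 stringsAsFactors = FALSE)
    }))
  }
  rules <- unique(rbind(fam(40, paste0("M", 1:7), 23),
                        fam(40, paste0("P", 1:7), 24)))
  class(rules) <- c("rule_set", "data.frame")
  g <- build_rules_graph(rules)
  qs <- vapply(1:10, function(s) detect_communities(g, seed = s)$Q, 0)
  expect_lt(max(qs) - min(qs), 0.02)
  expect_gte(min(qs), 0)   # never worse than the one-module partition
})

test_that("factor contributions normalise closeness within constructs", {
  cat10 <- toy_catalog()
  # single-factor construct: 100%
  g1 <- build_rules_graph(rule_df("Speeding;TireFailure", "Rain"))
  fc <- factor_contributions(g1, cat10)
  expect_equal(fc$contribution_pct[fc$construct == "vehicle"], 100)
  # symmetric graph: two roadway factors with equal closeness get 50/50
  g2 <- build_rules_graph(rule_df(c("SharpCurve;Rain", "NarrowLanes;Rain"),
                                  c("NarrowLanes", "SharpCurve")))
  fc2 <- factor_contributions(g2, cat10)
  rw <- fc2[fc2$construct == "roadway", ]
  expect_equal(rw$contribution_pct, c(50, 50))
  # a factor dominating antecedents ranks first in its construct
  rules <- rule_df(c("Speeding;Rain", "Speeding;NarrowLanes",
                     "Speeding;SharpCurve", "Fatigue;Rain"),
                   c("TireFailure", "TireFailure", "Rain", "TireFailure"))
  fc3 <- factor_contributions(build_rules_graph(rules), cat10)
  dr <- fc3[fc3$construct == "driver", ]
  expect_equal(dr$item[dr$rank == 1], "Speeding")
})

test_that("graph exports are written and GraphML reads back with attributes", {
  rules <- random_rules(10, n_factors = 6, seed = 29)
  g <- build_rules_graph(rules)
  part <- detect_communities(g, seed = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_rules_graphml(g, gml)
  write_rules_gexf(g, gexf, partition = part)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$kind, c("factor", "rule"))
  txt <- readLines(gexf)
  expect_true(any(grepl("<gexf", txt)))
  expect_equal(sum(grepl("<node id=", txt)), igraph::vcount(g))
  expect_equal(sum(grepl("<edge id=", txt)), igraph::ecount(g))
})
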