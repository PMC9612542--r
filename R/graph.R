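#' Build a rules graph structure (RGS)
#'
#' Casts a kept rule set into a directed graph: one node per factor occurring
#' in any rule and one node per rule. Each antecedent factor points into its
#' rule node, and the rule node points to its consequent factor. Structural
#' identities: node count = factors + rules; edge count = sum over rules of
#' (|antecedent| + 1); every rule node has out-degree exactly 1 and in-degree
#' equal to its antecedent size.
#'
#' @param rules a nonempty `rule_set` data frame (typically [kept_rules()]).
#' @return An `igraph` directed graph with vertex attributes `kind`
#'   (`"factor"` or `"rule"`), `label`, and for rule nodes `support`,
#'   `confidence`, `lift`.
#' @export
build_rules_graph <- function(rules) {
  if (is.null(rules) || nrow(rules) == 0) stop("empty rule list")
  lhs_list <- strsplit(rules$lhs, ITEM_SEP, fixed = TRUE)
  factors <- sort(unique(c(unlist(lhs_list), rules$rhs)))
  rule_ids <- sprintf("rule_%04d", seq_len(nrow(rules)))

  edges <- character(0)
  for (i in seq_len(nrow(rules))) {
    edges <- c(edges,
               rbind(lhs_list[[i]], rule_ids[i]),     # antecedent -> rule
               rule_ids[i], rules$rhs[i])             # rule -> consequent
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(factors, rule_ids))
  g <- igraph::add_edges(g, edges)
  nf <- length(factors); nr <- length(rule_ids)
  igraph::V(g)$kind <- c(rep("factor", nf), rep("rule", nr))
  igraph::V(g)$label <- c(factors,
                          paste(rules$lhs, rules$rhs, sep = " => "))
  igraph::V(g)$support <- c(rep(NA_real_, nf), rules$support)
  igraph::V(g)$confidence <- c(rep(NA_real_, nf), rules$confidence)
  igraph::V(g)$lift <- c(rep(NA_real_, nf), rules$lift)
  g
}

#' Factor node names of a rules graph
#' @param graph a rules graph from [build_rules_graph()].
#' @return Character vector of factor-node names.
#' @export
factor_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$kind == "factor"]
}

#' In/out degrees of the factor nodes
#'
#' A factor's in-degree is the number of kept rules with that factor as
#' consequent; its out-degree is the number of kept rules containing it as an
#' antecedent item (RHS and LHS frequency of the factor).
#'
#' @param graph a rules graph from [build_rules_graph()].
#' @return Data frame with columns `item`, `in_degree`, `out_degree`.
#' @export
factor_degrees <- function(graph) {
  f <- factor_nodes(graph)
  data.frame(
    item = f,
    in_degree = as.integer(igraph::degree(graph, v = f, mode = "in")),
    out_degree = as.integer(igraph::degree(graph, v = f, mode = "out")),
    stringsAsFactors = FALSE)
}

#' Closeness centrality on the undirected projection
#'
#' `C(x) = N / sum_y d(y, x)` with N the total node count and the sum over
#' the nodes reachable from x in the undirected projection; for disconnected
#' graphs each node's score is rescaled by the fraction of the graph it
#' reaches, `(r - 1) / (N - 1)` with `r` the size of its component
#' (reachable-set rescaling). Isolated nodes score 0.
#'
#' @param graph an `igraph` graph (directed graphs are projected).
#' @return Named numeric vector of closeness scores.
#' @export
closeness_rgs <- function(graph) {
  gu <- igraph::as_undirected(graph, mode = "collapse")
  n <- igraph::vcount(gu)
  d <- igraph::distances(gu)
  scores <- vapply(seq_len(n), function(i) {
    di <- d[, i]
    reach <- is.finite(di) & seq_len(n) != i
    s <- sum(di[reach])
    if (s == 0) return(0)
    scale <- if (n > 1) sum(reach) / (n - 1) else 1
    (n / s) * scale
  }, 0, USE.NAMES = FALSE)
  stats::setNames(scores, igraph::V(gu)$name)
}

#' PageRank by fixed-point iteration (unnormalised variant)
#'
#' Iterates `PR(v) = (1 - d) + d * sum_u PR(u) / outdeg(u)` over the incoming
#' neighbours `u` of `v`, starting from all-ones, until the max-norm change
#' drops below `tol`. This is the raw recursive formulation: scores need not
#' sum to 1, a node with no incoming edges scores exactly `1 - d`, and
#' dangling nodes simply contribute nothing (their rank is not
#' redistributed). `normalized = TRUE` instead returns the standard
#' probability-distribution PageRank (via [igraph::page_rank()]) for
#' cross-checks.
#'
#' @param graph a directed `igraph` graph.
#' @param d damping factor in (0, 1); default 0.85.
#' @param tol convergence tolerance on the max-norm change.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param normalized return the normalised variant instead.
#' @return Named numeric vector of PageRank scores.
#' @export
pagerank_rgs <- function(graph, d = 0.85, tol = 1e-10, max_iter = 1000L,
                         normalized = FALSE) {
  if (!is.numeric(d) || d <= 0 || d >= 1) stop("damping d must be in (0, 1)")
  if (normalized) {
    pr <- igraph::page_rank(graph, damping = d)$vector
    return(pr)
  }
  n <- igraph::vcount(graph)
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)  # adj[u, v]: u -> v
  outdeg <- igraph::degree(graph, mode = "out")
  w <- adj / pmax(outdeg, 1)   # row-scaled; dangling rows contribute nothing
  pr <- rep(1, n)
  for (it in seq_len(max_iter)) {
    pr_new <- (1 - d) + d * as.numeric(pr %*% w)
    delta <- max(abs(pr_new - pr))
    pr <- pr_new
    if (delta < tol) {
      return(stats::setNames(pr, igraph::V(graph)$name))
    }
  }
  stop(sprintf("PageRank did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

#' Modularity of a partition (Newman Q)
#'
#' `Q = 1/(2m) * sum_vw [A_vw - k_v k_w / (2m)] delta(c_v, c_w)` on the
#' undirected projection, with `m` the undirected edge count and `k_v` the
#' undirected degree. The whole graph in one module gives exactly 0.
#'
#' @param graph an `igraph` graph (directed graphs are projected).
#' @param membership integer/character module assignment covering every node.
#' @return Q in `[-0.5, 1]`.
#' @export
modularity_rgs <- function(graph, membership) {
  gu <- igraph::as_undirected(graph, mode = "collapse")
  if (length(membership) != igraph::vcount(gu) || anyNA(membership)) {
    stop("partition must assign every node to a module")
  }
  igraph::modularity(gu, as.integer(as.factor(membership)))
}

#' Louvain community detection
#'
#' Greedy hierarchical agglomeration (local moving plus graph aggregation
#' until no modularity gain) on the undirected projection, deterministic
#' under a fixed seed.
#'
#' @param graph an `igraph` graph.
#' @param seed RNG seed fixing tie-breaking.
#' @param resolution resolution parameter of the modularity objective
#'   (1 = plain Newman Q).
#' @return An object of class `rgs_partition`: list with `membership` (named
#'   integer vector), `n_modules`, `Q` (modularity of the partition).
#' @export
detect_communities <- function(graph, seed = 1L, resolution = 1) {
  gu <- igraph::as_undirected(graph, mode = "collapse")
  set.seed(seed)
  cl <- igraph::cluster_louvain(gu, resolution = resolution)
  memb <- igraph::membership(cl)
  structure(list(membership = stats::setNames(as.integer(memb),
                                              igraph::V(gu)$name),
                 n_modules = length(unique(memb)),
                 Q = igraph::modularity(gu, memb)),
            class = "rgs_partition")
}

#' @export
print.rgs_partition <- function(x, ...) {
  cat(sprintf("<rgs_partition> %d modules, Q = %.3f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Per-construct factor contributions
#'
#' Ranks the factors of each system-level construct by closeness and reports
#' each factor's share of its construct's total closeness (in percent).
#' Constructs with no factor in the graph are omitted.
#'
#' @param graph a rules graph from [build_rules_graph()].
#' @param catalog a [factor_catalog()] mapping items to constructs.
#' @param closeness optional precomputed [closeness_rgs()] scores.
#' @return Data frame with columns `construct`, `item`, `closeness`,
#'   `contribution_pct`, `rank`, ordered by construct then descending
#'   contribution.
#' @export
factor_contributions <- function(graph, catalog,
                                 closeness = closeness_rgs(graph)) {
  stopifnot(inherits(catalog, "factor_catalog"))
  f <- factor_nodes(graph)
  con_of <- stats::setNames(catalog$construct, catalog$item)
  known <- f[f %in% names(con_of)]
  parts <- lapply(split(known, con_of[known]), function(its) {
    cl <- closeness[its]
    tot <- sum(cl)
    df <- data.frame(item = its, closeness = unname(cl),
                     contribution_pct = if (tot > 0) unname(cl) / tot * 100
                                        else rep(NA_real_, length(its)),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$contribution_pct, df$item), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df
  })
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  out <- do.call(rbind, lapply(names(parts), function(cn) {
    cbind(construct = cn, parts[[cn]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a rules graph as GraphML
#' @param graph a rules graph.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_rules_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Export a rules graph as GEXF (Gephi)
#'
#' Minimal GEXF 1.2 writer carrying the node kind, rule metrics, and an
#' optional module id per node.
#'
#' @param graph a rules graph.
#' @param path output `.gexf` path.
#' @param partition optional `rgs_partition` whose module ids are attached.
#' @return `path`, invisibly.
#' @export
write_rules_gexf <- function(graph, path, partition = NULL) {
  v <- igraph::V(graph)
  memb <- if (!is.null(partition)) partition$membership[v$name] else
    rep(NA_integer_, length(v))
  attval <- function(id, val) {
    ifelse(is.na(val), "",
           sprintf('<attvalue for="%s" value="%s"/>', id, xml_escape(val)))
  }
  nodes <- sprintf(
    '      <node id="%s" label="%s"><attvalues>%s%s%s%s</attvalues></node>',
    xml_escape(v$name), xml_escape(v$label),
    attval("0", v$kind), attval("1", as.character(v$lift)),
    attval("2", as.character(v$support)), attval("3", as.character(memb)))
  el <- igraph::as_edgelist(graph)
  edges <- sprintf('      <edge id="%d" source="%s" target="%s"/>',
                   seq_len(nrow(el)) - 1L, xml_escape(el[, 1]),
                   xml_escape(el[, 2]))
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="directed">',
    '    <attributes class="node">',
    '      <attribute id="0" title="kind" type="string"/>',
    '      <attribute id="1" title="lift" type="double"/>',
    '      <attribute id="2" title="support" type="double"/>',
    '      <attribute id="3" title="module" type="integer"/>',
    '    </attributes>',
    '    <nodes>', nodes, '    </nodes>',
    '    <edges>', edges, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path)
  invisible(path)
}
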