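#' Top rules by a metric
#'
#' Stable descending sort by the chosen key; ties broken by the other two
#' metrics (descending) and finally by the canonical rule label, so output
#' order is deterministic.
#'
#' @param rules a `rule_set` data frame.
#' @param key one of `"lift"`, `"support"`, `"confidence"`.
#' @param n number of rules to return (clamped to the rule count).
#' @return The top-`n` rules as a `rule_set` data frame.
#' @export
top_rules <- function(rules, key = c("lift", "support", "confidence"), n = 15) {
  key <- match.arg(key)
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  others <- setdiff(c("lift", "support", "confidence"), key)
  label <- paste(rules$lhs, rules$rhs, sep = " => ")
  ord <- order(-rules[[key]], -rules[[others[1]]], -rules[[others[2]]], label)
  out <- rules[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Rules with a given consequent
#'
#' For a single item, the kept rules whose consequent is that item. For a
#' pair (typically two mutually exclusive items, e.g. the two severity
#' levels), a named list of the two disjoint subsets.
#'
#' @param rules a `rule_set` data frame.
#' @param rhs one consequent item, or a character vector of two.
#' @return A `rule_set`, or a named list of two for a pair. An item that
#'   never occurs as a consequent yields an empty subset with a warning.
#' @export
subset_by_rhs <- function(rules, rhs) {
  pick <- function(item) {
    if (!item %in% rules$rhs) {
      warning("item never occurs as a consequent: ", item)
    }
    out <- rules[rules$rhs == item, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("rule_set", "data.frame")
    out
  }
  if (length(rhs) == 1) return(pick(rhs))
  if (length(rhs) == 2) {
    return(stats::setNames(lapply(rhs, pick), rhs))
  }
  stop("rhs must be one item or a pair")
}

#' K-means grouping of rule antecedents
#'
#' Clusters the kept rules by their binary antecedent-membership vectors (one
#' dimension per factor appearing in any antecedent; consequents excluded),
#' using standard iterative refinement with a fixed seed. Groups are labelled
#' by their most frequent antecedent items.
#'
#' @param rules a `rule_set` data frame.
#' @param k number of groups (default 20); must not exceed the rule count.
#' @param seed RNG seed for the k-means initialisation.
#' @param n_label how many dominant items to put in each group label.
#' @return An object of class `grouped_antecedents`: list with `assignment`
#'   (integer vector, one group per rule), `k`, `labels` (character, per
#'   group), `sizes`.
#' @export
group_antecedents <- function(rules, k = 20, seed = 1L, n_label = 3L) {
  if (k > nrow(rules)) stop("k exceeds the rule count")
  lhs_list <- strsplit(rules$lhs, ITEM_SEP, fixed = TRUE)
  factors <- sort(unique(unlist(lhs_list)))
  x <- vapply(factors, function(f)
    vapply(lhs_list, function(l) f %in% l, TRUE), logical(nrow(rules)))
  if (nrow(rules) == 1) x <- matrix(x, nrow = 1, dimnames = list(NULL, factors))
  storage.mode(x) <- "double"
  set.seed(seed)
  km <- if (k == nrow(rules)) {
    # degenerate: one singleton group per rule (kmeans needs k < n)
    list(cluster = seq_len(nrow(rules)), size = rep(1L, nrow(rules)))
  } else {
    stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  }
  labels <- vapply(seq_len(k), function(g) {
    freq <- colSums(x[km$cluster == g, , drop = FALSE])
    top <- names(sort(freq[freq > 0], decreasing = TRUE))
    paste(utils::head(top, n_label), collapse = " + ")
  }, "")
  structure(list(assignment = km$cluster, k = as.integer(k),
                 labels = labels, sizes = as.integer(km$size)),
            class = "grouped_antecedents")
}

#' @export
print.grouped_antecedents <- function(x, ...) {
  cat(sprintf("<grouped_antecedents> %d groups over %d rules\n",
              x$k, length(x$assignment)))
  invisible(x)
}

#' Distribution summary of rule metrics
#'
#' The headline fractions used to characterise a kept rule set: share of
#' rules with support in the 6-10% band (inclusive), with confidence above
#' 80%, and with lift above 2 (strong association), plus the observed lift
#' range.
#'
#' @param rules a nonempty `rule_set` data frame.
#' @return List with `n_rules`, `frac_support_6_10`, `frac_confidence_gt_80`,
#'   `frac_lift_gt_2`, `min_lift`, `max_lift`.
#' @export
rule_value_distribution <- function(rules) {
  if (!nrow(rules)) stop("empty rule set")
  list(n_rules = nrow(rules),
       frac_support_6_10 = mean(rules$support >= 0.06 & rules$support <= 0.10),
       frac_confidence_gt_80 = mean(rules$confidence > 0.80),
       frac_lift_gt_2 = mean(rules$lift > 2),
       min_lift = min(rules$lift),
       max_lift = max(rules$lift))
}

#' Construct-combination profile (Venn cells)
#'
#' For every nonempty subset of the four contributing-factor constructs
#' (driver, vehicle, roadway, environment), the fraction of records whose
#' true items span exactly that subset. Cells are disjoint; their sum over
#' records with at least one construct item is at most 1, the remainder being
#' records with no contributing-factor item.
#'
#' @param table a [transaction_table()].
#' @param catalog a [factor_catalog()]; defaults to the table's.
#' @return Data frame with columns `combination` (items `"+"`-joined, e.g.
#'   `"driver+vehicle"`), `n_constructs`, `fraction`, ordered by subset size
#'   then label; only nonempty cells unless `drop_empty = FALSE`.
#' @param drop_empty drop zero-fraction cells (default `TRUE`).
#' @export
combination_profile <- function(table, catalog = table$catalog,
                                drop_empty = TRUE) {
  prof <- construct_profile(table, catalog)
  keys <- vapply(prof, function(p) paste(sort(p), collapse = "+"), "")
  n <- length(keys)
  constructs <- c("driver", "vehicle", "roadway", "environment")
  subsets <- unlist(lapply(seq_along(constructs), function(k) {
    apply(utils::combn(sort(constructs), k), 2, paste, collapse = "+")
  }))
  frac <- vapply(subsets, function(s) sum(keys == s) / n, 0)
  out <- data.frame(combination = subsets,
                    n_constructs = lengths(strsplit(subsets, "+", fixed = TRUE)),
                    fraction = unname(frac), stringsAsFactors = FALSE)
  out <- out[order(out$n_constructs, out$combination), , drop = FALSE]
  if (drop_empty) out <- out[out$fraction > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full crash-rules pipeline
#'
#' Encode (or take) a transaction table, mine candidate rules, apply the
#' three-stage filter, build the rules graph, detect communities, and
#' assemble the reports. Per-stage counts are logged to stderr; with a fixed
#' seed every artifact is reproducible byte for byte.
#'
#' @param input a [transaction_table()], a CSV path (loaded via
#'   [load_crash_table()]), or a [generator_config()] (simulated via
#'   [generate_with_planted_rules()]).
#' @param catalog optional [factor_catalog()].
#' @param mining a [mining_config()].
#' @param filtering a [filter_config()].
#' @param seed RNG seed for community detection and grouping.
#' @param k_groups antecedent k-means group count; skipped (with `NULL`
#'   grouping) when fewer kept rules than groups.
#' @param out_dir if non-`NULL`, artifacts are written there: `rules.csv`
#'   (kept rules), `filter_report.csv`, `rules_graph.graphml`,
#'   `rules_graph.gexf`, `partition.csv`, `report.json`.
#' @param quiet suppress stage logging.
#' @return List with `table`, `candidates`, `filtered`, `kept`, `graph`,
#'   `partition`, `degrees`, `closeness`, `pagerank`, `contributions`,
#'   `distribution`, `grouping`, `profile`.
#' @export
run_pipeline <- function(input, catalog = NULL,
                         mining = mining_config(),
                         filtering = filter_config(),
                         seed = 1L, k_groups = 20L,
                         out_dir = NULL, quiet = FALSE) {
  table <- if (inherits(input, "transaction_table")) {
    input
  } else if (inherits(input, "generator_config")) {
    if (length(input$planted)) generate_with_planted_rules(input)
    else generate_independent(input)
  } else if (is.character(input)) {
    load_crash_table(input, catalog = catalog)
  } else {
    stop("run_pipeline: unsupported input")
  }
  if (!is.null(catalog)) table$catalog <- catalog
  log_stage(quiet, "[encode] %d records x %d items", n_records(table),
            length(items(table)))

  candidates <- mine_rules(table, mining)
  log_stage(quiet, "[mine] %d candidate rules (S>=%.3g, C>=%.3g, L>%.3g)",
            nrow(candidates), mining$min_support, mining$min_confidence,
            mining$min_lift)
  if (!nrow(candidates)) {
    log_stage(quiet, "[filter] no candidates; empty rule set")
    return(list(table = table, candidates = candidates,
                filtered = candidates, kept = candidates, graph = NULL,
                partition = NULL, degrees = NULL, closeness = NULL,
                pagerank = NULL, contributions = NULL, distribution = NULL,
                grouping = NULL,
                profile = if (!is.null(table$catalog))
                  combination_profile(table) else NULL))
  }

  filtered <- filter_rules(candidates, table, config = filtering,
                           catalog = table$catalog)
  kept <- kept_rules(filtered)
  log_stage(quiet, "[filter] %d kept / %d candidates (lic %d, significance %d, meaningfulness %d rejected)",
            nrow(kept), nrow(filtered),
            sum(filtered$rejection_reason == "lic"),
            sum(filtered$rejection_reason == "significance"),
            sum(filtered$rejection_reason == "meaningfulness"))

  graph <- partition <- degrees <- cl <- pr <- contrib <- dist <- grouping <- NULL
  if (nrow(kept)) {
    graph <- build_rules_graph(kept)
    partition <- detect_communities(graph, seed = seed)
    degrees <- factor_degrees(graph)
    cl <- closeness_rgs(graph)
    pr <- pagerank_rgs(graph)
    contrib <- if (!is.null(table$catalog))
      factor_contributions(graph, table$catalog, closeness = cl) else NULL
    dist <- rule_value_distribution(kept)
    if (!is.null(k_groups) && k_groups <= nrow(kept)) {
      grouping <- group_antecedents(kept, k = k_groups, seed = seed)
    }
    log_stage(quiet, "[graph] %d nodes (%d factors), %d edges; %d modules, Q = %.3f",
              igraph::vcount(graph), length(factor_nodes(graph)),
              igraph::ecount(graph), partition$n_modules, partition$Q)
  }
  profile <- if (!is.null(table$catalog)) combination_profile(table) else NULL

  res <- list(table = table, candidates = candidates, filtered = filtered,
              kept = kept, graph = graph, partition = partition,
              degrees = degrees, closeness = cl, pagerank = pr,
              contributions = contrib, distribution = dist,
              grouping = grouping, profile = profile)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_rules(res$kept, file.path(out_dir, "rules.csv"))
  write_filter_report(res$filtered, file.path(out_dir, "filter_report.csv"))
  if (!is.null(res$graph)) {
    write_rules_graphml(res$graph, file.path(out_dir, "rules_graph.graphml"))
    write_rules_gexf(res$graph, file.path(out_dir, "rules_graph.gexf"),
                     partition = res$partition)
    utils::write.csv(
      data.frame(node = names(res$partition$membership),
                 module = unname(res$partition$membership)),
      file.path(out_dir, "partition.csv"), row.names = FALSE)
  }
  report <- list(
    n_records = n_records(res$table),
    n_candidates = nrow(res$candidates),
    n_kept = nrow(res$kept),
    distribution = res$distribution,
    modularity_Q = if (!is.null(res$partition)) res$partition$Q else NULL,
    n_modules = if (!is.null(res$partition)) res$partition$n_modules else NULL,
    combination_profile = res$profile)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
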