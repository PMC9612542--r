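#' Filter configuration
#'
#' Settings for the three-stage redundancy/validity screen applied after
#' mining: lift-increase (LIC) pruning against base rules, one-sided Fisher
#' significance with multiple-testing correction, and a declarative
#' meaningfulness blacklist.
#'
#' @param min_lic minimum lift-increase ratio an extended rule must achieve
#'   over its base rules (default 1.03).
#' @param alpha significance level before correction (default 0.01).
#' @param correction `"bonferroni"` (p compared to `alpha / m` with `m` the
#'   number of rules entering the stage), `"BH"` (Benjamini-Hochberg via
#'   [stats::p.adjust()], kept if adjusted p < alpha), or `"none"`.
#' @param blacklist list of meaningfulness exclusions; see
#'   [default_blacklist()].
#' @param lic_mode `"all"` requires the LIC bound against every immediate
#'   base rule; `"any"` against at least one.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_lic = 1.03, alpha = 0.01,
                          correction = c("bonferroni", "BH", "none"),
                          blacklist = default_blacklist(),
                          lic_mode = c("all", "any")) {
  if (!is.numeric(min_lic) || min_lic <= 0) stop("min_lic must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  structure(list(min_lic = min_lic, alpha = alpha,
                 correction = match.arg(correction),
                 blacklist = blacklist, lic_mode = match.arg(lic_mode)),
            class = "filter_config")
}

#' Lift-increase (LIC) of an extended rule over its base rule
#'
#' `LIC(X[n+1] -> Y) = Lift(X[n+1] -> Y) / Lift(X[n] -> Y)` for a base rule
#' whose antecedent is the extended antecedent minus exactly one item, with
#' the same consequent. An extension that fails to increase lift (LIC below
#' the threshold) adds no interest over the simpler rule and is redundant.
#'
#' @param extended,base rules: lists or one-row data frames with elements
#'   `lhs` (character vector or `";"`-joined key), `rhs`, `lift`.
#' @return The lift ratio (a single number).
#' @examples
#' lic(list(lhs = c("A", "B", "C"), rhs = "Y", lift = 1.76),
#'     list(lhs = c("A", "B"), rhs = "Y", lift = 1.40))  # 1.257...
#' @export
lic <- function(extended, base) {
  ex <- as_rule(extended); ba <- as_rule(base)
  if (!identical(ex$rhs, ba$rhs)) stop("LIC requires the same consequent")
  if (length(ex$lhs) != length(ba$lhs) + 1 || !all(ba$lhs %in% ex$lhs)) {
    stop("base antecedent must be the extended antecedent minus one item")
  }
  if (!is.finite(ba$lift) || ba$lift <= 0) stop("zero base lift")
  ex$lift / ba$lift
}

as_rule <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  lhs <- x$lhs
  if (length(lhs) == 1 && grepl(ITEM_SEP, lhs, fixed = TRUE)) {
    lhs <- split_items(lhs)
  }
  list(lhs = as.character(lhs), rhs = as.character(x$rhs),
       lift = as.numeric(x$lift))
}

# lift of lhs -> rhs, preferring the candidate lookup, else recomputed from
# the table (base rules need not themselves pass the mining thresholds)
base_lift <- function(lookup, table, lhs, rhs) {
  key <- paste(itemset_key(lhs), rhs, sep = " => ")
  if (!is.null(lookup[[key]])) return(lookup[[key]])
  unname(rule_metrics(table, lhs, rhs)["lift"])
}

#' LIC redundancy filter
#'
#' A rule with two or more antecedent items is kept only if its lift-increase
#' against its immediate base rules (same consequent, one antecedent item
#' removed) meets `min_lic`; single-antecedent rules pass vacuously. Base
#' lifts are taken from the candidate set when present and recomputed from
#' the table otherwise.
#'
#' @param rules a `rule_set` data frame.
#' @param table the [transaction_table()] the rules were mined from.
#' @param min_lic minimum lift-increase ratio.
#' @param mode `"all"` (default) or `"any"` base rule must satisfy the bound.
#' @return The rule data frame with added columns `lic` (the minimum LIC over
#'   base rules; `NA` for single-antecedent rules), `kept`,
#'   `rejection_reason` (`"lic"` or `"none"`).
#' @export
lic_filter <- function(rules, table, min_lic = 1.03,
                       mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "transaction_table"))
  lookup <- as.list(stats::setNames(
    rules$lift, paste(rules$lhs, rules$rhs, sep = " => ")))
  n <- nrow(rules)
  lic_v <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    lhs <- split_items(rules$lhs[i])
    if (length(lhs) < 2) next
    ratios <- vapply(seq_along(lhs), function(j) {
      rules$lift[i] / base_lift(lookup, table, lhs[-j], rules$rhs[i])
    }, 0)
    lic_v[i] <- min(ratios)
    keep[i] <- if (mode == "all") all(ratios >= min_lic) else any(ratios >= min_lic)
  }
  out <- rules
  out$lic <- lic_v
  out$kept <- keep
  out$rejection_reason <- ifelse(keep, "none", "lic")
  out
}

#' One-sided Fisher's exact p-value for a rule
#'
#' Tests the null of no association between antecedent and consequent against
#' the positive-association alternative (the direction implied by screening
#' on lift > 1). The p-value is the upper hypergeometric tail of the
#' co-occurrence count with the 2x2 margins fixed. Degenerate margins (an
#' empty row or column) give p = 1 by convention.
#'
#' @param table a [transaction_table()].
#' @param lhs antecedent items (character vector or `";"`-joined key).
#' @param rhs consequent item.
#' @return p-value in `(0, 1]`.
#' @export
fisher_p <- function(table, lhs, rhs) {
  stopifnot(inherits(table, "transaction_table"))
  if (length(lhs) == 1 && grepl(ITEM_SEP, lhs, fixed = TRUE)) {
    lhs <- split_items(lhs)
  }
  m <- table$matrix
  x <- rowSums(m[, lhs, drop = FALSE]) == length(lhs)
  y <- m[, rhs]
  fisher_p_counts(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
}

#' One-sided Fisher's exact p-value from 2x2 counts
#'
#' @param a,b,c,d counts of (X and Y), (X and not Y), (not X and Y),
#'   (not X and not Y).
#' @return Upper-tail hypergeometric probability `P(count >= a)` with the
#'   margins fixed; 1 for degenerate margins.
#' @export
fisher_p_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_x <- a + b      # margin: records with X
  n_y <- a + c      # margin: records with Y
  n <- a + b + c + d
  if (n_x == 0 || n_y == 0 || n_x == n || n_y == n) return(1)
  stats::phyper(a - 1, n_y, n - n_y, n_x, lower.tail = FALSE)
}

#' Significance filter with multiple-testing correction
#'
#' Computes Fisher p-values for the rules still kept, and under Bonferroni
#' keeps a rule only if `p < alpha / m`, where `m` is the number of rules
#' entering this stage (the post-LIC survivors).
#'
#' @param filtered rule data frame with `kept`/`rejection_reason` columns
#'   (output of [lic_filter()]); rules already rejected pass through
#'   untouched.
#' @param table the [transaction_table()].
#' @param alpha significance level.
#' @param correction `"bonferroni"`, `"BH"`, or `"none"`.
#' @return The data frame with a `p_value` column and updated
#'   `kept`/`rejection_reason` (`"significance"` for the newly rejected).
#' @export
significance_filter <- function(filtered, table, alpha = 0.01,
                                correction = "bonferroni") {
  stopifnot(inherits(table, "transaction_table"))
  enter <- which(filtered$kept)
  m_tests <- length(enter)
  if (m_tests == 0) stop("no rules enter the significance stage")
  p <- rep(NA_real_, nrow(filtered))
  p[enter] <- vapply(enter, function(i) {
    fisher_p(table, filtered$lhs[i], filtered$rhs[i])
  }, 0)
  sig <- switch(correction,
    bonferroni = p[enter] < alpha / m_tests,
    BH = stats::p.adjust(p[enter], method = "BH") < alpha,
    none = p[enter] < alpha,
    stop("unknown correction: ", correction))
  out <- filtered
  out$p_value <- p
  rej <- enter[!sig]
  out$kept[rej] <- FALSE
  out$rejection_reason[rej] <- "significance"
  out
}

#' Default meaningfulness blacklist
#'
#' Category-level exclusions for rules that are true by construction rather
#' than informative: time of day determines light condition, and posted speed
#' limit and road category determine each other administratively. Both
#' directions of both pairs are excluded.
#'
#' @return List of entries with elements `lhs` and `rhs`, each a category
#'   name or an item label.
#' @export
default_blacklist <- function() {
  list(list(lhs = "Time", rhs = "Light"),
       list(lhs = "Light", rhs = "Time"),
       list(lhs = "Limit speed", rhs = "Road category"),
       list(lhs = "Road category", rhs = "Limit speed"))
}

#' Read a meaningfulness blacklist from YAML
#' @param path YAML file: a list of mappings with keys `lhs` and `rhs`.
#' @return Blacklist list as used by [meaningfulness_filter()].
#' @export
read_blacklist <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(e) list(lhs = as.character(e$lhs),
                               rhs = as.character(e$rhs)))
}

matches_side <- function(items_v, pattern, catalog) {
  # TRUE for each item that equals the pattern or whose category equals it
  hit <- items_v == pattern
  if (!is.null(catalog)) {
    cat_of <- stats::setNames(catalog$category, catalog$item)
    known <- items_v %in% names(cat_of)
    hit[known] <- hit[known] | cat_of[items_v[known]] == pattern
  }
  hit
}

#' Meaningfulness filter
#'
#' Rejects rules whose antecedent-consequent pairing matches a blacklist
#' entry. An entry matches when every antecedent item equals the entry's
#' `lhs` (an item label or a catalog category) and the consequent matches its
#' `rhs`: such rules restate a deterministic relationship between the two
#' sides and carry no safety information.
#'
#' @param filtered rule data frame with `kept`/`rejection_reason` columns.
#' @param blacklist list of `lhs`/`rhs` entries; see [default_blacklist()].
#' @param catalog optional [factor_catalog()] enabling category-level
#'   matching (without it only exact item labels match).
#' @return The data frame with updated `kept`/`rejection_reason`
#'   (`"meaningfulness"` for the newly rejected).
#' @export
meaningfulness_filter <- function(filtered, blacklist = default_blacklist(),
                                  catalog = NULL) {
  if (!length(blacklist)) return(filtered)
  out <- filtered
  for (i in which(out$kept)) {
    lhs <- split_items(out$lhs[i])
    for (e in blacklist) {
      if (all(matches_side(lhs, e$lhs, catalog)) &&
          matches_side(out$rhs[i], e$rhs, catalog)) {
        out$kept[i] <- FALSE
        out$rejection_reason[i] <- "meaningfulness"
        break
      }
    }
  }
  out
}

#' Full three-stage rule filter
#'
#' Order-faithful screen: LIC redundancy pruning, then one-sided Fisher
#' significance with correction, then the meaningfulness blacklist. Each
#' stage only removes rules.
#'
#' @param rules a `rule_set` data frame (mined candidates).
#' @param table the [transaction_table()] they were mined from.
#' @param config a [filter_config()].
#' @param catalog optional [factor_catalog()] for category-level blacklist
#'   matching; defaults to the table's.
#' @return Rule data frame with columns `lic`, `p_value`, `kept`,
#'   `rejection_reason` covering every candidate.
#' @export
filter_rules <- function(rules, table, config = filter_config(),
                         catalog = table$catalog) {
  stopifnot(inherits(config, "filter_config"))
  out <- lic_filter(rules, table, min_lic = config$min_lic,
                    mode = config$lic_mode)
  out <- significance_filter(out, table, alpha = config$alpha,
                             correction = config$correction)
  meaningfulness_filter(out, blacklist = config$blacklist, catalog = catalog)
}

#' Kept rules of a filter report
#' @param filtered output of [filter_rules()].
#' @return The kept subset as a `rule_set` data frame.
#' @export
kept_rules <- function(filtered) {
  out <- filtered[filtered$kept, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Write a filter report as CSV
#' @param filtered output of [filter_rules()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(filtered, path) {
  utils::write.csv(as.data.frame(filtered), path, row.names = FALSE)
  invisible(path)
}
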