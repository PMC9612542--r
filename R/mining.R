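#' Mining configuration
#'
#' Thresholds for rule extraction: minimum support and confidence are
#' inclusive (`>=`), minimum lift is strict (`>`), and antecedents carry at
#' most `max_lhs_size` items. Defaults are the calibrated operating point for
#' severe-crash tables: S >= 6%, C >= 75%, L > 1.3, antecedents of up to three
#' items.
#'
#' @param min_support minimum rule support (fraction).
#' @param min_confidence minimum rule confidence (fraction).
#' @param min_lift strict lower bound on lift.
#' @param max_lhs_size maximum number of antecedent items (>= 1).
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.06, min_confidence = 0.75,
                          min_lift = 1.3, max_lhs_size = 3) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must be in [0, 1]")
  }
  if (!is.numeric(min_lift) || min_lift < 0) stop("min_lift must be >= 0")
  if (max_lhs_size < 1) stop("max_lhs_size must be >= 1")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, max_lhs_size = as.integer(max_lhs_size)),
            class = "mining_config")
}

ITEM_SEP <- ";"

itemset_key <- function(its) paste(sort(its), collapse = ITEM_SEP)

split_items <- function(key) {
  if (!nzchar(key)) character() else strsplit(key, ITEM_SEP, fixed = TRUE)[[1]]
}

#' Frequent itemsets by level-wise (Apriori) search
#'
#' Bottom-up enumeration exploiting downward closure of support: a size-k
#' candidate is counted only if all of its (k-1)-subsets are frequent.
#' Returns exactly the itemsets of size `<= max_size` with support
#' `>= min_support`, in canonical order (by size, then lexicographically on
#' the `";"`-joined sorted item labels).
#'
#' @param table a [transaction_table()].
#' @param min_support minimum support fraction, in `(0, 1]`.
#' @param max_size largest itemset size to enumerate.
#' @return Data frame with columns `items` (canonical `";"`-joined key),
#'   `size`, `support`.
#' @export
frequent_itemsets <- function(table, min_support, max_size = 4L) {
  stopifnot(inherits(table, "transaction_table"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  m <- table$matrix
  if (nrow(m) == 0) stop("empty table")
  m <- m[, order(colnames(m)), drop = FALSE]  # canonical item order
  n <- nrow(m)
  labels <- colnames(m)

  supp1 <- colMeans(m)
  keep1 <- which(supp1 >= min_support)
  out <- list()
  if (length(keep1)) {
    out[[1]] <- data.frame(items = labels[keep1], size = 1L,
                           support = unname(supp1[keep1]),
                           stringsAsFactors = FALSE)
  }

  # per-frequent-itemset row masks, itemsets as sorted integer index vectors
  sets <- lapply(keep1, identity)
  masks <- lapply(keep1, function(j) m[, j])
  k <- 2L
  while (length(sets) >= 2 && k <= max_size) {
    freq_keys <- vapply(sets, paste, "", collapse = ",")
    new_sets <- list(); new_masks <- list(); new_supp <- numeric()
    prefixes <- vapply(sets, function(s) paste(s[-length(s)], collapse = ","), "")
    for (pref in unique(prefixes)) {
      grp <- which(prefixes == pref)
      if (length(grp) < 2) next
      lasts <- vapply(sets[grp], function(s) s[length(s)], 0L)
      o <- order(lasts)
      grp <- grp[o]; lasts <- lasts[o]
      for (a in seq_len(length(grp) - 1)) {
        for (b in seq((a + 1), length(grp))) {
          cand <- c(sets[[grp[a]]], lasts[b])
          # downward-closure prune: all (k-1)-subsets frequent
          if (k > 2) {
            ok <- all(vapply(seq_len(k), function(drop_i) {
              paste(cand[-drop_i], collapse = ",") %in% freq_keys
            }, TRUE))
            if (!ok) next
          }
          mask <- masks[[grp[a]]] & m[, lasts[b]]
          s <- sum(mask) / n
          if (s >= min_support) {
            new_sets[[length(new_sets) + 1L]] <- cand
            new_masks[[length(new_masks) + 1L]] <- mask
            new_supp <- c(new_supp, s)
          }
        }
      }
    }
    if (length(new_sets)) {
      keys <- vapply(new_sets, function(s) itemset_key(labels[s]), "")
      df <- data.frame(items = keys, size = k, support = new_supp,
                       stringsAsFactors = FALSE)
      out[[k]] <- df[order(df$items), , drop = FALSE]
    }
    sets <- new_sets; masks <- new_masks
    k <- k + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(items = character(), size = integer(), support = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Support, confidence and lift of a single rule
#'
#' Exact count-based metrics over the transaction table:
#' `Supp = #(X u Y)/N`, `Conf = Supp(X u Y)/Supp(X)`,
#' `Lift = Conf/Supp(Y)`.
#'
#' @param table a [transaction_table()].
#' @param lhs character vector of antecedent items (nonempty).
#' @param rhs single consequent item, not in `lhs`.
#' @return Named numeric vector `c(support, confidence, lift)`.
#' @export
rule_metrics <- function(table, lhs, rhs) {
  stopifnot(inherits(table, "transaction_table"))
  lhs <- as.character(lhs); rhs <- as.character(rhs)
  if (!length(lhs)) stop("empty antecedent")
  if (length(rhs) != 1 || rhs %in% lhs) stop("rhs must be one item not in lhs")
  s_lhs <- marginal_support(table, lhs)
  if (s_lhs == 0) stop("zero-support antecedent: confidence undefined")
  s_rhs <- marginal_support(table, rhs)
  s_rule <- marginal_support(table, c(lhs, rhs))
  conf <- s_rule / s_lhs
  lift <- if (s_rhs == 0) {
    if (conf > 0) stop("zero-support consequent: lift undefined") else 0
  } else {
    conf / s_rhs
  }
  c(support = s_rule, confidence = conf, lift = lift)
}

#' Generate association rules from frequent itemsets
#'
#' Emits every rule `X -> Y` with `X u {Y}` frequent, a single-item
#' consequent, `|X| <= max_lhs_size`, confidence `>= min_confidence` and lift
#' strictly `> min_lift`. Output is in canonical order (antecedent size, then
#' lexicographic on the rule label), so repeated runs are byte-identical.
#'
#' @param frequents result of [frequent_itemsets()] computed at
#'   `config$min_support`.
#' @param table the [transaction_table()] the frequents came from.
#' @param config a [mining_config()].
#' @return A rule data frame (class `rule_set`) with columns `lhs`
#'   (`";"`-joined sorted items), `rhs`, `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(frequents, table, config = mining_config()) {
  stopifnot(inherits(table, "transaction_table"),
            inherits(config, "mining_config"))
  supp <- stats::setNames(frequents$support, frequents$items)
  marg <- colMeans(table$matrix)
  rows <- list()
  big <- frequents[frequents$size >= 2 &
                   frequents$size <= config$max_lhs_size + 1L, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    its <- split_items(big$items[i])
    s_rule <- big$support[i]
    for (y in its) {
      lhs <- setdiff(its, y)
      s_lhs <- supp[[itemset_key(lhs)]]  # frequent by downward closure
      conf <- s_rule / s_lhs
      if (conf < config$min_confidence) next
      lift <- conf / marg[[y]]
      if (!(lift > config$min_lift)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lhs = itemset_key(lhs), rhs = y, support = s_rule,
        confidence = conf, lift = lift, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty_rule_set()
  res <- res[order(nchar_size(res$lhs), res$lhs, res$rhs), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("rule_set", "data.frame")
  res
}

nchar_size <- function(lhs_keys) {
  vapply(lhs_keys, function(k) length(split_items(k)), 0L)
}

empty_rule_set <- function() {
  structure(data.frame(lhs = character(), rhs = character(),
                       support = numeric(), confidence = numeric(),
                       lift = numeric(), stringsAsFactors = FALSE),
            class = c("rule_set", "data.frame"))
}

#' Mine association rules in one call
#'
#' Convenience wrapper: [frequent_itemsets()] at `config$min_support` and
#' sizes up to `config$max_lhs_size + 1`, then [generate_rules()].
#'
#' @param table a [transaction_table()].
#' @param config a [mining_config()].
#' @return A `rule_set` data frame.
#' @export
mine_rules <- function(table, config = mining_config()) {
  fi <- frequent_itemsets(table, config$min_support,
                          max_size = config$max_lhs_size + 1L)
  generate_rules(fi, table, config)
}

#' Rule counts and lift ranges over a threshold grid
#'
#' Reproduces the trial-and-error threshold calibration: for every
#' `(min_support, min_confidence)` grid point, the number of rules passing all
#' thresholds and the range of their lifts. Mining is done once at the loosest
#' grid point; per-point counts are exact recounts by threshold.
#'
#' @param table a [transaction_table()].
#' @param min_supports numeric vector of support thresholds.
#' @param min_confidences numeric vector of confidence thresholds.
#' @param min_lift strict lift bound applied at every grid point.
#' @param max_lhs_size maximum antecedent size.
#' @return Data frame with columns `min_support`, `min_confidence`,
#'   `n_rules`, `min_lift_observed`, `max_lift_observed`.
#' @export
threshold_sweep <- function(table, min_supports, min_confidences,
                            min_lift = 1.3, max_lhs_size = 3) {
  stopifnot(all(min_supports > 0), all(min_supports <= 1),
            all(min_confidences >= 0), all(min_confidences <= 1))
  base <- mining_config(min_support = min(min_supports),
                        min_confidence = min(min_confidences),
                        min_lift = 0, max_lhs_size = max_lhs_size)
  all_rules <- mine_rules(table, base)
  grid <- expand.grid(min_support = min_supports,
                      min_confidence = min_confidences,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- all_rules$support >= grid$min_support[i] &
      all_rules$confidence >= grid$min_confidence[i] &
      all_rules$lift > min_lift
    lifts <- all_rules$lift[sel]
    data.frame(min_support = grid$min_support[i],
               min_confidence = grid$min_confidence[i],
               n_rules = sum(sel),
               min_lift_observed = if (length(lifts)) min(lifts) else NA_real_,
               max_lift_observed = if (length(lifts)) max(lifts) else NA_real_)
  })
  do.call(rbind, res)
}

#' Write a rule set as CSV
#'
#' Dialect: columns `lhs` (items `";"`-joined), `rhs`, `support`,
#' `confidence`, `lift` -- the same shape as deposited supplementary rule
#' files, so those can be read back with [read_rules()].
#'
#' @param rules a `rule_set` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(as.data.frame(rules)[, c("lhs", "rhs", "support",
                                            "confidence", "lift")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a rule-set CSV
#' @param path CSV with columns `lhs`, `rhs`, `support`, `confidence`, `lift`
#'   (extra columns are kept). Percent-scaled support/confidence (values
#'   above 1) are converted to fractions.
#' @return A `rule_set` data frame with canonicalised `lhs` keys.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("lhs", "rhs", "support", "confidence", "lift")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("rules file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$lhs <- vapply(strsplit(df$lhs, ITEM_SEP, fixed = TRUE),
                   function(x) itemset_key(trimws(x)), "")
  df$rhs <- trimws(df$rhs)
  for (cc in c("support", "confidence")) {
    if (any(df[[cc]] > 1, na.rm = TRUE)) df[[cc]] <- df[[cc]] / 100
  }
  class(df) <- c("rule_set", "data.frame")
  df
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rule(s)\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}
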