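# Shared fixtures and independent oracles.

# transaction table straight from a 0/1 matrix with named columns
tt <- function(...) {
  transaction_table(cbind(...))
}

# 10-record toy: X true in rows 1-4, Y true in rows 3-7
toy_xy <- function() {
  tt(X = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
     Y = c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0))
}

# 10-record toy: A in 6 records, B in 5, A&B in 4
toy_ab <- function() {
  tt(A = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
     B = c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0))
}

# random boolean table for property tests
random_table <- function(n, m, p = 0.4) {
  x <- matrix(runif(n * m) < p, n, m,
              dimnames = list(NULL, LETTERS[seq_len(m)]))
  transaction_table(x)
}

# Oracle: exhaustive frequent-itemset enumeration over all item subsets.
# Independent of the miner: no level-wise search, no pruning.
oracle_frequent <- function(table, min_support, max_size) {
  m <- table$matrix
  its <- sort(colnames(m))
  out <- list()
  for (k in seq_len(min(max_size, length(its)))) {
    sets <- utils::combn(its, k, simplify = FALSE)
    for (s in sets) {
      supp <- mean(rowSums(m[, s, drop = FALSE]) == k)
      if (supp >= min_support) {
        out[[length(out) + 1L]] <- data.frame(
          items = paste(s, collapse = ";"), size = k, support = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(items = character(), size = integer(), support = numeric())
  res[order(res$size, res$items), , drop = FALSE]
}

# Oracle: one-sided Fisher p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing hypergeometric point masses of tables at
# least as positively associated (a' >= a). Pure combinatorics via choose().
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  n_x <- a + b
  n_y <- a + c
  if (n_x == 0 || n_y == 0 || n_x == n || n_y == n) return(1)
  a_vals <- max(0, n_x + n_y - n):min(n_x, n_y)
  probs <- vapply(a_vals, function(ai) {
    choose(n_y, ai) * choose(n - n_y, n_x - ai) / choose(n, n_x)
  }, 0)
  sum(probs[a_vals >= a])
}

# tiny kept-rule-set builder for graph/report tests
rule_df <- function(lhs, rhs, support = 0.1, confidence = 0.8, lift = 2) {
  df <- if (!length(lhs)) {
    data.frame(lhs = character(), rhs = character(), support = numeric(),
               confidence = numeric(), lift = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(lhs = lhs, rhs = rhs, support = support,
               confidence = confidence, lift = lift,
               stringsAsFactors = FALSE)
  }
  class(df) <- c("rule_set", "data.frame")
  df
}

# random rule set over a small factor alphabet (for structural invariants)
random_rules <- function(n_rules, n_factors = 8, seed = 1) {
  set.seed(seed)
  facs <- paste0("F", seq_len(n_factors))
  rows <- lapply(seq_len(n_rules), function(i) {
    k <- sample(1:3, 1)
    pick <- sample(facs, k + 1)
    data.frame(lhs = paste(sort(pick[-1]), collapse = ";"), rhs = pick[1],
               support = runif(1, 0.05, 0.3), confidence = runif(1, 0.7, 1),
               lift = runif(1, 1.3, 5), stringsAsFactors = FALSE)
  })
  df <- unique(do.call(rbind, rows))
  class(df) <- c("rule_set", "data.frame")
  df
}

# minimal catalog over uppercase letter items, split across constructs
toy_catalog <- function() {
  factor_catalog(
    items = c("Speeding", "Fatigue", "TireFailure", "Overload",
              "SharpCurve", "NarrowLanes", "Rain", "NightNoLight",
              "TimeEarly", "Daylight"),
    category = c("Violation", "Driver condition", "Vehicle condition",
                 "Violation", "Segment", "Lanes", "Environment", "Light",
                 "Time", "Light"),
    construct = c("driver", "driver", "vehicle", "vehicle",
                  "roadway", "roadway", "environment", "environment",
                  "context", "environment"),
    exclusive_groups = list(light = c("NightNoLight", "Daylight")))
}
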